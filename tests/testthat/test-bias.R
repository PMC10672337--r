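fake_profiles <- function(x, y, gc3 = NULL, gc12 = NULL, gc3s = NULL, enc = NULL) {
  n <- length(x)
  tibble::tibble(
    genome_id = "g", locus_id = sprintf("L%03d", seq_len(n)),
    pr2_x = x, pr2_y = y,
    gc3 = if (is.null(gc3)) rep(0.3, n) else gc3,
    gc12 = if (is.null(gc12)) rep(0.3, n) else gc12,
    gc3s = if (is.null(gc3s)) rep(0.3, n) else gc3s,
    enc = if (is.null(enc)) rep(45, n) else enc)
}

test_that("PR2 summary assigns quadrants with the half-open boundary rule", {
  # all points in the G/A-rich quadrant with a degenerate ellipse
  s <- pr2_summary(fake_profiles(rep(0.6, 5), rep(0.6, 5)), "all-q1")
  expect_equal(unname(s$quadrant_counts), c(5L, 0L, 0L, 0L))
  expect_equal(unname(s$ellipse$axes), c(0, 0))
  expect_equal(unname(s$mean), c(0.6, 0.6))

  # one point per open quadrant
  s2 <- pr2_summary(fake_profiles(c(0.6, 0.4, 0.4, 0.6), c(0.6, 0.6, 0.4, 0.4)),
                    "cross")
  expect_equal(unname(s2$quadrant_counts), c(1L, 1L, 1L, 1L))

  # boundary points go upper/right; NA coordinates are excluded and counted
  s3 <- pr2_summary(fake_profiles(c(0.5, 0.5, 0.2, NA), c(0.5, 0.2, 0.5, 0.5)),
                    "edge")
  expect_equal(unname(s3$quadrant_counts), c(1L, 1L, 0L, 1L))
  expect_equal(s3$n_excluded, 1L)
  expect_error(pr2_summary(fake_profiles(c(0.6, NA), c(0.6, 0.5))), "3 genes")

  # the mean point lies inside the bounding box of the points
  pts <- fake_profiles(runif(20, 0.3, 0.9), runif(20, 0.2, 0.8))
  s4 <- pr2_summary(pts, "hull")
  expect_true(s4$mean[["x"]] >= min(pts$pr2_x) & s4$mean[["x"]] <= max(pts$pr2_x))
  expect_true(s4$mean[["y"]] >= min(pts$pr2_y) & s4$mean[["y"]] <= max(pts$pr2_y))
})

test_that("PR2 of an A/G-skewed synthetic panel lands in the expected quadrant", {
  stats <- codon_usage_stats(small_cds())
  s <- pr2_summary(stats, "panel")
  expect_equal(names(which.max(s$quadrant_counts)), "Q1")
  expect_gt(s$mean[["x"]], 0.5)
  expect_gt(s$mean[["y"]], 0.5)
})

test_that("neutrality regression follows the GC12-on-GC3 convention", {
  x <- seq(0.1, 0.6, length.out = 10)
  f <- neutrality_fit(fake_profiles(rep(0.6, 10), rep(0.6, 10),
                                    gc3 = x, gc12 = x), "identity")
  expect_equal(f$slope, 1)
  expect_equal(f$intercept, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)

  f2 <- neutrality_fit(fake_profiles(rep(0.6, 10), rep(0.6, 10),
                                     gc3 = x, gc12 = rep(0.4, 10)), "flat")
  expect_equal(f2$slope, 0, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0)

  expect_error(neutrality_fit(fake_profiles(rep(0.6, 5), rep(0.6, 5),
                                            gc3 = rep(0.3, 5))), "degenerate")

  # invariant under reordering and duplication of the gene set
  d <- fake_profiles(rep(0.6, 10), rep(0.6, 10), gc3 = x,
                     gc12 = 0.2 + 0.3 * x + c(rep(0.01, 5), rep(-0.01, 5)))
  f3 <- neutrality_fit(d)
  f4 <- neutrality_fit(d[sample(10), ])
  f5 <- neutrality_fit(rbind(d, d))
  expect_equal(f4$slope, f3$slope)
  expect_equal(f5$slope, f3$slope)
  expect_equal(f5$r_squared, f3$r_squared)

  g <- glance(f3)
  expect_equal(g$r.squared, f3$r_squared)
  expect_equal(nrow(tidy(f3)), 2)
})

test_that("ENC-plot deviations flag genes beneath the reference curve", {
  gc3s <- c(0.2, 0.3, 0.4)
  on_curve <- enc_expected(gc3s)
  s <- enc_plot_summary(fake_profiles(rep(0.6, 3), rep(0.6, 3), gc3s = gc3s,
                                      enc = on_curve), "oncurve")
  expect_equal(s$genes$deviation, rep(0, 3))
  expect_equal(s$fraction_below, 0)

  s2 <- enc_plot_summary(fake_profiles(rep(0.6, 3), rep(0.6, 3), gc3s = gc3s,
                                       enc = 0.9 * on_curve), "below")
  expect_equal(s2$genes$deviation, rep(0.1, 3), tolerance = 1e-12)
  expect_equal(s2$fraction_below, 1)

  # genes drawn with a strong third-position A/G skew (beyond what their
  # GC3s alone predicts) fall mostly below the curve ...
  withr::with_seed(71, {
    skewed <- profile_genes(build_codon_profile(0.2, c(0.85, 0.80)), 60, 200)
    s3 <- enc_plot_summary(codon_usage_stats(skewed), "skewed")
    expect_gt(s3$fraction_below, 0.5)
    # ... while unbiased genes track the no-selection curve and stay centred
    neutral <- profile_genes(build_codon_profile(0.5, c(0.5, 0.5)), 60, 200)
    stats_n <- codon_usage_stats(neutral)
    s4 <- enc_plot_summary(stats_n, "neutral")
    expect_lte(s4$fraction_below, 0.1)
    p4 <- pr2_summary(stats_n, "neutral")
    expect_lt(abs(p4$mean[["x"]] - 0.5), 0.05)
    expect_lt(abs(p4$mean[["y"]] - 0.5), 0.05)
  })
})

test_that("autoplot methods return ggplot objects", {
  stats <- codon_usage_stats(small_cds()[1:60, ])
  expect_s3_class(autoplot(pr2_summary(stats, "p")), "ggplot")
  expect_s3_class(autoplot(neutrality_fit(stats, "p")), "ggplot")
  expect_s3_class(autoplot(enc_plot_summary(stats, "p")), "ggplot")
})
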