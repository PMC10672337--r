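#' PR2 bias summary for a group of genes
#'
#' Summarises the parity-rule-2 scatter of a gene set: mean point, quadrant
#' occupancy around (0.5, 0.5) and the 95% confidence ellipse of the sample
#' covariance (chi-square, 2 df). Genes with an undefined coordinate (zero
#' denominator) are excluded and counted. Points exactly on a boundary go to
#' the upper/right quadrant (`>= 0.5`), so the assignment is deterministic.
#'
#' @param profiles Per-gene statistics from [codon_usage_stats()] (columns
#'   `pr2_x`, `pr2_y`), already restricted to the group of interest.
#' @param group_id Label stored with the summary.
#' @return A `pr2_summary` object: points tibble, `mean` (x, y),
#'   `quadrant_counts` (`Q1` top-right, `Q2` top-left, `Q3` bottom-left,
#'   `Q4` bottom-right), `ellipse` (center, semi-axes, angle in radians) and
#'   `n_excluded`.
#' @export
pr2_summary <- function(profiles, group_id = "group") {
  stopifnot(all(c("pr2_x", "pr2_y") %in% names(profiles)))
  usable <- !is.na(profiles$pr2_x) & !is.na(profiles$pr2_y)
  pts <- tibble(locus_id = profiles$locus_id[usable],
                genome_id = profiles$genome_id[usable],
                x = profiles$pr2_x[usable], y = profiles$pr2_y[usable])
  if (nrow(pts) < 3) stop("fewer than 3 genes with defined PR2 coordinates")
  quad <- dplyr::case_when(
    pts$x >= 0.5 & pts$y >= 0.5 ~ "Q1",
    pts$x < 0.5 & pts$y >= 0.5 ~ "Q2",
    pts$x < 0.5 & pts$y < 0.5 ~ "Q3",
    TRUE ~ "Q4")
  qc <- table(factor(quad, levels = c("Q1", "Q2", "Q3", "Q4")))
  ctr <- c(x = mean(pts$x), y = mean(pts$y))
  cv <- cov(cbind(pts$x, pts$y))
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  axes <- sqrt(lam * qchisq(0.95, df = 2))
  angle <- atan2(eg$vectors[2, 1], eg$vectors[1, 1])
  structure(list(group_id = group_id, points = pts, mean = ctr,
                 quadrant_counts = setNames(as.integer(qc), names(qc)),
                 ellipse = list(center = ctr, axes = axes, angle = angle),
                 n_excluded = sum(!usable)),
            class = "pr2_summary")
}

#' @export
print.pr2_summary <- function(x, ...) {
  cat(sprintf("<pr2_summary> %s: %d genes, mean (%.3f, %.3f)\n", x$group_id,
              nrow(x$points), x$mean[["x"]], x$mean[["y"]]))
  cat("  quadrants:", paste(names(x$quadrant_counts), x$quadrant_counts,
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.pr2_summary <- function(x, ...) {
  tibble(group_id = x$group_id,
         quadrant = names(x$quadrant_counts),
         n_genes = unname(x$quadrant_counts),
         fraction = unname(x$quadrant_counts) / nrow(x$points))
}

#' @export
glance.pr2_summary <- function(x, ...) {
  tibble(group_id = x$group_id, n_genes = nrow(x$points),
         mean_x = x$mean[["x"]], mean_y = x$mean[["y"]],
         majority_quadrant = names(which.max(x$quadrant_counts)),
         n_excluded = x$n_excluded)
}

.ellipse_path <- function(ellipse, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- cbind(ellipse$axes[1] * cos(t), ellipse$axes[2] * sin(t))
  rot <- matrix(c(cos(ellipse$angle), sin(ellipse$angle),
                  -sin(ellipse$angle), cos(ellipse$angle)), 2, 2)
  xy <- u %*% t(rot)
  tibble(x = xy[, 1] + ellipse$center[["x"]], y = xy[, 2] + ellipse$center[["y"]])
}

#' @export
autoplot.pr2_summary <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_path(data = .ellipse_path(object$ellipse), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = 2) +
    ggplot2::annotate("point", x = object$mean[["x"]], y = object$mean[["y"]],
                      colour = "red", shape = 3, size = 3) +
    ggplot2::labs(x = "G3 / (G3 + C3)", y = "A3 / (A3 + T3)",
                  title = paste("PR2 bias plot:", object$group_id)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1))
}

#' Neutrality-plot regression for a group of genes
#'
#' Ordinary least squares of GC12 (response) on GC3 (predictor) over the
#' genes of a group. A slope near 1 indicates that directional mutation
#' pressure dominates codon usage; a slope near 0 indicates selection or
#' other constraints decoupling the first two codon positions from the third.
#'
#' @param profiles Per-gene statistics from [codon_usage_stats()] (columns
#'   `gc12`, `gc3`), restricted to the group of interest.
#' @param group_id Label stored with the fit.
#' @return A `neutrality_fit` object with `slope`, `intercept`, `r_squared`,
#'   `n_genes` and the underlying `lm` fit.
#' @export
neutrality_fit <- function(profiles, group_id = "group") {
  stopifnot(all(c("gc12", "gc3") %in% names(profiles)))
  d <- tibble(gc3 = profiles$gc3, gc12 = profiles$gc12)
  d <- d[stats::complete.cases(d), ]
  if (nrow(d) < 3) stop("fewer than 3 genes for neutrality regression")
  if (var(d$gc3) == 0) stop("degenerate regression: GC3 is constant")
  fit <- lm(gc12 ~ gc3, data = d)
  # R^2 as squared Pearson correlation; a constant response has no
  # explainable variance, so R^2 = 0 (cor is undefined there)
  r2 <- if (var(d$gc12) == 0) 0 else cor(d$gc3, d$gc12)^2
  structure(list(group_id = group_id, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]), r_squared = r2,
                 n_genes = nrow(d), fit = fit, data = d),
            class = "neutrality_fit")
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf(
    "<neutrality_fit> %s: GC12 = %.4f + %.4f GC3 (R^2 = %.5f, n = %d)\n",
    x$group_id, x$intercept, x$slope, x$r_squared, x$n_genes))
  invisible(x)
}

#' @export
tidy.neutrality_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(group_id = x$group_id, term = c("(Intercept)", "gc3"),
         estimate = unname(s[, 1]), std.error = unname(s[, 2]),
         statistic = unname(s[, 3]), p.value = unname(s[, 4]))
}

#' @export
glance.neutrality_fit <- function(x, ...) {
  tibble(group_id = x$group_id, slope = x$slope, intercept = x$intercept,
         r.squared = x$r_squared, n_genes = x$n_genes)
}

#' @export
autoplot.neutrality_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$gc3, y = .data$gc12)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "GC3", y = "GC12",
                  title = sprintf("Neutrality plot: %s (R² = %.4f)",
                                  object$group_id, object$r_squared))
}

#' ENC-plot summary for a group of genes
#'
#' Compares each gene's observed ENC with the expected ENC at its GC3s under
#' the no-selection reference curve. The relative deviation
#' `(ENC_exp - ENC) / ENC_exp` measures how far a gene falls beneath the
#' curve; genes beneath by more than `margin` are flagged as under selection
#' pressure.
#'
#' @param profiles Per-gene statistics from [codon_usage_stats()] (columns
#'   `gc3s`, `enc`), restricted to the group of interest.
#' @param group_id Label stored with the summary.
#' @param margin Relative deviation beyond which a gene counts as below the
#'   curve (default 0.05, i.e. a 5% error margin).
#' @return An `enc_plot_summary` object with a per-gene tibble (`gc3s`,
#'   `enc`, `enc_exp`, `deviation`, `below`) and `fraction_below`.
#' @export
enc_plot_summary <- function(profiles, group_id = "group", margin = 0.05) {
  stopifnot(all(c("gc3s", "enc") %in% names(profiles)))
  usable <- !is.na(profiles$gc3s) & !is.na(profiles$enc)
  if (!any(usable)) stop("no genes with defined ENC and GC3s")
  d <- tibble(locus_id = profiles$locus_id[usable],
              genome_id = profiles$genome_id[usable],
              gc3s = profiles$gc3s[usable], enc = profiles$enc[usable])
  d$enc_exp <- enc_expected(d$gc3s)
  d$deviation <- (d$enc_exp - d$enc) / d$enc_exp
  d$below <- d$deviation > margin
  structure(list(group_id = group_id, genes = d, margin = margin,
                 fraction_below = mean(d$below)),
            class = "enc_plot_summary")
}

#' @export
print.enc_plot_summary <- function(x, ...) {
  cat(sprintf(
    "<enc_plot_summary> %s: %d genes, %.1f%% below curve by > %.0f%%\n",
    x$group_id, nrow(x$genes), 100 * x$fraction_below, 100 * x$margin))
  invisible(x)
}

#' @export
tidy.enc_plot_summary <- function(x, ...) {
  dplyr::mutate(x$genes, group_id = x$group_id, .before = 1)
}

#' @export
glance.enc_plot_summary <- function(x, ...) {
  tibble(group_id = x$group_id, n_genes = nrow(x$genes), margin = x$margin,
         fraction_below = x$fraction_below,
         mean_enc = mean(x$genes$enc), mean_gc3s = mean(x$genes$gc3s))
}

#' @export
autoplot.enc_plot_summary <- function(object, ...) {
  curve <- tibble(gc3s = seq(0.001, 0.999, length.out = 300))
  curve$enc_exp <- enc_expected(curve$gc3s)
  ggplot2::ggplot(object$genes, ggplot2::aes(x = .data$gc3s, y = .data$enc)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$below), alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = curve, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$gc3s, y = .data$enc_exp)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "GC3s", y = "ENC",
                  title = paste("ENC plot:", object$group_id)) +
    ggplot2::coord_cartesian(ylim = c(20, 61))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
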