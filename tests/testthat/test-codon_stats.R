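# independent oracle: per-codon tally written without the package's helpers
oracle_codons <- function(nt) {
  v <- strsplit(nt, "")[[1]]
  sapply(seq(1, length(v) - 2, by = 3), function(i) paste0(v[i:(i + 2)], collapse = ""))
}

test_that("codon_counts tallies sense codons and strips the terminal stop", {
  cc <- codon_counts("ATGAAATAA")
  expect_equal(cc[["ATG"]], 1L)
  expect_equal(cc[["AAA"]], 1L)
  expect_equal(sum(cc), 2L)
  expect_equal(sum(codon_counts("ATG")), 1L)
  # property: counts sum to n_codons on random genes
  for (seed in 1:20) {
    nt <- random_cds(sample(10:200, 1), seed = seed)
    expect_equal(sum(codon_counts(nt)), nchar(nt) / 3 - 1)
  }
})

test_that("positional GC matches hand counts and a brute-force recount", {
  g <- positional_gc(codon_counts(paste0("ATG", "GCC", "TAA")))
  expect_equal(unname(g), c(0.5, 0.5, 1.0, 0.5))
  g2 <- positional_gc(codon_counts(strrep("GCG", 30)))
  expect_equal(unname(g2), c(1, 1, 1, 1))
  # brute-force oracle on a long random gene
  nt <- random_cds(1000, seed = 99)
  cods <- oracle_codons(substr(nt, 1, nchar(nt) - 3))
  byp <- sapply(1:3, function(p) mean(substr(cods, p, p) %in% c("G", "C")))
  g3 <- positional_gc(codon_counts(nt))
  expect_equal(unname(g3), c(byp, mean(byp[1:2])), tolerance = 1e-12)
})

test_that("PR2 coordinates follow the G3/(G3+C3), A3/(A3+T3) definition", {
  # third bases G, C, A, A, T
  cc <- codon_counts(paste0("AAG", "AAC", "AAA", "GGA", "GGT"))
  p <- pr2_coordinates(cc)
  expect_equal(p[["x"]], 0.5)
  expect_equal(p[["y"]], 2 / 3)
  expect_equal(sum(p[c("a3", "t3", "c3", "g3")]), 5)
  # all-A third bases: y defined, x missing
  p2 <- pr2_coordinates(codon_counts(strrep("AAA", 10)))
  expect_equal(p2[["y"]], 1)
  expect_true(is.na(p2[["x"]]))
  # balanced composition sits at the parity point
  p3 <- pr2_coordinates(codon_counts(paste0("AAA", "AAT", "AAG", "AAC")))
  expect_equal(unname(p3[c("x", "y")]), c(0.5, 0.5))
})

test_that("GC3s excludes Met, Trp and stop codons", {
  expect_equal(gc3s(codon_counts(paste0("ATG", "TTT", "TTT"))), 0)
  expect_equal(gc3s(codon_counts(paste0("ATG", "TTC", "TTC"))), 1)
  expect_true(is.na(gc3s(codon_counts(paste0("ATG", "TGG", "TAA")))))
  # per-codon oracle on random genes
  for (seed in 1:10) {
    nt <- random_cds(150, seed = seed)
    cods <- oracle_codons(substr(nt, 1, nchar(nt) - 3))
    keep <- !cods %in% c("ATG", "TGG")
    expect_equal(gc3s(codon_counts(nt)),
                 mean(substr(cods[keep], 3, 3) %in% c("G", "C")))
  }
})

# straight-from-the-formula ENC oracle, independent of the package's
# family bookkeeping (families derived from Biostrings' genetic code)
oracle_enc <- function(counts) {
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  fams <- unname(split(sense, code[sense]))
  f_of <- sapply(fams, function(cs) {
    n <- sum(counts[cs])
    if (n < 2) return(NA_real_)
    (n * sum((counts[cs] / n)^2) - 1) / (n - 1)
  })
  deg <- lengths(fams)
  cm <- function(k) { v <- f_of[deg == k]; v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else NA_real_ }
  f2 <- cm(2); f3 <- cm(3); f4 <- cm(4); f6 <- cm(6)
  if (is.na(f3)) f3 <- mean(c(f2, f4))
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(val, 20), 61)
}

test_that("ENC hits Wright's limits and agrees with the formula oracle", {
  sense <- names(which(Biostrings::getGeneticCode("11") != "*"))
  # uniform usage of all 61 sense codons at n = 10^4: no bias, ENC = 61
  uniform <- setNames(rep(0L, 64), sort(c(sense, c("TAA", "TAG", "TGA"))))
  uniform[sense] <- 164L  # 61 * 164 = 10004 codons
  expect_equal(enc(uniform), 61, tolerance = 1e-6)
  # one codon per amino acid at large n: maximal bias, ENC = 20
  one_per_aa <- setNames(rep(0L, 64), names(uniform))
  aa <- Biostrings::getGeneticCode("11")[sense]
  first_codon <- sapply(split(sense, aa), `[`, 1)
  one_per_aa[first_codon] <- 500L
  expect_equal(enc(one_per_aa), 20, tolerance = 1e-6)
  # fixed random gene matches the independent oracle to 1e-9
  for (seed in c(7, 21, 77)) {
    cc <- codon_counts(random_cds(300, seed = seed))
    expect_equal(enc(cc), oracle_enc(cc), tolerance = 1e-9)
  }
})

test_that("ENC depends only on within-family proportions", {
  cc <- codon_counts(random_cds(400, seed = 5))
  # swapping counts of two codons in the same family leaves ENC unchanged
  # only if proportions multiset is preserved; doubling all counts must too
  expect_equal(enc(cc * 2L), enc(cc), tolerance = 0.5)
  cc2 <- cc
  cc2[c("GGT", "GGC")] <- cc[c("GGC", "GGT")]  # permute within Gly family
  expect_equal(enc(cc2), enc(cc), tolerance = 1e-12)
})

test_that("expected-ENC curve evaluates the reference formula exactly", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(1), 32)
  # symmetry: ENC_exp(x) - x = ENC_exp(1-x) - (1-x)
  x <- seq(0.05, 0.95, by = 0.05)
  expect_equal(enc_expected(x) - x, enc_expected(1 - x) - (1 - x))
})

test_that("codon_usage_stats assembles a coherent per-gene table", {
  stats <- codon_usage_stats(small_cds()[1:20, ])
  expect_equal(nrow(stats), 20)
  expect_true(all(stats$gc12 == (stats$gc1 + stats$gc2) / 2))
  expect_true(all(stats$a3 + stats$t3 + stats$c3 + stats$g3 == stats$n_codons))
  expect_true(all(stats$enc >= 20 & stats$enc <= 61, na.rm = TRUE))
  expect_true(all(stats$gc3s >= 0 & stats$gc3s <= 1, na.rm = TRUE))
})
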