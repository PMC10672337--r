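#' Codon counts of a coding sequence
#'
#' Counts sense codons of an in-frame CDS; a terminal stop codon is stripped
#' before counting.
#'
#' @param nt In-frame nucleotide string (length divisible by 3).
#' @return Named integer vector of length 64 over all codons (alphabetical).
#' @export
codon_counts <- function(nt) {
  codons <- .split_codons(toupper(nt))
  n <- length(codons)
  if (n && codons[n] %in% .STOP_CODONS) codons <- codons[-n]
  tab <- table(factor(codons, levels = .CODONS))
  setNames(as.integer(tab), .CODONS)
}

.check_counts <- function(counts) {
  if (is.null(names(counts)) || !identical(sort(names(counts)), .CODONS))
    stop("counts must be a named 64-vector over all codons")
  counts[.CODONS]
}

#' Positional GC content of a gene
#'
#' GC fraction at each codon position, plus GC12 (the mean of GC1 and GC2),
#' computed from sense-codon counts (stop codons are ignored).
#'
#' @param counts Named 64-vector of codon counts (see [codon_counts()]).
#' @return Named numeric vector `c(gc1, gc2, gc3, gc12)`.
#' @export
positional_gc <- function(counts) {
  counts <- .check_counts(counts)
  counts <- counts[.SENSE_CODONS]
  n <- sum(counts)
  if (n < 1) stop("no sense codons")
  pos_gc <- vapply(1:3, function(p) {
    b <- substr(names(counts), p, p)
    sum(counts[b %in% c("G", "C")]) / n
  }, 0)
  c(gc1 = pos_gc[1], gc2 = pos_gc[2], gc3 = pos_gc[3],
    gc12 = (pos_gc[1] + pos_gc[2]) / 2)
}

#' Third-position base counts and PR2 coordinates
#'
#' Parity-rule-2 coordinates of a gene: `x = G3/(G3+C3)` and
#' `y = A3/(A3+T3)`, from third-position base counts over sense codons.
#' A zero denominator yields `NA` for that coordinate (the gene is excluded
#' from PR2 plots).
#'
#' @param counts Named 64-vector of codon counts.
#' @return Named numeric vector `c(a3, t3, c3, g3, x, y)`.
#' @export
pr2_coordinates <- function(counts) {
  counts <- .check_counts(counts)[.SENSE_CODONS]
  third <- substr(names(counts), 3, 3)
  b <- vapply(c("A", "T", "C", "G"), function(k) sum(counts[third == k]), 0)
  x <- if ((b["G"] + b["C"]) > 0) b[["G"]] / (b[["G"]] + b[["C"]]) else NA_real_
  y <- if ((b["A"] + b["T"]) > 0) b[["A"]] / (b[["A"]] + b[["T"]]) else NA_real_
  c(a3 = b[["A"]], t3 = b[["T"]], c3 = b[["C"]], g3 = b[["G"]], x = x, y = y)
}

#' GC content at synonymous third positions (GC3s)
#'
#' GC fraction at third codon positions over codons with synonymous
#' alternatives: all sense codons except Met (ATG) and Trp (TGG); stop codons
#' are excluded. A gene with no such codons yields `NA`.
#'
#' @param counts Named 64-vector of codon counts.
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
gc3s <- function(counts) {
  counts <- .check_counts(counts)
  syn <- setdiff(.SENSE_CODONS, c("ATG", "TGG"))
  counts <- counts[syn]
  n <- sum(counts)
  if (n < 1) return(NA_real_)
  third <- substr(syn, 3, 3)
  sum(counts[third %in% c("G", "C")]) / n
}

# synonymous families under code 11, with Leu/Ser/Arg each one 6-fold family
.enc_families <- local({
  aa <- .CODON_AA[.SENSE_CODONS]
  fam <- split(names(aa), unname(aa))
  deg <- lengths(fam)
  list(families = fam, degeneracy = deg)
})

#' Effective number of codons (ENC)
#'
#' Wright's (1990) ENC as popularised by CodonW. For each amino-acid family
#' with total count `n >= 2`, the codon homozygosity is
#' `F = (n * sum(p_i^2) - 1) / (n - 1)`; class means over families of
#' degeneracy 2, 3, 4 and 6 give `ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.
#' A missing threefold mean (Ile unused) is imputed as the mean of the two-
#' and fourfold means; the result is clamped to `[20, 61]`. `NA` is returned
#' when a required class mean is undefined.
#'
#' @param counts Named 64-vector of codon counts.
#' @return ENC value in `[20, 61]`, or `NA`.
#' @export
enc <- function(counts) {
  counts <- .check_counts(counts)
  fam <- .enc_families$families
  deg <- .enc_families$degeneracy
  fvals <- vapply(fam, function(codons) {
    n <- sum(counts[codons])
    if (n < 2) return(NA_real_)
    p <- counts[codons] / n
    (n * sum(p^2) - 1) / (n - 1)
  }, 0)
  class_mean <- function(k) {
    v <- fvals[deg == k]
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) NA_real_ else mean(v)
  }
  f2 <- class_mean(2); f3 <- class_mean(3); f4 <- class_mean(4); f6 <- class_mean(6)
  if (is.na(f3) && !is.na(f2) && !is.na(f4)) f3 <- (f2 + f4) / 2
  if (anyNA(c(f2, f3, f4, f6))) return(NA_real_)
  val <- 2 + 9 / f2 + 1 / f3 + 5 / f4 + 3 / f6
  min(max(val, 20), 61)
}

#' Expected ENC under no selection
#'
#' The theoretical ENC-plot reference curve
#' `ENC_exp = 2 + GC3s + 29 / (GC3s^2 + (1 - GC3s)^2)`.
#'
#' @param gc3s_value GC3s value(s) in `[0, 1]`.
#' @return Expected ENC (vectorised).
#' @export
enc_expected <- function(gc3s_value) {
  stopifnot(all(gc3s_value >= 0 & gc3s_value <= 1, na.rm = TRUE))
  2 + gc3s_value + 29 / (gc3s_value^2 + (1 - gc3s_value)^2)
}

#' Per-gene codon usage statistics for a panel
#'
#' Computes the full per-gene profile used by the bias analyses: positional
#' GC, third-position base counts and PR2 coordinates, GC3s and ENC.
#'
#' @param cds Tibble of coding sequences from [extract_cds()] /
#'   [extract_cds_panel()] (columns `genome_id`, `locus_id`, `nt`).
#' @return Tibble with one row per gene: `genome_id`, `locus_id`, `n_codons`,
#'   `gc1`, `gc2`, `gc3`, `gc12`, `a3`, `t3`, `c3`, `g3`, `pr2_x`, `pr2_y`,
#'   `gc3s`, `enc`.
#' @export
codon_usage_stats <- function(cds) {
  stopifnot(all(c("genome_id", "locus_id", "nt") %in% names(cds)))
  rows <- purrr::map(seq_len(nrow(cds)), function(i) {
    cc <- codon_counts(cds$nt[i])
    g <- positional_gc(cc)
    p <- pr2_coordinates(cc)
    tibble(genome_id = cds$genome_id[i], locus_id = cds$locus_id[i],
           n_codons = sum(cc[.SENSE_CODONS]),
           gc1 = g[["gc1"]], gc2 = g[["gc2"]], gc3 = g[["gc3"]],
           gc12 = g[["gc12"]],
           a3 = p[["a3"]], t3 = p[["t3"]], c3 = p[["c3"]], g3 = p[["g3"]],
           pr2_x = p[["x"]], pr2_y = p[["y"]],
           gc3s = gc3s(cc), enc = enc(cc))
  })
  dplyr::bind_rows(rows)
}
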