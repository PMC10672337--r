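# Nei-Gojobori (1986) counting: fractional site counts per codon, equal
# weighting of minimal mutational pathways between codons, Jukes-Cantor
# correction of the proportions.

.ng86_cache <- new.env(parent = emptyenv())

.ng86_site_table <- function() {
  if (!is.null(.ng86_cache$sites)) return(.ng86_cache$sites)
  bases <- c("A", "C", "G", "T")
  s <- setNames(numeric(length(.SENSE_CODONS)), .SENSE_CODONS)
  for (codon in .SENSE_CODONS) {
    aa <- .CODON_AA[[codon]]
    syn <- 0
    for (pos in 1:3) {
      for (b in setdiff(bases, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- b
        # changes to stop codons count as nonsynonymous
        if (.CODON_AA[[mut]] != "*" && .CODON_AA[[mut]] == aa) syn <- syn + 1
      }
    }
    s[codon] <- syn / 3
  }
  .ng86_cache$sites <- s
  s
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each codon position the fraction of the three possible single-base
#' changes that are synonymous is accumulated into `s`; changes creating a
#' stop codon count as nonsynonymous. `n = 3 - s`.
#'
#' @param codon A sense codon string, e.g. `"GCT"`.
#' @return Named numeric vector `c(s, n)`.
#' @export
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  if (!codon %in% .SENSE_CODONS) stop("not a sense codon: ", codon)
  s <- .ng86_site_table()[[codon]]
  c(s = s, n = 3 - s)
}

# enumerate minimal pathways between two sense codons; average (sd, nd) over
# pathways avoiding stop intermediates, falling back to all pathways with
# stop steps counted as nonsynonymous when every pathway is blocked
.ng86_pair <- function(a, b) {
  key <- paste0(a, b)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  diff_pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  nd_steps <- length(diff_pos)
  out <- if (nd_steps == 0L) {
    c(sd = 0, nd = 0)
  } else {
    perms <- .permutations(diff_pos)
    paths <- lapply(perms, function(ord) {
      cur <- a
      sd <- nd <- 0
      via_stop <- FALSE
      for (pos in ord) {
        nxt <- cur
        substr(nxt, pos, pos) <- substr(b, pos, pos)
        if (.CODON_AA[[nxt]] == "*") via_stop <- TRUE
        # a step is synonymous iff both codons code the same amino acid;
        # steps into or out of a stop codon are nonsynonymous
        if (.CODON_AA[[nxt]] != "*" && .CODON_AA[[cur]] == .CODON_AA[[nxt]])
          sd <- sd + 1
        else nd <- nd + 1
        cur <- nxt
      }
      c(sd = sd, nd = nd, via_stop = via_stop)
    })
    m <- do.call(rbind, paths)
    ok <- m[, "via_stop"] == 0
    use <- if (any(ok)) m[ok, , drop = FALSE] else m
    c(sd = mean(use[, "sd"]), nd = mean(use[, "nd"]))
  }
  assign(key, out, envir = .ng86_cache)
  out
}

.permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- c(out, lapply(rest, function(r) c(x[i], r)))
  }
  out
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Averages the step classifications over all minimal mutational pathways
#' between the codons, excluding pathways passing through stop codons; if
#' every pathway is blocked, all pathways are used with stop-creating steps
#' counted as nonsynonymous.
#'
#' @param codon_a,codon_b Sense codon strings.
#' @return Named numeric vector `c(sd, nd)`.
#' @export
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  if (!codon_a %in% .SENSE_CODONS || !codon_b %in% .SENSE_CODONS)
    stop("both codons must be sense codons")
  .ng86_pair(codon_a, codon_b)
}

#' NG86 Ka/Ks for a codon alignment
#'
#' Counts sites and differences over the ungapped codon columns of a
#' [codon_align()] result, averages site counts over both sequences, and
#' applies the Jukes-Cantor correction `K = -(3/4) log(1 - 4p/3)` to the
#' synonymous and nonsynonymous proportions. A proportion at or beyond the
#' correction's domain (`p >= 3/4`) yields a missing rate flagged
#' `"saturation"`.
#'
#' @param alignment A `codon_alignment` from [codon_align()].
#' @return One-row tibble: `n_codons` (ungapped columns), `S`, `N`, `Sd`,
#'   `Nd`, `ps`, `pn`, `ks`, `ka`, `omega`, `flag`.
#' @export
kaks <- function(alignment) {
  stopifnot(inherits(alignment, "codon_alignment"))
  cols <- .alignment_codons(alignment, ungapped = TRUE)
  ok <- cols[1, ] %in% .SENSE_CODONS & cols[2, ] %in% .SENSE_CODONS
  cols <- cols[, ok, drop = FALSE]
  if (!ncol(cols)) stop("no ungapped sense codon columns")
  st <- .ng86_site_table()
  s_a <- sum(st[cols[1, ]]); s_b <- sum(st[cols[2, ]])
  S <- (s_a + s_b) / 2
  N <- 3 * ncol(cols) - S
  diffs <- vapply(seq_len(ncol(cols)), function(i)
    .ng86_pair(cols[1, i], cols[2, i]), c(sd = 0, nd = 0))
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) if (is.na(p) || p >= 3 / 4) NA_real_ else -3 / 4 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  flag <- if ((!is.na(ps) && ps >= 3 / 4) || (!is.na(pn) && pn >= 3 / 4))
    "saturation" else "ok"
  omega <- if (!is.na(ka) && !is.na(ks) && ks > 0) ka / ks else NA_real_
  tibble(n_codons = ncol(cols), S = S, N = N, Sd = Sd, Nd = Nd,
         ps = ps, pn = pn, ks = ks, ka = ka, omega = omega, flag = flag)
}

#' Ka/Ks of every ortholog against a reference genome
#'
#' For each single-copy ortholog group, aligns the reference genome's gene
#' to its ortholog in every other genome and computes NG86 Ka/Ks.
#'
#' @param orthologs Ortholog table from [reciprocal_best_hits()].
#' @param cds Panel tibble from [extract_cds_panel()].
#' @param reference Genome id used as the reference.
#' @return Tibble sorted by `group_id`, `genome_id` with the reference locus,
#'   the compared locus and the [kaks()] columns.
#' @export
kaks_vs_reference <- function(orthologs, cds, reference) {
  genomes <- unique(orthologs$genome_id)
  if (!reference %in% genomes)
    stop("reference genome ", reference, " not in the ortholog table")
  seqs <- setNames(cds$nt, paste(cds$genome_id, cds$locus_id, sep = "\r"))
  ref <- orthologs[orthologs$genome_id == reference, ]
  other <- orthologs[orthologs$genome_id != reference, ]
  rows <- purrr::map(seq_len(nrow(other)), function(i) {
    g <- other$group_id[i]
    ref_locus <- ref$locus_id[ref$group_id == g]
    aln <- codon_align(seqs[[paste(reference, ref_locus, sep = "\r")]],
                       seqs[[paste(other$genome_id[i], other$locus_id[i],
                                   sep = "\r")]])
    dplyr::bind_cols(tibble(group_id = g, genome_id = other$genome_id[i],
                            reference_locus = ref_locus,
                            locus_id = other$locus_id[i]),
                     kaks(aln))
  })
  dplyr::bind_rows(rows) |> dplyr::arrange(.data$group_id, .data$genome_id)
}
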