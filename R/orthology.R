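#' Global protein alignment
#'
#' Needleman-Wunsch global alignment with BLOSUM62 scores and affine gap
#' penalties (open 11, extend 1; a gap of length L costs `11 + L`). Identity
#' is matches over aligned columns (gap-gap columns cannot occur in a
#' pairwise global alignment).
#'
#' @param a,b Protein sequences (strings).
#' @return List with `score`, `identity`, `aligned_a`, `aligned_b`.
#' @export
align_proteins <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  .cpp_nw_align(toupper(a), toupper(b), .blosum62(), 11, 1)
}

# best hit of each query among targets: full NW score on the top_k candidates
# ranked by shared amino-acid 3-mers; near-ties resolved by alignment
# identity, then lexicographic target name. Exact ties (equal score and
# equal identity, e.g. duplicated genes) are kept as a tie set: such targets
# are indistinguishable and poison single-copy orthology downstream.
.best_hits <- function(queries, targets, top_k = 8L, min_frac = 0.5) {
  res <- .cpp_best_hit_search(queries, targets, .blosum62(), 11, 1,
                              as.integer(top_k), min_frac)
  best <- integer(length(queries))
  ties <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    cand <- res[[i]]$candidates
    score <- res[[i]]$scores
    top <- which(score == max(score))
    if (length(top) > 1L) {
      idents <- vapply(top, function(j)
        .cpp_nw_align(queries[[i]], targets[[cand[j]]], .blosum62(), 11, 1)$identity,
        0)
      top <- top[idents == max(idents)]
      if (length(top) > 1L) {
        ties[[i]] <- cand[top]
        top <- top[order(names(targets)[cand[top]])[1]]
      }
    }
    best[i] <- cand[top[1]]
  }
  list(best = best, ties = ties)
}

#' Single-copy orthologs by reciprocal best hits
#'
#' All-vs-all reciprocal-best-hit orthology over a panel of proteomes. For
#' every genome pair, each protein's best hit (by global alignment score,
#' ties broken by alignment identity then lexicographic locus id) is
#' computed in both directions; mutual best hits become edges, connected
#' components become candidate groups, and only components with exactly one
#' member in every genome of the panel are retained (single-copy groups).
#' The exhaustive quadratic search is accelerated by ranking candidates with
#' shared amino-acid 3-mer counts and fully aligning only the top
#' candidates, which is exact at the identity levels of a congeneric panel.
#'
#' @param cds Panel tibble from [extract_cds_panel()] (columns `genome_id`,
#'   `locus_id`, `aa`).
#' @param top_k Number of prefilter candidates considered per query.
#' @param min_frac Candidates sharing fewer than `min_frac` times the
#'   leading candidate's 3-mer count are not fully aligned (they cannot win
#'   at the identity levels of a congeneric panel).
#' @return Tibble with columns `group_id`, `genome_id`, `locus_id`; one row
#'   per group and genome, sorted by group then genome.
#' @export
reciprocal_best_hits <- function(cds, top_k = 8L, min_frac = 0.5) {
  stopifnot(all(c("genome_id", "locus_id", "aa") %in% names(cds)))
  genomes <- sort(unique(cds$genome_id))
  if (length(genomes) < 2L) stop("need at least 2 genomes")
  prot <- lapply(genomes, function(g) {
    d <- cds[cds$genome_id == g, ]
    setNames(d$aa, d$locus_id)
  })
  names(prot) <- genomes
  # global locus index for union-find
  key <- paste(cds$genome_id, cds$locus_id, sep = "\r")
  parent <- seq_along(key)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  unite <- function(i, j) { ri <- find(i); rj <- find(j); if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj) }
  kidx <- setNames(seq_along(key), key)
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (i >= j) next
      a <- prot[[i]]; b <- prot[[j]]
      hab <- .best_hits(a, b, top_k, min_frac)
      hba <- .best_hits(b, a, top_k, min_frac)
      ab <- hab$best; ba <- hba$best
      mutual <- which(ba[ab] == seq_along(a))
      for (q in mutual) {
        unite(kidx[[paste(genomes[i], names(a)[q], sep = "\r")]],
              kidx[[paste(genomes[j], names(b)[ab[q]], sep = "\r")]])
      }
      # exact ties are indistinguishable targets: unite them so the
      # single-copy filter rejects the whole component
      for (q in seq_along(a)) {
        ts <- hab$ties[[q]]
        if (length(ts) > 1L) for (t2 in ts[-1])
          unite(kidx[[paste(genomes[j], names(b)[ts[1]], sep = "\r")]],
                kidx[[paste(genomes[j], names(b)[t2], sep = "\r")]])
      }
      for (q in seq_along(b)) {
        ts <- hba$ties[[q]]
        if (length(ts) > 1L) for (t2 in ts[-1])
          unite(kidx[[paste(genomes[i], names(a)[ts[1]], sep = "\r")]],
                kidx[[paste(genomes[i], names(a)[t2], sep = "\r")]])
      }
    }
  }
  comp <- vapply(seq_along(key), find, 1L)
  d <- tibble(genome_id = cds$genome_id, locus_id = cds$locus_id, comp = comp)
  groups <- d |>
    dplyr::group_by(.data$comp) |>
    dplyr::filter(dplyr::n() == length(genomes),
                  dplyr::n_distinct(.data$genome_id) == length(genomes)) |>
    dplyr::ungroup()
  if (!nrow(groups)) {
    return(tibble(group_id = character(), genome_id = character(),
                  locus_id = character()))
  }
  # deterministic group ids: order by the locus id in the first genome
  anchor <- groups |>
    dplyr::filter(.data$genome_id == genomes[1]) |>
    dplyr::arrange(.data$locus_id) |>
    dplyr::mutate(group_id = sprintf("OG%04d", dplyr::row_number()))
  out <- groups |>
    dplyr::inner_join(anchor[, c("comp", "group_id")], by = "comp") |>
    dplyr::select("group_id", "genome_id", "locus_id") |>
    dplyr::arrange(.data$group_id, .data$genome_id)
  out
}

#' Codon-aware pairwise alignment of two coding sequences
#'
#' Aligns the translated proteins globally and maps the alignment back onto
#' codons, so gaps come in multiples of 3 and the reading frame is
#' preserved. Terminal stop codons are stripped first. Columns where either
#' side is a gap are flagged; downstream Ka/Ks, ANI and AAI use only the
#' ungapped codon columns.
#'
#' @param nt_a,nt_b In-frame coding sequences (QC-passing).
#' @return A `codon_alignment`: list with gapped nucleotide strings `a`,
#'   `b`, logical `gap` (per codon column), and the aligned proteins.
#' @export
codon_align <- function(nt_a, nt_b) {
  nt_a <- .strip_stop(toupper(nt_a)); nt_b <- .strip_stop(toupper(nt_b))
  aa_a <- .translate_cds(nt_a); aa_b <- .translate_cds(nt_b)
  if (grepl("\\*", aa_a) || grepl("\\*", aa_b))
    stop("internal stop codon in codon_align input")
  aln <- align_proteins(aa_a, aa_b)
  ca <- .split_codons(nt_a); cb <- .split_codons(nt_b)
  pa <- strsplit(aln$aligned_a, "")[[1]]
  pb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- ib <- 0L
  out_a <- out_b <- character(length(pa))
  for (k in seq_along(pa)) {
    if (pa[k] == "-") out_a[k] <- "---" else { ia <- ia + 1L; out_a[k] <- ca[ia] }
    if (pb[k] == "-") out_b[k] <- "---" else { ib <- ib + 1L; out_b[k] <- cb[ib] }
  }
  if (ia != length(ca) || ib != length(cb))
    stop("translation mismatch: protein alignment does not cover all codons")
  structure(list(a = paste0(out_a, collapse = ""),
                 b = paste0(out_b, collapse = ""),
                 gap = pa == "-" | pb == "-",
                 aligned_aa_a = aln$aligned_a, aligned_aa_b = aln$aligned_b,
                 identity_aa = aln$identity),
            class = "codon_alignment")
}

.strip_stop <- function(nt) {
  codons <- .split_codons(nt)
  n <- length(codons)
  if (n && codons[n] %in% .STOP_CODONS) codons <- codons[-n]
  paste0(codons, collapse = "")
}

# codon columns of an alignment as a 2 x n matrix, optionally ungapped only
.alignment_codons <- function(aln, ungapped = TRUE) {
  ca <- .split_codons(aln$a); cb <- .split_codons(aln$b)
  if (ungapped) { ca <- ca[!aln$gap]; cb <- cb[!aln$gap] }
  rbind(ca, cb)
}
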