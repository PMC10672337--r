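# Shared fixtures, built once per test run and cached. The small panel is
# three clades of 2/2/2 genomes with 30 short genes each: big enough to
# exercise every stage, small enough to keep the suite fast.

.fixture_env <- new.env(parent = emptyenv())

small_spec <- function() {
  panel_spec(
    clades = list(
      clade_spec("A", 2, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.16, pr2_skew = c(0.62, 0.62), gc12_target = 0.3),
      clade_spec("B", 2, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.20, pr2_skew = c(0.60, 0.58), gc12_target = 0.3),
      clade_spec("C", 2, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.24, pr2_skew = c(0.58, 0.60), gc12_target = 0.3)),
    n_genes = 30L, mean_gene_len = 70L, seed = 42L)
}

small_panel <- function() {
  if (is.null(.fixture_env$panel)) .fixture_env$panel <- generate_panel(small_spec())
  .fixture_env$panel
}

small_cds <- function() {
  if (is.null(.fixture_env$cds))
    .fixture_env$cds <- extract_cds_panel(small_panel()$genomes)
  .fixture_env$cds
}

small_orthologs <- function() {
  if (is.null(.fixture_env$orthologs))
    .fixture_env$orthologs <- reciprocal_best_hits(small_cds())
  .fixture_env$orthologs
}

small_relatedness <- function() {
  if (is.null(.fixture_env$rel))
    .fixture_env$rel <- relatedness_matrices(small_orthologs(), small_cds())
  .fixture_env$rel
}

# a deterministic random in-frame CDS (ATG ... stop, no internal stops)
random_cds <- function(n_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sense <- setdiff(names(which(Biostrings::getGeneticCode("11") != "*")), NULL)
  body <- sample(sense, n_codons - 2L, replace = TRUE)
  paste0(c("ATG", body, "TAA"), collapse = "")
}

# a tiny two-gene annotated genome used by seqio tests
toy_genome <- function() {
  seqs <- c("ATGAAAGGTTAA", "ATGATGTAA")
  spacer1 <- "TTTT"; spacer2 <- "CC"; spacer3 <- "AAA"
  # second gene on minus strand: genome carries its reverse complement
  genome <- paste0(spacer1, seqs[1], spacer2, .rc(seqs[2]), spacer3)
  feats <- tibble::tibble(
    kind = c("CDS", "CDS", "tRNA"),
    start = c(nchar(spacer1), nchar(spacer1) + 12L + nchar(spacer2), 0L),
    end = c(nchar(spacer1) + 12L, nchar(spacer1) + 12L + nchar(spacer2) + 9L, 2L),
    strand = c(1L, -1L, 1L),
    locus_id = c("g1", "g2", "t1"))
  annotated_genome("toy", genome, feats, "circular")
}

.rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# genes sampled straight from a codon profile, as a cds-shaped tibble
profile_genes <- function(profile, n_genes, len_codons) {
  nt <- vapply(seq_len(n_genes), function(i)
    paste0(c("ATG", sample(profile$codon, len_codons, TRUE, prob = profile$p),
             "TAA"), collapse = ""), "")
  tibble::tibble(genome_id = "sim", locus_id = sprintf("s%03d", seq_len(n_genes)),
                 nt = nt, aa = NA_character_)
}

# neutral per-base mutation of a plain sequence (test-side divergence)
.evolve_seq_for_test <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste0(x, collapse = "")
}
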