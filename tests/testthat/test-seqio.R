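test_that("GenBank write/read round trip preserves sequence and features", {
  g <- toy_genome()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, g$sequence)
  expect_identical(g2$topology, "circular")
  expect_equal(as.data.frame(g2$features), as.data.frame(g$features))

  # and a larger simulated genome survives the round trip bit-for-bit
  sim <- small_panel()$genomes[[1]]
  p2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(sim, p2)
  sim2 <- read_genbank(p2)
  expect_identical(sim2$sequence, sim$sequence)
  expect_equal(as.data.frame(sim2$features), as.data.frame(sim$features))
})

test_that("FASTA pair round trip reconstructs the annotation", {
  g <- toy_genome()
  fa <- withr::local_tempfile(fileext = ".fna")
  cds_fa <- withr::local_tempfile(fileext = ".cds.fna")
  write_fasta_pair(g, fa, cds_fa)
  g2 <- read_genome(fa, format = "fasta", cds_path = cds_fa)
  expect_identical(g2$sequence, g$sequence)
  expect_equal(as.data.frame(g2$features), as.data.frame(g$features))
  # coordinate metadata is verified against the genome
  bad <- readLines(cds_fa)
  bad <- sub("loc=4..16", "loc=3..15", bad, fixed = TRUE)
  writeLines(bad, cds_fa)
  expect_error(read_genome(fa, format = "fasta", cds_path = cds_fa),
               "coordinates")
})

test_that("malformed GenBank input gives a parse error", {
  p <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS  x 10 bp", "ORIGIN", "1 ATGXXX", "//"), p)
  expect_error(read_genbank(p), "unknown residue")
  writeLines("not a genbank file", p)
  expect_error(read_genbank(p), "LOCUS")
})

test_that("extract_cds resolves strands and translates with code 11", {
  g <- toy_genome()
  cds <- extract_cds(g, qc_policy(min_len = 0))
  expect_identical(cds$nt[cds$locus_id == "g1"], "ATGAAAGGTTAA")
  expect_identical(cds$aa[cds$locus_id == "g1"], "MKG")
  # minus-strand feature: forward slice revcomps back to the coding strand
  expect_identical(cds$nt[cds$locus_id == "g2"], "ATGATGTAA")
  expect_identical(cds$aa[cds$locus_id == "g2"], "MM")
})

test_that("QC policy drops out-of-frame, short, ambiguous and stop-containing genes", {
  feats <- tibble::tibble(
    kind = "CDS",
    start = c(0L, 120L, 240L, 360L, 480L),
    end = c(0L, 120L, 240L, 360L, 480L) + c(99L, 100L, 99L, 99L, 99L),
    strand = 1L,
    locus_id = c("ok", "frame", "short", "withN", "stop"))
  ok <- random_cds(33, seed = 1)
  stopgene <- paste0("ATG", "TAA", substr(ok, 7, 99))
  withN <- paste0(substr(ok, 1, 50), "N", substr(ok, 52, 99))
  seq <- paste0(ok, strrep("T", 21),
                substr(random_cds(40, seed = 2), 1, 100), strrep("T", 20),
                substr(ok, 1, 99), strrep("T", 21),
                withN, strrep("T", 21),
                stopgene, strrep("T", 21))
  feats$end[3] <- 240L + 60L # short gene: 60 nt < 90
  g <- annotated_genome("qc", seq, feats, "linear")
  cds <- extract_cds(g, qc_policy(min_len = 90))
  expect_identical(cds$locus_id, "ok")
  dropped <- attr(cds, "dropped")
  expect_setequal(dropped$locus_id, c("frame", "short", "withN", "stop"))
  expect_match(dropped$reason[dropped$locus_id == "frame"], "divisible")
  expect_match(dropped$reason[dropped$locus_id == "stop"], "internal stop")
  expect_error(extract_cds(g, qc_policy(min_len = 1e6)), "empty gene set")
})

test_that("summarize_genome computes GC and interval-union coding density", {
  # no features: zero GC genome, zero density
  g0 <- annotated_genome("at", "ATAT", topology = "linear")
  s0 <- summarize_genome(g0)
  expect_equal(s0$gc_percent, 0)
  expect_equal(s0$coding_density_percent, 0)

  # overlapping features [0,50) + [25,75) on a 100 bp genome cover 75%
  g1 <- annotated_genome("ov", strrep("ACGT", 25), tibble::tibble(
    kind = c("CDS", "CDS"), start = c(0L, 25L), end = c(50L, 75L),
    strand = 1L, locus_id = c("a", "b")), "linear")
  expect_equal(summarize_genome(g1)$coding_density_percent, 75)

  # disjoint features: density equals the sum of their lengths
  g2 <- annotated_genome("dj", strrep("ACGT", 25), tibble::tibble(
    kind = c("CDS", "tRNA"), start = c(0L, 60L), end = c(30L, 80L),
    strand = 1L, locus_id = c("a", "t")), "linear")
  expect_equal(summarize_genome(g2)$coding_density_percent, 50)
  expect_equal(summarize_genome(g2)$n_cds, 1L)
  expect_equal(summarize_genome(g2)$n_trna, 1L)

  # invariant under feature reordering
  g3 <- g2; g3$features <- g3$features[2:1, ]
  expect_equal(summarize_genome(g3)[-1], summarize_genome(g2)[-1],
               ignore_attr = TRUE)
})

test_that("write_tables round trips tibbles deterministically", {
  dir <- withr::local_tempdir()
  tabs <- list(one = tibble::tibble(a = 1:3, b = c("x", "y", "z")),
               two = tibble::tibble(p = c(0.5, 2.25)))
  paths <- write_tables(tabs, dir)
  back <- readr::read_tsv(file.path(dir, "one.tsv"), show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(tabs$one))
  h1 <- tools::md5sum(file.path(dir, "one.tsv"))
  write_tables(tabs, dir)
  expect_identical(unname(tools::md5sum(file.path(dir, "one.tsv"))), unname(h1))
})
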