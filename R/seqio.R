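#' Construct an annotated genome
#'
#' An `annotated_genome` is the light container used throughout the package:
#' a nucleotide sequence plus a tibble of typed features. Coordinates are
#' 0-based half-open on the forward strand (GenBank's 1-based inclusive
#' coordinates are converted on input). For circular genomes a single feature
#' may span the origin, in which case `end` exceeds the genome length and the
#' slice wraps around.
#'
#' @param id Short genome label, e.g. `"AdSh"`.
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#' @param features Tibble with columns `kind` (`CDS`, `tRNA`, `rRNA`, `tmRNA`
#'   or `other`), `start`, `end` (0-based half-open), `strand` (`+1`/`-1`) and
#'   `locus_id`.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features = NULL,
                             topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("genome sequence must be non-empty")
  if (grepl("[^ACGTN]", sequence))
    stop("genome sequence contains characters outside {A,C,G,T,N}")
  if (is.null(features)) {
    features <- tibble(kind = character(), start = integer(), end = integer(),
                       strand = integer(), locus_id = character())
  }
  features <- as_tibble(features)[, c("kind", "start", "end", "strand", "locus_id")]
  len <- nchar(sequence)
  ok_kind <- features$kind %in% c("CDS", "tRNA", "rRNA", "tmRNA", "other")
  if (!all(ok_kind)) stop("unknown feature kind: ", features$kind[!ok_kind][1])
  if (any(features$start >= features$end)) stop("feature with start >= end")
  if (any(features$start < 0L) || any(features$start >= len))
    stop("feature start outside [0, genome length)")
  max_end <- if (topology == "circular") 2L * len else len
  if (any(features$end > max_end)) stop("feature end beyond genome")
  if (anyDuplicated(features$locus_id)) stop("duplicate locus ids")
  structure(list(id = id, sequence = sequence, topology = topology,
                 features = features),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp (%s), %d features\n", x$id,
              format(nchar(x$sequence), big.mark = ","), x$topology,
              nrow(x$features)))
  invisible(x)
}

# ---- GenBank flat-file I/O -------------------------------------------------

.parse_gb_location <- function(loc, genome_len, topology) {
  strand <- 1L
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- -1L
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    m <- regmatches(parts, regexec("^(\\d+)\\.\\.(\\d+)$", parts))
    if (any(lengths(m) != 3)) return(NULL)
    starts <- as.integer(vapply(m, `[`, "", 2L))
    ends <- as.integer(vapply(m, `[`, "", 3L))
    # only circular origin-spanning joins are supported
    if (length(starts) == 2L && topology == "circular" &&
        ends[1] == genome_len && starts[2] == 1L) {
      return(list(start = starts[1] - 1L, end = genome_len + ends[2],
                  strand = strand))
    }
    return(NULL)
  }
  m <- regexec("^(\\d+)\\.\\.(\\d+)$", loc)
  g <- regmatches(loc, m)[[1]]
  if (length(g) != 3) {
    m1 <- regmatches(loc, regexec("^(\\d+)$", loc))[[1]]
    if (length(m1) == 2) {
      p <- as.integer(m1[2])
      return(list(start = p - 1L, end = p, strand = strand))
    }
    return(NULL)
  }
  list(start = as.integer(g[2]) - 1L, end = as.integer(g[3]), strand = strand)
}

#' Read a GenBank flat file
#'
#' Minimal reader for the LOCUS/FEATURES/ORIGIN dialect: sequence, topology
#' and `CDS`/`tRNA`/`rRNA`/`tmRNA` features (other feature keys are kept as
#' `other`; `source` and `gene` lines are skipped as they duplicate the CDS
#' annotation). Compound `join()` locations are supported only for
#' origin-spanning features of circular genomes; other compound locations are
#' dropped with a warning.
#'
#' @param path Path to a single-record GenBank flat file.
#' @param id Genome label; defaults to the LOCUS name.
#' @return An [annotated_genome].
#' @export
read_genbank <- function(path, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (!length(locus_i)) stop("malformed GenBank record: no LOCUS line in ", path)
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  topology <- if (any(tolower(locus) == "circular")) "circular" else "linear"
  if (is.null(id)) id <- locus[2]
  stated_len <- suppressWarnings(as.integer(locus[grep("^bp$", locus) - 1][1]))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (!length(orig_i)) stop("malformed GenBank record: no ORIGIN section (line ",
                            length(lines), ")")
  seq_lines <- lines[(orig_i[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste0(seq_lines, collapse = "")))
  if (grepl("[^ACGTN]", sequence))
    stop("unknown residue characters in ORIGIN of ", path)
  genome_len <- nchar(sequence)
  if (!is.na(stated_len) && stated_len != genome_len)
    warning("LOCUS length ", stated_len, " != sequence length ", genome_len)

  features <- tibble(kind = character(), start = integer(), end = integer(),
                     strand = integer(), locus_id = character())
  if (length(feat_i)) {
    fend <- if (length(orig_i)) orig_i[1] - 1L else length(lines)
    flines <- lines[(feat_i[1] + 1L):fend]
    # a feature header line has a key in columns 6-20 and a location after it
    is_key <- grepl("^ {5}\\S", flines)
    keys <- which(is_key)
    recs <- list()
    for (ki in seq_along(keys)) {
      i0 <- keys[ki]
      i1 <- if (ki < length(keys)) keys[ki + 1] - 1L else length(flines)
      header <- trimws(flines[i0])
      key <- sub("\\s.*$", "", header)
      loc <- trimws(sub("^\\S+\\s+", "", header))
      qual <- flines[seq.int(i0, i1)][-1]
      # location may continue before the first qualifier
      cont <- qual[!grepl("^\\s+/", qual)]
      if (length(cont)) loc <- paste0(loc, paste0(trimws(cont), collapse = ""))
      if (key %in% c("source", "gene")) next
      kind <- if (key %in% c("CDS", "tRNA", "rRNA", "tmRNA")) key else "other"
      lt <- regmatches(qual, regexec('/locus_tag="([^"]+)"', qual))
      lt <- unlist(lapply(lt, function(g) if (length(g) == 2) g[2] else NULL))
      locus_id <- if (length(lt)) lt[1] else sprintf("%s_f%04d", id, ki)
      parsed <- .parse_gb_location(loc, genome_len, topology)
      if (is.null(parsed)) {
        warning("dropping feature with unsupported compound location: ", loc)
        next
      }
      recs[[length(recs) + 1L]] <- tibble(kind = kind, start = parsed$start,
                                          end = parsed$end,
                                          strand = parsed$strand,
                                          locus_id = locus_id)
    }
    if (length(recs)) features <- dplyr::bind_rows(recs)
  }
  annotated_genome(id, sequence, features, topology)
}

#' Write a GenBank flat file
#'
#' @param genome An [annotated_genome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  len <- nchar(genome$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s   BCT",
                     genome$id, len, genome$topology), con)
  writeLines(sprintf("DEFINITION  %s synthetic annotated genome.", genome$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", len), con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    if (f$end[i] <= len) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    } else { # origin-spanning
      loc <- sprintf("join(%d..%d,1..%d)", f$start[i] + 1L, len, f$end[i] - len)
    }
    if (f$strand[i] < 0) loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", f$kind[i], loc), con)
    writeLines(sprintf('                     /locus_tag="%s"', f$locus_id[i]), con)
  }
  writeLines("ORIGIN", con)
  pos <- seq(1L, len, 60L)
  for (p in pos) {
    chunk <- substr(genome$sequence, p, min(p + 59L, len))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---- FASTA I/O -------------------------------------------------------------

#' Write a genome (and optionally its CDS set) as FASTA
#'
#' CDS headers carry the feature metadata needed to reconstruct the
#' annotation: `>locus_id kind=CDS loc=start..end strand=+/-` with 0-based
#' half-open coordinates.
#'
#' @param genome An [annotated_genome].
#' @param path Genome FASTA path.
#' @param cds_path Optional path for the companion feature FASTA.
#' @return `path`, invisibly.
#' @export
write_fasta_pair <- function(genome, path, cds_path = NULL) {
  x <- Biostrings::DNAStringSet(setNames(genome$sequence, paste0(
    genome$id, " topology=", genome$topology)))
  Biostrings::writeXStringSet(x, path, width = 70L)
  if (!is.null(cds_path)) {
    f <- genome$features
    seqs <- vapply(seq_len(nrow(f)), function(i)
      .feature_slice(genome, f$start[i], f$end[i], f$strand[i]), "")
    names(seqs) <- sprintf("%s kind=%s loc=%d..%d strand=%s", f$locus_id,
                           f$kind, f$start, f$end,
                           ifelse(f$strand > 0, "+", "-"))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), cds_path,
                                width = 70L)
  }
  invisible(path)
}

#' Read a genome from FASTA plus a feature FASTA
#'
#' Counterpart of [write_fasta_pair()]: features are reconstructed from the
#' coordinate metadata in the feature FASTA headers and verified against the
#' genome sequence.
#'
#' @param path Genome FASTA (single record).
#' @param cds_path Feature FASTA with `kind=`/`loc=`/`strand=` headers.
#' @param id Optional genome label override.
#' @return An [annotated_genome].
#' @export
read_fasta_pair <- function(path, cds_path = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) stop("genome FASTA must contain exactly one record: ", path)
  header <- names(x)[1]
  gid <- if (!is.null(id)) id else strsplit(header, "\\s+")[[1]][1]
  topology <- if (grepl("topology=circular", header)) "circular" else "linear"
  sequence <- as.character(x[[1]])
  features <- NULL
  if (!is.null(cds_path)) {
    y <- Biostrings::readDNAStringSet(cds_path)
    h <- names(y)
    locus <- sub("\\s.*$", "", h)
    kind <- sub(".*kind=(\\S+).*", "\\1", h)
    start <- as.integer(sub(".*loc=(\\d+)\\.\\..*", "\\1", h))
    end <- as.integer(sub(".*loc=\\d+\\.\\.(\\d+).*", "\\1", h))
    strand <- ifelse(grepl("strand=-", h), -1L, 1L)
    features <- tibble(kind = kind, start = start, end = end, strand = strand,
                      locus_id = locus)
    g <- annotated_genome(gid, sequence, features, topology)
    for (i in seq_len(nrow(features))) {
      got <- .feature_slice(g, start[i], end[i], strand[i])
      if (got != toupper(as.character(y[[i]])))
        stop("feature ", locus[i], " does not match its stated coordinates")
    }
    return(g)
  }
  annotated_genome(gid, sequence, features, topology)
}

#' Read an annotated genome in a standard format
#'
#' @param path GenBank flat file, or genome FASTA when `format = "fasta"`.
#' @param format `"genbank"` or `"fasta"` (the latter expects `cds_path`).
#' @param cds_path Companion feature FASTA for `format = "fasta"`.
#' @param id Optional genome label override.
#' @return An [annotated_genome].
#' @export
read_genome <- function(path, format = c("genbank", "fasta"), cds_path = NULL,
                        id = NULL) {
  format <- match.arg(format)
  if (format == "genbank") read_genbank(path, id = id)
  else read_fasta_pair(path, cds_path = cds_path, id = id)
}

# slice [start, end) on forward strand, wrapping past the origin if needed;
# reverse-complement for minus-strand features
.feature_slice <- function(genome, start, end, strand) {
  len <- nchar(genome$sequence)
  s <- if (end <= len) {
    substr(genome$sequence, start + 1L, end)
  } else {
    paste0(substr(genome$sequence, start + 1L, len),
           substr(genome$sequence, 1L, end - len))
  }
  if (strand < 0) .revcomp(s) else s
}

# ---- CDS extraction with QC ------------------------------------------------

#' Quality-control policy for extracted coding sequences
#'
#' Codon-level statistics need clean reading frames, so the default policy
#' drops genes whose length is not divisible by 3, genes shorter than 90 nt,
#' genes containing ambiguous bases, and genes with internal stop codons.
#'
#' @param min_len Minimum nucleotide length.
#' @param drop_ambiguous Drop genes containing `N`.
#' @param drop_internal_stop Drop genes with a stop codon before the last codon.
#' @param require_frame Drop genes whose length is not a multiple of 3.
#' @return A `qc_policy` list.
#' @export
qc_policy <- function(min_len = 90L, drop_ambiguous = TRUE,
                      drop_internal_stop = TRUE, require_frame = TRUE) {
  structure(list(min_len = as.integer(min_len), drop_ambiguous = drop_ambiguous,
                 drop_internal_stop = drop_internal_stop,
                 require_frame = require_frame), class = "qc_policy")
}

#' Extract coding sequences from an annotated genome
#'
#' Minus-strand features are reverse-complemented so every returned sequence
#' is the 5'->3' coding strand. Genes failing the QC policy are dropped and
#' listed in the `dropped` attribute (a tibble of locus ids and reasons).
#'
#' @param genome An [annotated_genome].
#' @param qc A [qc_policy()].
#' @return Tibble with columns `genome_id`, `locus_id`, `nt`, `aa` and
#'   `n_codons` (sense codons, terminal stop excluded), one row per retained
#'   CDS; attribute `dropped` logs the discarded genes.
#' @export
extract_cds <- function(genome, qc = qc_policy()) {
  f <- dplyr::filter(genome$features, .data$kind == "CDS")
  if (!nrow(f)) stop("genome ", genome$id, " has no CDS features")
  nt <- vapply(seq_len(nrow(f)), function(i)
    .feature_slice(genome, f$start[i], f$end[i], f$strand[i]), "")
  reason <- rep(NA_character_, length(nt))
  check <- function(bad, why) reason <<- ifelse(is.na(reason) & bad, why, reason)
  if (qc$require_frame) check(nchar(nt) %% 3L != 0L, "length not divisible by 3")
  check(nchar(nt) < qc$min_len, sprintf("shorter than %d nt", qc$min_len))
  if (qc$drop_ambiguous) check(grepl("N", nt, fixed = TRUE), "ambiguous base")
  if (qc$drop_internal_stop) {
    has_internal <- vapply(seq_along(nt), function(i) {
      if (!is.na(reason[i]) || nchar(nt[i]) %% 3L != 0L) return(FALSE)
      aa <- .translate_codons(.split_codons(nt[i]))
      any(aa[-length(aa)] == "*")
    }, TRUE)
    check(has_internal, "internal stop codon")
  }
  keep <- is.na(reason)
  dropped <- tibble(locus_id = f$locus_id[!keep], reason = reason[!keep])
  if (!any(keep)) stop("empty gene set: all CDS of ", genome$id, " failed QC")
  aa <- vapply(nt[keep], .translate_cds, "", USE.NAMES = FALSE)
  out <- tibble(genome_id = genome$id, locus_id = f$locus_id[keep],
                nt = nt[keep], aa = aa, n_codons = nchar(aa))
  attr(out, "dropped") <- dropped
  out
}

#' Extract QC-passing coding sequences for a whole panel
#'
#' @param genomes List of [annotated_genome] objects.
#' @param qc A [qc_policy()].
#' @return One tibble of coding sequences for all genomes (see
#'   [extract_cds()]).
#' @export
extract_cds_panel <- function(genomes, qc = qc_policy()) {
  ids <- vapply(genomes, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("genome ids must be unique within a panel")
  dplyr::bind_rows(lapply(genomes, extract_cds, qc = qc))
}

# ---- Genome summary --------------------------------------------------------

.interval_union_width <- function(starts, ends, genome_len) {
  if (!length(starts)) return(0L)
  # unwrap origin-spanning intervals into two pieces, then clip
  s <- c(starts, rep(0L, sum(ends > genome_len)))
  e <- c(pmin(ends, genome_len), ends[ends > genome_len] - genome_len)
  ir <- IRanges::IRanges(start = s + 1L, end = e)
  sum(IRanges::width(IRanges::reduce(ir)))
}

#' Summarize an annotated genome
#'
#' Reports length, GC content, feature counts and coding density. Coding
#' density is the fraction of the genome covered by the union of all
#' annotated features (CDS and RNA genes, overlaps counted once) — the usual
#' convention for highly reduced endosymbiont genomes; a CDS-only density is
#' reported alongside.
#'
#' @param genome An [annotated_genome].
#' @return One-row tibble: `id`, `length_bp`, `gc_percent`, `n_cds`, `n_trna`,
#'   `n_rrna`, `coding_density_percent` (all features) and
#'   `coding_density_cds_percent`.
#' @export
summarize_genome <- function(genome) {
  len <- nchar(genome$sequence)
  base_counts <- table(factor(strsplit(genome$sequence, "")[[1]],
                              levels = c("A", "C", "G", "T", "N")))
  acgt <- sum(base_counts[c("A", "C", "G", "T")])
  gc <- if (acgt > 0) 100 * sum(base_counts[c("G", "C")]) / acgt else 0
  f <- genome$features
  dens_all <- 100 * .interval_union_width(f$start, f$end, len) / len
  fc <- dplyr::filter(f, .data$kind == "CDS")
  dens_cds <- 100 * .interval_union_width(fc$start, fc$end, len) / len
  tibble(id = genome$id, length_bp = len, gc_percent = gc,
         n_cds = sum(f$kind == "CDS"), n_trna = sum(f$kind == "tRNA"),
         n_rrna = sum(f$kind == "rRNA"),
         coding_density_percent = dens_all,
         coding_density_cds_percent = dens_cds)
}

#' Summarize a panel of genomes
#'
#' @param genomes List of [annotated_genome] objects.
#' @return Tibble with one row per genome (see [summarize_genome()]).
#' @export
summarize_panel <- function(genomes) {
  dplyr::bind_rows(lapply(genomes, summarize_genome))
}

# ---- Table / tree writers --------------------------------------------------

#' Write result tables as TSV
#'
#' Writes each element of a named list of data frames to `<dir>/<name>.tsv`
#' with its column order preserved, so reruns are byte-identical.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) readr::write_tsv(tables[[i]], paths[i])
  invisible(paths)
}

#' Write a phylogenetic tree in Newick format
#'
#' @param tree An `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
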