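#' Configuration for the end-to-end pipeline
#'
#' @param input Either a named list of [annotated_genome] objects, or a
#'   character vector of file paths readable by [read_genome()].
#' @param format Input format for file paths (`"genbank"` or `"fasta"`).
#' @param out_dir Output directory for tables, trees and the manifest.
#' @param reference Genome id used as Ka/Ks reference; default the first
#'   genome (alphabetically) of the largest genetic group.
#' @param qc [qc_policy()] applied during CDS extraction.
#' @param groups `"auto"` (classify from ANI/AAI, the default) or a tibble
#'   `genome_id`/`group` declaring the groups.
#' @param ani_min,aai_min Group-classification thresholds (fractions).
#' @param mash_k,mash_s,mash_seed MinHash parameters.
#' @param mash_input `"cds"` (concatenated gene set, default) or
#'   `"genome"`.
#' @param seed Seed recorded in the manifest (the analysis stages are
#'   deterministic; the seed matters only when the input panel is
#'   simulated).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, format = "genbank",
                            reference = NULL, qc = qc_policy(),
                            groups = "auto", ani_min = 0.95, aai_min = 0.90,
                            mash_k = 21L, mash_s = 1000L, mash_seed = 42L,
                            mash_input = c("cds", "genome"), seed = 1L) {
  mash_input <- match.arg(mash_input)
  if (!is.list(input) && !is.character(input))
    stop("input must be a list of annotated genomes or a vector of paths")
  if (is.character(groups) && !identical(groups, "auto"))
    stop('groups must be "auto" or a genome_id/group data frame')
  structure(list(input = input, format = format, out_dir = out_dir,
                 reference = reference, qc = qc, groups = groups,
                 ani_min = ani_min, aai_min = aai_min,
                 mash_k = as.integer(mash_k), mash_s = as.integer(mash_s),
                 mash_seed = as.integer(mash_seed), mash_input = mash_input,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.matrix_to_tibble <- function(m) {
  dplyr::bind_cols(tibble(id = rownames(m)), as_tibble(m))
}

#' Run the full comparative-genomics pipeline
#'
#' Stages, in order: genome summaries; CDS extraction with QC; single-copy
#' orthology (reciprocal best hits); per-gene codon usage statistics;
#' ANI/AAI and genetic-group classification (or user-declared groups); PR2,
#' neutrality and ENC-plot analyses per group and per genome; Ka/Ks against
#' the reference; Mash distances; neighbor-joining tree. All tables are
#' written as TSV under `out_dir` together with a `manifest.json` recording
#' the configuration, a configuration hash and the MD5 of every output, so
#' a rerun with the same config is verifiably identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate result (summaries,
#'   cds, orthologs, codon stats, matrices, group assignment, bias
#'   summaries, kaks table, tree, manifest).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  genomes <- stage("load", {
    if (is.character(config$input)) {
      g <- lapply(config$input, read_genome, format = config$format)
      setNames(g, vapply(g, `[[`, "", "id"))
    } else config$input
  })
  if (length(genomes) < 2) stop("pipeline needs at least 2 genomes")

  summaries <- stage("summarize", summarize_panel(genomes))
  cds <- stage("extract_cds", extract_cds_panel(genomes, config$qc))
  orthologs <- stage("orthology", reciprocal_best_hits(cds))
  if (!nrow(orthologs)) stop("pipeline stage 'orthology' failed: no single-copy orthologs")
  stats <- stage("codon_stats", codon_usage_stats(cds))
  rel <- stage("ani_aai", relatedness_matrices(orthologs, cds))
  groups <- stage("classify", {
    if (identical(config$groups, "auto"))
      classify_groups(rel$ani, rel$aai, config$ani_min, config$aai_min)
    else as_tibble(config$groups)
  })
  reference <- config$reference
  if (is.null(reference)) {
    big <- names(sort(table(groups$group), decreasing = TRUE))[1]
    reference <- sort(groups$genome_id[groups$group == big])[1]
  }

  stats_grouped <- dplyr::left_join(stats, groups, by = "genome_id")
  bias_units <- c(split(stats_grouped, stats_grouped$group),
                  split(stats_grouped, stats_grouped$genome_id))
  bias <- stage("bias_analysis", lapply(names(bias_units), function(u) {
    d <- bias_units[[u]]
    list(unit = u,
         pr2 = tryCatch(pr2_summary(d, u), error = function(e) NULL),
         neutrality = tryCatch(neutrality_fit(d, u), error = function(e) NULL),
         encp = tryCatch(enc_plot_summary(d, u), error = function(e) NULL))
  }))
  names(bias) <- names(bias_units)

  kaks_tbl <- stage("kaks", kaks_vs_reference(orthologs, cds, reference))
  mash <- stage("mash", {
    x <- if (config$mash_input == "cds") cds else genomes
    mash_matrix(x, config$mash_k, config$mash_s, config$mash_seed)
  })
  tree <- stage("nj_tree", nj_tree(mash))

  pr2_tbl <- dplyr::bind_rows(lapply(bias, function(b)
    if (!is.null(b$pr2)) glance(b$pr2)))
  neut_tbl <- dplyr::bind_rows(lapply(bias, function(b)
    if (!is.null(b$neutrality)) glance(b$neutrality)))
  encp_tbl <- dplyr::bind_rows(lapply(bias, function(b)
    if (!is.null(b$encp)) glance(b$encp)))

  out <- config$out_dir
  tables <- list(
    genome_summary = summaries,
    cds_qc_drops = dplyr::bind_rows(lapply(genomes, function(g)
      attr(extract_cds(g, config$qc), "dropped"))),
    orthologs = orthologs,
    codon_stats = stats_grouped,
    pr2_summary = pr2_tbl,
    neutrality = neut_tbl,
    enc_plot = encp_tbl,
    kaks = kaks_tbl,
    groups = as_tibble(groups),
    ani = .matrix_to_tibble(rel$ani),
    aai = .matrix_to_tibble(rel$aai),
    mash = .matrix_to_tibble(mash))
  stage("write", {
    write_tables(tables, out)
    write_newick(tree, file.path(out, "tree.nwk"))
  })
  manifest <- stage("manifest", {
    cfg <- list(format = config$format, reference = reference,
                qc = unclass(config$qc),
                groups = if (identical(config$groups, "auto")) "auto" else "declared",
                ani_min = config$ani_min, aai_min = config$aai_min,
                mash = list(k = config$mash_k, s = config$mash_s,
                            hash_seed = config$mash_seed,
                            input = config$mash_input),
                kaks_method = "NG86 + Jukes-Cantor",
                gc3s_definition = "third positions of sense codons excluding ATG and TGG",
                seed = config$seed,
                package_version = as.character(utils::packageVersion("endosym")))
    cfg_hash <- .string_md5(jsonlite::toJSON(cfg, auto_unbox = TRUE))
    files <- sort(list.files(out, pattern = "\\.(tsv|nwk)$"))
    m <- list(config = cfg, config_hash = cfg_hash,
              files = setNames(as.list(unname(
                tools::md5sum(file.path(out, files)))), files))
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })
  invisible(list(genomes = genomes, summaries = summaries, cds = cds,
                 orthologs = orthologs, stats = stats_grouped,
                 relatedness = rel, groups = groups, reference = reference,
                 bias = bias, kaks = kaks_tbl, mash = mash, tree = tree,
                 tables = tables, manifest = manifest))
}

.string_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(x), tf)
  unname(tools::md5sum(tf))
}
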