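# Synthetic annotated-genome panels with controlled codon bias, divergence
# structure and selection strength. The generator emulates the statistical
# shape of a reduced, AT-rich endosymbiont panel: a few clades of small
# genomes, high within-clade identity, strong purifying selection, and
# clade-specific third-codon-position composition.

#' Specification of one clade of a synthetic panel
#'
#' @param name Clade label (used as genome id prefix).
#' @param n_genomes Number of genomes (tips) in the clade.
#' @param branch_in Expected substitutions/site from the panel root to the
#'   clade ancestor.
#' @param branch_within Expected substitutions/site from the clade ancestor
#'   to each tip.
#' @param omega Acceptance probability of nonsynonymous proposals
#'   (nonsynonymous/synonymous acceptance ratio); `omega < 1` is purifying
#'   selection.
#' @param kappa Transition/transversion rate ratio of the proposal process.
#' @param gc3_target Target GC fraction at third codon positions, in (0, 1).
#' @param pr2_skew Length-2 vector `(a_skew, g_skew)`: target values of
#'   `A3/(A3+T3)` and `G3/(G3+C3)`.
#' @param gc12_target GC fraction targeted at the first and second codon
#'   positions (0.5 = uniform); AT-rich endosymbiont proteomes sit near 0.3.
#' @return A `clade_spec` list.
#' @export
clade_spec <- function(name, n_genomes, branch_in, branch_within,
                       omega = 0.1, kappa = 2, gc3_target = 0.24,
                       pr2_skew = c(0.6, 0.6), gc12_target = 0.32) {
  stopifnot(n_genomes >= 1, branch_in >= 0, branch_within >= 0, omega >= 0,
            kappa > 0, gc3_target > 0, gc3_target < 1,
            all(pr2_skew > 0), all(pr2_skew < 1),
            gc12_target > 0, gc12_target < 1)
  structure(list(name = name, n_genomes = as.integer(n_genomes),
                 branch_in = branch_in, branch_within = branch_within,
                 omega = omega, kappa = kappa, gc3_target = gc3_target,
                 pr2_skew = pr2_skew, gc12_target = gc12_target),
            class = "clade_spec")
}

#' Specification of a synthetic genome panel
#'
#' Defaults follow the shape of a small-endosymbiont panel: ~250 genes per
#' genome averaging 150 codons (genes of roughly 180-720 nt), ~91% coding
#' density and AT-rich composition.
#'
#' @param clades List of [clade_spec()] objects.
#' @param n_genes Genes per genome (no gene gain/loss is simulated).
#' @param mean_gene_len Mean gene length in codons.
#' @param coding_density Target fraction of the genome covered by genes.
#' @param seed Integer seed; recorded in the output so panels are
#'   reproducible bit-for-bit.
#' @return A `panel_spec` list.
#' @export
panel_spec <- function(clades, n_genes = 250L, mean_gene_len = 150L,
                       coding_density = 0.91, seed = 1L) {
  stopifnot(length(clades) >= 1, n_genes >= 1,
            coding_density > 0, coding_density <= 1)
  structure(list(clades = clades, n_genes = as.integer(n_genes),
                 mean_gene_len = as.integer(mean_gene_len),
                 coding_density = coding_density, seed = as.integer(seed)),
            class = "panel_spec")
}

#' A ready-made three-clade panel specification
#'
#' Three clades of 4, 3 and 2 genomes with short within-clade branches
#' (0.01 substitutions/site) and long stem branches (0.15), omega = 0.1 and
#' clade-specific third-position composition — the divergence structure of a
#' panel that separates cleanly into three genetic groups under the
#' ANI > 95% / AAI > 90% criteria.
#'
#' @param n_genes Genes per genome.
#' @param seed Integer seed.
#' @param mean_gene_len Mean gene length in codons.
#' @return A [panel_spec()].
#' @export
example_panel_spec <- function(n_genes = 200L, seed = 1L, mean_gene_len = 150L) {
  panel_spec(
    clades = list(
      clade_spec("A", 4, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.14, pr2_skew = c(0.62, 0.62), gc12_target = 0.28),
      clade_spec("B", 3, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.18, pr2_skew = c(0.58, 0.60), gc12_target = 0.28),
      clade_spec("C", 2, branch_in = 0.15, branch_within = 0.01,
                 gc3_target = 0.22, pr2_skew = c(0.60, 0.56), gc12_target = 0.28)),
    n_genes = n_genes, mean_gene_len = mean_gene_len, seed = seed)
}

#' Codon probability profile from composition targets
#'
#' Builds the codon distribution used to draw synthetic genes: a product of
#' per-position base distributions — first and second positions set by
#' `gc12_target` (uniform by default), third-position base probabilities by
#' `gc3_target` and the PR2 skews (`P(A3) = (1-gc3) a_skew`,
#' `P(T3) = (1-gc3)(1-a_skew)`, `P(G3) = gc3 g_skew`,
#' `P(C3) = gc3 (1-g_skew)`), conditioned on sense codons. Excluding the
#' three stop codons perturbs the realized composition by well under 0.02,
#' so the expected GC3 of a long random gene stays within the stated band of
#' the target; the construction errors out if it would not.
#'
#' @param gc3_target Target GC3 in (0, 1).
#' @param pr2_skew Length-2 vector `(a_skew, g_skew)`.
#' @param gc12_target GC fraction of the base distribution at the first and
#'   second positions; the default 0.5 keeps those positions uniform (and
#'   within-family probabilities exactly uniform at neutral targets), while
#'   AT-rich proteomes call for ~0.3.
#' @return A `codon_profile` tibble: `codon`, `aa`, `p` (global sense-codon
#'   probability) and `p_family` (probability within the codon's synonymous
#'   family, summing to 1 per amino acid).
#' @export
build_codon_profile <- function(gc3_target, pr2_skew = c(0.5, 0.5),
                                gc12_target = 0.5) {
  stopifnot(gc3_target > 0, gc3_target < 1,
            length(pr2_skew) == 2, all(pr2_skew > 0), all(pr2_skew < 1),
            gc12_target > 0, gc12_target < 1)
  a_skew <- pr2_skew[[1]]; g_skew <- pr2_skew[[2]]
  p3 <- c(A = (1 - gc3_target) * a_skew, T = (1 - gc3_target) * (1 - a_skew),
          G = gc3_target * g_skew, C = gc3_target * (1 - g_skew))
  p12 <- c(A = (1 - gc12_target) / 2, T = (1 - gc12_target) / 2,
           G = gc12_target / 2, C = gc12_target / 2)
  w <- p12[substr(.SENSE_CODONS, 1, 1)] * p12[substr(.SENSE_CODONS, 2, 2)] *
    p3[substr(.SENSE_CODONS, 3, 3)]
  p <- w / sum(w)
  aa <- unname(.CODON_AA[.SENSE_CODONS])
  prof <- tibble(codon = .SENSE_CODONS, aa = aa, p = unname(p)) |>
    dplyr::group_by(.data$aa) |>
    dplyr::mutate(p_family = .data$p / sum(.data$p)) |>
    dplyr::ungroup()
  third_gc <- substr(prof$codon, 3, 3) %in% c("G", "C")
  expected_gc3 <- sum(prof$p[third_gc])
  if (abs(expected_gc3 - gc3_target) > 0.02)
    stop("infeasible joint targets: expected GC3 ", round(expected_gc3, 4),
         " deviates from gc3_target ", gc3_target,
         " by more than 0.02 (stop-codon exclusion is the binding constraint)")
  attr(prof, "gc3_target") <- gc3_target
  attr(prof, "pr2_skew") <- c(a_skew = a_skew, g_skew = g_skew)
  attr(prof, "expected_gc3") <- expected_gc3
  class(prof) <- c("codon_profile", class(prof))
  prof
}

# overall base frequencies (A, C, G, T) implied by a codon profile
.profile_base_freqs <- function(profile) {
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (pos in 1:3) {
    b <- substr(profile$codon, pos, pos)
    for (k in names(counts)) counts[k] <- counts[k] + sum(profile$p[b == k])
  }
  counts / sum(counts)
}

.sample_gene <- function(len_codons, profile, stop_weights = c(TAA = 0.7, TAG = 0.15, TGA = 0.15)) {
  body <- sample(profile$codon, len_codons - 2L, replace = TRUE, prob = profile$p)
  stop <- sample(names(stop_weights), 1L, prob = stop_weights)
  paste0(c("ATG", body, stop), collapse = "")
}

#' Generate the ancestral genome of a synthetic panel
#'
#' Draws `n_genes` genes (ATG start, stop end, no internal stops) from the
#' root codon profile (the average of the clade targets), places them on
#' random strands separated by intergenic spacers drawn i.i.d. from the
#' genes' background base composition, and sizes the spacers to hit the
#' requested coding density.
#'
#' @param spec A [panel_spec()]. Uses the current RNG state; seed the stream
#'   with `set.seed(spec$seed)` (as [generate_panel()] does) for
#'   reproducibility.
#' @return An [annotated_genome] with one CDS feature per gene.
#' @export
generate_ancestor <- function(spec) {
  gc3 <- mean(vapply(spec$clades, `[[`, 0, "gc3_target"))
  skew <- rowMeans(vapply(spec$clades, `[[`, c(0, 0), "pr2_skew"))
  gc12 <- mean(vapply(spec$clades, `[[`, 0, "gc12_target"))
  profile <- build_codon_profile(gc3, skew, gc12)
  lens <- pmax(32L, round(runif(spec$n_genes, 0.4, 1.6) * spec$mean_gene_len))
  genes <- vapply(lens, .sample_gene, "", profile = profile)
  strands <- sample(c(1L, -1L), spec$n_genes, replace = TRUE)
  total_gene <- sum(nchar(genes))
  genome_len <- round(total_gene / spec$coding_density)
  spacer_total <- max(0L, genome_len - total_gene)
  cuts <- sort(sample.int(spacer_total + 1L, spec$n_genes, replace = TRUE) - 1L)
  spacer_lens <- diff(c(0L, cuts, spacer_total))  # n_genes + 1 blocks
  bg <- .profile_base_freqs(profile)
  spacers <- vapply(spacer_lens, function(L)
    paste0(sample(names(bg), L, replace = TRUE, prob = bg), collapse = ""), "")
  pieces <- character(0)
  feats <- vector("list", spec$n_genes)
  pos <- 0L
  for (i in seq_len(spec$n_genes)) {
    pieces <- c(pieces, spacers[i])
    pos <- pos + nchar(spacers[i])
    on_genome <- if (strands[i] > 0) genes[i] else .revcomp(genes[i])
    pieces <- c(pieces, on_genome)
    feats[[i]] <- tibble(kind = "CDS", start = pos,
                         end = pos + nchar(genes[i]), strand = strands[i],
                         locus_id = sprintf("g%04d", i))
    pos <- pos + nchar(genes[i])
  }
  pieces <- c(pieces, spacers[spec$n_genes + 1L])
  g <- annotated_genome("ANC", paste0(pieces, collapse = ""),
                        dplyr::bind_rows(feats), topology = "circular")
  attr(g, "profile") <- profile
  g
}

#' Evolve a coding sequence along a branch
#'
#' Codon-level rejection simulation of substitution under purifying
#' selection: nucleotide changes are proposed per site at rate `t` (expected
#' proposals/site over the branch) with HKY-style transition bias `kappa`
#' and proposal base frequencies `pi`; proposals creating a stop codon are
#' rejected (the terminal stop may only change into another stop),
#' synonymous proposals are always accepted, and nonsynonymous proposals
#' are accepted with probability `omega`.
#'
#' @param nt In-frame coding sequence (ATG...stop).
#' @param t Branch length (expected proposals per site), >= 0.
#' @param kappa Transition/transversion rate ratio.
#' @param omega Nonsynonymous acceptance probability.
#' @param pi Proposal base frequencies, named `A`, `C`, `G`, `T`.
#' @return The evolved coding sequence (same length).
#' @export
evolve_cds <- function(nt, t, kappa = 2, omega = 0.1,
                       pi = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(t >= 0, kappa > 0, omega >= 0)
  if (t == 0) return(nt)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  x <- strsplit(toupper(nt), "")[[1]]
  L <- length(x)
  n_codons <- L %/% 3L
  n_events <- rpois(1L, L * t)
  if (n_events == 0) return(nt)
  positions <- sample.int(L, n_events, replace = TRUE)
  for (pos in positions) {
    cur <- x[pos]
    alt <- setdiff(bases, cur)
    wts <- pi[alt] * ifelse(alt == transition[[cur]], kappa, 1)
    prop <- sample(alt, 1L, prob = wts)
    ci <- (pos - 1L) %/% 3L
    codon <- paste0(x[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    new_codon <- codon
    substr(new_codon, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- prop
    aa_old <- .CODON_AA[[codon]]
    aa_new <- .CODON_AA[[new_codon]]
    accept <- if (aa_old == "*") {
      aa_new == "*"                      # terminal stop may switch stop codons
    } else if (aa_new == "*") {
      FALSE                              # no premature stops
    } else if (aa_new == aa_old) {
      TRUE
    } else {
      runif(1) < omega
    }
    if (accept) x[pos] <- prop
  }
  paste0(x, collapse = "")
}

# neutral substitution of non-coding sequence (spacers)
.evolve_neutral <- function(seq, t, kappa, pi) {
  if (t == 0 || !nzchar(seq)) return(seq)
  x <- strsplit(seq, "")[[1]]
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  bases <- c("A", "C", "G", "T")
  n_events <- rpois(1L, length(x) * t)
  if (!n_events) return(seq)
  positions <- sample.int(length(x), n_events, replace = TRUE)
  for (pos in positions) {
    alt <- setdiff(bases, x[pos])
    wts <- pi[alt] * ifelse(alt == transition[[x[pos]]], kappa, 1)
    x[pos] <- sample(alt, 1L, prob = wts)
  }
  paste0(x, collapse = "")
}

# rebuild a genome from evolved genes, preserving the ancestral layout
.rebuild_genome <- function(ancestor, genes, spacers, id) {
  f <- ancestor$features
  pieces <- character(0)
  for (i in seq_len(nrow(f))) {
    pieces <- c(pieces, spacers[i],
                if (f$strand[i] > 0) genes[i] else .revcomp(genes[i]))
  }
  pieces <- c(pieces, spacers[nrow(f) + 1L])
  feats <- f
  feats$locus_id <- sprintf("%s_%s", id, f$locus_id)
  annotated_genome(id, paste0(pieces, collapse = ""), feats, ancestor$topology)
}

# split a genome back into its gene strings (coding strand) and spacers
.genome_parts <- function(genome) {
  f <- genome$features
  genes <- vapply(seq_len(nrow(f)), function(i)
    .feature_slice(genome, f$start[i], f$end[i], f$strand[i]), "")
  bounds <- c(0L, as.vector(rbind(f$start, f$end)), nchar(genome$sequence))
  spacers <- vapply(seq_len(nrow(f) + 1L), function(i)
    substr(genome$sequence, bounds[2L * i - 1L] + 1L, bounds[2L * i]), "")
  list(genes = genes, spacers = spacers)
}

#' Generate a synthetic genome panel with known truth
#'
#' Seeds the RNG from the spec, draws an ancestral genome, evolves a clade
#' ancestor along each clade's stem branch using clade-specific proposal
#' base frequencies (so third-position composition drifts toward the
#' clade's profile), then evolves each tip from its clade ancestor.
#' Intergenic spacers evolve neutrally at the same rates.
#'
#' @param spec A [panel_spec()].
#' @return List with `genomes` (named list of [annotated_genome]), `truth`
#'   (tibble `genome_id`, `clade`, `t_root`: expected proposals/site from
#'   the root), `tree` (the true `ape::phylo` topology with branch
#'   lengths), `ancestor`, and `spec`.
#' @export
generate_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  set.seed(spec$seed)
  ancestor <- generate_ancestor(spec)
  parts <- .genome_parts(ancestor)
  genomes <- list()
  truth <- list()
  tip_strings <- character(0)
  for (cl in spec$clades) {
    prof <- build_codon_profile(cl$gc3_target, cl$pr2_skew, cl$gc12_target)
    pi <- .profile_base_freqs(prof)
    cl_genes <- vapply(parts$genes, evolve_cds, "", t = cl$branch_in,
                       kappa = cl$kappa, omega = cl$omega, pi = pi,
                       USE.NAMES = FALSE)
    cl_spacers <- vapply(parts$spacers, .evolve_neutral, "", t = cl$branch_in,
                         kappa = cl$kappa, pi = pi, USE.NAMES = FALSE)
    tips <- character(0)
    for (g in seq_len(cl$n_genomes)) {
      gid <- sprintf("%s%d", cl$name, g)
      tip_genes <- vapply(cl_genes, evolve_cds, "", t = cl$branch_within,
                          kappa = cl$kappa, omega = cl$omega, pi = pi,
                          USE.NAMES = FALSE)
      tip_spacers <- vapply(cl_spacers, .evolve_neutral, "",
                            t = cl$branch_within, kappa = cl$kappa, pi = pi,
                            USE.NAMES = FALSE)
      genomes[[gid]] <- .rebuild_genome(ancestor, tip_genes, tip_spacers, gid)
      truth[[gid]] <- tibble(genome_id = gid, clade = cl$name,
                             t_root = cl$branch_in + cl$branch_within)
      tips <- c(tips, sprintf("%s:%g", gid, cl$branch_within))
    }
    tip_strings <- c(tip_strings,
                     if (length(tips) > 1)
                       sprintf("(%s):%g", paste(tips, collapse = ","), cl$branch_in)
                     else sprintf("%s:%g", sub(":.*", "", tips),
                                  cl$branch_in + cl$branch_within))
  }
  tree <- ape::read.tree(text = sprintf("(%s);", paste(tip_strings, collapse = ",")))
  list(genomes = genomes, truth = dplyr::bind_rows(truth), tree = tree,
       ancestor = ancestor, spec = spec)
}

#' Write a synthetic panel to disk
#'
#' Writes each genome as a GenBank flat file and a FASTA pair, the truth
#' table as TSV and the true tree as Newick.
#'
#' @param panel Result of [generate_panel()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (g in panel$genomes) {
    write_genbank(g, file.path(dir, paste0(g$id, ".gbk")))
    write_fasta_pair(g, file.path(dir, paste0(g$id, ".fna")),
                     file.path(dir, paste0(g$id, ".cds.fna")))
  }
  readr::write_tsv(panel$truth, file.path(dir, "truth.tsv"))
  write_newick(panel$tree, file.path(dir, "true_tree.nwk"))
  invisible(dir)
}
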