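# Pairwise genome relatedness: ortholog-based ANI/AAI, MinHash (Mash)
# distances, neighbor-joining tree, and threshold-based group classification.

.pair_identities <- function(orthologs, cds, a, b) {
  ga <- orthologs[orthologs$genome_id == a, ]
  gb <- orthologs[orthologs$genome_id == b, ]
  shared <- intersect(ga$group_id, gb$group_id)
  if (!length(shared)) stop("no shared single-copy orthologs between ",
                            a, " and ", b)
  seqs <- setNames(cds$nt, paste(cds$genome_id, cds$locus_id, sep = "\r"))
  nt_match <- nt_tot <- aa_match <- aa_tot <- 0
  for (g in sort(shared)) {
    la <- ga$locus_id[ga$group_id == g]
    lb <- gb$locus_id[gb$group_id == g]
    aln <- codon_align(seqs[[paste(a, la, sep = "\r")]],
                       seqs[[paste(b, lb, sep = "\r")]])
    cols <- .alignment_codons(aln, ungapped = TRUE)
    if (ncol(cols)) {
      xa <- strsplit(paste0(cols[1, ], collapse = ""), "")[[1]]
      xb <- strsplit(paste0(cols[2, ], collapse = ""), "")[[1]]
      nt_match <- nt_match + sum(xa == xb)
      nt_tot <- nt_tot + length(xa)
    }
    pa <- strsplit(aln$aligned_aa_a, "")[[1]]
    pb <- strsplit(aln$aligned_aa_b, "")[[1]]
    keep <- pa != "-" & pb != "-"
    aa_match <- aa_match + sum(pa[keep] == pb[keep])
    aa_tot <- aa_tot + sum(keep)
  }
  c(ani = nt_match / nt_tot, aai = aa_match / aa_tot)
}

#' Average nucleotide identity between two genomes
#'
#' Mean nucleotide identity over the ungapped codon columns of the
#' codon-aware alignments of all shared single-copy orthologs, weighted by
#' aligned length.
#'
#' @param orthologs Ortholog table from [reciprocal_best_hits()].
#' @param cds Panel tibble from [extract_cds_panel()].
#' @param a,b Genome ids.
#' @return ANI as a fraction in `[0, 1]`.
#' @export
ani <- function(orthologs, cds, a, b) {
  if (identical(a, b)) return(1)
  .pair_identities(orthologs, cds, a, b)[["ani"]]
}

#' Average amino-acid identity between two genomes
#'
#' As [ani()] but on the protein alignments: identical residues over
#' gap-free aligned columns, length-weighted over shared orthologs.
#'
#' @inheritParams ani
#' @return AAI as a fraction in `[0, 1]`.
#' @export
aai <- function(orthologs, cds, a, b) {
  if (identical(a, b)) return(1)
  .pair_identities(orthologs, cds, a, b)[["aai"]]
}

#' ANI and AAI matrices for a genome panel
#'
#' @inheritParams ani
#' @return List with symmetric matrices `ani` and `aai` (diagonal 1) over
#'   the genomes of the ortholog table, plus a tidy `pairs` tibble.
#' @export
relatedness_matrices <- function(orthologs, cds) {
  genomes <- sort(unique(orthologs$genome_id))
  n <- length(genomes)
  ani_m <- aai_m <- matrix(1, n, n, dimnames = list(genomes, genomes))
  pairs <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      id <- .pair_identities(orthologs, cds, genomes[i], genomes[j])
      ani_m[i, j] <- ani_m[j, i] <- id[["ani"]]
      aai_m[i, j] <- aai_m[j, i] <- id[["aai"]]
      pairs[[length(pairs) + 1L]] <- tibble(a = genomes[i], b = genomes[j],
                                            ani = id[["ani"]], aai = id[["aai"]])
    }
  }
  list(ani = ani_m, aai = aai_m, pairs = dplyr::bind_rows(pairs))
}

# ---- MinHash / Mash --------------------------------------------------------

#' MinHash sketch of a nucleotide sequence
#'
#' Bottom-s sketch of the 64-bit hashes (masked to 53 bits) of canonical
#' k-mers (the lexicographic minimum of each k-mer and its reverse
#' complement); k-mers containing ambiguous bases are skipped. Defaults
#' match the Mash/Mashtree convention (k = 21, s = 1000).
#'
#' @param x Nucleotide string, [annotated_genome], or tibble of coding
#'   sequences (whose `nt` column is concatenated in row order).
#' @param k K-mer size (<= 31).
#' @param s Sketch size.
#' @param hash_seed Seed of the hash function; sketches are only comparable
#'   at equal `k`, `s` and `hash_seed`.
#' @param id Label stored with the sketch.
#' @return A `minhash_sketch`: `id`, `k`, `s`, `hash_seed` and the sorted
#'   `hashes`.
#' @export
minhash_sketch <- function(x, k = 21L, s = 1000L, hash_seed = 42L, id = NULL) {
  if (inherits(x, "annotated_genome")) {
    if (is.null(id)) id <- x$id
    x <- x$sequence
  } else if (is.data.frame(x)) {
    if (is.null(id) && "genome_id" %in% names(x)) id <- x$genome_id[1]
    x <- paste0(x$nt, collapse = "")
  }
  if (nchar(x) < k) stop("sequence shorter than k = ", k)
  h <- .cpp_minhash_sketch(toupper(x), as.integer(k), as.integer(s),
                           as.numeric(hash_seed))
  structure(list(id = if (is.null(id)) "seq" else id, k = as.integer(k),
                 s = as.integer(s), hash_seed = as.integer(hash_seed),
                 hashes = h),
            class = "minhash_sketch")
}

#' Mash distance between two sketches
#'
#' Estimates the k-mer Jaccard index `j` from the joint bottom-s sketch (the
#' s smallest distinct hashes of the union; the fraction of them present in
#' both sketches) and converts it to a distance
#' `d = -log(2j / (1 + j)) / k`. Disjoint sketches give `Inf`.
#'
#' @param sa,sb `minhash_sketch` objects with equal `k`, `s`, `hash_seed`.
#' @return List with `jaccard` and `distance`.
#' @export
mash_distance <- function(sa, sb) {
  stopifnot(inherits(sa, "minhash_sketch"), inherits(sb, "minhash_sketch"))
  if (sa$k != sb$k || sa$s != sb$s || sa$hash_seed != sb$hash_seed)
    stop("sketch parameter mismatch (k, s, hash_seed must agree)")
  merged <- sort(unique(c(sa$hashes, sb$hashes)))
  merged <- head(merged, sa$s)
  shared <- sum(merged %in% sa$hashes & merged %in% sb$hashes)
  j <- shared / length(merged)
  d <- if (j <= 0) Inf else -log(2 * j / (1 + j)) / sa$k
  if (j >= 1) d <- 0
  list(jaccard = j, distance = d)
}

#' Mash distance matrix for a genome panel
#'
#' @param genomes List of [annotated_genome] objects, or a panel tibble of
#'   coding sequences from [extract_cds_panel()] (the default input: the
#'   concatenated gene set of each genome is sketched).
#' @inheritParams minhash_sketch
#' @return Symmetric matrix of Mash distances (diagonal 0).
#' @export
mash_matrix <- function(genomes, k = 21L, s = 1000L, hash_seed = 42L) {
  sketches <- if (is.data.frame(genomes)) {
    ids <- unique(genomes$genome_id)
    lapply(ids, function(g)
      minhash_sketch(genomes[genomes$genome_id == g, ], k, s, hash_seed, id = g))
  } else {
    lapply(genomes, minhash_sketch, k = k, s = s, hash_seed = hash_seed)
  }
  ids <- vapply(sketches, `[[`, "", "id")
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    d <- mash_distance(sketches[[i]], sketches[[j]])$distance
    m[i, j] <- m[j, i] <- d
  }
  m
}

# ---- Neighbor joining and group classification -----------------------------

#' Neighbor-joining tree from a distance matrix
#'
#' Classical Saitou-Nei neighbor joining (via \pkg{ape}); negative branch
#' lengths, which NJ can produce on non-additive matrices, are clamped to
#' zero with the deficit moved to a sibling branch so path lengths are
#' approximately preserved.
#'
#' @param d Symmetric non-negative distance matrix with labels as dimnames.
#' @param clamp_negative Apply the negative-branch correction.
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(d, clamp_negative = TRUE) {
  stopifnot(is.matrix(d), isTRUE(all.equal(d, t(d))))
  if (nrow(d) < 2) stop("need at least 2 taxa")
  if (nrow(d) == 2) { # trivial two-tip tree
    tree <- structure(list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
                           edge.length = rep(d[1, 2] / 2, 2),
                           tip.label = rownames(d), Nnode = 1L),
                      class = "phylo", order = "cladewise")
    return(tree)
  }
  tree <- ape::nj(as.dist(d))
  if (clamp_negative && !is.null(tree$edge.length)) {
    repeat {
      neg <- which(tree$edge.length < 0)
      if (!length(neg)) break
      i <- neg[1]
      deficit <- tree$edge.length[i]
      tree$edge.length[i] <- 0
      sibs <- setdiff(which(tree$edge[, 1] == tree$edge[i, 1]), i)
      if (length(sibs)) {
        tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] + deficit
        if (tree$edge.length[sibs[1]] < 0) tree$edge.length[sibs[1]] <- 0
      }
    }
  }
  tree
}

#' Classify genomes into genetic groups by ANI/AAI thresholds
#'
#' Builds a graph with an edge between two genomes iff `ANI > ani_min` and
#' `AAI > aai_min` (strict inequalities) and reports the connected
#' components as genetic groups. The defaults are the conventional
#' prokaryotic relatedness thresholds ANI > 95% and AAI > 90%.
#'
#' @param ani_m,aai_m Symmetric identity matrices on the same panel (as from
#'   [relatedness_matrices()]).
#' @param ani_min,aai_min Thresholds as fractions.
#' @return A `group_assignment` tibble with columns `genome_id` and `group`
#'   (`G1`, `G2`, ... in order of first appearance); thresholds are stored
#'   as attributes.
#' @export
classify_groups <- function(ani_m, aai_m, ani_min = 0.95, aai_min = 0.90) {
  stopifnot(identical(dimnames(ani_m), dimnames(aai_m)))
  ids <- rownames(ani_m)
  adj <- (ani_m > ani_min) & (aai_m > aai_min)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- paste0("G", match(comp, unique(comp)))
  out <- tibble(genome_id = ids, group = labels)
  attr(out, "ani_min") <- ani_min
  attr(out, "aai_min") <- aai_min
  class(out) <- c("group_assignment", class(out))
  out
}
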