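test_that("ANI/AAI of identical gene sets is 1 and mismatches count linearly", {
  cds <- small_cds()
  g1 <- cds[cds$genome_id == "A1", ]
  g2 <- g1; g2$genome_id <- "X"
  og <- reciprocal_best_hits(rbind(g1, g2))
  expect_equal(ani(og, rbind(g1, g2), "A1", "X"), 1)
  expect_equal(aai(og, rbind(g1, g2), "A1", "X"), 1)

  # one 100-codon gene with 2 nucleotide mismatches -> ANI 2/300 below 1
  a <- random_cds(100, seed = 13)
  b <- a
  substr(b, 10, 10) <- if (substr(a, 10, 10) == "A") "T" else "A"
  substr(b, 22, 22) <- if (substr(a, 22, 22) == "A") "T" else "A"
  two <- tibble::tibble(genome_id = c("p", "q"), locus_id = c("x", "y"),
                        nt = c(a, b), aa = c("", ""))
  two$aa <- vapply(two$nt, function(s) {
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
          genetic.code = Biostrings::getGeneticCode("11")))
    sub("\\*$", "", aa)
  }, "")
  og2 <- reciprocal_best_hits(two)
  expect_equal(ani(og2, two, "p", "q"), 1 - 2 / (3 * 99), tolerance = 1e-12)
})

test_that("minhash sketches canonicalize and estimate Jaccard accurately", {
  set.seed(8)
  s <- paste0(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  sk1 <- minhash_sketch(s, id = "fwd")
  sk2 <- minhash_sketch(as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s))), id = "rev")
  expect_identical(sk1$hashes, sk2$hashes)
  expect_equal(mash_distance(sk1, sk2)$distance, 0)
  expect_error(minhash_sketch("ACGT", k = 21), "shorter")
  expect_error(mash_distance(sk1, minhash_sketch(s, k = 15)), "mismatch")

  # sketch Jaccard vs exact k-mer-set Jaccard on a diverged 20 kb pair
  exact_jaccard <- function(x, y, k = 21) {
    canon <- function(z) {
      km <- substring(z, 1:(nchar(z) - k + 1), k:nchar(z))
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
      unique(pmin(km, rc))
    }
    a <- canon(x); b <- canon(y)
    length(intersect(a, b)) / length(union(a, b))
  }
  x <- paste0(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  y <- .evolve_seq_for_test(x, 0.02)
  skx <- minhash_sketch(x, id = "x"); sky <- minhash_sketch(y, id = "y")
  expect_lt(abs(mash_distance(skx, sky)$jaccard - exact_jaccard(x, y)), 0.05)
})

test_that("mash distance follows the closed-form Jaccard transform", {
  fake <- function(h) structure(list(id = "f", k = 21L, s = 10L,
                                     hash_seed = 42L, hashes = h),
                                class = "minhash_sketch")
  sa <- fake(as.numeric(1:10))
  sb <- fake(as.numeric(c(1:9, 101)))  # joint bottom-10 shares 9 of 10
  d <- mash_distance(sa, sb)
  expect_equal(d$jaccard, 0.9)
  expect_equal(d$distance, -log(1.8 / 1.9) / 21, tolerance = 1e-9)
  expect_true(is.infinite(mash_distance(sa, fake(as.numeric(101:110)))$distance))
})

test_that("neighbor joining recovers additive distances exactly", {
  # 3 taxa: branch lengths from the three-point formulas
  d3 <- matrix(c(0, 5, 9, 5, 0, 10, 9, 10, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d3)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(bl[c("a", "b", "c")]), c(2, 3, 7))

  # 4 taxa, additive on ((a,b),(c,d)): topology recovered
  tree_txt <- "((a:1,b:2):3,(c:1.5,d:2.5):0);"
  tr_true <- ape::read.tree(text = tree_txt)
  d4 <- ape::cophenetic.phylo(tr_true)
  tr4 <- nj_tree(d4[order(rownames(d4)), order(colnames(d4))])
  expect_equal(ape::dist.topo(ape::unroot(tr4), ape::unroot(tr_true)), 0,
               ignore_attr = TRUE)

  # permuting the label order leaves the unrooted topology unchanged
  p <- c(3, 1, 4, 2)
  tr4p <- nj_tree(d4[p, p])
  expect_equal(ape::dist.topo(ape::unroot(tr4p), ape::unroot(tr4)), 0,
               ignore_attr = TRUE)
})

test_that("NJ reproduces random additive trees and clamps negative branches", {
  withr::with_seed(19, {
    for (rep in 1:10) {
      tr_true <- ape::rtree(6)
      d <- ape::cophenetic.phylo(tr_true)
      tr <- nj_tree(d)
      expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(tr_true)), 0,
                   ignore_attr = TRUE)
    }
  })
  # a non-additive matrix that drives NJ negative still yields lengths >= 0
  d <- matrix(c(0, 1, 1, 1, 10,
                1, 0, 1, 1, 10,
                1, 1, 0, 1, 10,
                1, 1, 1, 0, 1,
                10, 10, 10, 1, 0), 5, 5,
              dimnames = list(letters[1:5], letters[1:5]))
  tr <- nj_tree(d)
  expect_true(all(tr$edge.length >= 0))
})

test_that("threshold classification matches the published matrix pattern", {
  ids <- c("BTB", "BTQ", "BTZ1", "BTZ3", "AdSh", "PeMo", "TrVa", "AlDi", "AlFl")
  bm <- ids[1:4]; ad <- ids[5:7]; al <- ids[8:9]
  ani_m <- matrix(0.88, 9, 9, dimnames = list(ids, ids))
  aai_m <- matrix(0.82, 9, 9, dimnames = list(ids, ids))
  ani_m[bm, bm] <- 0.995; aai_m[bm, bm] <- 0.995
  ani_m[ad, ad] <- 0.96;  aai_m[ad, ad] <- 0.93
  ani_m[al, al] <- 0.98;  aai_m[al, al] <- 0.98
  diag(ani_m) <- diag(aai_m) <- 1
  ga <- classify_groups(ani_m, aai_m)
  grp <- setNames(ga$group, ga$genome_id)
  expect_equal(length(unique(grp)), 3)
  expect_equal(length(unique(grp[bm])), 1)
  expect_equal(length(unique(grp[ad])), 1)
  expect_equal(length(unique(grp[al])), 1)
  expect_false(grp[["BTB"]] == grp[["AdSh"]])
  expect_false(grp[["AdSh"]] == grp[["AlDi"]])

  # classification is invariant to genome order and to threshold shifts
  # inside the gap between within- and between-group identities
  p <- c(5, 3, 9, 1, 2, 8, 7, 4, 6)
  ga2 <- classify_groups(ani_m[p, p], aai_m[p, p])
  grp2 <- setNames(ga2$group, ga2$genome_id)
  expect_true(all(tapply(names(grp2), grp2, function(x)
    length(unique(grp[x])) == 1)))
  ga3 <- classify_groups(ani_m, aai_m, ani_min = 0.93, aai_min = 0.88)
  expect_equal(length(unique(ga3$group)), 3)

  # degenerate panels
  one <- matrix(1, 1, 1, dimnames = list("solo", "solo"))
  expect_equal(nrow(classify_groups(one, one)), 1)
  all_same <- matrix(1, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(length(unique(classify_groups(all_same, all_same)$group)), 1)
})

test_that("boundary identities do not link groups (strict inequality)", {
  ids <- c("a", "b")
  ani_m <- matrix(c(1, 0.95, 0.95, 1), 2, 2, dimnames = list(ids, ids))
  aai_m <- matrix(c(1, 0.95, 0.95, 1), 2, 2, dimnames = list(ids, ids))
  ga <- classify_groups(ani_m, aai_m, ani_min = 0.95, aai_min = 0.90)
  expect_equal(length(unique(ga$group)), 2)
})
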