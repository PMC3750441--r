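# Tree building, parsimony, bootstraps and tree-comparison metrics.

test_that("NJ solves the three-point closed form and recovers additive trees", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  phy <- nj_tree(d)
  el <- setNames(phy$edge.length, phy$tip.label[phy$edge[, 2]])
  expect_equal(el[["a"]], 0.1)
  expect_equal(el[["b"]], 0.1)
  expect_equal(el[["c"]], 0.3)

  # additive 4-taxon matrix from a known tree is recovered exactly
  tr <- ape::read.tree(text = "((a:0.1,b:0.2):0.05,(c:0.3,d:0.15):0.05);")
  pm <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(pm)
  expect_equal(rf_distance(rec, ape::unroot(tr)), 0)
  expect_equal(ape::cophenetic.phylo(rec)[rownames(pm), colnames(pm)], pm,
               tolerance = 1e-10)

  expect_error(nj_tree(matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               ">= 3")
})

test_that("NJ is an additivity fixed point on random trees", {
  set.seed(5)
  for (i in 1:8) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    pm <- ape::cophenetic.phylo(tr)
    rec <- nj_tree(pm)
    expect_equal(ape::cophenetic.phylo(rec)[rownames(pm), colnames(pm)], pm,
                 tolerance = 1e-8)
  }
})

test_that("Fitch scores match brute force on toy columns", {
  tr <- ape::unroot(ape::read.tree(text = "((a,b),(c,d));"))
  aln <- new_alignment(c(a = "AAA", b = "AAC", c = "CCG", d = "CCT"))
  # col1 (A,A,C,C) costs 1; col2 (A,A,C,C) 1; col3 (A,C,G,T) 3
  expect_equal(fitch_score(tr, new_alignment(c(a = "A", b = "A", c = "C",
                                               d = "C"))), 1)
  expect_equal(fitch_score(tr, new_alignment(c(a = "A", b = "A", c = "A",
                                               d = "A"))), 0)
  all3 <- phangorn::allTrees(4, tip.label = c("a", "b", "c", "d"))
  for (i in seq_along(all3))
    expect_equal(fitch_score(all3[[i]],
                             new_alignment(c(a = "A", b = "C", c = "G",
                                             d = "T"))), 3)
  expect_equal(fitch_score(tr, aln), 5)
  # gaps and N are missing: they never add cost
  expect_equal(fitch_score(tr, new_alignment(c(a = "A", b = "-", c = "N",
                                               d = "A"))), 0)
})

test_that("exhaustive MP search enumerates (2n-5)!! topologies and matches
           an independent parsimony oracle", {
  aln4 <- rand_alignment(4, 60, seed = 31, gap_frac = 0, n_frac = 0)
  expect_equal(mp_search(aln4)$n_enumerated, 3)
  aln7 <- rand_alignment(7, 40, seed = 32, gap_frac = 0, n_frac = 0)
  expect_equal(mp_search(aln7)$n_enumerated, 945)
  expect_error(mp_search(rand_alignment(3, 10, seed = 1)), ">= 4")

  # oracle: phangorn's Fitch parsimony rescoring every enumerated topology
  for (s in 1:3) {
    n <- 4 + s
    aln <- rand_alignment(n, 80, seed = 40 + s, gap_frac = 0.03)
    labs <- names(aln)
    pd <- phangorn::phyDat(aln_matrix(aln), type = "DNA")
    trees <- phangorn::allTrees(n, tip.label = labs)
    oracle_scores <- phangorn::parsimony(trees, pd, method = "fitch")
    res <- mp_search(aln)
    expect_equal(res$best_score, min(oracle_scores))
    # and every returned optimum attains the oracle minimum
    expect_true(all(phangorn::parsimony(res$trees, pd) == min(oracle_scores)))
  }
})

test_that("MP recovers the generating topology of a simulated 6-taxon tree", {
  fx <- sim_fixture_cached("hotspot")
  sets <- extract_region_sets(fx$sim$leaves, fx$sim$features)
  ids <- vapply(sets, function(s) s$region_id, character(1))
  aln <- progressive_align(sets[[which(ids == "gene1")]])
  res <- mp_search(aln)
  truth <- ape::unroot(ape::read.tree(text = fx$sim$truth$tree))
  scores_truth <- fitch_score(truth, aln)
  expect_equal(scores_truth, res$best_score)
})

test_that("bootstrap supports: strong signal, symmetry, determinism", {
  # two clades separated by 25 fixed differences
  set.seed(51)
  base <- rand_dna_str(300)
  v <- strsplit(base, "")[[1]]
  pos <- sample(300, 25)
  w <- v
  w[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  aln <- new_alignment(c(a = base, b = base,
                         c = paste(w, collapse = ""),
                         d = paste(w, collapse = "")))
  bs <- bootstrap_support(aln, builder = "mp", B = 100, seed = 4)
  expect_gte(min(attr(bs, "supports")), 99)

  # same seed twice gives identical supports; row order does not matter
  bs2 <- bootstrap_support(aln, builder = "mp", B = 100, seed = 4)
  expect_identical(attr(bs, "supports"), attr(bs2, "supports"))
  aln_r <- new_alignment(unclass(aln)[c("d", "b", "a", "c")])
  bs3 <- bootstrap_support(aln_r, builder = "mp", B = 100, seed = 4)
  expect_identical(attr(bs, "supports"), attr(bs3, "supports"))

  expect_error(bootstrap_support(aln, B = 0), "B")

  # nj builder works too and agrees on the resolved split
  bs_nj <- bootstrap_support(aln, builder = "nj", B = 50, seed = 4)
  expect_gte(min(attr(bs_nj, "supports")), 98)
})

test_that("RF distance is a metric and matches phangorn", {
  set.seed(61)
  trees <- lapply(1:6, function(i) ape::rtree(7, rooted = FALSE,
                                              tip.label = paste0("t", 1:7)))
  for (i in seq_along(trees)) {
    expect_equal(rf_distance(trees[[i]], trees[[i]]), 0)
    for (j in seq_along(trees)) {
      dij <- rf_distance(trees[[i]], trees[[j]])
      expect_equal(dij, rf_distance(trees[[j]], trees[[i]]))
      expect_equal(dij, as.integer(phangorn::RF.dist(trees[[i]],
                                                     trees[[j]])))
      for (k in seq_along(trees))
        expect_lte(dij, rf_distance(trees[[i]], trees[[k]]) +
                     rf_distance(trees[[k]], trees[[j]]))
    }
  }
  t_bad <- ape::rtree(7, tip.label = paste0("u", 1:7))
  expect_error(rf_distance(trees[[1]], t_bad), "differ")
})

test_that("matrix Euclidean distance matches a flat-loop recount", {
  labs <- paste0("s", 1:7)
  set.seed(71)
  mk <- function() {
    m <- matrix(runif(49), 7, 7, dimnames = list(labs, labs))
    m <- (m + t(m)) / 2; diag(m) <- 0; m
  }
  m1 <- mk(); m2 <- mk()
  expect_equal(matrix_euclidean(m1, m1), 0)
  # single differing pair of 0.1
  m3 <- m1; m3["s1", "s2"] <- m3["s2", "s1"] <- m1["s1", "s2"] + 0.1
  expect_equal(matrix_euclidean(m1, m3), 0.1)
  # flat loop oracle
  ss <- 0
  for (i in 1:6) for (j in (i + 1):7)
    ss <- ss + (m1[labs[i], labs[j]] - m2[labs[i], labs[j]])^2
  expect_equal(matrix_euclidean(m1, m2), sqrt(ss))
  expect_equal(matrix_euclidean(m1, m2, normalize = TRUE), sqrt(ss / 21))
})

test_that("newick round trip keeps topology and supports", {
  d <- withr::local_tempdir()
  aln <- rand_alignment(5, 150, seed = 81, gap_frac = 0)
  bs <- bootstrap_support(aln, "nj", B = 20, seed = 2)
  p <- file.path(d, "t.nwk")
  write_newick(bs, p)
  back <- read_newick(p)
  expect_equal(rf_distance(back, bs), 0)
  expect_true(!is.null(back$node.label))
})
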