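# Perfect microsatellite detection and cross-strain comparison.

test_that("SSR detection on hand-built sequences", {
  # mono run at threshold (10) detected, one short of it (9) not
  pad <- "GCTGACGTCG"    # starts/ends with G so planted runs stay maximal
  expect_equal(nrow(find_ssrs(paste0(pad, strrep("A", 10), pad))), 1)
  expect_equal(nrow(find_ssrs(paste0(pad, strrep("A", 9), pad))), 0)
  hit <- find_ssrs(paste0(pad, strrep("A", 10), pad))
  expect_equal(hit$motif, "A")
  expect_equal(hit$total_len, 10)
  expect_equal(hit$start, 11)

  # (TA)x7 di repeat, canonical motif AT
  di <- find_ssrs(paste0(pad, strrep("TA", 7), pad))
  expect_equal(di$motif, "AT")
  expect_equal(di$copies, 7)
  # the 10-nt example exactly at the di threshold
  d2 <- find_ssrs(paste0(pad, "ATATATATAT", "GC", pad))
  expect_equal(d2$motif, "AT")
  expect_equal(d2$total_len, 10)

  # a poly-A run is reported once, as mono (primitivity)
  mono <- find_ssrs(paste0(pad, strrep("A", 14), pad))
  expect_equal(nrow(mono), 1)
  expect_equal(mono$unit_len, 1)

  # case invariance
  expect_equal(find_ssrs(tolower(paste0(pad, strrep("A", 10), pad)))$motif,
               "A")
})

test_that("detection matches an exhaustive brute-force oracle", {
  thresholds <- c(10L, 10L, 12L, 12L, 12L, 12L)
  # oracle: test every (start, unit) for a maximal primitive perfect repeat
  oracle <- function(s, min_len = thresholds) {
    x <- strsplit(s, "")[[1]]
    n <- length(x)
    prim <- function(mot) {
      u <- nchar(mot)
      if (u == 1) return(TRUE)
      for (d in seq_len(u - 1))
        if (u %% d == 0 &&
            paste(rep(substr(mot, 1, d), u / d), collapse = "") == mot)
          return(FALSE)
      TRUE
    }
    out <- NULL
    for (u in 1:6) for (st in seq_len(n)) {
      k <- 0
      while (st + (k + 1) * u - 1 <= n &&
             all(x[st:(st + u - 1)] ==
                   x[(st + k * u):(st + (k + 1) * u - 1)])) k <- k + 1
      if (k < 2 || k * u < min_len[u]) next
      mot <- paste(x[st:(st + u - 1)], collapse = "")
      if (!prim(mot)) next
      # maximal: not preceded by another unit or single period char
      if (st > 1 && x[st - 1] == x[st + u - 1]) next
      out <- rbind(out, data.frame(start = st, unit_len = u,
                                   total_len = k * u))
    }
    if (is.null(out)) return(NULL)
    out[order(out$start, out$unit_len), , drop = FALSE]
  }
  set.seed(301)
  for (i in 1:15) {
    s <- rand_dna_str(300)
    # plant a repeat in half the cases to guarantee coverage
    if (i %% 2 == 0) {
      mot <- sample(c("A", "T", "AT", "AAC", "AGAT"), 1)
      reps <- ceiling(12 / nchar(mot)) + sample(0:2, 1)
      pos <- sample(50:200, 1)
      s <- paste0(substr(s, 1, pos), strrep(mot, reps),
                  substr(s, pos + 1, 300))
    }
    got <- find_ssrs(s, min_len = thresholds)
    want <- oracle(s)
    expect_equal(nrow(got), if (is.null(want)) 0 else nrow(want), info = i)
    if (!is.null(want) && nrow(want)) {
      got <- got[order(got$start, got$unit_len), ]
      expect_equal(got$start, want$start, info = i)
      expect_equal(got$total_len, want$total_len, info = i)
    }
    # every reported locus re-validates: exact copies, not extendable
    for (r in seq_len(nrow(got))) {
      sub <- substr(s, got$start[r], got$end[r])
      raw_mot <- substr(s, got$start[r], got$start[r] + got$unit_len[r] - 1)
      expect_equal(sub, strrep(raw_mot, got$copies[r]))
      after <- substr(s, got$end[r] + 1, got$end[r] + got$unit_len[r])
      expect_false(identical(after, raw_mot))
    }
  }
})

test_that("planted SSRs are recovered with precision and recall 1", {
  fx <- sim_fixture_cached("ssr-panel")
  sim <- fx$sim
  truth <- fx$ancestor$ssr_truth
  for (leaf in names(sim$leaves)) {
    found <- find_ssrs(sim$leaves[[leaf]],
                       sim$features[sim$features$genome == leaf, ,
                                    drop = FALSE])
    expect_equal(nrow(found), nrow(truth))
    # match by canonical motif + position overlap with the planted locus
    coords <- leaf_region_coords(sim, leaf)
    for (r in seq_len(nrow(truth))) {
      reg <- coords[coords$region == truth$region[r], ]
      hit <- found$start >= reg$start & found$start <= reg$end &
        found$motif == organphylo:::canonical_motif(truth$motif[r])
      expect_equal(sum(hit), 1, info = truth$region[r])
      # at least the planted number of copies survives
      expect_gte(found$copies[hit], truth$copies[r])
    }
  }
})

test_that("cross-strain comparison separates shared and specific loci", {
  a <- data.frame(genome = "s1", organelle = "pt",
                  motif = c("A", "AT"), unit_len = c(1, 2),
                  copies = c(10, 7), total_len = c(10, 14),
                  start = c(5, 50), end = c(14, 63),
                  context = "intergenic", context_name = c("x-y", "y-z"))
  b <- a
  b$genome <- "s2"
  b$total_len[1] <- 12                  # copy-number polymorphism
  b <- b[1, ]                           # second locus absent in s2
  cmp <- compare_ssrs(rbind(a, b))
  expect_equal(nrow(cmp$shared), 1)
  expect_true(cmp$shared$length_polymorphic)
  expect_equal(nrow(cmp$specific), 1)
  expect_equal(cmp$specific$genome, "s1")

  # disjoint motif panels share nothing
  c2 <- a
  c2$genome <- "s2"; c2$motif <- c("G", "GC")
  expect_equal(nrow(compare_ssrs(rbind(a, c2))$shared), 0)
})
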