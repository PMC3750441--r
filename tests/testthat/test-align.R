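# Pairwise/anchored/progressive alignment and distance statistics.

test_that("global pairwise alignment on toy cases", {
  pr <- pairwise_align(c(a = "ACGT"), c(b = "ACGT"))
  expect_identical(unname(pr), c("ACGT", "ACGT"))

  # one single-base gap opposite the G (brute-force optimum at this scoring)
  pr2 <- pairwise_align(c(a = "ACGT"), c(b = "ACT"))
  expect_equal(nchar(pr2[[1]]), 4)
  expect_identical(unname(pr2[1]), "ACGT")
  expect_equal(sum(strsplit(pr2[[2]], "")[[1]] == "-"), 1)
  # the gapped row still reads ACT
  expect_identical(gsub("-", "", pr2[[2]]), "ACT")

  expect_error(pairwise_align(c(a = ""), c(b = "A")), "empty")
})

test_that("progressive alignment preserves substitutions and places gaps", {
  ids <- c("x", "y", "z")
  aln <- progressive_align(setNames(c("ACGTACGT", "ACGTACGT", "ACGTACGT"),
                                    ids))
  expect_identical(unname(unclass(aln)), rep("ACGTACGT", 3))

  # single substitutions: alignment stays ungapped at input length
  aln2 <- progressive_align(setNames(c("ACGTACGT", "ACTTACGT", "ACGTACCT"),
                                     ids))
  expect_equal(nchar(aln2[[1]]), 8)
  m <- aln_matrix(aln2)
  expect_equal(sum(apply(m, 2, function(cl) length(unique(cl)) > 1)), 2)

  # one short member gets the gap (brute force: deleting G is optimal)
  aln3 <- progressive_align(setNames(c("ACGT", "ACT", "ACGT"), ids))
  expect_equal(nchar(aln3[[1]]), 4)
  expect_equal(sum(aln_matrix(aln3) == "-"), 1)
  expect_true(grepl("-", aln3[["y"]]))
})

test_that("p-distance matches definition and a brute-force recount", {
  aln <- new_alignment(c(a = "AAAA", b = "AAAT"))
  expect_equal(p_distance(aln)["a", "b"], 0.25)

  aln2 <- new_alignment(c(a = "AA-A", b = "AAAA"))
  expect_equal(p_distance(aln2, "pairwise")["a", "b"], 0)

  # independent double-loop oracle on a random gapped alignment
  aln3 <- rand_alignment(6, 1000, seed = 3)
  d <- p_distance(aln3, "pairwise")
  m <- aln_matrix(aln3)
  for (i in 1:5) for (j in (i + 1):6) {
    mm <- 0L; nn <- 0L
    for (k in seq_len(ncol(m))) {
      x <- m[i, k]; y <- m[j, k]
      if (x %in% c("-", "N") || y %in% c("-", "N")) next
      nn <- nn + 1L
      if (x != y) mm <- mm + 1L
    }
    expect_equal(d[i, j], mm / nn)
  }
  # symmetry and range hold for generated alignments
  for (s in 4:6) {
    dd <- p_distance(rand_alignment(4, 200, seed = s))
    expect_identical(dd, t(dd))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_true(all(diag(dd) == 0))
  }

  # complete deletion drops any gapped column
  aln4 <- new_alignment(c(a = "A-CT", b = "AACT", c = "AACA"))
  expect_equal(p_distance(aln4, "complete")["a", "c"], 1 / 3)
})

test_that("percent nucleotide difference counts polymorphic columns", {
  set.seed(9)
  base <- rand_dna_str(100)
  v <- strsplit(base, "")[[1]]
  w <- v
  pos <- sample(100, 10)
  w[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  aln <- new_alignment(c(a = base, b = paste(w, collapse = ""), c = base))
  expect_equal(percent_difference(aln), 10)
  expect_equal(percent_difference(new_alignment(c(a = base, b = base))), 0)
  # row order invariance
  aln_r <- new_alignment(unclass(aln)[c("c", "a", "b")])
  expect_equal(percent_difference(aln_r), percent_difference(aln))
  # gap against base is a polymorphism
  expect_equal(percent_difference(new_alignment(c(a = "A-CT", b = "AACT"))),
               25)
})

test_that("SNP classification partitions variant columns exactly", {
  aln <- new_alignment(c(a = "ATGAAATTTGGG", b = "ATGAAGTTTGAG",
                         c = "ATGAATTTTGGG"), frame = 1)
  res <- classify_snps(aln)
  # column 6: A/G/T multiallelic; column 11 G/A transition
  expect_equal(res$summary$n_multiallelic, 1)
  expect_equal(res$summary$n_transition, 1)
  expect_equal(res$summary$total, nrow(res$records))
  expect_equal(res$records$klass[res$records$column == 11], "transition")

  # a 3-base gap in a codon-aligned gene is a triplet indel, not frameshift
  aln2 <- new_alignment(c(a = "ATGAAATTTTAA", b = "ATG---TTTTAA"), frame = 1)
  res2 <- classify_snps(aln2)
  expect_true(all(res2$records$coding_effect[res2$records$klass == "indel"]
                  == "triplet_indel"))
  expect_equal(res2$summary$n_indel, 3)       # columns
  expect_equal(res2$summary$n_indel_events, 1)

  # frameshifting gap runs (lengths 1 and 2) flagged when frame is known
  aln3 <- new_alignment(c(a = "ATGCAATGGTAA", b = "ATG-AAT--TAA"),
                        frame = NULL)
  res3 <- classify_snps(aln3, frame = 1)
  expect_true(all(res3$records$coding_effect[res3$records$klass == "indel"]
                  == "frameshift"))
  expect_warning(classify_snps(new_alignment(c(a = "ATGAA", b = "ATGAT")),
                               frame = 1), "multiple of 3")

  # partition property over random alignments
  for (s in 1:5) {
    a <- rand_alignment(5, 300, seed = 100 + s)
    sm <- classify_snps(a)$summary
    expect_equal(sm$n_transition + sm$n_transversion + sm$n_indel +
                   sm$n_multiallelic, sm$total)
  }
})

test_that("synonymous vs nonsynonymous annotation uses the codon frame", {
  # CTT->CTC (Leu->Leu) synonymous; AAA->AGA (Lys->Arg) nonsynonymous
  aln <- new_alignment(c(a = "CTTAAATAA", b = "CTCAGATAA"), frame = 1)
  rec <- classify_snps(aln)$records
  expect_equal(rec$coding_effect[rec$column == 3], "synonymous")
  expect_equal(rec$coding_effect[rec$column == 5], "nonsynonymous")
})

test_that("anchored genome alignment recovers planted substitutions", {
  g1 <- rand_dna_str(8000, seed = 21)
  aln0 <- anchored_align(g1, g1, ids = c("a", "b"))
  m0 <- aln_matrix(aln0)
  expect_equal(ncol(m0), 8000)
  expect_equal(sum(m0[1, ] != m0[2, ]), 0)

  set.seed(22)
  v <- strsplit(g1, "")[[1]]
  pos <- sort(sample(8000, 100))
  v[pos] <- vapply(v[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  g2 <- paste(v, collapse = "")
  aln <- anchored_align(g1, g2, ids = c("a", "b"))
  m <- aln_matrix(aln)
  mism <- which(m[1, ] != m[2, ] & m[1, ] != "-" & m[2, ] != "-")
  expect_equal(length(mism), 100)
  # mismatch columns map back to the planted positions
  rpos <- cumsum(m[1, ] != "-")
  expect_equal(unname(rpos[mism]), pos)

  # reversed partner on large input: collinearity violated, no anchors
  g_big <- rand_dna_str(60000, seed = 23)
  g_rev <- paste(rev(strsplit(g_big, "")[[1]]), collapse = "")
  expect_error(anchored_align(g_big, g_rev), "anchor")
})
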