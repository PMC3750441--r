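#' Alignment container
#'
#' A multiple alignment is a named character vector of equal-length gapped
#' DNA strings (over A, C, G, T, N, `-`) carrying optional `region_id` and
#' codon `frame` attributes.  Columns consisting only of gaps are invalid.
#'
#' @param seqs Named character vector of gapped sequences.
#' @param region_id Optional region label.
#' @param frame Optional codon frame (genic alignments).
#' @return An object of class `dna_alignment`.
#' @export
new_alignment <- function(seqs, region_id = NULL, frame = NULL) {
  if (length(seqs) < 2L) stop("alignment needs >= 2 rows")
  if (length(unique(nchar(seqs))) != 1L)
    stop("alignment rows differ in length")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("alignment rows must be named by strain id")
  aln <- structure(seqs, class = "dna_alignment",
                   region_id = region_id, frame = frame)
  m <- aln_matrix(aln)
  if (any(colSums(m != "-") == 0L)) stop("alignment has an all-gap column")
  aln
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment>", attr(x, "region_id") %||% "", length(x), "rows x",
      nchar(x[[1L]]), "columns\n")
  invisible(x)
}

#' Alignment as a character matrix (rows = strains, columns = sites)
#' @param aln A `dna_alignment`.
#' @return Character matrix with strain rownames.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(toupper(unclass(aln)), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

alignment_from_matrix <- function(m, region_id = NULL, frame = NULL) {
  new_alignment(setNames(apply(m, 1L, paste, collapse = ""), rownames(m)),
                region_id = region_id, frame = frame)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment via Biostrings, with scoring defaults
#' chosen for near-identical organelle sequences.
#'
#' @param a,b DNA strings (non-empty, each <= 50 kb; use [anchored_align()]
#'   beyond that).
#' @param match,mismatch,gap_open,gap_extend Scores; penalties are negative.
#' @return Character vector of the two gapped rows, named after `a` and `b`
#'   (falling back to `"seq1"`/`"seq2"`).
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  ids <- c(names(a) %||% "seq1", names(b) %||% "seq2")
  a <- unname(a); b <- unname(b)
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_align: empty input sequence")
  if (nchar(a) > 50000 || nchar(b) > 50000)
    stop("pairwise_align: sequence over 50 kb; use anchored_align")
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sub,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  setNames(c(as.character(Biostrings::alignedPattern(pa)),
             as.character(Biostrings::alignedSubject(pa))), ids)
}

## Longest strictly increasing subsequence; returns indices.
lis_indices <- function(x) {
  n <- length(x)
  if (!n) return(integer())
  tails <- integer(0)      # indices into x of tail elements
  prev <- integer(n)
  for (i in seq_len(n)) {
    lo <- 1L; hi <- length(tails) + 1L
    while (lo < hi) {       # first tail with value >= x[i]
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
  }
  out <- integer(0)
  k <- tails[length(tails)]
  while (k > 0L) { out <- c(k, out); k <- prev[k] }
  out
}

#' Anchored alignment of two whole organelle genomes
#'
#' Collinear genome-scale pairwise alignment: unique shared k-mers are
#' chained by longest increasing subsequence and the gaps between anchors
#' closed with [pairwise_align()].  Intended for broadly collinear sequences
#' such as two conspecific organelle genomes.
#'
#' @param g1,g2 DNA strings (>= 1 kb recommended).
#' @param k Anchor k-mer size (anchors must be unique in both genomes).
#' @param ids Row names of the result.
#' @inheritParams pairwise_align
#' @return A two-row [new_alignment()] covering both sequences end to end.
#' @export
anchored_align <- function(g1, g2, k = 21L, ids = c("g1", "g2"),
                           match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  g1 <- toupper(g1); g2 <- toupper(g2)
  n1 <- nchar(g1); n2 <- nchar(g2)
  unique_kmers <- function(g, n) {
    if (n < k) return(list(km = character(), pos = integer()))
    st <- seq_len(n - k + 1L)
    km <- substring(g, st, st + k - 1L)
    keep <- !(duplicated(km) | duplicated(km, fromLast = TRUE))
    list(km = km[keep], pos = st[keep])
  }
  u1 <- unique_kmers(g1, n1); u2 <- unique_kmers(g2, n2)
  shared <- intersect(u1$km, u2$km)
  fallback <- function() {
    if (n1 <= 50000 && n2 <= 50000) {
      pr <- pairwise_align(g1, g2, match, mismatch, gap_open, gap_extend)
      return(new_alignment(setNames(pr, ids)))
    }
    stop("anchored_align: no anchors found (sequences not collinear?) and ",
         "input too large for direct pairwise alignment")
  }
  if (!length(shared)) return(fallback())
  p1 <- u1$pos[match(shared, u1$km)]
  p2 <- u2$pos[match(shared, u2$km)]
  o <- order(p1)
  p1 <- p1[o]; p2 <- p2[o]
  sel <- lis_indices(p2)
  p1 <- p1[sel]; p2 <- p2[sel]

  r1 <- character(0); r2 <- character(0)
  cur1 <- 0L; cur2 <- 0L
  close_gap <- function(s1, s2) {
    if (!nzchar(s1) && !nzchar(s2)) return(c("", ""))
    if (!nzchar(s1)) return(c(strrep("-", nchar(s2)), s2))
    if (!nzchar(s2)) return(c(s1, strrep("-", nchar(s1))))
    pairwise_align(s1, s2, match, mismatch, gap_open, gap_extend)
  }
  for (i in seq_along(p1)) {
    if (p1[i] <= cur1 || p2[i] <= cur2) next   # overlaps previous anchor
    seg <- close_gap(substr(g1, cur1 + 1L, p1[i] - 1L),
                     substr(g2, cur2 + 1L, p2[i] - 1L))
    anchor <- substr(g1, p1[i], p1[i] + k - 1L)
    r1 <- c(r1, seg[1L], anchor)
    r2 <- c(r2, seg[2L], anchor)
    cur1 <- p1[i] + k - 1L; cur2 <- p2[i] + k - 1L
  }
  seg <- close_gap(substr(g1, cur1 + 1L, n1), substr(g2, cur2 + 1L, n2))
  r1 <- c(r1, seg[1L]); r2 <- c(r2, seg[2L])
  new_alignment(setNames(c(paste(r1, collapse = ""),
                           paste(r2, collapse = "")), ids))
}

## p-distance between two gapped rows (pairwise deletion of '-' and N).
pair_p_distance <- function(a, b) {
  x <- seq_chars(a); y <- seq_chars(b)
  ok <- x != "-" & y != "-" & x != "N" & y != "N"
  if (!any(ok)) return(NA_real_)
  sum(x[ok] != y[ok]) / sum(ok)
}

#' Progressive (center-star) multiple alignment
#'
#' Aligns every member to a center sequence (the member minimizing total
#' pairwise p-distance, the medoid of the NJ guide distances) and merges the
#' pairwise alignments under a once-a-gap-always-a-gap rule.  Adequate for
#' the near-identical sequences this package screens; not a general-purpose
#' aligner.
#'
#' @param rs A [region_set()] (or named character vector of sequences).
#' @inheritParams pairwise_align
#' @return A [new_alignment()] with rows in input member order.
#' @export
progressive_align <- function(rs, match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  if (inherits(rs, "region_set")) {
    members <- rs$members; region_id <- rs$region_id; frame <- rs$frame
  } else {
    members <- rs; region_id <- NULL; frame <- NULL
  }
  ids <- names(members)
  n <- length(members)
  if (n < 2L) stop("progressive_align: need >= 2 members")
  if (n == 2L) {
    pr <- pairwise_align(setNames(members[1L], ids[1L]),
                         setNames(members[2L], ids[2L]),
                         match, mismatch, gap_open, gap_extend)
    return(new_alignment(pr, region_id = region_id, frame = frame))
  }
  ## all-pairs alignments involving each candidate center are needed anyway;
  ## compute the full pair table once (n is small for organelle strain sets)
  pairs <- utils::combn(n, 2L)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  paln <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    pr <- pairwise_align(setNames(members[i1], ids[i1]),
                         setNames(members[i2], ids[i2]),
                         match, mismatch, gap_open, gap_extend)
    paln[[j]] <- pr
    d[i1, i2] <- d[i2, i1] <- pair_p_distance(pr[1L], pr[2L])
  }
  center <- which.min(rowSums(d))
  L <- nchar(members[center])
  others <- setdiff(seq_len(n), center)
  matched <- matrix("-", n, L)          # char matched to each center position
  ins <- matrix("", n, L + 1L)          # insertions after center position 0..L
  matched[center, ] <- seq_chars(members[center])
  for (i in others) {
    j <- which((pairs[1L, ] == center & pairs[2L, ] == i) |
               (pairs[1L, ] == i & pairs[2L, ] == center))
    pr <- paln[[j]]
    crow <- seq_chars(pr[[which(names(pr) == ids[center])]])
    srow <- seq_chars(pr[[which(names(pr) == ids[i])]])
    ci <- 0L
    for (col in seq_along(crow)) {
      if (crow[col] != "-") {
        ci <- ci + 1L
        matched[i, ci] <- srow[col]
      } else {
        ins[i, ci + 1L] <- paste0(ins[i, ci + 1L], srow[col])
      }
    }
  }
  widths <- apply(ins, 2L, function(x) max(nchar(x)))
  rows <- vapply(seq_len(n), function(i) {
    parts <- character(0)
    for (s in 0:L) {
      blk <- ins[i, s + 1L]
      blk <- paste0(blk, strrep("-", widths[s + 1L] - nchar(blk)))
      parts <- c(parts, blk, if (s < L) matched[i, s + 1L])
    }
    paste(parts, collapse = "")
  }, character(1))
  new_alignment(setNames(rows, ids), region_id = region_id, frame = frame)
}
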