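## Base-state bitmasks for Fitch parsimony; '-' and N are missing (full set,
## unioned with anything at no cost).
BASE_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, "-" = 15L)

## Compress alignment columns into unique site patterns with weights.
aln_patterns <- function(aln) {
  m <- aln_matrix(aln)
  mask <- matrix(BASE_MASK[m], nrow(m), ncol(m),
                 dimnames = list(rownames(m), NULL))
  if (any(is.na(mask))) stop("alignment contains characters without a state")
  key <- apply(mask, 2L, paste, collapse = ",")
  first <- !duplicated(key)
  colpat <- match(key, key[first])
  list(masks = mask[, first, drop = FALSE],
       w = as.integer(tabulate(colpat, nbins = sum(first))),
       colpat = colpat)
}

## Fitch small-parsimony change count per site pattern, vectorized across
## patterns.  Children are folded into the parent sequentially; for a binary
## tree with a basal trichotomy this equals rooting on the last child's edge.
fitch_pattern_counts <- function(phy, masks) {
  phy <- ape::reorder.phylo(phy, "postorder")
  nt <- length(phy$tip.label)
  P <- ncol(masks)
  state <- matrix(0L, nt + phy$Nnode, P)
  state[seq_len(nt), ] <- masks[phy$tip.label, , drop = FALSE]
  count <- integer(P)
  seen <- logical(nt + phy$Nnode)
  seen[seq_len(nt)] <- TRUE
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    if (!seen[par]) {
      state[par, ] <- state[child, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(state[par, ], state[child, ])
      z <- inter == 0L
      if (any(z)) {
        inter[z] <- bitwOr(state[par, ], state[child, ])[z]
        count[z] <- count[z] + 1L
      }
      state[par, ] <- inter
    }
  }
  count
}

#' Fitch parsimony score of a topology
#'
#' Minimum total number of character changes the alignment requires on the
#' given (unrooted) topology, summed over columns.  Gaps and `N` are treated
#' as missing states.
#'
#' @param phy An `ape::phylo` tree whose tip labels are alignment row names.
#' @param aln A [new_alignment()].
#' @return Integer score.
#' @export
fitch_score <- function(phy, aln) {
  if (!all(phy$tip.label %in% names(aln)))
    stop("tree tips not all present in alignment: ",
         paste(setdiff(phy$tip.label, names(aln)), collapse = ", "))
  aln <- new_alignment(unclass(aln)[phy$tip.label])
  cp <- aln_patterns(aln)
  as.integer(sum(fitch_pattern_counts(phy, cp$masks) * cp$w))
}

#' Exhaustive (or NNI-heuristic) maximum-parsimony search
#'
#' For 4--`max_exhaustive` leaves, every one of the (2n-5)!! unrooted
#' topologies is enumerated and scored with Fitch parsimony; the minimum and
#' all tied optima are returned.  Beyond that, a neighbor-joining start with
#' nearest-neighbor-interchange hill climbing is used and the result is
#' flagged heuristic.
#'
#' @param aln A [new_alignment()] of at least 4 rows.
#' @param max_exhaustive Largest leaf count enumerated exhaustively
#'   (default 9).
#' @return An object of class `parsimony_result`: `best_score`, `trees`
#'   (multiPhylo of optima), `n_enumerated`, `heuristic`.
#' @export
mp_search <- function(aln, max_exhaustive = 9L) {
  n <- length(aln)
  if (n < 4L) stop("mp_search: need >= 4 leaves")
  cp <- aln_patterns(aln)
  if (n <= max_exhaustive) {
    trees <- phangorn::allTrees(n, rooted = FALSE, tip.label = names(aln))
    scores <- vapply(trees, function(t)
      sum(fitch_pattern_counts(t, cp$masks) * cp$w), numeric(1))
    best <- min(scores)
    res <- list(best_score = as.integer(best),
                trees = trees[scores == best],
                n_enumerated = length(trees),
                heuristic = FALSE)
  } else {
    cur <- ape::unroot(nj_tree(p_distance(aln)))
    cur_s <- sum(fitch_pattern_counts(cur, cp$masks) * cp$w)
    repeat {
      nbs <- phangorn::nni(cur)
      ns <- vapply(nbs, function(t)
        sum(fitch_pattern_counts(t, cp$masks) * cp$w), numeric(1))
      if (min(ns) < cur_s) {
        cur <- nbs[[which.min(ns)]]
        cur_s <- min(ns)
      } else break
    }
    res <- list(best_score = as.integer(cur_s), trees = c(cur),
                n_enumerated = NA_integer_, heuristic = TRUE)
  }
  class(res$trees) <- "multiPhylo"
  structure(res, class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("<parsimony_result> best score", x$best_score, "(",
      length(x$trees), "optimal topolog",
      if (length(x$trees) == 1L) "y" else "ies", ",",
      if (x$heuristic) "NNI heuristic" else
        paste(x$n_enumerated, "enumerated"), ")\n")
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix (via `ape::nj`).  Negative
#' branch lengths are clamped to zero with the deficit shifted onto the
#' sister edge (then clamped again), so output lengths are non-negative.
#'
#' @param d Symmetric distance matrix with labels (or a `dist`).
#' @param permissive Allow a degenerate 2-taxon tree (single edge split in
#'   two); otherwise fewer than 3 labels is an error.
#' @return An `ape::phylo` tree.
#' @export
nj_tree <- function(d, permissive = FALSE) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) {
    if (n == 2L && permissive) {
      phy <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, 2L, byrow = TRUE),
                  edge.length = rep(d[1L, 2L] / 2, 2L),
                  tip.label = rownames(d), Nnode = 1L)
      class(phy) <- "phylo"
      return(phy)
    }
    stop("nj_tree: need >= 3 labels")
  }
  labs <- rownames(d)
  d <- d[order(labs), order(labs)]   # deterministic tie-break on label order
  phy <- ape::nj(as.dist(d))
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    sis <- setdiff(which(phy$edge[, 1L] == phy$edge[e, 1L]), e)
    if (length(sis))
      phy$edge.length[sis[1L]] <- phy$edge.length[sis[1L]] + deficit
  }
  phy$edge.length[phy$edge.length < 0] <- 0
  phy
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge defines a split of the leaf set; splits are returned as
#' canonical keys (the side not containing the alphabetically first leaf,
#' sorted, joined by `|`).
#'
#' @param phy An `ape::phylo`.
#' @return Character vector of split keys (possibly empty).
#' @export
tree_splits <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4L || is.null(phy$edge)) return(character(0))
  phy <- ape::reorder.phylo(phy, "postorder")
  anchor <- sort(phy$tip.label)[1L]
  tipsets <- vector("list", nt + phy$Nnode)
  for (i in seq_len(nt)) tipsets[[i]] <- phy$tip.label[i]
  for (e in seq_len(nrow(phy$edge))) {
    par <- phy$edge[e, 1L]; child <- phy$edge[e, 2L]
    tipsets[[par]] <- c(tipsets[[par]], tipsets[[child]])
  }
  keys <- character(0)
  for (e in seq_len(nrow(phy$edge))) {
    child <- phy$edge[e, 2L]
    if (child <= nt) next                      # leaf edge
    side <- tipsets[[child]]
    if (anchor %in% side) side <- setdiff(phy$tip.label, side)
    if (length(side) < 2L || length(side) > nt - 2L) next
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance
#'
#' Size of the symmetric difference of the two trees' internal split sets.
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return Non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("leaf sets differ: only in t1 {",
         paste(setdiff(t1$tip.label, t2$tip.label), collapse = ", "),
         "}; only in t2 {",
         paste(setdiff(t2$tip.label, t1$tip.label), collapse = ", "), "}")
  s1 <- tree_splits(t1); s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Euclidean distance between two distance matrices
#'
#' The quantitative tree-similarity measure of the marker screen: the square
#' root of the sum, over unordered label pairs, of squared differences
#' between corresponding p-distance entries.
#'
#' @param m1,m2 Symmetric labelled matrices over the same label set.
#' @param normalize Divide the sum by the number of pairs before the square
#'   root.
#' @return Non-negative number.
#' @export
matrix_euclidean <- function(m1, m2, normalize = FALSE) {
  if (!setequal(rownames(m1), rownames(m2)))
    stop("label sets differ: only in m1 {",
         paste(setdiff(rownames(m1), rownames(m2)), collapse = ", "),
         "}; only in m2 {",
         paste(setdiff(rownames(m2), rownames(m1)), collapse = ", "), "}")
  labs <- rownames(m1)
  m2 <- m2[labs, labs]
  diffs <- (m1 - m2)[lower.tri(m1)]
  ss <- sum(diffs^2)
  if (normalize) ss <- ss / length(diffs)
  sqrt(ss)
}

#' Bootstrap supports for an alignment's tree
#'
#' Columns are resampled with replacement `B` times; the support of a split
#' is 100 times the fraction of replicate trees containing it.  The `"mp"`
#' builder exhaustively rescoring is made cheap by precomputing per-topology,
#' per-site-pattern Fitch counts once: a replicate only reweights patterns.
#'
#' @param aln A [new_alignment()].
#' @param builder `"mp"` (maximum parsimony, first tied optimum) or `"nj"`.
#' @param B Number of replicates (>= 1).
#' @param seed RNG seed; identical seeds give identical supports.
#' @param max_exhaustive Passed to the MP builder.
#' @return The point-estimate tree (`ape::phylo`) with node labels and an
#'   attribute `supports`: named percentage vector over its internal splits.
#' @export
bootstrap_support <- function(aln, builder = c("mp", "nj"), B = 100L,
                              seed = 1L, max_exhaustive = 9L) {
  builder <- match.arg(builder)
  if (B < 1L) stop("bootstrap_support: B must be >= 1")
  aln <- new_alignment(unclass(aln)[sort(names(aln))],
                       region_id = attr(aln, "region_id"),
                       frame = attr(aln, "frame"))
  m <- aln_matrix(aln)
  L <- ncol(m)
  cp <- aln_patterns(aln)
  P <- ncol(cp$masks)

  if (builder == "mp") {
    trees <- phangorn::allTrees(length(aln), rooted = FALSE,
                                tip.label = names(aln))
    Fmat <- t(vapply(trees, function(t)
      as.numeric(fitch_pattern_counts(t, cp$masks)), numeric(P)))
    point_tree <- trees[[which.min(Fmat %*% cp$w)]]
    rep_tree <- function(w) trees[[which.min(Fmat %*% w)]]
  } else {
    np <- nrow(m)
    prs <- utils::combn(np, 2L)
    mm <- matrix(0, ncol(prs), P)   # per-pattern mismatch indicator
    vv <- matrix(0, ncol(prs), P)   # per-pattern comparability indicator
    miss <- cp$masks == 15L
    for (j in seq_len(ncol(prs))) {
      i1 <- prs[1L, j]; i2 <- prs[2L, j]
      ok <- !miss[i1, ] & !miss[i2, ]
      vv[j, ] <- as.numeric(ok)
      mm[j, ] <- as.numeric(ok & cp$masks[i1, ] != cp$masks[i2, ])
    }
    dist_from_w <- function(w) {
      num <- mm %*% w; den <- vv %*% w
      d <- matrix(0, np, np, dimnames = list(rownames(m), rownames(m)))
      for (j in seq_len(ncol(prs))) {
        v <- if (den[j] > 0) num[j] / den[j] else 0
        d[prs[1L, j], prs[2L, j]] <- d[prs[2L, j], prs[1L, j]] <- v
      }
      d
    }
    point_tree <- nj_tree(dist_from_w(cp$w))
    rep_tree <- function(w) nj_tree(dist_from_w(w))
  }

  set.seed(seed)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(B)) {
    idx <- sample.int(L, L, replace = TRUE)
    w <- as.numeric(tabulate(cp$colpat[idx], nbins = P))
    for (k in tree_splits(rep_tree(w)))
      assign(k, (get0(k, tally) %||% 0L) + 1L, tally)
  }
  pt_splits <- tree_splits(point_tree)
  supports <- vapply(pt_splits, function(k)
    100 * (get0(k, tally) %||% 0L) / B, numeric(1))
  names(supports) <- pt_splits

  nt <- length(point_tree$tip.label)
  labs <- rep("", point_tree$Nnode)
  po <- ape::reorder.phylo(point_tree, "postorder")
  tipsets <- vector("list", nt + point_tree$Nnode)
  for (i in seq_len(nt)) tipsets[[i]] <- point_tree$tip.label[i]
  for (e in seq_len(nrow(po$edge)))
    tipsets[[po$edge[e, 1L]]] <- c(tipsets[[po$edge[e, 1L]]],
                                   tipsets[[po$edge[e, 2L]]])
  anchor <- sort(point_tree$tip.label)[1L]
  for (nd in (nt + 1L):(nt + point_tree$Nnode)) {
    side <- tipsets[[nd]]
    if (anchor %in% side) side <- setdiff(point_tree$tip.label, side)
    key <- paste(sort(side), collapse = "|")
    if (key %in% pt_splits)
      labs[nd - nt] <- format(supports[[key]], trim = TRUE)
  }
  point_tree$node.label <- labs
  attr(point_tree, "supports") <- supports
  point_tree
}

#' Mean internal-split bootstrap support
#' @param bs_tree Result of [bootstrap_support()].
#' @return Mean of the support percentages over internal splits, or `NA`
#'   when the tree resolves none.
#' @export
mean_internal_support <- function(bs_tree) {
  s <- attr(bs_tree, "supports")
  if (is.null(s) || !length(s)) return(NA_real_)
  mean(s)
}

#' Root a tree on an outgroup for display
#'
#' Comparisons in this package are on unrooted topologies; rooting is
#' display-only.
#'
#' @param phy An `ape::phylo`.
#' @param outgroup Leaf label.
#' @return Rooted `ape::phylo`.
#' @export
root_on <- function(phy, outgroup) {
  if (!outgroup %in% phy$tip.label)
    stop("outgroup '", outgroup, "' not among leaves")
  ape::root(phy, outgroup = outgroup, resolve.root = TRUE)
}

#' Read and write Newick trees
#'
#' Thin wrappers over `ape`; supports are written as internal node labels and
#' branch lengths with 6 decimals.
#'
#' @param phy Tree; `path` file path.
#' @return `read_newick` returns an `ape::phylo`; `write_newick` returns
#'   `path` invisibly.
#' @export
write_newick <- function(phy, path) {
  ape::write.tree(phy, file = path, digits = 6)
  invisible(path)
}

#' @rdname write_newick
#' @param path File path.
#' @export
read_newick <- function(path) ape::read.tree(path)
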