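## Interspecies marker discovery: evaluate every region for consistency,
## sensitivity and specificity against a reference built from concatenated
## protein-coding genes, then rank against a baseline marker.

## Subset alignment rows, dropping columns left all-gap.
subset_alignment <- function(aln, ids) {
  m <- aln_matrix(aln)[ids, , drop = FALSE]
  keep <- colSums(m != "-") > 0L
  alignment_from_matrix(m[, keep, drop = FALSE],
                        region_id = attr(aln, "region_id"),
                        frame = attr(aln, "frame"))
}

#' Build the reference tree from concatenated protein-coding genes
#'
#' Each genic region set is aligned and the alignments concatenated over the
#' strains shared by every gene; the reference topology is the exhaustive
#' maximum-parsimony tree of the concatenation and the reference p-distance
#' matrix is computed from the same concatenation.
#'
#' @param region_sets List of [region_set()]s (non-genic entries ignored).
#' @param min_strains Minimum shared strains (default 4, the smallest leaf
#'   count a parsimony topology can resolve).
#' @return List of class `reference_tree`: `tree` (first MP optimum,
#'   unrooted), `mp` (the full [mp_search()] result), `dist` (p-distance
#'   matrix), `strains`, `concat_length`.
#' @export
build_reference_tree <- function(region_sets, min_strains = 4L) {
  genic <- Filter(function(rs) rs$rtype == "genic", region_sets)
  if (!length(genic)) stop("no genic region sets supplied")
  common <- Reduce(intersect, lapply(genic, function(rs) names(rs$members)))
  if (length(common) < min_strains)
    stop("only ", length(common), " strain(s) share all protein-coding ",
         "genes; need >= ", min_strains)
  rows <- setNames(rep("", length(common)), common)
  for (rs in genic) {
    sub <- region_set(rs$region_id, rs$members[common], rs$rtype, rs$frame)
    aln <- progressive_align(sub)
    rows <- paste0(rows, unclass(aln)[common])
  }
  names(rows) <- common
  concat <- new_alignment(rows, region_id = "concatenated")
  mp <- mp_search(concat)
  structure(list(tree = mp$trees[[1L]], mp = mp,
                 dist = p_distance(concat), strains = common,
                 concat_length = nchar(rows[[1L]])),
            class = "reference_tree")
}

## Is the reference topology (restricted to the marker's strains) among the
## minimum-Fitch-score topologies for this marker?  Exact under exhaustive
## search; FALSE whenever the search would be heuristic.
reference_consistent <- function(aln, reference) {
  common <- intersect(reference$strains, names(aln))
  if (length(common) < 4L) return(FALSE)
  if (length(common) > 9L) return(FALSE)      # heuristic regime
  sub <- subset_alignment(aln, common)
  ref_sub <- ape::unroot(ape::keep.tip(reference$tree, common))
  mp <- mp_search(sub)
  if (length(mp$trees) == mp$n_enumerated) return(FALSE)  # nothing resolved
  fitch_score(ref_sub, sub) == mp$best_score
}

#' Evaluate one candidate marker region
#'
#' Aligns the region and scores the three indices of the screen: sensitivity
#' (percent nucleotide difference), specificity (mean bootstrap support over
#' the internal splits of the region's own MP tree) and consistency (the
#' reference topology attains the minimum Fitch score among all enumerated
#' topologies for this region, ties allowed).  The Euclidean distance
#' between the region's p-distance matrix and the reference's, restricted to
#' common strains, quantifies tree similarity.
#'
#' @param rs A [region_set()].
#' @param reference A [build_reference_tree()] result.
#' @param origin Compartment of origin (`pt`, `mt`, `nc`).
#' @param conspecific_pairs Optional list of length-2 strain vectors declared
#'   conspecific; the intraspecies percent difference is averaged over them.
#' @param B,seed Bootstrap replicates and seed.
#' @param diff_method Passed to [percent_difference()].
#' @return One-row data.frame (a marker-evaluation record).
#' @export
evaluate_marker <- function(rs, reference, origin = NA_character_,
                            conspecific_pairs = NULL, B = 100L, seed = 1L,
                            diff_method = "polymorphic") {
  aln <- progressive_align(rs)
  lens <- nchar(rs$members)
  pct_inter <- percent_difference(aln, diff_method)
  pct_intra <- NA_real_
  if (!is.null(conspecific_pairs)) {
    vals <- vapply(conspecific_pairs, function(pr) {
      if (!all(pr %in% names(aln))) return(NA_real_)
      percent_difference(subset_alignment(aln, pr), diff_method)
    }, numeric(1))
    pct_intra <- mean(vals, na.rm = TRUE)
  }
  mean_bs <- NA_real_; euclid <- NA_real_; consistent <- FALSE
  if (length(rs$members) >= 4L) {
    bs <- bootstrap_support(aln, builder = "mp", B = B, seed = seed)
    mean_bs <- mean_internal_support(bs)
    common <- intersect(reference$strains, names(aln))
    if (length(common) >= 3L) {
      sub <- subset_alignment(aln, common)
      euclid <- matrix_euclidean(p_distance(sub),
                                 reference$dist[common, common])
    }
    consistent <- reference_consistent(aln, reference)
  }
  data.frame(
    region_id = rs$region_id, origin = origin, rtype = rs$rtype,
    size_min = min(lens), size_max = max(lens),
    n_members = length(rs$members),
    pct_difference_interspecies = pct_inter,
    pct_difference_intraspecies = pct_intra,
    mean_bootstrap = mean_bs, euclid_to_reference = euclid,
    consistent = consistent, stringsAsFactors = FALSE)
}

#' Rank evaluated markers against a baseline
#'
#' Consistent markers are sorted by interspecies percent difference
#' (descending; ties broken by mean bootstrap then region id) and compared
#' with a baseline marker (e.g. the ITS2 row): the relative sensitivity gain
#' is `100 * (marker% - baseline%) / baseline%`.
#'
#' @param evaluations data.frame of [evaluate_marker()] rows (the baseline
#'   must be one of them).
#' @param baseline_id Region id of the baseline marker.
#' @return List of class `screen_report`: `evaluations` (ranked, with
#'   `rank` and `gain_over_baseline_pct` columns), `baseline_id`,
#'   `n_candidates` (consistent markers, baseline excluded),
#'   `n_above_baseline` (those more sensitive than the baseline).
#' @export
rank_markers <- function(evaluations, baseline_id) {
  ev <- as.data.frame(evaluations)
  if (!baseline_id %in% ev$region_id)
    stop("baseline '", baseline_id, "' missing from evaluations")
  base_pct <- ev$pct_difference_interspecies[ev$region_id == baseline_id][1L]
  ev$gain_over_baseline_pct <-
    100 * (ev$pct_difference_interspecies - base_pct) / base_pct
  cand <- ev[ev$consistent & ev$region_id != baseline_id, , drop = FALSE]
  ord <- order(-cand$pct_difference_interspecies,
               -ifelse(is.na(cand$mean_bootstrap), -Inf, cand$mean_bootstrap),
               cand$region_id)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rest <- ev[!(ev$consistent & ev$region_id != baseline_id), , drop = FALSE]
  rest <- rest[order(-rest$pct_difference_interspecies), , drop = FALSE]
  rest$rank <- NA_integer_
  out <- rbind(cand, rest)
  rownames(out) <- NULL
  structure(list(
    evaluations = out, baseline_id = baseline_id,
    n_candidates = nrow(cand),
    n_above_baseline = sum(cand$pct_difference_interspecies > base_pct)),
    class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>", x$n_candidates, "consistent candidates,",
      x$n_above_baseline, "more sensitive than baseline '",
      x$baseline_id, "'\n")
  invisible(x)
}

#' Evaluate and rank every region in one call
#'
#' @param region_sets List of [region_set()]s to screen (the baseline region
#'   must be among them, e.g. an ITS2 set added with origin `nc`).
#' @param reference A [build_reference_tree()] result.
#' @param baseline_id Baseline region id.
#' @param origins Optional named character vector region_id -> origin.
#' @inheritParams evaluate_marker
#' @return A [rank_markers()] report.
#' @export
screen_markers <- function(region_sets, reference, baseline_id,
                           origins = NULL, conspecific_pairs = NULL,
                           B = 100L, seed = 1L,
                           diff_method = "polymorphic") {
  ev <- do.call(rbind, lapply(region_sets, function(rs)
    evaluate_marker(rs, reference,
                    origin = origins[rs$region_id] %||% NA_character_,
                    conspecific_pairs = conspecific_pairs,
                    B = B, seed = seed, diff_method = diff_method)))
  rank_markers(ev, baseline_id)
}
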