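#' p-distance matrix of an alignment
#'
#' Proportion of differing sites per strain pair over comparable sites.
#' Gap (`-`) and ambiguous (`N`) positions are excluded: per pair under
#' `pairwise` deletion (the MEGA default for p-distance), or any such column
#' under `complete` deletion.
#'
#' @param aln A [new_alignment()].
#' @param deletion_mode `"pairwise"` (default) or `"complete"`.
#' @return Symmetric numeric matrix with strain dimnames; entries in
#'   `[0, 1]`, zero diagonal.
#' @export
p_distance <- function(aln, deletion_mode = c("pairwise", "complete")) {
  deletion_mode <- match.arg(deletion_mode)
  m <- aln_matrix(aln)
  miss <- m == "-" | m == "N"
  if (deletion_mode == "complete") {
    keep <- colSums(miss) == 0L
    m <- m[, keep, drop = FALSE]
    miss <- miss[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !miss[i, ] & !miss[j, ]
    if (!any(ok))
      stop("zero comparable sites between ", rownames(m)[i], " and ",
           rownames(m)[j])
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  d
}

#' Percent nucleotide difference (sensitivity index)
#'
#' The marker-sensitivity index: by default, 100 times the proportion of
#' polymorphic alignment columns (columns with at least two distinct
#' characters, gaps counting as a state against bases, `N` treated as
#' missing).  The alternative reading, mean pairwise p-distance times 100,
#' is available via `method = "mean_pairwise"`.
#'
#' @param aln A [new_alignment()].
#' @param method `"polymorphic"` (default) or `"mean_pairwise"`.
#' @return Percentage in `[0, 100]`.
#' @export
percent_difference <- function(aln,
                               method = c("polymorphic", "mean_pairwise")) {
  method <- match.arg(method)
  m <- aln_matrix(aln)
  if (method == "mean_pairwise") {
    d <- p_distance(aln, "pairwise")
    return(100 * mean(d[lower.tri(d)]))
  }
  npoly <- sum(apply(m, 2L, function(col) {
    s <- unique(col[col != "N"])
    length(s) >= 2L
  }))
  100 * npoly / ncol(m)
}

#' SNP summary arithmetic
#'
#' Assembles the substitution bookkeeping used throughout the package:
#' transition + transversion + indel + multiallelic columns partition the
#' variant columns exactly, and the Ts/Tv ratio is transitions over
#' transversions.
#'
#' @param n_transition,n_transversion,n_indel Counts of biallelic
#'   purine-purine/pyrimidine-pyrimidine columns, purine-pyrimidine columns,
#'   and gap-containing columns.
#' @param n_multiallelic Columns with three or more distinct bases.
#' @param n_indel_events Number of contiguous gap runs (an indel event may
#'   span several columns).
#' @param n_syn,n_nonsyn Optional coding-effect counts.
#' @return A list with the counts, `total` (all variant columns) and
#'   `ts_tv_ratio`.
#' @export
snp_summary <- function(n_transition, n_transversion, n_indel = 0L,
                        n_multiallelic = 0L, n_indel_events = NA_integer_,
                        n_syn = NA_integer_, n_nonsyn = NA_integer_) {
  list(
    n_transition = n_transition,
    n_transversion = n_transversion,
    n_indel = n_indel,
    n_multiallelic = n_multiallelic,
    n_indel_events = n_indel_events,
    n_syn = n_syn,
    n_nonsyn = n_nonsyn,
    total = n_transition + n_transversion + n_indel + n_multiallelic,
    ts_tv_ratio = if (n_transversion > 0) n_transition / n_transversion
                  else NA_real_
  )
}

is_transition <- function(b1, b2) {
  (b1 %in% PURINES && b2 %in% PURINES) ||
    (b1 %in% PYRIMIDINES && b2 %in% PYRIMIDINES)
}

#' Classify SNPs in an alignment
#'
#' Every variant column is classified: biallelic base substitutions as
#' transition (purine-purine or pyrimidine-pyrimidine) or transversion
#' (purine-pyrimidine); columns containing `-` as indels; columns with three
#' or more bases tallied separately as multiallelic.  With a codon `frame`,
#' biallelic substitutions are annotated synonymous/nonsynonymous and gap
#' runs whose length is a multiple of 3 as frame-preserving `triplet_indel`
#' (else `frameshift`).
#'
#' @param aln A [new_alignment()].
#' @param frame Codon frame (1 = rows start in-frame); defaults to the
#'   alignment's own `frame` attribute.  Rows whose ungapped length is not a
#'   multiple of 3 trigger a warning and coding effects are omitted.
#' @param code NCBI genetic code id (see [Biostrings::getGeneticCode()]).
#' @return List with `records` (data.frame: column, klass, coding_effect,
#'   plus one allele column per strain) and `summary` (see [snp_summary()]).
#' @export
classify_snps <- function(aln, frame = attr(aln, "frame"), code = "1") {
  m <- aln_matrix(aln)
  L <- ncol(m)
  coding <- !is.null(frame) && !is.na(frame)
  if (coding) {
    unglen <- apply(m, 1L, function(r) sum(r != "-"))
    if (any(unglen %% 3L != 0L)) {
      warning("ungapped row length not a multiple of 3; coding effects omitted")
      coding <- FALSE
    }
  }
  gcode <- Biostrings::getGeneticCode(as.character(code))
  translate_codon <- function(cd) gcode[[paste(cd, collapse = "")]] %||% "X"

  ## per-row gap runs, for indel event counting and triplet classification
  runs <- list()
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    gap <- which(r$values)
    if (length(gap))
      runs[[length(runs) + 1L]] <-
        data.frame(row = i, start = starts[gap], end = ends[gap],
                   len = r$lengths[gap])
  }
  runs <- if (length(runs)) do.call(rbind, runs) else
    data.frame(row = integer(), start = integer(), end = integer(),
               len = integer())

  cols <- integer(0); klass <- character(0); effect <- character(0)
  for (cc in seq_len(L)) {
    col <- m[, cc]
    states <- unique(col[col != "N"])
    if (length(states) < 2L) next
    cols <- c(cols, cc)
    if ("-" %in% states) {
      klass <- c(klass, "indel")
      if (coding) {
        cover <- runs[runs$start <= cc & runs$end >= cc, , drop = FALSE]
        effect <- c(effect,
                    if (nrow(cover) && all(cover$len %% 3L == 0L))
                      "triplet_indel" else "frameshift")
      } else effect <- c(effect, NA_character_)
    } else if (length(states) == 2L) {
      klass <- c(klass, if (is_transition(states[1L], states[2L]))
        "transition" else "transversion")
      if (coding) {
        reps <- vapply(states, function(s) which(col == s)[1L], integer(1))
        aas <- vapply(reps, function(i) {
          ung <- which(m[i, ] != "-")
          u <- match(cc, ung)
          idx <- (u - 1L) %/% 3L
          translate_codon(m[i, ung[(3L * idx + 1L):(3L * idx + 3L)]])
        }, character(1))
        effect <- c(effect, if (aas[1L] == aas[2L]) "synonymous"
                    else "nonsynonymous")
      } else effect <- c(effect, NA_character_)
    } else {
      klass <- c(klass, "multiallelic")
      effect <- c(effect, NA_character_)
    }
  }
  records <- data.frame(column = cols, klass = klass, coding_effect = effect,
                        stringsAsFactors = FALSE)
  if (length(cols)) {
    alle <- t(m[, cols, drop = FALSE])
    colnames(alle) <- rownames(m)
    records <- cbind(records, as.data.frame(alle, stringsAsFactors = FALSE))
  }
  summary <- snp_summary(
    n_transition = sum(klass == "transition"),
    n_transversion = sum(klass == "transversion"),
    n_indel = sum(klass == "indel"),
    n_multiallelic = sum(klass == "multiallelic"),
    n_indel_events = nrow(runs),
    n_syn = if (coding) sum(effect == "synonymous", na.rm = TRUE)
            else NA_integer_,
    n_nonsyn = if (coding) sum(effect == "nonsynonymous", na.rm = TRUE)
               else NA_integer_
  )
  list(records = records, summary = summary)
}

#' Write a SNP report as TSV
#' @param snps Result of [classify_snps()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_snp_report <- function(snps, path) {
  write.table(snps$records, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
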