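## Perfect microsatellite (SSR) detection and cross-strain comparison.

## Smallest rotation of a motif, the canonical representative.
canonical_motif <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  rot <- vapply(seq_len(u), function(i)
    paste0(substr(motif, i, u), substr(motif, 1L, i - 1L)), character(1))
  min(rot)
}

## TRUE when the motif is not a repetition of a shorter unit.
is_primitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(TRUE)
  for (d in seq_len(u - 1L)) {
    if (u %% d != 0L) next
    if (strrep(substr(motif, 1L, d), u %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Detect perfect microsatellites in a genome
#'
#' Perfect tandem repeats of primitive 1--6 nt motifs, maximal in full units
#' and not extendable by a unit in either direction.  A run is reported once,
#' at the unit length of its primitive motif (poly-A is mono, not di); motifs
#' are canonicalized to their lexicographically smallest rotation.  Circular
#' genomes are scanned on the doubled sequence and loci deduplicated.
#'
#' @param genome A [genome_record()] (or a plain DNA string).
#' @param features Optional feature data.frame for the same genome, used to
#'   assign `context` (genic/intergenic) and `context_name` (gene or
#'   `left-right` flank pair).
#' @param min_len Minimum total length (nt) per unit length 1..6.  Defaults
#'   mono >= 10, di >= 10, tri--hexa >= 12.
#' @return data.frame: genome, organelle, motif, unit_len, copies,
#'   total_len, start, end, context, context_name; sorted by start.
#' @export
find_ssrs <- function(genome, features = NULL,
                      min_len = c(10L, 10L, 12L, 12L, 12L, 12L)) {
  if (inherits(genome, "genome_record")) {
    s <- genome$sequence; sid <- genome$strain_id
    org <- genome$compartment; circular <- genome$circular
  } else {
    s <- toupper(genome); sid <- NA_character_
    org <- NA_character_; circular <- FALSE
  }
  n <- nchar(s)
  scan_s <- if (circular) paste0(s, s) else s
  x <- seq_chars(scan_s)
  n2 <- length(x)
  out <- list()
  for (u in 1:6) {
    if (n2 <= u) next
    eq <- x[seq_len(n2 - u)] == x[(u + 1L):n2]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      total_run <- r$lengths[i] + u            # length of the periodic span
      copies <- total_run %/% u
      tl <- copies * u
      if (copies < 2L || tl < min_len[u]) next
      st <- starts[i]
      motif <- substr(scan_s, st, st + u - 1L)
      if (!is_primitive(motif)) next           # caught at its true period
      out[[length(out) + 1L]] <- data.frame(
        start = st, unit_len = u, copies = copies, total_len = tl,
        motif = canonical_motif(motif), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(genome = character(), organelle = character(),
                      motif = character(), unit_len = integer(),
                      copies = integer(), total_len = integer(),
                      start = integer(), end = integer(),
                      context = character(), context_name = character()))
  loci <- do.call(rbind, out)
  loci$end <- loci$start + loci$total_len - 1L
  if (circular) {
    loci <- loci[loci$start <= n, , drop = FALSE]
    wrap <- loci$end > n
    loci$end[wrap] <- loci$end[wrap] - n
  }
  loci <- loci[!duplicated(loci[c("motif", "start")]), , drop = FALSE]
  loci <- loci[order(loci$start), , drop = FALSE]

  ctx <- rep("intergenic", nrow(loci))
  ctxn <- rep(NA_character_, nrow(loci))
  if (!is.null(features) && nrow(features)) {
    f <- features[!features$wraps_origin, , drop = FALSE]
    f <- f[order(f$start), , drop = FALSE]
    for (i in seq_len(nrow(loci))) {
      st <- loci$start[i]; en <- if (loci$end[i] >= st) loci$end[i] else n
      hit <- which(f$start <= en & f$end >= st)
      if (length(hit)) {
        ctx[i] <- "genic"
        ctxn[i] <- f$name[hit[1L]]
      } else {
        left <- which(f$end < st)
        right <- which(f$start > en)
        lname <- if (length(left)) f$name[max(left)] else
          if (circular && nrow(f)) f$name[nrow(f)] else NA_character_
        rname <- if (length(right)) f$name[min(right)] else
          if (circular && nrow(f)) f$name[1L] else NA_character_
        ctxn[i] <- if (!is.na(lname) && !is.na(rname))
          paste0(lname, "-", rname) else NA_character_
      }
    }
  }
  data.frame(genome = sid, organelle = org,
             motif = loci$motif, unit_len = loci$unit_len,
             copies = loci$copies, total_len = loci$total_len,
             start = loci$start, end = loci$end,
             context = ctx, context_name = ctxn,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare SSR panels across strains
#'
#' Loci are matched across strains by (organelle, motif, context name): a
#' locus present in every compared strain is shared (copy-number differences
#' are flagged, not treated as absence); the remainder are strain-specific.
#'
#' @param loci data.frame of [find_ssrs()] rows for two or more strains
#'   (distinguished by the `genome` column), or a list of such data.frames.
#' @return List with `shared` (one row per matched locus: key columns,
#'   per-strain total lengths, `length_polymorphic`) and `specific`
#'   (original locus rows keyed by strain).
#' @export
compare_ssrs <- function(loci) {
  if (is.list(loci) && !is.data.frame(loci))
    loci <- do.call(rbind, loci)
  strains <- unique(loci$genome)
  if (length(strains) < 2L) stop("compare_ssrs: need loci from >= 2 strains")
  key <- paste(loci$organelle, loci$motif, loci$context_name, sep = "\r")
  by_key <- split(seq_len(nrow(loci)), key)
  shared_rows <- list(); specific_idx <- integer(0)
  for (k in names(by_key)) {
    idx <- by_key[[k]]
    have <- unique(loci$genome[idx])
    if (setequal(have, strains)) {
      lens <- vapply(strains, function(s)
        loci$total_len[idx[loci$genome[idx] == s][1L]], numeric(1))
      r <- loci[idx[1L], c("organelle", "motif", "unit_len",
                           "context", "context_name")]
      for (s in strains) r[[paste0("len_", s)]] <- lens[[s]]
      r$length_polymorphic <- length(unique(lens)) > 1L
      shared_rows[[length(shared_rows) + 1L]] <- r
    } else {
      specific_idx <- c(specific_idx, idx)
    }
  }
  shared <- if (length(shared_rows)) do.call(rbind, shared_rows) else
    data.frame()
  rownames(shared) <- NULL
  specific <- loci[specific_idx, , drop = FALSE]
  specific <- specific[order(specific$genome, specific$start), , drop = FALSE]
  rownames(specific) <- NULL
  list(shared = shared, specific = specific)
}

#' Export SSR loci as BED (0-based half-open)
#' @param loci [find_ssrs()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ssr_bed <- function(loci, path) {
  z <- to_zero_based(loci$start, loci$end)
  bed <- data.frame(loci$genome, z$start, z$end,
                    paste0("(", loci$motif, ")", loci$copies))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
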