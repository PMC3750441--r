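## Intraspecies typing: sliding-window variable-region discovery between two
## conspecific genomes, and MLST allele calling for additional strains.

#' Sliding-window segregating-site scan of a pairwise alignment
#'
#' Counts, per window, the columns where the two rows carry differing
#' non-gap characters (`S`).  Gap columns are excluded from `S` and tallied
#' separately; `N` is missing.  Windows have full length except a final
#' truncated window appended so the alignment is covered end to end.
#'
#' @param aln A 2-row [new_alignment()].
#' @param window_len Window length in sites (default 500).
#' @param step Step size in sites (default 25).
#' @return An object of class `window_scan`: data.frame with `start`, `end`,
#'   `S`, `gaps` on alignment coordinates, plus `window_len`/`step`
#'   attributes.
#' @export
window_scan <- function(aln, window_len = 500L, step = 25L) {
  m <- aln_matrix(aln)
  if (nrow(m) != 2L) stop("window_scan: alignment must have exactly 2 rows")
  L <- ncol(m)
  gap <- m[1L, ] == "-" | m[2L, ] == "-"
  nn <- m[1L, ] == "N" | m[2L, ] == "N"
  mism <- !gap & !nn & m[1L, ] != m[2L, ]
  cs_m <- c(0L, cumsum(mism))
  cs_g <- c(0L, cumsum(gap))
  if (L < window_len) {
    warning("alignment shorter than window_len; single full-length window")
    starts <- 1L; ends <- L
  } else {
    starts <- seq.int(1L, L - window_len + 1L, by = step)
    ends <- starts + window_len - 1L
    if (max(ends) < L) {                      # final truncated window
      starts <- c(starts, starts[length(starts)] + step)
      ends <- c(ends, L)
    }
  }
  scan <- data.frame(
    start = starts, end = ends,
    S = cs_m[ends + 1L] - cs_m[starts],
    gaps = cs_g[ends + 1L] - cs_g[starts])
  structure(scan, class = c("window_scan", "data.frame"),
            window_len = window_len, step = step)
}

#' Select highly variable regions from a window scan
#'
#' Windows reaching the segregating-site threshold (default `S >= 6`) are
#' merged when overlapping or adjacent; each merged interval carries the
#' maximum `S` among its windows.
#'
#' @param scan A [window_scan()].
#' @param threshold Minimum `S` (default 6).
#' @return data.frame with `start`, `end`, `max_S` (possibly 0 rows).
#' @export
call_variable_regions <- function(scan, threshold = 6L) {
  sel <- scan[scan$S >= threshold, , drop = FALSE]
  if (!nrow(sel))
    return(data.frame(start = integer(), end = integer(),
                      max_S = integer()))
  sel <- sel[order(sel$start), , drop = FALSE]
  out <- list()
  cur <- sel[1L, ]
  cur_max <- cur$S
  for (i in seq_len(nrow(sel))[-1L]) {
    w <- sel[i, ]
    if (w$start <= cur$end + 1L) {
      cur$end <- max(cur$end, w$end)
      cur_max <- max(cur_max, w$S)
    } else {
      out[[length(out) + 1L]] <- data.frame(start = cur$start, end = cur$end,
                                            max_S = cur_max)
      cur <- w; cur_max <- w$S
    }
  }
  out[[length(out) + 1L]] <- data.frame(start = cur$start, end = cur$end,
                                        max_S = cur_max)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Map alignment columns to 1-based ungapped positions on one row.
aln_col_to_seq_pos <- function(row_chars) cumsum(row_chars != "-")

## Name an interval on the reference genome from its annotation: the gene
## containing it, else "left-right" of the nearest flanking features.
interval_locus_name <- function(features, start, end) {
  if (is.null(features) || !nrow(features))
    return(paste0("pos", start, "-", end))
  f <- features[!features$wraps_origin, , drop = FALSE]
  f <- f[order(f$start), , drop = FALSE]
  contain <- which(f$start <= start & f$end >= end)
  if (length(contain)) return(f$name[contain[1L]])
  left <- which(f$start <= start)
  right <- which(f$end >= end)
  lname <- if (length(left)) f$name[max(left)] else NA_character_
  rname <- if (length(right)) f$name[min(right)] else NA_character_
  if (is.na(lname) && is.na(rname)) return(paste0("pos", start, "-", end))
  if (is.na(lname)) return(rname)
  if (is.na(rname)) return(lname)
  if (lname == rname) lname else paste0(lname, "-", rname)
}

#' Discover MLST loci between two conspecific genomes
#'
#' Aligns the two genomes ([anchored_align()]), scans for segregating sites,
#' merges windows over threshold and converts each interval into an MLST
#' locus on reference-genome coordinates: the locus sequence, its flanking
#' anchors, and every variant position with the two strains' alleles.
#'
#' @param ref,alt [genome_record()]s of the reference and second strain.
#' @param features Optional features of the reference genome (locus naming).
#' @param window_len,step,threshold See [window_scan()] and
#'   [call_variable_regions()].
#' @param flank Flanking-anchor length in bp used later to recover loci from
#'   further strains (default 25).
#' @param k Anchor k-mer size for the genome alignment.
#' @return List of class `mlst_loci`: one element per locus with `locus_id`,
#'   `interval` (ref coordinates), `ref_seq`, `left_flank`, `right_flank`,
#'   `variant_positions`, `ref_alleles`, `alt_alleles`, `max_S`.
#' @export
discover_mlst_loci <- function(ref, alt, features = NULL,
                               window_len = 500L, step = 25L,
                               threshold = 6L, flank = 25L, k = 21L) {
  aln <- anchored_align(ref$sequence, alt$sequence, k = k,
                        ids = c(ref$strain_id, alt$strain_id))
  scan <- window_scan(aln, window_len, step)
  ivs <- call_variable_regions(scan, threshold)
  m <- aln_matrix(aln)
  rpos <- aln_col_to_seq_pos(m[1L, ])
  refseq <- ref$sequence
  loci <- lapply(seq_len(nrow(ivs)), function(i) {
    a0 <- ivs$start[i]; a1 <- ivs$end[i]
    vs <- which(m[1L, ] != m[2L, ] & m[1L, ] != "N" & m[2L, ] != "N")
    vs <- vs[vs >= a0 & vs <= a1]
    ## reported locus interval: the span of its variant columns (published
    ## MLST loci are delimited by their first and last SNP); the anchoring
    ## and recovery machinery keeps the full merged-window interval, whose
    ## flanks lie in background-rate sequence
    t0 <- if (length(vs)) min(vs) else a0
    t1 <- if (length(vs)) max(vs) else a1
    w0 <- max(rpos[a0], 1L); w1 <- rpos[a1]
    list(locus_id = interval_locus_name(features, max(rpos[t0], 1L),
                                        rpos[t1]),
         interval = c(start = max(rpos[t0], 1L), end = rpos[t1]),
         window_interval = c(start = w0, end = w1),
         ref_seq = substr(refseq, w0, w1),
         left_flank = substr(refseq, max(1L, w0 - flank), w0 - 1L),
         right_flank = substr(refseq, w1 + 1L,
                              min(nchar(refseq), w1 + flank)),
         variant_positions = rpos[vs],
         ref_alleles = m[1L, vs],
         alt_alleles = m[2L, vs],
         max_S = ivs$max_S[i])
  })
  structure(loci, class = "mlst_loci",
            ref_strain = ref$strain_id, alt_strain = alt$strain_id)
}

#' MLST profile from an allele table
#'
#' Pairwise difference counts (and an NJ tree when three or more strains are
#' typed) from a table of variant positions by strain.  Indel alleles (`-`)
#' count as ordinary genotype characters; missing calls (`NA` or empty) are
#' excluded pairwise.
#'
#' @param alleles data.frame with columns `region`, `position`, then one
#'   column of single-character alleles per strain.
#' @return List of class `mlst_profile`: `alleles`, `diffs` (symmetric
#'   count matrix), `per_region` (named list of per-region diff matrices),
#'   `tree` (`ape::phylo` or `NULL`).
#' @export
mlst_profile <- function(alleles) {
  strains <- setdiff(names(alleles), c("region", "position"))
  if (length(strains) < 2L) stop("mlst_profile: need >= 2 strain columns")
  av <- as.matrix(alleles[strains])
  av[av == ""] <- NA_character_
  count_diffs <- function(rows) {
    d <- matrix(0L, length(strains), length(strains),
                dimnames = list(strains, strains))
    for (i in seq_along(strains)[-length(strains)])
      for (j in (i + 1L):length(strains)) {
        ok <- !is.na(av[rows, i]) & !is.na(av[rows, j])
        d[i, j] <- d[j, i] <- sum(av[rows, i][ok] != av[rows, j][ok])
      }
    d
  }
  all_d <- count_diffs(seq_len(nrow(av)))
  per_region <- lapply(split(seq_len(nrow(av)), alleles$region), count_diffs)
  tree <- if (length(strains) >= 3L)
    nj_tree(all_d / max(1L, nrow(av))) else NULL
  structure(list(alleles = alleles, diffs = all_d,
                 per_region = per_region, tree = tree),
            class = "mlst_profile")
}

#' @export
print.mlst_profile <- function(x, ...) {
  cat("<mlst_profile>", nrow(x$alleles), "variant positions,",
      ncol(x$diffs), "strains\n")
  print(x$diffs)
  invisible(x)
}

## Recover one locus sequence from a strain genome via flanking anchors;
## a couple of mismatches are tolerated so slightly diverged strains still
## anchor.
locate_locus <- function(locus, seq, max_mismatch = 2L) {
  subject <- Biostrings::DNAString(seq)
  find1 <- function(pat) {
    if (!nzchar(pat)) return(NA_integer_)
    hits <- Biostrings::matchPattern(pat, subject,
                                     max.mismatch = max_mismatch)
    if (!length(hits)) return(NA_integer_)
    as.integer(BiocGenerics::start(hits))[1L]
  }
  lpos <- find1(locus$left_flank)
  rpos <- find1(locus$right_flank)
  if (is.na(lpos) || is.na(rpos)) return(NULL)
  s0 <- lpos + nchar(locus$left_flank)
  s1 <- rpos - 1L
  if (s1 < s0) return(NULL)
  substr(seq, s0, s1)
}

#' Genotype strains at MLST loci
#'
#' Recovers each locus from each strain (by flanking-anchor search), aligns
#' it to the reference locus sequence and reads the allele at every variant
#' position.  Strains where a locus cannot be recovered get missing alleles
#' with a warning.
#'
#' @param loci [discover_mlst_loci()] result.
#' @param genomes Named list of [genome_record()]s (or DNA strings) to type;
#'   should include the reference strain for a self-check.
#' @return An [mlst_profile()] over all variant positions (positions are
#'   1-based on the reference genome, Table-style).
#' @export
genotype_mlst <- function(loci, genomes) {
  seqs <- vapply(genomes, function(g)
    if (inherits(g, "genome_record")) g$sequence else toupper(g), character(1))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    names(seqs) <- vapply(genomes, function(g) g$strain_id, character(1))
  rows <- list()
  for (lc in loci) {
    if (!length(lc$variant_positions)) next
    tbl <- data.frame(region = lc$locus_id,
                      position = lc$variant_positions,
                      stringsAsFactors = FALSE)
    rel <- lc$variant_positions - lc$window_interval[["start"]] + 1L
    for (s in names(seqs)) {
      obs <- locate_locus(lc, seqs[[s]])
      if (is.null(obs)) {
        warning("locus ", lc$locus_id, " not found in strain ", s)
        tbl[[s]] <- NA_character_
        next
      }
      pr <- pairwise_align(lc$ref_seq, obs)
      rr <- seq_chars(pr[[1L]]); ss <- seq_chars(pr[[2L]])
      rmap <- aln_col_to_seq_pos(rr)
      cols <- vapply(rel, function(p) which(rmap == p & rr != "-")[1L],
                     integer(1))
      tbl[[s]] <- ifelse(is.na(cols), NA_character_, ss[cols])
    }
    rows[[length(rows) + 1L]] <- tbl
  }
  if (!length(rows)) stop("genotype_mlst: loci carry no variant positions")
  mlst_profile(do.call(rbind, rows))
}

#' Write MLST loci as BED and the allele table as TSV
#' @param loci [discover_mlst_loci()] result.
#' @param profile [mlst_profile()] result.
#' @param bed_path,tsv_path Output files.
#' @return Invisibly, the paths written.
#' @export
write_mlst_report <- function(loci, profile, bed_path, tsv_path) {
  iv <- do.call(rbind, lapply(loci, function(lc)
    data.frame(chrom = attr(loci, "ref_strain"),
               start = lc$interval[["start"]] - 1L,
               end = lc$interval[["end"]], name = lc$locus_id)))
  write.table(iv, bed_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(profile$alleles, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(bed_path, tsv_path))
}
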