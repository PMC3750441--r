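#' Genome record constructor
#'
#' One strain's organelle genome: a circular (by default) DNA sequence with a
#' compartment label.  Sizes in this genus run roughly 38--120 kb but no size
#' bound is enforced.
#'
#' @param strain_id Strain label, unique within a run.
#' @param sequence DNA string over A, C, G, T, N.
#' @param compartment `"pt"` (plastid) or `"mt"` (mitochondrial).
#' @param circular Logical; organelle genomes are circular.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(strain_id, sequence, compartment = c("pt", "mt"),
                          circular = TRUE) {
  compartment <- match.arg(compartment)
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence for strain ", strain_id)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence of ", strain_id, " contains characters outside {A,C,G,T,N}")
  structure(
    list(strain_id = strain_id, compartment = compartment,
         sequence = sequence, circular = circular),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat("<genome_record> ", x$strain_id, " (", x$compartment, ", ",
      nchar(x$sequence), " bp, ",
      if (x$circular) "circular" else "linear", ")\n", sep = "")
  invisible(x)
}

#' Feature table constructor
#'
#' Annotated features on one or more genomes, GFF3-style 1-based inclusive
#' coordinates on the forward strand.  A feature whose `end` is smaller than
#' its `start` wraps the origin of a circular genome.
#'
#' @param genome Strain id each feature belongs to.
#' @param name Locus label (e.g. `rps3`, `trnQ(uug)`); must be non-empty and
#'   unique within a genome (duplicated inverted-repeat copies must carry
#'   distinct names such as `psbV` / `psbV_1`).
#' @param ftype Feature type: `gene`, `tRNA`, `rRNA` or `orf`.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @return A `data.frame` with a `wraps_origin` column (`end < start`).
#' @export
feature_table <- function(genome, name, ftype = "gene", start, end,
                          strand = "+") {
  if (!length(name))
    return(data.frame(genome = character(), name = character(),
                      ftype = character(), start = integer(),
                      end = integer(), strand = character(),
                      wraps_origin = logical(), stringsAsFactors = FALSE))
  stopifnot(all(nzchar(name)))
  if (!all(ftype %in% c("gene", "tRNA", "rRNA", "orf")))
    stop("ftype must be one of gene, tRNA, rRNA, orf")
  data.frame(
    genome = genome, name = name, ftype = ftype,
    start = as.integer(start), end = as.integer(end), strand = strand,
    wraps_origin = as.integer(end) < as.integer(start),
    stringsAsFactors = FALSE
  )
}

## Parse one GFF3 file (columns seqid, type, start, end, strand, attributes
## with a Name= key).  Hand-parsed because the circular-wrap convention
## (end < start) used here is not legal GFF3 for standard importers.
parse_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(feature_table(character(), character(), "gene", integer(), integer()))
  f <- read.delim(text = paste(lines, collapse = "\n"), header = FALSE,
                  stringsAsFactors = FALSE)
  if (ncol(f) < 9L) stop("GFF3 file ", path, " has fewer than 9 columns")
  nm <- sub(".*Name=([^;]+).*", "\\1", f[[9L]])
  no_name <- !grepl("Name=", f[[9L]])
  nm[no_name] <- sub(".*ID=([^;]+).*", "\\1", f[[9L]][no_name])
  ftype <- f[[3L]]
  ftype[!ftype %in% c("gene", "tRNA", "rRNA", "orf")] <- "gene"
  feature_table(genome = f[[1L]], name = nm, ftype = ftype,
                start = f[[4L]], end = f[[5L]], strand = f[[7L]])
}

#' Load genomes and annotations
#'
#' Reads multi-record FASTA files and GFF3 annotations, attaching features to
#' genomes by sequence id.  `wraps_origin` is set on circular genomes where a
#' feature's end precedes its start.
#'
#' @param fasta_paths FASTA file(s); each record id is a strain id.
#' @param gff_paths GFF3 file(s); column 1 must match a strain id, column 9
#'   must carry a `Name=` (or `ID=`) attribute.
#' @param compartment Compartment label applied to all genomes read.
#' @param circular Logical, applied to all genomes read.
#' @return A list with `genomes` (named list of [genome_record()]) and
#'   `features` (data.frame).
#' @export
load_genomes <- function(fasta_paths, gff_paths = character(),
                         compartment = c("pt", "mt"), circular = TRUE) {
  compartment <- match.arg(compartment)
  genomes <- list()
  for (fp in fasta_paths) {
    ss <- Biostrings::readDNAStringSet(fp)
    ids <- sub("\\s.*", "", names(ss))
    for (i in seq_along(ss)) {
      if (ids[i] %in% names(genomes))
        stop("duplicate strain_id '", ids[i], "' across FASTA records")
      genomes[[ids[i]]] <- genome_record(ids[i], as.character(ss[[i]]),
                                         compartment, circular)
    }
  }
  feats <- do.call(rbind, lapply(gff_paths, parse_gff3))
  if (is.null(feats))
    feats <- feature_table(character(), character(), "gene",
                           integer(), integer())
  if (nrow(feats)) {
    unknown <- setdiff(unique(feats$genome), names(genomes))
    if (length(unknown))
      stop("features reference unknown genomes: ",
           paste(unknown, collapse = ", "))
    for (i in seq_len(nrow(feats))) {
      n <- nchar(genomes[[feats$genome[i]]]$sequence)
      if (feats$start[i] < 1L || feats$start[i] > n ||
          feats$end[i] < 1L || feats$end[i] > n)
        stop("feature '", feats$name[i], "' on ", feats$genome[i],
             " has coordinates [", feats$start[i], ", ", feats$end[i],
             "] outside genome length ", n)
      if (feats$wraps_origin[i] && !circular)
        stop("feature '", feats$name[i], "' wraps the origin of a ",
             "non-circular genome")
    }
  }
  list(genomes = genomes, features = feats)
}

#' Extract the sequence of one feature
#'
#' Handles origin wrap on circular genomes and reverse-complements
#' minus-strand features.
#'
#' @param genome A [genome_record()].
#' @param feature One row of a feature table.
#' @return DNA string.
#' @export
extract_feature_seq <- function(genome, feature) {
  s <- circular_substr(genome$sequence, feature$start, feature$end,
                       genome$circular)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

#' Region set constructor
#'
#' An orthologous set of sequences for one candidate marker region across
#' strains.
#'
#' @param region_id Locus name (genic) or `"left-right"` flank pair
#'   (intergenic).
#' @param members Named character vector, strain id to DNA string.
#' @param rtype `"genic"` or `"intergenic"`.
#' @param frame Optional codon frame (genic only); `1` means the member
#'   sequences start in-frame.
#' @return An object of class `region_set`.
#' @export
region_set <- function(region_id, members, rtype = c("genic", "intergenic"),
                       frame = NULL) {
  rtype <- match.arg(rtype)
  if (length(members) < 2L)
    stop("region '", region_id, "' needs >= 2 members")
  if (any(!nzchar(members)))
    stop("region '", region_id, "' has empty member sequences")
  structure(
    list(region_id = region_id, rtype = rtype,
         members = members, frame = frame),
    class = "region_set"
  )
}

#' @export
print.region_set <- function(x, ...) {
  cat("<region_set> ", x$region_id, " (", x$rtype, ", ",
      length(x$members), " members, ",
      min(nchar(x$members)), "-", max(nchar(x$members)), " bp)\n", sep = "")
  invisible(x)
}

#' Extract orthologous genic and intergenic region sets
#'
#' Orthology is by exact feature-name match across strains.  One genic set is
#' produced per feature name present in at least `min_members` strains
#' (minus-strand members reverse-complemented); one intergenic set per
#' ordered adjacent feature pair shared by at least `min_members` strains,
#' named `"<left>-<right>"`.  Pairs whose spacer has length <= 0 in a genome
#' (overlapping or abutting features) contribute no member from that genome.
#'
#' @param genomes Named list of [genome_record()].
#' @param features Feature data.frame (see [feature_table()]).
#' @param min_members Minimum strains a region must span (default 2).
#' @param genic_frame Frame recorded on genic sets whose `ftype` is `gene` or
#'   `orf` (default 1, i.e. annotated genes start in-frame).
#' @return List of [region_set()] objects, genic sets first.
#' @export
extract_region_sets <- function(genomes, features, min_members = 2L,
                                genic_frame = 1L) {
  if (!nrow(features)) {
    warning("no features; no region sets extracted")
    return(list())
  }
  dup <- unlist(lapply(split(features$name, features$genome), function(x)
    x[duplicated(x)]))
  if (length(dup))
    stop("duplicated feature names within a genome (rename copies, e.g. ",
         "psbV_1): ", paste(unique(dup), collapse = ", "))

  sets <- list()
  ## genic
  for (nm in unique(features$name)) {
    rows <- features[features$name == nm, , drop = FALSE]
    if (nrow(rows) < min_members) next
    members <- vapply(seq_len(nrow(rows)), function(i)
      extract_feature_seq(genomes[[rows$genome[i]]], rows[i, ]),
      character(1))
    names(members) <- rows$genome
    coding <- all(rows$ftype %in% c("gene", "orf"))
    sets[[length(sets) + 1L]] <- region_set(
      nm, members, "genic", frame = if (coding) genic_frame else NULL)
  }
  ## intergenic: adjacent pairs per genome in start order (linear adjacency)
  pair_members <- list()
  for (g in names(genomes)) {
    rows <- features[features$genome == g & !features$wraps_origin, ,
                     drop = FALSE]
    rows <- rows[order(rows$start), , drop = FALSE]
    if (nrow(rows) < 2L) next
    for (i in seq_len(nrow(rows) - 1L)) {
      left <- rows[i, ]; right <- rows[i + 1L, ]
      zs <- left$end + 1L; ze <- right$start - 1L
      if (ze < zs) next   # overlap or zero-length spacer
      pid <- paste0(left$name, "-", right$name)
      pair_members[[pid]] <- c(pair_members[[pid]],
                               setNames(substr(genomes[[g]]$sequence, zs, ze),
                                        g))
    }
  }
  for (pid in names(pair_members)) {
    m <- pair_members[[pid]]
    if (length(m) >= min_members)
      sets[[length(sets) + 1L]] <- region_set(pid, m, "intergenic")
  }
  if (!length(sets)) warning("no shared features across strains")
  sets
}

#' Write a region set as multi-FASTA
#'
#' @param rs A [region_set()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(rs, path) {
  x <- Biostrings::DNAStringSet(rs$members)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a region set back from multi-FASTA
#'
#' @param path FASTA file, one record per strain.
#' @param region_id Region label (defaults to file name sans extension).
#' @param rtype Region type.
#' @inheritParams region_set
#' @return A [region_set()].
#' @export
read_region_fasta <- function(path, region_id = NULL,
                              rtype = c("genic", "intergenic"), frame = NULL) {
  rtype <- match.arg(rtype)
  ss <- Biostrings::readDNAStringSet(path)
  members <- setNames(as.character(ss), sub("\\s.*", "", names(ss)))
  region_set(region_id %||% sub("\\.[^.]*$", "", basename(path)),
             members, rtype, frame)
}
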