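## Readers for curated panel tables shipped with the package: a published
## marker-comparison panel, an MLST allele table and an SSR panel for the
## Nannochloropsis oceanica strains IMET1, CCMP531 and CCMP1779.  These let
## the worked examples run without the underlying genome sequences.

#' Read a marker-comparison panel
#'
#' A TSV with one evaluated marker per row (`region_id`, `origin`, `size`,
#' `pct_difference_interspecies`, ...), e.g. the shipped
#' `marker_panel_interspecies.tsv`.  Rows are marked consistent so the panel
#' can be ranked directly with [rank_markers()].
#'
#' @param path TSV path; defaults to the shipped interspecies panel.
#' @return data.frame of marker-evaluation rows.
#' @export
read_marker_panel <- function(path = system.file(
    "extdata", "marker_panel_interspecies.tsv", package = "organphylo")) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  ev$consistent <- TRUE
  ev$mean_bootstrap <- NA_real_
  ev
}

#' Read an MLST allele table
#'
#' A TSV shaped like the intraspecies typing tables of this genus: `region`,
#' `position` (1-based on the reference genome), one single-character allele
#' column per strain, and an optional `effect` column.
#'
#' @param path TSV path; defaults to the shipped *N. oceanica* table.
#' @return data.frame suitable for [mlst_profile()].
#' @export
read_mlst_allele_table <- function(path = system.file(
    "extdata", "mlst_alleles_noceanica.tsv", package = "organphylo")) {
  tbl <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE)
  tbl
}

#' Read an SSR panel
#'
#' A TSV of SSR loci with a `strains` column (comma-separated strain ids
#' carrying the locus); expanded to one row per strain so it can be fed to
#' [compare_ssrs()].
#'
#' @param path TSV path; defaults to the shipped *N. oceanica* panel.
#' @return data.frame of per-strain SSR locus rows (`genome`, `organelle`,
#'   `motif`, `total_len`, `context`, `context_name`).
#' @export
read_ssr_panel <- function(path = system.file(
    "extdata", "ssr_panel_noceanica.tsv", package = "organphylo")) {
  tbl <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  rows <- lapply(seq_len(nrow(tbl)), function(i) {
    strains <- strsplit(tbl$strains[i], ",", fixed = TRUE)[[1L]]
    data.frame(genome = trimws(strains), organelle = tbl$organelle[i],
               motif = tbl$motif[i], unit_len = nchar(tbl$motif[i]),
               total_len = tbl$total_len[i],
               context = tbl$context[i], context_name = tbl$context_name[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$copies <- out$total_len %/% out$unit_len
  out$start <- NA_integer_
  out$end <- NA_integer_
  out
}
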