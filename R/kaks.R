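## Nei-Gojobori (1986) synonymous/nonsynonymous rates with Jukes-Cantor
## correction.  Site counting and pathway averaging follow the classic NG86
## conventions: mutations to stop codons are excluded from site denominators
## and mutational pathways passing through a stop are discarded.

codon_neighbours <- function(codon) {
  out <- character(0)
  for (pos in 1:3) for (b in DNA_BASES) {
    if (b == codon[pos]) next
    nb <- codon; nb[pos] <- b
    out <- c(out, paste(nb, collapse = ""))
  }
  out
}

#' Synonymous and nonsynonymous site counts of one codon
#'
#' For each codon position, the synonymous fraction is the number of the 3
#' possible point mutations preserving the amino acid divided by the number
#' of counted mutations (mutations to stop codons are excluded from the
#' denominator).  `S` sums the fractions; `N = 3 - S`.
#'
#' @param codon 3-letter DNA string (or length-3 character vector), not a
#'   stop codon.
#' @param code NCBI genetic code id (default `"1"`, standard).
#' @return List with `frac` (per-position synonymous fractions), `S`, `N`.
#' @export
codon_sites <- function(codon, code = "1") {
  gc <- Biostrings::getGeneticCode(as.character(code))
  if (length(codon) == 1L) codon <- seq_chars(toupper(codon))
  cstr <- paste(codon, collapse = "")
  aa <- gc[[cstr]]
  if (is.null(aa) || aa == "*")
    stop("codon_sites: '", cstr, "' is a stop codon or invalid")
  frac <- numeric(3)
  for (pos in 1:3) {
    syn <- 0L; counted <- 0L
    for (b in DNA_BASES) {
      if (b == codon[pos]) next
      nb <- codon; nb[pos] <- b
      naa <- gc[[paste(nb, collapse = "")]]
      if (naa == "*") next
      counted <- counted + 1L
      if (naa == aa) syn <- syn + 1L
    }
    frac[pos] <- if (counted > 0L) syn / counted else 0
  }
  list(frac = frac, S = sum(frac), N = 3 - sum(frac))
}

## Pathway-averaged synonymous/nonsynonymous difference counts between two
## codons.  All orderings of the differing positions are enumerated with
## equal weight; orderings passing through a stop codon are discarded.
codon_path_diffs <- function(c1, c2, gcode) {
  diffpos <- which(c1 != c2)
  nd <- length(diffpos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(diffpos)
           else if (nd == 2L) list(diffpos, rev(diffpos))
           else {
    idx <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
    lapply(idx, function(o) diffpos[o])
  }
  syn_tot <- 0; non_tot <- 0; nvalid <- 0L
  for (p in perms) {
    cur <- c1; syn <- 0L; non <- 0L; valid <- TRUE
    for (pos in p) {
      nxt <- cur; nxt[pos] <- c2[pos]
      a1 <- gcode[[paste(cur, collapse = "")]]
      a2 <- gcode[[paste(nxt, collapse = "")]]
      if (a2 == "*") { valid <- FALSE; break }
      if (a1 == a2) syn <- syn + 1L else non <- non + 1L
      cur <- nxt
    }
    if (valid) {
      syn_tot <- syn_tot + syn; non_tot <- non_tot + non
      nvalid <- nvalid + 1L
    }
  }
  if (nvalid == 0L) return(c(syn = NA_real_, nonsyn = NA_real_))
  c(syn = syn_tot / nvalid, nonsyn = non_tot / nvalid)
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)   # correction undefined
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for one aligned coding sequence pair
#'
#' Codons containing gaps or `N` in either sequence are dropped pairwise;
#' codons that are stops in either sequence are dropped with a warning.
#' Differences are averaged with equal weight over all minimal mutational
#' pathways (pathways through stop codons discarded; codon pairs whose
#' pathways all hit stops are skipped with a warning).  Proportions use site
#' counts averaged over the two sequences and are Jukes-Cantor corrected:
#' `Ks = -3/4 log(1 - 4 ps / 3)`, likewise `Ka`.
#'
#' @param a,b Aligned coding sequences (equal length, in frame); may contain
#'   `-`/`N`.
#' @param code NCBI genetic code id.
#' @param gene_id,pair Labels carried into the result.
#' @return List of class `kaks_result`: `S_sites`, `N_sites`, `Sd`, `Nd`,
#'   `ps`, `pn`, `Ks`, `Ka`, `ratio` (`NA` when `Ks` is 0 or a correction is
#'   undefined), `n_codons`.
#' @export
ng86 <- function(a, b, code = "1", gene_id = NA_character_,
                 pair = c(NA_character_, NA_character_)) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("ng86: sequences must be aligned")
  if (nchar(a) %% 3L != 0L) stop("ng86: alignment length not a multiple of 3")
  gcode <- Biostrings::getGeneticCode(as.character(code))
  ca <- seq_chars(a); cb <- seq_chars(b)
  nc <- nchar(a) %/% 3L
  Sa <- 0; Sb <- 0; Sd <- 0; Nd <- 0; used <- 0L
  skipped_stop <- 0L; skipped_path <- 0L
  for (i in seq_len(nc)) {
    ia <- (3L * (i - 1L) + 1L):(3L * i)
    c1 <- ca[ia]; c2 <- cb[ia]
    if (any(c(c1, c2) %in% c("-", "N"))) next
    aa1 <- gcode[[paste(c1, collapse = "")]]
    aa2 <- gcode[[paste(c2, collapse = "")]]
    if (aa1 == "*" || aa2 == "*") { skipped_stop <- skipped_stop + 1L; next }
    dd <- codon_path_diffs(c1, c2, gcode)
    if (any(is.na(dd))) { skipped_path <- skipped_path + 1L; next }
    Sa <- Sa + codon_sites(c1, code)$S
    Sb <- Sb + codon_sites(c2, code)$S
    Sd <- Sd + dd[["syn"]]
    Nd <- Nd + dd[["nonsyn"]]
    used <- used + 1L
  }
  if (skipped_stop) warning(skipped_stop, " codon(s) with a stop dropped")
  if (skipped_path)
    warning(skipped_path, " codon pair(s) skipped: all pathways hit stops")
  if (used == 0L) stop("ng86: zero comparable codons")
  S_sites <- (Sa + Sb) / 2
  N_sites <- 3 * used - S_sites
  ps <- Sd / S_sites
  pn <- Nd / N_sites
  Ks <- jc_correct(ps); Ka <- jc_correct(pn)
  structure(list(
    gene_id = gene_id, pair = pair,
    S_sites = S_sites, N_sites = N_sites, Sd = Sd, Nd = Nd,
    ps = ps, pn = pn, Ks = Ks, Ka = Ka,
    ratio = if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_,
    n_codons = used
  ), class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat("<kaks_result>", x$gene_id %||% "", "Ka =", signif(x$Ka, 4),
      "Ks =", signif(x$Ks, 4), "Ka/Ks =", signif(x$ratio, 4), "\n")
  invisible(x)
}

#' NG86 over all member pairs of a genic region set
#'
#' @param rs A genic [region_set()] (members aligned first with
#'   [progressive_align()] when lengths differ).
#' @param code NCBI genetic code id.
#' @return data.frame, one row per unordered strain pair.
#' @export
kaks_region <- function(rs, code = "1") {
  if (rs$rtype != "genic") stop("kaks_region: region is not genic")
  seqs <- rs$members
  if (length(unique(nchar(seqs))) > 1L)
    seqs <- unclass(progressive_align(rs))
  prs <- utils::combn(names(seqs), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    r <- ng86(seqs[[prs[1L, j]]], seqs[[prs[2L, j]]], code,
              gene_id = rs$region_id, pair = prs[, j])
    data.frame(gene = rs$region_id, strain_a = prs[1L, j],
               strain_b = prs[2L, j], S = r$S_sites, N = r$N_sites,
               Sd = r$Sd, Nd = r$Nd, Ka = r$Ka, Ks = r$Ks,
               ratio = r$ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compartment-level rate summaries
#'
#' Arithmetic mean of per-gene rates per group, and pairwise percentage
#' ratios of the group means rounded to whole percent.
#'
#' @param rates Named list (or data.frame with `group` and `rate` columns):
#'   one numeric vector of per-gene rates per group, e.g. `pt`, `mt`,
#'   `nuclear`.
#' @return List with `means` (named) and `pct_ratios` (data.frame of group
#'   pairs with `ratio_pct = round(100 * mean_a / mean_b)`).
#' @export
rate_summary <- function(rates) {
  if (is.data.frame(rates))
    rates <- split(rates$rate, rates$group)
  empty <- vapply(rates, function(x) !length(x), logical(1))
  if (any(empty)) {
    warning("empty rate group(s) omitted: ",
            paste(names(rates)[empty], collapse = ", "))
    rates <- rates[!empty]
  }
  if (!length(rates)) stop("rate_summary: no non-empty groups")
  means <- vapply(rates, mean, numeric(1))
  grp <- names(means)
  out <- list()
  if (length(grp) > 1L) {
    prs <- utils::combn(grp, 2L)
    out <- data.frame(
      group_a = prs[1L, ], group_b = prs[2L, ],
      ratio_pct = round(100 * means[prs[1L, ]] / means[prs[2L, ]]),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    out <- data.frame(group_a = character(), group_b = character(),
                      ratio_pct = numeric())
  }
  list(means = means, pct_ratios = out)
}
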