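## End-to-end orchestration: simulate (or load) -> screen -> mlst -> ssr ->
## kaks, with a run manifest and deterministic TSV outputs.

PIPELINE_STAGES <- c("simulate", "screen", "mlst", "ssr", "kaks")

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", force = TRUE)
  unname(tools::md5sum(tmp))
}

write_report_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(paste0("# config=", hash), con)
  suppressWarnings(
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE))
  close(con)
  invisible(path)
}

#' Run the phylotyping pipeline
#'
#' Executes the requested stages in dependency order on either a simulated
#' dataset or genomes loaded from disk, writing marker, MLST and SSR reports
#' (TSV), Newick trees and a JSON run manifest to `outdir`.
#'
#' @param config A list, or path to a JSON file, with elements:
#'   \describe{
#'     \item{seed}{integer; seeds every stochastic step.}
#'     \item{outdir}{output directory.}
#'     \item{stages}{subset of `simulate`, `screen`, `mlst`, `ssr`, `kaks`.}
#'     \item{simulate}{either `fixture` (a [fixture_config()] name) or a
#'       full [sim_config()] argument list.}
#'     \item{genomes}{alternatively, `fasta`/`gff` path vectors plus
#'       `compartment` (when not simulating).}
#'     \item{screen}{`baseline` (region id, required for the screen stage),
#'       optional `conspecific_pairs`, `B`, `diff_method`.}
#'     \item{mlst}{`ref`, `alt` (strain ids), optional `type` (further
#'       strains), `window_len`, `step`, `threshold`.}
#'     \item{ssr}{optional `min_len` (6 thresholds).}
#'     \item{kaks}{optional `code` (NCBI table id).}
#'   }
#' @return List of class `pipeline_result` with the per-stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stages <- unlist(config$stages) %||% PIPELINE_STAGES
  unknown <- setdiff(stages, PIPELINE_STAGES)
  if (length(unknown))
    stop("unknown stage name(s): ", paste(unknown, collapse = ", "))
  if ("screen" %in% stages && is.null(config$screen$baseline))
    stop("screen stage requires a baseline marker (config$screen$baseline)")
  seed <- as.integer(config$seed %||% 1L)
  outdir <- config$outdir %||% stop("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  manifest <- list(config_hash = hash, seed = seed,
                   version = as.character(utils::packageVersion("organphylo")),
                   stages = list())
  results <- list()
  mark <- function(stage, status)
    manifest$stages[[stage]] <<- status

  ## --- inputs: simulate or load -------------------------------------------
  if ("simulate" %in% stages) {
    sc <- if (!is.null(config$simulate$fixture))
      fixture_config(config$simulate$fixture, seed = seed)
    else do.call(sim_config, c(config$simulate, list(seed = seed)))
    anc <- generate_ancestor(sc)
    sim <- evolve(anc)
    write_fixture(sim, file.path(outdir, "simulated"))
    genomes <- sim$leaves
    features <- sim$features
    results$simulate <- sim
    mark("simulate", "ok")
  } else {
    if (is.null(config$genomes$fasta))
      stop("either the simulate stage or config$genomes$fasta is required")
    gl <- load_genomes(unlist(config$genomes$fasta),
                       unlist(config$genomes$gff) %||% character(),
                       compartment = config$genomes$compartment %||% "pt")
    genomes <- gl$genomes
    features <- gl$features
  }
  region_sets <- extract_region_sets(genomes, features)
  names(region_sets) <- vapply(region_sets, function(rs) rs$region_id,
                               character(1))

  ## --- screen -------------------------------------------------------------
  if ("screen" %in% stages) {
    reference <- build_reference_tree(region_sets)
    origins <- setNames(
      rep(genomes[[1L]]$compartment, length(region_sets)),
      names(region_sets))
    pairs <- config$screen$conspecific_pairs
    if (!is.null(pairs) && !is.list(pairs)) pairs <- list(pairs)
    report <- screen_markers(
      region_sets, reference, baseline_id = config$screen$baseline,
      origins = origins, conspecific_pairs = pairs,
      B = as.integer(config$screen$B %||% 100L), seed = seed,
      diff_method = config$screen$diff_method %||% "polymorphic")
    write_report_tsv(report$evaluations,
                     file.path(outdir, "marker_report.tsv"), hash)
    write_newick(reference$tree, file.path(outdir, "reference_tree.nwk"))
    results$screen <- report
    results$reference <- reference
    mark("screen", "ok")
  }

  ## --- mlst ---------------------------------------------------------------
  if ("mlst" %in% stages) {
    mc <- config$mlst %||% list()
    ids <- names(genomes)
    ref_id <- mc$ref %||% ids[1L]
    alt_id <- mc$alt %||% ids[2L]
    loci <- discover_mlst_loci(
      genomes[[ref_id]], genomes[[alt_id]],
      features = features[features$genome == ref_id, , drop = FALSE],
      window_len = as.integer(mc$window_len %||% 500L),
      step = as.integer(mc$step %||% 25L),
      threshold = as.integer(mc$threshold %||% 6L))
    typed <- unique(c(ref_id, alt_id, unlist(mc$type)))
    profile <- genotype_mlst(loci, genomes[typed])
    write_mlst_report(loci, profile,
                      file.path(outdir, "mlst_loci.bed"),
                      file.path(outdir, "mlst_alleles.tsv"))
    if (!is.null(profile$tree))
      write_newick(profile$tree, file.path(outdir, "mlst_tree.nwk"))
    results$mlst <- list(loci = loci, profile = profile)
    mark("mlst", "ok")
  }

  ## --- ssr ----------------------------------------------------------------
  if ("ssr" %in% stages) {
    min_len <- as.integer(unlist(config$ssr$min_len) %||%
                            c(10L, 10L, 12L, 12L, 12L, 12L))
    loci <- do.call(rbind, lapply(names(genomes), function(g)
      find_ssrs(genomes[[g]],
                features[features$genome == g, , drop = FALSE],
                min_len = min_len)))
    cmp <- if (length(unique(loci$genome)) >= 2L) compare_ssrs(loci)
           else list(shared = data.frame(), specific = loci)
    write_report_tsv(loci, file.path(outdir, "ssr_report.tsv"), hash)
    results$ssr <- list(loci = loci, comparison = cmp)
    mark("ssr", "ok")
  }

  ## --- kaks ---------------------------------------------------------------
  if ("kaks" %in% stages) {
    code <- config$kaks$code %||% "1"
    genic <- Filter(function(rs) rs$rtype == "genic", region_sets)
    tab <- do.call(rbind, lapply(genic, function(rs)
      tryCatch(suppressWarnings(kaks_region(rs, code = code)),
               error = function(e) NULL)))
    rownames(tab) <- NULL
    write_report_tsv(tab, file.path(outdir, "kaks_report.tsv"), hash)
    gene_means <- vapply(split(tab$Ka, tab$gene), mean, numeric(1))
    results$kaks <- list(table = tab,
                         summary = rate_summary(list(all = gene_means)))
    mark("kaks", "ok")
  }

  manifest$outputs <- list.files(outdir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  structure(results, class = "pipeline_result")
}
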