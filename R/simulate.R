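## Synthetic organelle-genome evolution: an annotated ancestor built from a
## region blueprint, evolved along a known tree with per-region rate
## multipliers, transition bias, purifying selection in genes, triplet
## indels and planted SSRs.  Every accepted event is recorded so leaves can
## be replayed from the ancestor exactly.

#' Simulation configuration
#'
#' @param tree Newick string (branch lengths in expected substitutions per
#'   site) or an `ape::phylo`.
#' @param blueprint data.frame with columns `name`, `rtype`
#'   (`genic`/`intergenic`), `length` (bp; genic lengths must be multiples
#'   of 3), `rate_multiplier` (default 1) and `omega` (genic only; accepted
#'   fraction of proposed nonsynonymous changes, default 0.1 -- strong
#'   purifying selection as seen in organelle genes).
#' @param kappa Transition/transversion rate ratio (> 0).  Default 2.8: with
#'   near-equal base use the observed transition/transversion count ratio is
#'   about kappa/2, and organelle SNP surveys in this genus run ~1.4--1.5.
#' @param gc_target Genomic GC fraction (default 0.333, the compact
#'   AT-rich organelle range).
#' @param indel_rate Indel events per site per unit branch length (default
#'   5e-4; indels are rare relative to substitutions, and in coding regions
#'   essentially always frame-preserving).
#' @param triplet_only_in_genes Force genic indels to length 3 (default
#'   TRUE).
#' @param planted_ssrs Optional data.frame `motif`, `copies`, `region`:
#'   perfect repeats written into the ancestor verbatim.
#' @param compartment Compartment label for the simulated genomes.
#' @param seed Integer seed; all randomness flows from it.
#' @param code NCBI genetic code id.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(tree, blueprint, kappa = 2.8, gc_target = 0.333,
                       indel_rate = 5e-4, triplet_only_in_genes = TRUE,
                       planted_ssrs = NULL, compartment = "pt",
                       seed = 1L, code = "1") {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  bp <- as.data.frame(blueprint)
  if (is.null(bp$rate_multiplier)) bp$rate_multiplier <- 1
  if (is.null(bp$omega)) bp$omega <- NA_real_
  bp$omega[is.na(bp$omega) & bp$rtype == "genic"] <- 0.1
  stopifnot(all(bp$length > 0), all(bp$rtype %in% c("genic", "intergenic")),
            all(bp$omega[bp$rtype == "genic"] >= 0), kappa > 0)
  if (any(bp$rtype == "genic" & bp$length %% 3L != 0L))
    stop("genic blueprint lengths must be multiples of 3")
  if (any(duplicated(bp$name))) stop("blueprint names must be unique")
  structure(list(tree = tree, blueprint = bp, kappa = kappa,
                 gc_target = gc_target, indel_rate = indel_rate,
                 triplet_only_in_genes = triplet_only_in_genes,
                 planted_ssrs = planted_ssrs, compartment = compartment,
                 seed = as.integer(seed), code = as.character(code)),
            class = "sim_config")
}

sense_codons <- function(code = "1") {
  gc <- Biostrings::getGeneticCode(as.character(code))
  names(gc)[gc != "*"]
}

## Random in-frame coding interior (no internal stops) at a GC target.
random_coding <- function(n_codons, gc_target, code) {
  cods <- sense_codons(code)
  w <- vapply(strsplit(cods, ""), function(cd)
    prod(ifelse(cd %in% c("G", "C"), gc_target / 2, (1 - gc_target) / 2)),
    numeric(1))
  paste(sample(cods, n_codons, replace = TRUE, prob = w), collapse = "")
}

## Break chance perfect repeats close to the detection thresholds so that
## planted SSRs are the only loci at/above threshold.  Substitutions keep
## coding regions stop-free.
suppress_runs <- function(s, genic, keep = NULL, code = "1",
                          min_len = c(8L, 8L, 10L, 10L, 10L, 10L)) {
  gc <- Biostrings::getGeneticCode(as.character(code))
  for (iter in 1:10) {
    loci <- find_ssrs(s, min_len = min_len)
    if (!is.null(keep) && nrow(loci))
      loci <- loci[!(loci$start <= keep[2L] & loci$end >= keep[1L]), ,
                   drop = FALSE]
    if (!nrow(loci)) return(s)
    for (i in seq_len(nrow(loci))) {
      pos <- loci$start[i] + loci$total_len[i] %/% 2L
      cur <- substr(s, pos, pos)
      for (b in sample(setdiff(DNA_BASES, cur))) {
        cand <- s
        substr(cand, pos, pos) <- b
        if (genic) {
          ci <- (pos - 1L) %/% 3L
          cod <- substr(cand, 3L * ci + 1L, 3L * ci + 3L)
          if (gc[[cod]] == "*") next
        }
        s <- cand
        break
      }
    }
  }
  s
}

#' Generate the ancestral genome from a blueprint
#'
#' Genes are valid ORFs (ATG start, TAA stop, no internal stop under the
#' configured code); intergenic spacers are random sequence at the GC
#' target; planted SSRs are inserted verbatim (at a codon boundary inside
#' genes) and chance repeats near the detection thresholds are broken.
#' Deterministic under the config seed.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_ancestor`: `genome` ([genome_record()]),
#'   `features` (genic features, cumulative coordinates), `regions` (named
#'   list of region sequences), `ssr_truth` (planted SSR coordinates on the
#'   ancestor), `config`.
#' @export
generate_ancestor <- function(config) {
  set.seed(config$seed)
  bp <- config$blueprint
  regions <- list()
  ssr_truth <- list()
  for (i in seq_len(nrow(bp))) {
    nm <- bp$name[i]; len <- bp$length[i]
    if (bp$rtype[i] == "genic") {
      if (len < 9L) stop("genic region '", nm, "' shorter than 9 bp")
      s <- paste0("ATG", random_coding(len %/% 3L - 2L, config$gc_target,
                                       config$code), "TAA")
    } else {
      s <- chars_seq(random_dna(len, config$gc_target))
    }
    keep <- NULL
    ps <- config$planted_ssrs
    if (!is.null(ps) && nm %in% ps$region) {
      row <- ps[ps$region == nm, , drop = FALSE][1L, ]
      ssr <- strrep(row$motif, row$copies)
      sl <- nchar(ssr)
      if (bp$rtype[i] == "genic") {
        if (sl + 6L > len)
          stop("planted SSR longer than region '", nm, "'")
        base <- 3L * (((len - sl) %/% 2L) %/% 3L) + 1L
        pos <- NA_integer_
        for (off in c(0L, 3L, -3L, 6L, -6L)) {
          p <- base + off
          if (p < 4L || p + sl - 1L > len - 3L) next
          cand <- s
          substr(cand, p, p + sl - 1L) <- ssr
          aa <- as.character(Biostrings::translate(
            Biostrings::DNAString(cand),
            genetic.code = Biostrings::getGeneticCode(config$code)))
          if (!grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) {
            s <- cand; pos <- p; break
          }
        }
        if (is.na(pos))
          stop("cannot plant SSR in '", nm, "' without creating a stop")
      } else {
        if (sl > len) stop("planted SSR longer than region '", nm, "'")
        pos <- max(1L, (len - sl) %/% 2L)
        substr(s, pos, pos + sl - 1L) <- ssr
      }
      keep <- c(pos, pos + sl - 1L)
      ssr_truth[[length(ssr_truth) + 1L]] <- data.frame(
        region = nm, motif = row$motif, copies = row$copies,
        region_start = pos, stringsAsFactors = FALSE)
    }
    regions[[nm]] <- suppress_runs(s, bp$rtype[i] == "genic", keep,
                                   config$code)
  }
  seqs <- unlist(regions)
  ends <- cumsum(nchar(seqs))
  starts <- ends - nchar(seqs) + 1L
  genic <- bp$rtype == "genic"
  features <- feature_table(genome = "ancestor", name = bp$name[genic],
                            ftype = "gene", start = starts[genic],
                            end = ends[genic], strand = "+")
  st <- if (length(ssr_truth)) do.call(rbind, ssr_truth) else
    data.frame(region = character(), motif = character(),
               copies = integer(), region_start = integer())
  st$genome_start <- st$region_start + starts[match(st$region, bp$name)] - 1L
  structure(list(genome = genome_record("ancestor", paste(seqs, collapse = ""),
                                        config$compartment),
                 features = features, regions = regions,
                 ssr_truth = st, config = config),
            class = "sim_ancestor")
}

## Mutate one region sequence along one branch; returns new sequence and the
## ordered event list.  Positions are relative to the sequence state at the
## time of each event (sequential application).
mutate_region <- function(s, rtype, mult, omega, bl, config, gcode) {
  kappa <- config$kappa
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  events <- list()
  rec <- function(type, pos, from, to, klass = NA_character_,
                  effect = NA_character_) {
    events[[length(events) + 1L]] <<- data.frame(
      type = type, pos = pos, from = from, to = to, klass = klass,
      effect = effect, stringsAsFactors = FALSE)
  }
  len <- nchar(s)
  nsub <- rpois(1L, bl * mult * len)
  for (k in seq_len(nsub)) {
    for (attempt in 1:200) {
      len <- nchar(s)
      lo <- if (rtype == "genic") 4L else 1L
      hi <- if (rtype == "genic") len - 3L else len
      if (hi < lo) break
      pos <- sample(lo:hi, 1L)
      cur <- substr(s, pos, pos)
      is_ts <- runif(1L) < kappa / (kappa + 2)
      nb <- if (is_ts) transition_of[[cur]] else
        sample(setdiff(DNA_BASES, c(cur, transition_of[[cur]])), 1L)
      effect <- NA_character_
      if (rtype == "genic") {
        ci <- (pos - 1L) %/% 3L
        cod <- seq_chars(substr(s, 3L * ci + 1L, 3L * ci + 3L))
        ncod <- cod; ncod[(pos - 1L) %% 3L + 1L] <- nb
        a1 <- gcode[[paste(cod, collapse = "")]]
        a2 <- gcode[[paste(ncod, collapse = "")]]
        if (a2 == "*") next
        if (a1 != a2) {
          if (runif(1L) > min(1, omega)) next
          effect <- "nonsynonymous"
        } else effect <- "synonymous"
      }
      substr(s, pos, pos) <- nb
      rec("substitution", pos, cur, nb,
          klass = if (is_ts) "transition" else "transversion",
          effect = effect)
      break
    }
  }
  nind <- rpois(1L, bl * config$indel_rate * len)
  cods <- sense_codons(config$code)
  for (k in seq_len(nind)) {
    len <- nchar(s)
    if (rtype == "genic" && config$triplet_only_in_genes) {
      ncod_now <- len %/% 3L
      if (ncod_now < 4L) next
      del <- runif(1L) < 0.5
      if (del) {
        ci <- sample(2:(ncod_now - 1L), 1L)     # internal codon
        pos <- 3L * (ci - 1L) + 1L
        rec("deletion", pos, substr(s, pos, pos + 2L), "")
        s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + 3L, len))
      } else {
        ci <- sample(2:(ncod_now - 1L), 1L)
        pos <- 3L * (ci - 1L) + 1L
        ins <- sample(cods, 1L)
        rec("insertion", pos, "", ins)
        s <- paste0(substr(s, 1L, pos - 1L), ins, substr(s, pos, len))
      }
    } else {
      ilen <- sample(1:3, 1L)
      del <- runif(1L) < 0.5 && len > ilen + 2L
      if (del) {
        pos <- sample(seq_len(len - ilen + 1L), 1L)
        rec("deletion", pos, substr(s, pos, pos + ilen - 1L), "")
        s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + ilen, len))
      } else {
        pos <- sample(seq_len(len + 1L), 1L)
        ins <- chars_seq(random_dna(ilen, config$gc_target))
        rec("insertion", pos, "", ins)
        s <- paste0(substr(s, 1L, pos - 1L), ins,
                    substr(s, pos, len))
      }
    }
  }
  list(seq = s, events = if (length(events)) do.call(rbind, events) else NULL)
}

## Apply one recorded event to a sequence (replay).
apply_event <- function(s, ev) {
  len <- nchar(s)
  switch(ev$type,
    substitution = { substr(s, ev$pos, ev$pos) <- ev$to; s },
    deletion = paste0(substr(s, 1L, ev$pos - 1L),
                      substr(s, ev$pos + nchar(ev$from), len)),
    insertion = paste0(substr(s, 1L, ev$pos - 1L), ev$to,
                       substr(s, ev$pos, len)),
    stop("unknown event type ", ev$type))
}

#' Evolve the ancestor along the configured tree
#'
#' Along each branch, per region, substitution counts are Poisson with mean
#' branch length x rate multiplier x region length; substitution types are
#' Kimura-biased by `kappa`; in genes a proposed nonsynonymous change is
#' accepted with probability `min(1, omega)` (synonymous always accepted,
#' rejected proposals resampled) and changes creating stops are rejected;
#' indels are Poisson at `indel_rate` and frame-preserving triplets inside
#' genes.  Every accepted event is recorded in the truth.
#'
#' @param ancestor A [generate_ancestor()] result.
#' @param config Defaults to the ancestor's own config.
#' @return List of class `sim_result`: `leaves` (named list of
#'   [genome_record()]), `features` (per-leaf feature data.frame),
#'   `regions` (per-leaf region sequence lists), `truth` (tree, per-edge
#'   event tables, per-region realized substitution counts, planted SSRs).
#' @export
evolve <- function(ancestor, config = ancestor$config) {
  set.seed(config$seed + 1L)
  phy <- config$tree
  if (length(phy$tip.label) < 2L) stop("evolve: tree needs >= 2 leaves")
  gcode <- Biostrings::getGeneticCode(config$code)
  bp <- config$blueprint
  nt <- length(phy$tip.label)
  nodes_regions <- vector("list", nt + phy$Nnode)
  root <- nt + 1L
  nodes_regions[[root]] <- ancestor$regions
  edges <- list()
  ord <- ape::reorder.phylo(phy, "cladewise")   # parents before children
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; child <- ord$edge[e, 2L]
    bl <- ord$edge.length[e]
    regs <- nodes_regions[[par]]
    evs <- list()
    for (i in seq_len(nrow(bp))) {
      nm <- bp$name[i]
      mr <- mutate_region(regs[[nm]], bp$rtype[i], bp$rate_multiplier[i],
                          bp$omega[i], bl, config, gcode)
      regs[[nm]] <- mr$seq
      if (!is.null(mr$events)) {
        mr$events <- cbind(region = nm, mr$events)
        evs[[length(evs) + 1L]] <- mr$events
      }
    }
    nodes_regions[[child]] <- regs
    edges[[length(edges) + 1L]] <- list(
      parent = par, child = child,
      child_label = if (child <= nt) phy$tip.label[child] else
        paste0("node", child),
      events = if (length(evs)) do.call(rbind, evs) else NULL)
  }
  leaves <- list(); features <- list(); leaf_regions <- list()
  for (i in seq_len(nt)) {
    lab <- phy$tip.label[i]
    regs <- nodes_regions[[i]]
    seqs <- unlist(regs[bp$name])
    ends <- cumsum(nchar(seqs))
    starts <- ends - nchar(seqs) + 1L
    genic <- bp$rtype == "genic"
    leaves[[lab]] <- genome_record(lab, paste(seqs, collapse = ""),
                                   config$compartment)
    features[[lab]] <- feature_table(genome = lab, name = bp$name[genic],
                                     ftype = "gene", start = starts[genic],
                                     end = ends[genic], strand = "+")
    leaf_regions[[lab]] <- regs
  }
  counts <- do.call(rbind, lapply(edges, function(ed) {
    if (is.null(ed$events)) return(NULL)
    subs <- ed$events[ed$events$type == "substitution", , drop = FALSE]
    if (!nrow(subs)) return(NULL)
    data.frame(edge = ed$child_label,
               region = names(table(subs$region)),
               n_sub = as.integer(table(subs$region)))
  }))
  truth <- list(tree = ape::write.tree(phy), edges = edges,
                region_counts = counts, ssr_truth = ancestor$ssr_truth)
  structure(list(leaves = leaves, features = do.call(rbind, features),
                 regions = leaf_regions, truth = truth),
            class = "sim_result")
}

#' Replay recorded mutations from the ancestor
#'
#' Applies the truth's per-edge event lists to the ancestral regions; the
#' result must equal each simulated leaf byte for byte.
#'
#' @param ancestor A [generate_ancestor()] result.
#' @param truth The `truth` element of [evolve()].
#' @return Named list (by leaf) of named region-sequence lists.
#' @export
replay_truth <- function(ancestor, truth) {
  edges <- truth$edges
  parents <- vapply(edges, function(e) e$parent, numeric(1))
  children <- vapply(edges, function(e) e$child, numeric(1))
  root <- setdiff(parents, children)
  if (length(root) != 1L) stop("truth edge list is not a rooted tree")
  states <- list()
  states[[as.character(root)]] <- ancestor$regions
  out <- list()
  for (ed in edges) {
    regs <- states[[as.character(ed$parent)]]
    if (!is.null(ed$events)) {
      for (r in seq_len(nrow(ed$events))) {
        ev <- ed$events[r, ]
        regs[[ev$region]] <- apply_event(regs[[ev$region]], ev)
      }
    }
    if (ed$child %in% parents) {
      states[[as.character(ed$child)]] <- regs
    } else {
      out[[ed$child_label]] <- regs
    }
  }
  out
}

#' Write a simulated dataset to disk
#'
#' One FASTA and one GFF3 per leaf, the generating tree as Newick and the
#' truth as JSON; round-trip readable by [load_genomes()].
#'
#' @param sim An [evolve()] result.
#' @param outdir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_fixture <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (lab in names(sim$leaves)) {
    fa <- file.path(outdir, paste0(lab, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(setNames(sim$leaves[[lab]]$sequence, lab)), fa)
    gff <- file.path(outdir, paste0(lab, ".gff3"))
    f <- sim$features[sim$features$genome == lab, , drop = FALSE]
    lines <- c("##gff-version 3",
               sprintf("%s\torganphylo\t%s\t%d\t%d\t.\t%s\t.\tName=%s",
                       f$genome, f$ftype, f$start, f$end, f$strand, f$name))
    writeLines(lines, gff)
    written <- c(written, fa, gff)
  }
  tr <- file.path(outdir, "tree.nwk")
  writeLines(sim$truth$tree, tr)
  tj <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    list(tree = sim$truth$tree,
         region_counts = sim$truth$region_counts,
         ssr_truth = sim$truth$ssr_truth),
    tj, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(written, tr, tj))
}

#' Standard simulated fixtures
#'
#' Three ready-made configurations exercising the analysis stages:
#' `"hotspot"` (six strains, three high-rate regions among many background
#' regions, for the marker screen), `"conspecific-pair"` (a nearly identical
#' strain pair with localized variable regions plus a third strain, for the
#' MLST scan) and `"ssr-panel"` (two strains with planted microsatellites).
#'
#' @param name Fixture name.
#' @param seed Seed recorded in the config.
#' @return A [sim_config()].
#' @export
fixture_config <- function(name = c("hotspot", "conspecific-pair",
                                    "ssr-panel"), seed = 1L) {
  name <- match.arg(name)
  gene <- function(nm, len, mult = 1, omega = 0.1)
    data.frame(name = nm, rtype = "genic", length = len,
               rate_multiplier = mult, omega = omega)
  spacer <- function(nm, len, mult = 1)
    data.frame(name = nm, rtype = "intergenic", length = len,
               rate_multiplier = mult, omega = NA)
  if (name == "hotspot") {
    ## genes and spacers interleaved so every spacer is an extractable
    ## intergenic region; the three planted hotspots are the spacer between
    ## gene4 and gene5 (hotA), the gene hotB and the spacer between gene8
    ## and gene9 (hotC)
    g <- lapply(1:10, function(i) gene(paste0("gene", i),
                                       300L + 60L * (i %% 5)))
    s <- lapply(1:7, function(i) spacer(paste0("spc", i),
                                        120L + 20L * (i %% 4)))
    bp <- rbind(g[[1]], s[[1]], g[[2]], s[[2]], g[[3]], s[[3]], g[[4]],
                spacer("hotA", 600L, mult = 5), g[[5]], s[[4]], g[[6]],
                s[[5]], g[[7]], gene("hotB", 600L, mult = 5, omega = 1),
                g[[8]], spacer("hotC", 600L, mult = 5), g[[9]], s[[6]],
                g[[10]], s[[7]])
    tree <- paste0("((s1:0.02,s2:0.02):0.015,(s3:0.02,s4:0.02):0.015,",
                   "(s5:0.02,s6:0.02):0.015);")
    sim_config(tree, bp, seed = seed, indel_rate = 1e-4)
  } else if (name == "conspecific-pair") {
    g <- lapply(1:12, function(i) gene(paste0("gene", i), 420L))
    s <- lapply(1:9, function(i) spacer(paste0("spc", i), 200L))
    bp <- rbind(g[[1]], s[[1]], g[[2]], s[[2]], g[[3]], s[[3]], g[[4]],
                spacer("varA", 700L, mult = 60), g[[5]], s[[4]], g[[6]],
                s[[5]], g[[7]], s[[6]], g[[8]],
                gene("varB", 600L, mult = 60, omega = 1), g[[9]], s[[7]],
                g[[10]], spacer("varC", 700L, mult = 60), g[[11]], s[[8]],
                g[[12]], s[[9]])
    tree <- "((REF:0.0004,ALT:0.0004):0.0008,TYP:0.0012);"
    sim_config(tree, bp, seed = seed, indel_rate = 0, compartment = "mt")
  } else {
    bp <- do.call(rbind, lapply(1:6, function(i)
      rbind(gene(paste0("gene", i), 360L),
            spacer(paste0("spc", i), 250L))))
    ssrs <- data.frame(
      motif = c("A", "T", "TA", "AAT"),
      copies = c(12L, 10L, 7L, 5L),
      region = c("spc1", "gene2", "spc3", "spc5"),
      stringsAsFactors = FALSE)
    tree <- "(IM:0.001,CC:0.001);"
    sim_config(tree, bp, planted_ssrs = ssrs, seed = seed, indel_rate = 0)
  }
}
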