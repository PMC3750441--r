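# The genome-evolution simulator: determinism, ORF validity, truth replay
# and Monte-Carlo behaviour of its knobs.

toy_bp <- function() {
  rbind(data.frame(name = "g1", rtype = "genic", length = 300,
                   rate_multiplier = 1, omega = 0.1),
        data.frame(name = "s1", rtype = "intergenic", length = 200,
                   rate_multiplier = 1, omega = NA),
        data.frame(name = "g2", rtype = "genic", length = 240,
                   rate_multiplier = 1, omega = 0.1))
}

test_that("ancestor generation: structure, ORFs, determinism", {
  cfg <- sim_config("(a:0.05,b:0.05);", toy_bp(), seed = 401)
  anc <- generate_ancestor(cfg)
  expect_equal(nchar(anc$genome$sequence), 740)
  expect_equal(nrow(anc$features), 2)
  # genes are valid ORFs
  for (g in c("g1", "g2")) {
    s <- anc$regions[[g]]
    expect_equal(substr(s, 1, 3), "ATG")
    expect_equal(substr(s, nchar(s) - 2, nchar(s)), "TAA")
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # same seed, same genome; different seed, different genome
  anc2 <- generate_ancestor(cfg)
  expect_identical(anc2$genome$sequence, anc$genome$sequence)
  anc3 <- generate_ancestor(sim_config("(a:0.05,b:0.05);", toy_bp(),
                                       seed = 402))
  expect_false(identical(anc3$genome$sequence, anc$genome$sequence))

  # infeasible blueprint: SSR longer than its region
  cfg_bad <- sim_config("(a:0.1,b:0.1);", toy_bp(),
                        planted_ssrs = data.frame(motif = "A", copies = 300,
                                                  region = "s1"),
                        seed = 1)
  expect_error(generate_ancestor(cfg_bad), "longer than")
})

test_that("zero-length branches leave the leaves identical to the ancestor", {
  cfg <- sim_config("(a:0,b:0);", toy_bp(), seed = 403)
  anc <- generate_ancestor(cfg)
  sim <- evolve(anc)
  for (leaf in names(sim$leaves))
    expect_identical(sim$leaves[[leaf]]$sequence, anc$genome$sequence)
})

test_that("truth replay reproduces every leaf byte-identically", {
  cfg <- sim_config("((a:0.05,b:0.04):0.02,c:0.06);", toy_bp(),
                    indel_rate = 2e-3, seed = 404)
  anc <- generate_ancestor(cfg)
  sim <- evolve(anc)
  rp <- replay_truth(anc, sim$truth)
  for (leaf in names(sim$regions))
    expect_identical(rp[[leaf]], sim$regions[[leaf]])
})

test_that("omega = 0 freezes protein sequences", {
  bp <- toy_bp()
  bp$omega[bp$rtype == "genic"] <- 0
  cfg <- sim_config("(a:0.2,b:0.2);", bp, indel_rate = 0, seed = 405)
  anc <- generate_ancestor(cfg)
  sim <- evolve(anc)
  for (g in c("g1", "g2")) {
    anc_aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(anc$regions[[g]])))
    for (leaf in names(sim$regions))
      expect_identical(as.character(Biostrings::translate(
        Biostrings::DNAString(sim$regions[[leaf]][[g]]))), anc_aa)
  }
})

test_that("kappa controls the realized Ts/Tv ratio (paired Monte-Carlo)", {
  ratio_for <- function(kappa, seed) {
    cfg <- sim_config("(a:0.15,b:0.15);",
                      data.frame(name = "s", rtype = "intergenic",
                                 length = 3000, rate_multiplier = 1,
                                 omega = NA),
                      kappa = kappa, indel_rate = 0, seed = seed)
    sim <- evolve(generate_ancestor(cfg))
    ev <- do.call(rbind, lapply(sim$truth$edges, `[[`, "events"))
    sum(ev$klass == "transition") / sum(ev$klass == "transversion")
  }
  wins <- vapply(1:15, function(s)
    ratio_for(5, 500 + s) > ratio_for(0.5, 500 + s), logical(1))
  expect_true(all(wins))
  # and the kappa = 5 ratios are centred near kappa/2
  r5 <- vapply(1:10, function(s) ratio_for(5, 600 + s), numeric(1))
  expect_gt(mean(r5), 1.8)
  expect_lt(mean(r5), 3.4)
})

test_that("realized substitution counts follow the Poisson mean", {
  bl <- 0.1; len <- 2000
  counts <- vapply(1:30, function(s) {
    cfg <- sim_config(sprintf("(a:%f,b:0);", bl),
                      data.frame(name = "s", rtype = "intergenic",
                                 length = len, rate_multiplier = 1,
                                 omega = NA),
                      indel_rate = 0, seed = 700 + s)
    sim <- evolve(generate_ancestor(cfg))
    ev <- do.call(rbind, lapply(sim$truth$edges, `[[`, "events"))
    if (is.null(ev)) 0L else sum(ev$type == "substitution")
  }, numeric(1))
  mu <- bl * len
  se <- sqrt(mu / 30)
  expect_lt(abs(mean(counts) - mu), 3 * se)
})

test_that("rate multipliers raise realized divergence above background", {
  hits <- vapply(1:20, function(s) {
    bp <- rbind(data.frame(name = "bg", rtype = "intergenic", length = 1000,
                           rate_multiplier = 1, omega = NA),
                data.frame(name = "hot", rtype = "intergenic", length = 1000,
                           rate_multiplier = 5, omega = NA))
    cfg <- sim_config("(a:0.02,b:0.02);", bp, indel_rate = 0,
                      seed = 800 + s)
    sim <- evolve(generate_ancestor(cfg))
    pd <- function(r) pair_dist(sim$regions$a[[r]], sim$regions$b[[r]])
    pd("hot") > pd("bg")
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("fixtures round-trip through genome_io", {
  d <- withr::local_tempdir()
  fx <- sim_fixture_cached("ssr-panel")
  write_fixture(fx$sim, d)
  fas <- list.files(d, pattern = "\\.fasta$", full.names = TRUE)
  gffs <- list.files(d, pattern = "\\.gff3$", full.names = TRUE)
  gl <- load_genomes(fas, gffs)
  for (leaf in names(fx$sim$leaves))
    expect_identical(gl$genomes[[leaf]]$sequence,
                     fx$sim$leaves[[leaf]]$sequence)
  expect_equal(nrow(gl$features), nrow(fx$sim$features))
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$tree, fx$sim$truth$tree)
})
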