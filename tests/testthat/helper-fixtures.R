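# Shared fixtures built in code.  Simulations are cached per test run so
# several test files can reuse the same dataset without re-simulating.

rand_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# random gapped alignment (no all-gap columns by construction)
rand_alignment <- function(n_rows, n_cols, seed, gap_frac = 0.05,
                           n_frac = 0.02) {
  set.seed(seed)
  m <- matrix(sample(c("A", "C", "G", "T"), n_rows * n_cols, replace = TRUE),
              n_rows, n_cols)
  if (gap_frac > 0 && n_rows > 2) {
    idx <- which(matrix(runif(n_rows * n_cols) < gap_frac, n_rows))
    m[idx] <- "-"
    allgap <- colSums(m != "-") == 0
    m[1, allgap] <- "A"
  }
  if (n_frac > 0) {
    idx <- which(matrix(runif(n_rows * n_cols) < n_frac, n_rows) & m != "-")
    m[idx] <- "N"
  }
  rownames(m) <- paste0("t", seq_len(n_rows))
  new_alignment(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

local({
  cache <- new.env(parent = emptyenv())
  sim_fixture_cached <<- function(name, seed = 11L) {
    key <- paste0(name, "_", seed)
    if (is.null(cache[[key]])) {
      anc <- generate_ancestor(fixture_config(name, seed = seed))
      cache[[key]] <- list(ancestor = anc, sim = evolve(anc))
    }
    cache[[key]]
  }
})

# simple proportion of differing sites between two equal-length sequences
pair_dist <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  mean(x != y)
}

# coordinates of each blueprint region on a given leaf genome (1-based)
leaf_region_coords <- function(sim, leaf) {
  regs <- sim$regions[[leaf]]
  lens <- nchar(unlist(regs))
  ends <- cumsum(lens)
  data.frame(region = names(regs), start = ends - lens + 1L, end = ends,
             stringsAsFactors = FALSE)
}
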