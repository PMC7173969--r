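# shared fixtures: toy matrices and small cached simulations

toy_hm <- function(alleles, positions = NULL, scaffold = "scf1",
                   lengths = NULL, ...) {
  alleles <- as.matrix(alleles)
  if (is.null(positions)) positions <- seq_len(ncol(alleles)) * 10L
  haplotype_matrix(alleles, positions,
                   rep_len(scaffold, ncol(alleles)),
                   scaffold_lengths = lengths, ...)
}

rand_hm <- function(H, S, seed = 1, p = NULL, miss = 0) {
  set.seed(seed)
  if (is.null(p)) p <- runif(S, 0.05, 0.95)
  A <- matrix(rbinom(H * S, 1L, rep(p, each = H)), H, S)
  if (miss > 0) A[runif(H * S) < miss] <- NA_integer_
  toy_hm(A)
}

two_pop_map <- function(hm, split = n_haplotypes(hm) / 4L) {
  n <- length(hm$samples)
  data.frame(sample_id = hm$samples,
             population = rep(c("A", "B"), c(split, n - split)),
             phenotype_class = "neutral", distance_code = NA)
}

# lazily-built shared simulations (helpers are sourced once per test run)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_sim <- function() cached("small_sim", {
  simulate_demography(demography_params(n_scaffolds = 1, scaffold_bp = 1e5),
                      seed = 101)
})

neutral_sim <- function() cached("neutral_sim", {
  simulate_demography(
    neutral_demography(n_pops = 3, Ne = 10000, split_time = 500, mu = 1e-7,
                       scaffold_bp = 1e5, block_bp = 2000),
    seed = 102)
})

neutral_fit <- function() cached("neutral_fit", {
  b <- neutral_sim()
  hm <- filter_sites(b$hm, b$popmap, maf_min = 0.05, min_individuals = 3)
  model <- fit_haplotype_clusters(hm, K = 3, n_fits = 2, max_iter = 20,
                                  seed = 103)
  D <- reynolds_matrix(hm, b$popmap)
  kin <- kinship_from_tree(D)
  rows <- population_rows(hm, b$popmap)
  list(bundle = b, hm = hm, model = model, kin = kin, rows = rows)
})
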