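test_that("simulation is seeded and validates its demography", {
  p <- demography_params(n_scaffolds = 1, scaffold_bp = 3e4)
  f1 <- tempfile(fileext = ".vcf")
  f2 <- tempfile(fileext = ".vcf")
  write_vcf(simulate_demography(p, seed = 7)$hm, f1)
  write_vcf(simulate_demography(p, seed = 7)$hm, f2)
  expect_identical(readLines(f1), readLines(f2))  # byte-identical VCF

  expect_error(demography_params(pulse_time = 20000), "pulse")
  expect_error(demography_params(pulse_frac = 1), "pulse_frac")
})

test_that("neutral diversity matches the coalescent expectation", {
  b <- cached("sfs_sim", simulate_demography(
    neutral_demography(n_pops = 1, Ne = 10000, mu = 1e-7, n_per_pop = 10,
                       scaffold_bp = 6e5, block_bp = 2000), seed = 104))
  A <- b$hm$alleles
  p <- colMeans(A)
  n <- nrow(A)
  pi_hat <- sum(2 * p * (1 - p) * n / (n - 1)) / 6e5
  expect_lt(abs(pi_hat - 4 * 10000 * 1e-7) / (4 * 10000 * 1e-7), 0.1)
})

test_that("divergence between isolated populations grows with split time", {
  fst_of <- function(split) {
    b <- simulate_demography(
      neutral_demography(n_pops = 2, Ne = 5000, split_time = split,
                         mu = 1e-7, scaffold_bp = 5e4, block_bp = 2000),
      seed = 110 + split)
    rows <- population_rows(b$hm, b$popmap)
    comp <- hudson_components(b$hm, rows$pop1, rows$pop2)
    sum(comp$num) / sum(comp$den)
  }
  fsts <- c(fst_of(500), fst_of(2500), fst_of(8000))
  expect_gt(fsts[1], 0)
  expect_true(all(diff(fsts) > 0))
})

test_that("sweep injection is targeted, bounded and leaves residuals", {
  b0 <- cached("scan_sim", simulate_demography(
    demography_params(include_outgroup = FALSE, n_scaffolds = 1,
                      scaffold_bp = 3e5), seed = 105))
  expect_error(inject_sweep(b0, "resident", "hard", f = 1), "fixation")

  b <- inject_sweep(b0, "resident", "hard", f = 0.9, width = 50000, seed = 90)
  sw <- b$truth$sweep
  out_iv <- b$hm$positions - 1L < sw$start | b$hm$positions - 1L >= sw$end
  expect_identical(b$hm$alleles[, out_iv], b0$hm$alleles[, out_iv])
  rows <- population_rows(b$hm, b$popmap, pops = "resident")[[1]]
  tgt <- which(b$hm$positions == sw$target_pos)
  expect_equal(mean(b$hm$alleles[rows, tgt]), 0.9)

  # haplotype homozygosity in the swept region exceeds background
  in_iv <- !out_iv
  hh <- function(M) {
    keys <- apply(M, 1, paste, collapse = "")
    sum((table(keys) / length(keys))^2)
  }
  expect_gt(hh(b$hm$alleles[rows, in_iv]),
            hh(b$hm$alleles[rows, which(out_iv)[1:sum(in_iv)]]))
  # hard sweep: carriers share a single background over the interval
  carriers <- rows[b$hm$alleles[rows, tgt] == 1L]
  expect_equal(nrow(unique(b$hm$alleles[carriers, in_iv])), 1L)

  # standing sweep keeps >= 2 distinct carrier backgrounds
  bs <- inject_sweep(b0, "resident", "standing", f = 0.8, width = 50000,
                     seed = 91)
  sws <- bs$truth$sweep
  iv2 <- bs$hm$positions - 1L >= sws$start & bs$hm$positions - 1L < sws$end
  tgt2 <- which(bs$hm$positions == sws$target_pos)
  carriers2 <- rows[bs$hm$alleles[rows, tgt2] == 1L]
  expect_gte(nrow(unique(bs$hm$alleles[carriers2, iv2])), 2L)

  # asking for the current frequency is a no-op
  p_now <- mean(b0$hm$alleles[rows, tgt])
  expect_message(b_same <- inject_sweep(b0, "resident", "hard", f = p_now,
                                        width = 50000, scaffold = "scaffold_1",
                                        center = sw$target_pos, seed = 92),
                 "no-op")
  expect_identical(b_same$hm$alleles, b0$hm$alleles)
})

test_that("rCCR is ~1 for split labels of one panmictic population", {
  pn <- neutral_demography(n_pops = 2, Ne = 8000, split_time = 1,
                           n_per_pop = 6, scaffold_bp = 4e5, block_bp = 2000)
  b <- simulate_demography(pn, mutations = FALSE, seed = 93)
  cc <- relative_ccr(b, "pop1", "pop2",
                     breaks = exp(seq(log(100), log(2e5), length.out = 13)))
  ok <- !is.na(cc$rccr) & cc$at_risk > 500
  expect_gt(sum(ok), 3)
  expect_lt(max(abs(cc$rccr[ok] - 1)), 0.35)
  expect_lt(abs(mean(cc$rccr[ok]) - 1), 0.1)
})

test_that("rCCR is ~0 recent of a clean ancient split", {
  pn <- neutral_demography(n_pops = 2, Ne = 8000, split_time = 30000,
                           n_per_pop = 6, scaffold_bp = 3e5, block_bp = 2000)
  b <- simulate_demography(pn, mutations = FALSE, seed = 94)
  cc <- relative_ccr(b, "pop1", "pop2")
  recent <- !is.na(cc$rccr) & cc$right < 10000
  expect_true(any(recent))
  expect_equal(max(cc$rccr[recent]), 0)
})

test_that("split-time interpolation is exact for a step at a bin edge", {
  breaks <- seq(0, 1000, by = 100)
  mid <- (breaks[-11] + breaks[-1]) / 2
  curve <- structure(
    data.frame(left = breaks[-11], right = breaks[-1], mid = mid,
               mid_years = mid * 2,
               rate_within_A = 1, rate_within_B = 1,
               rate_between = NA, rccr = as.numeric(mid > 500),
               at_risk = 1000),
    class = c("ccr_curve", "data.frame"), gen_time = 2)
  st <- estimate_split_time(curve)
  expect_equal(st$generations, 500)
  expect_equal(st$years, 1000)

  flat <- curve
  flat$rccr <- 0.2
  expect_message(st0 <- estimate_split_time(flat), "never crosses")
  expect_true(is.na(st0$generations))

  # onset detection: post-split minimum plus delta rule
  curve2 <- curve
  curve2$rccr <- c(0, 0, 0.25, 0.25, 0.25, 0.3, 1, 1, 1, 1)
  on <- estimate_admixture_onset(curve2)
  expect_equal(on$generations, 250)  # first bin rising above min + 0.1
})
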