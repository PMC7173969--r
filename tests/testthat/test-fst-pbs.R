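test_that("windowed Hudson FST equals a hand-coded per-site oracle", {
  hm <- rand_hm(24, 10, seed = 21)
  map <- two_pop_map(hm, split = 5)
  w <- make_windows(hm, width = 10000)  # one window holds all 10 sites
  wf <- window_fst(hm, map, "A", "B", w)
  rowsA <- hap_rows(hm, map$sample_id[map$population == "A"])
  rowsB <- hap_rows(hm, map$sample_id[map$population == "B"])
  num <- den <- 0
  for (s in 1:10) {
    a <- hm$alleles[rowsA, s]; b <- hm$alleles[rowsB, s]
    p1 <- mean(a); p2 <- mean(b); n1 <- length(a); n2 <- length(b)
    num <- num + (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  expect_equal(wf$fst[1], num / den, tolerance = 1e-12)

  # equal frequencies in both populations: FST <= 0
  A <- matrix(rep(c(0L, 1L), 20), 40, 6)   # p = 0.5 in every subsample
  hm2 <- toy_hm(A)
  map2 <- two_pop_map(hm2, split = 5)      # pop A: rows 1-10
  wf2 <- window_fst(hm2, map2, "A", "B", make_windows(hm2, 1000))
  expect_lte(wf2$fst[1], 0)
  # fixed difference with large n: FST -> 1
  A3 <- matrix(rep(c(0L, 1L), c(10, 30)), 40, 4)
  wf3 <- window_fst(toy_hm(A3), map2, "A", "B", make_windows(toy_hm(A3), 1000))
  expect_gt(wf3$fst[1], 0.95)
})

test_that("log-transform T clamps and matches the closed form", {
  expect_equal(log_transform_T(0), 0)
  expect_equal(log_transform_T(-0.3), 0)
  expect_equal(log_transform_T(0.5), log(2))
  expect_true(is.finite(log_transform_T(1)))
})

test_that("PBS modes match the printed algebra and the classic reduction", {
  w <- data.frame(scaffold = "s", start = 0, end = 100, window = 1)
  pops <- c("R", "NW", "SW", "SE")
  prs <- utils::combn(sort(pops), 2)
  t0 <- 0.37
  Tm <- matrix(t0, 1, ncol(prs),
               dimnames = list(NULL, paste(prs[1, ], prs[2, ], sep = "|")))
  # all T equal with 3 non-focal, as printed: (3t - 2t)/3 = t/3
  expect_equal(pbs(Tm, "R", c("NW", "SW", "SE")), t0 / 3)
  # all FST = 0 -> PBS = 0
  expect_equal(pbs(Tm * 0, "R", c("NW", "SW", "SE")), 0)
  # two non-focal populations: both modes equal the classic PBS
  set.seed(22)
  Tr <- matrix(runif(6 * 8), 8, 6,
               dimnames = list(NULL, colnames(Tm)))
  classic <- (Tr[, "NW|R"] + Tr[, "R|SW"] - Tr[, "NW|SW"]) / 2
  expect_equal(pbs(Tr, "R", c("NW", "SW")), classic)
  expect_equal(pbs(Tr, "R", c("NW", "SW"), mode = "mean_triplet"), classic)
  expect_error(pbs(Tm, "R", "NW"), "two non-focal")
})

test_that("delta-PBS differences focal against the best non-focal window", {
  pm <- cbind(R = c(0.5, 0.2), NW = c(0.1, 0.2), SW = c(0.3, 0.2))
  expect_equal(delta_pbs(pm, "R"), c(0.5 - 0.3, 0))
  # identical columns give 0 everywhere
  pm2 <- cbind(R = 1:5 / 10, NW = 1:5 / 10, SW = 1:5 / 10)
  expect_equal(delta_pbs(pm2, "R"), rep(0, 5))
  # invariant to adding a per-window constant to every population
  shift <- pm + c(2, -1)
  expect_equal(delta_pbs(shift, "R"), delta_pbs(pm, "R"))
})

test_that("region calling merges adjacent above-threshold windows", {
  hm <- toy_hm(matrix(0L, 2, 1), positions = 1L,
               lengths = c(scf1 = 300 * 2500))
  w <- make_windows(hm, 2500)
  stat <- rnorm(nrow(w), sd = 0.01)
  stat[101:103] <- 10  # three consecutive extreme windows
  reg <- suppressWarnings(call_regions(w, stat))
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$end - reg$start, 7500)
  expect_equal(reg$peak, 10)
  expect_equal(reg$n_windows, 3L)

  # constant statistic: nothing strictly above its own quantile
  expect_equal(nrow(suppressWarnings(call_regions(w, rep(1, nrow(w))))), 0L)
  expect_error(call_regions(w, rep(NA_real_, nrow(w))), "all-missing")
})

test_that("island replacement with an identical population reproduces PBS", {
  b <- cached("scan_sim", {
    bb <- simulate_demography(
      demography_params(include_outgroup = FALSE, n_scaffolds = 1,
                        scaffold_bp = 3e5), seed = 105)
    bb
  })
  hm <- filter_sites(b$hm, b$popmap, min_individuals = 4)
  w <- make_windows(hm)
  pops <- c("resident", "mig_NW", "mig_SW", "mig_SE")
  pm <- pbs_all(hm, b$popmap, pops, w)
  d <- delta_pbs(pm, "resident")
  reg <- call_regions(w, d, statistic = "delta_pbs", focal = "resident")
  # a "replacement" population identical in composition to the original
  map2 <- b$popmap
  map2$population[map2$population == "resident"] <- "island_like"
  res <- island_replacement_pbs(hm, map2, w, "island_like",
                                c("mig_NW", "mig_SW", "mig_SE"), reg)
  expect_equal(unname(res$pbs[, "island_like"]), unname(pm[, "resident"]))
  expect_equal(res$delta, d)
  if (nrow(reg)) expect_true(all(res$recaptured))
})
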