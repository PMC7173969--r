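# independent all-pairs oracle built on pairwise_sl
nsl_oracle <- function(hm, anc, rows) {
  S <- n_sites(hm)
  flip <- anc$ancestral == "alt"
  out <- data.frame(sl_a = rep(NA_real_, S), sl_d = NA_real_, nsl = NA_real_)
  polar <- anc$ancestral %in% c("ref", "alt")
  for (s in which(polar)) {
    der <- hm$alleles[rows, s]
    if (flip[s]) der <- 1L - der
    a_rows <- rows[!is.na(der) & der == 0L]
    d_rows <- rows[!is.na(der) & der == 1L]
    if (length(a_rows) < 2 || length(d_rows) < 2) next
    mean_sl <- function(rr) {
      vals <- c()
      for (i in seq_along(rr)[-length(rr)])
        for (j in seq(i + 1, length(rr)))
          vals <- c(vals, pairwise_sl(hm, s, rr[i], rr[j]))
      mean(vals, na.rm = TRUE)
    }
    sa <- mean_sl(a_rows)
    sd_ <- mean_sl(d_rows)
    out$sl_a[s] <- sa
    out$sl_d[s] <- sd_
    if (is.finite(sa) && is.finite(sd_) && sa > 0 && sd_ > 0)
      out$nsl[s] <- log(sa / sd_)
  }
  out
}

test_that("pairwise shared-length counts inclusively and truncates at edges", {
  X <- rbind(c(0L, 1L, 0L, 1L, 0L),
             c(0L, 1L, 0L, 1L, 0L))
  hm <- toy_hm(X)
  expect_equal(pairwise_sl(hm, 3, 1, 2), 5)  # identical over all S sites
  Y <- rbind(c(0L, 1L, 0L, 1L, 0L),
             c(0L, 0L, 0L, 0L, 0L))   # differs at sites 2 and 4
  hmY <- toy_hm(Y)
  expect_equal(pairwise_sl(hmY, 3, 1, 2), 1)  # flanked by mismatches
  expect_true(is.na(pairwise_sl(hmY, 2, 1, 2)))  # differs at the focal site
  # missing data truncates like a mismatch: identical over sites 1-3,
  # NA at site 4 ends the interval there
  Z <- Y
  Z[2, 2] <- 1L
  Z[2, 4] <- NA_integer_
  hmZ <- toy_hm(Z)
  expect_equal(pairwise_sl(hmZ, 3, 1, 2), 3)
})

test_that("nsl_scores equals the all-pairs brute force and is direction-free", {
  hm <- rand_hm(10, 60, seed = 61)
  anc <- data.frame(scaffold = hm$scaffold, pos = hm$positions,
                    ancestral = sample(c("ref", "alt", "undetermined"), 60,
                                       replace = TRUE, prob = c(.6, .3, .1)),
                    reason = "none")
  map <- data.frame(sample_id = hm$samples, population = "P",
                    phenotype_class = "neutral")
  sc <- nsl_scores(hm, anc, map, "P")
  # unpolarized sites are dropped before the scan; the oracle sees the same
  # polarized submatrix
  sel <- which(anc$ancestral %in% c("ref", "alt"))
  or <- nsl_oracle(subset_sites(hm, sel), anc[sel, , drop = FALSE], 1:10)
  expect_equal(sc$sl_a[sel], or$sl_a)
  expect_equal(sc$sl_d[sel], or$sl_d)
  expect_equal(sc$nsl[sel], or$nsl)
  expect_true(all(is.na(sc$nsl[-sel])))

  # reversing site order reverses nothing
  rev_idx <- 60:1
  hmr <- toy_hm(hm$alleles[, rev_idx], positions = hm$positions)
  ancr <- anc
  ancr$ancestral <- anc$ancestral[rev_idx]
  scr <- nsl_scores(hmr, ancr, map, "P")
  expect_equal(scr$nsl, sc$nsl[rev_idx])
})

test_that("nSL sign convention: long derived haplotypes push nSL negative", {
  # derived carriers share one long identical haplotype, ancestral carriers
  # are mutually diverse
  set.seed(62)
  S <- 41
  anc_haps <- matrix(rbinom(6 * S, 1, 0.5), 6, S)
  der_hap <- rbinom(S, 1, 0.5)
  X <- rbind(anc_haps, matrix(der_hap, 6, S, byrow = TRUE))
  X[, 21] <- rep(c(0L, 1L), each = 6)   # focal site splits the classes
  hm <- toy_hm(X)
  anc <- data.frame(scaffold = hm$scaffold, pos = hm$positions,
                    ancestral = "ref", reason = "none")
  map <- data.frame(sample_id = hm$samples, population = "P",
                    phenotype_class = "neutral")
  sc <- nsl_scores(hm, anc, map, "P")
  expect_lt(sc$nsl[21], 0)

  # mirror-image class structure gives nSL = 0
  Xm <- rbind(anc_haps, anc_haps)
  Xm[, 21] <- rep(c(0L, 1L), each = 6)
  scm <- nsl_scores(toy_hm(Xm), anc, map, "P")
  expect_equal(scm$nsl[21], 0)
})

test_that("frequency-bin standardization centres and scales per bin", {
  set.seed(63)
  sc <- data.frame(scaffold = "s", pos = seq_len(400) * 5,
                   daf = runif(400, 0.05, 0.95),
                   sl_a = 1, sl_d = 1, nsl = rnorm(400, mean = 2, sd = 3))
  st <- standardize_nsl(sc, bin_width = 0.25, min_bin = 50)
  for (b in unique(na.omit(st$bin))) {
    v <- st$nsl_std[which(st$bin == b)]
    expect_equal(mean(v), 0, tolerance = 1e-10)
    expect_equal(sd(v), 1, tolerance = 1e-10)
  }
  # single-bin degenerate input equals the global z-score
  st2 <- standardize_nsl(sc, bin_width = 1, min_bin = 1)
  expect_equal(st2$nsl_std, (sc$nsl - mean(sc$nsl)) / sd(sc$nsl))
})

test_that("window summaries flag only windows holding extreme scores", {
  sc <- data.frame(scaffold = "s", pos = c(100, 600, 3000),
                   daf = 0.5, sl_a = 1, sl_d = 1, nsl = 0,
                   bin = 1L, nsl_std = c(0, 0, 0))
  w <- data.frame(scaffold = "s", start = c(0, 2500), end = c(2500, 5000),
                  window = 1:2)
  expect_equal(window_summarize_nsl(sc, w), c(0, 0))
  sc$nsl_std <- c(0, -4, 0)
  expect_equal(window_summarize_nsl(sc, w), c(4, 0))
  expect_equal(window_summarize_nsl(sc, w, reduce = "mean"), c(-2, 0))
})
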