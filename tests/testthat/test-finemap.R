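# independent enumeration oracle: plain loops, dense solve, no shared code
caviar_oracle <- function(z, Sigma, c_max = 2, gamma = 0.01, s2 = 5.2) {
  m <- length(z)
  configs <- list(integer(0))
  for (k in 1:c_max) configs <- c(configs, utils::combn(m, k, simplify = FALSE))
  w <- numeric(length(configs))
  for (i in seq_along(configs)) {
    C <- configs[[i]]
    V <- Sigma
    if (length(C)) {
      Sc <- matrix(0, m, m)
      diag(Sc)[C] <- s2
      V <- Sigma + Sigma %*% Sc %*% Sigma
    }
    dens <- (2 * pi)^(-m / 2) * det(V)^(-0.5) *
      exp(-0.5 * as.numeric(t(z) %*% solve(V) %*% z))
    w[i] <- dens * gamma^length(C) * (1 - gamma)^(m - length(C))
  }
  post <- w / sum(w)
  incl <- sapply(seq_len(m), function(i)
    sum(post[sapply(configs, function(C) i %in% C)]))
  list(post = post, incl = incl)
}

test_that("candidate selection keeps sub-threshold SNPs inside the region", {
  scan <- data.frame(scaffold = "s", pos = c(50, 150, 250, 950),
                     p = c(1e-5, 5e-4, 2e-5, 1e-9))
  region <- list(scaffold = "s", start = 0, end = 300)
  expect_equal(select_candidate_snps(scan, region), c(1L, 3L))
  expect_equal(length(select_candidate_snps(scan, region, p_threshold = 1)), 3L)
  scan2 <- scan
  scan2$p <- 0.5
  expect_warning(idx <- select_candidate_snps(scan2, region), "skipped")
  expect_length(idx, 0)
})

test_that("signal correlation reproduces hand-computed whitened correlations", {
  Fm <- matrix(0.01, 4, 4) + diag(0.04, 4)
  rownames(Fm) <- colnames(Fm) <- paste0("p", 1:4)
  set.seed(71)
  freqs <- matrix(runif(4 * 3, 0.2, 0.8), 4, 3)
  Sig <- flk_signal_correlation(freqs, Fm)
  # hand computation of the whitened deviations
  eg <- eigen(Fm, symmetric = TRUE)
  Fih <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  Finv <- solve(Fm)
  ones <- rep(1, 4)
  W <- sapply(1:3, function(j) {
    p <- freqs[, j]
    p0 <- as.numeric(t(ones) %*% Finv %*% p) / as.numeric(t(ones) %*% Finv %*% ones)
    Fih %*% (p - p0 * ones) / sqrt(p0 * (1 - p0))
  })
  expect_equal(unclass(Sig)[1:3, 1:3], cor(W), ignore_attr = TRUE,
               tolerance = 1e-10)
  # z-scores square to the per-SNP FLK quadratic form
  expect_equal(attr(Sig, "z")^2, colSums(W^2), tolerance = 1e-10)

  # duplicated SNP -> correlation exactly 1 (no ridge on Sigma itself)
  freqs2 <- cbind(freqs, freqs[, 1])
  Sig2 <- flk_signal_correlation(freqs2, Fm)
  expect_equal(Sig2[1, 4], 1)
  expect_equal(attr(Sig2, "lambda"), 0)
  expect_error(flk_signal_correlation(freqs[, 1, drop = FALSE], Fm), "two")
})

test_that("caviar posterior matches exhaustive enumeration and basic laws", {
  set.seed(72)
  m <- 8
  R <- matrix(rnorm(m * m), m)
  Sigma <- cov2cor(crossprod(R) + diag(m))
  z <- rnorm(m, sd = 1.5)
  z[3] <- 5
  res <- caviar_posterior(z, Sigma)
  or <- caviar_oracle(z, Sigma)
  expect_equal(sum(res$configs$posterior), 1, tolerance = 1e-10)
  expect_equal(res$configs$posterior, or$post, tolerance = 1e-8)
  expect_equal(res$inclusion, or$incl, tolerance = 1e-8)
  expect_true(3 %in% res$rho_set)

  # permuting SNP order permutes results consistently
  perm <- sample(m)
  res_p <- caviar_posterior(z[perm], Sigma[perm, perm])
  expect_equal(res_p$inclusion, res$inclusion[perm], tolerance = 1e-8)
  expect_equal(sort(perm[res_p$rho_set]), res$rho_set)

  # m = 1 degenerate: the single strong SNP is the whole rho-set
  r1 <- caviar_posterior(6, matrix(1, 1, 1))
  expect_equal(r1$rho_set, 1L)
  expect_gte(r1$inclusion, 0.95)

  # strong signal on SNP 1 with an independent null SNP
  r2 <- caviar_posterior(c(6, 0), diag(2))
  expect_equal(r2$rho_set, 1L)
  expect_gt(r2$inclusion[1], 0.95)
  expect_lt(r2$inclusion[2], 0.1)

  expect_error(caviar_posterior(rep(1, 60), diag(60)), "cap")
})

test_that("the 95% causal set covers the true causal SNP in most draws", {
  set.seed(73)
  m <- 6
  base <- 0.6^abs(outer(1:m, 1:m, "-"))   # AR(1)-like signal correlation
  s2 <- 5.2
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    causal <- sample(m, 1)
    V <- base + s2 * base[, causal, drop = FALSE] %*% base[causal, , drop = FALSE]
    z <- as.numeric(t(chol(V)) %*% rnorm(m))
    res <- caviar_posterior(z, base, max_causal = 2, sigma_sq = s2)
    hits <- hits + (causal %in% res$rho_set)
  }
  expect_gte(hits / reps, 0.9)
})
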