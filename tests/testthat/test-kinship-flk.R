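test_that("Reynolds distance matches the per-site formula and its limits", {
  expect_equal(reynolds_distance(c(0.3, 0.6), c(0.3, 0.6)), 0)
  expect_equal(reynolds_distance(1, 0), 1)
  p1 <- c(0.2, 0.5, 0.9, 0.4, 0.7)
  p2 <- c(0.3, 0.5, 0.2, 0.8, 0.6)
  oracle <- mean(sapply(1:5, function(s) {
    (p1[s] - p2[s])^2 / (1 - p1[s] * p2[s] - (1 - p1[s]) * (1 - p2[s]))
  }))
  expect_equal(reynolds_distance(p1, p2), oracle)
  expect_error(reynolds_distance(numeric(0), numeric(0)), "no shared")
})

test_that("kinship from a rooted tree reads co-drift off path lengths", {
  # ((A:0.1, B:0.15):0.05, C:0.2, OUT:0.5) rooted at the outgroup attachment
  tips <- c("A", "B", "C", "OUT")
  depth_to <- c(A = 0.15, B = 0.20, C = 0.20, OUT = 0.50)
  D <- matrix(0, 4, 4, dimnames = list(tips, tips))
  D["A", "B"] <- 0.25            # via X only
  D["A", "C"] <- 0.1 + 0.05 + 0.2
  D["B", "C"] <- 0.15 + 0.05 + 0.2
  D["A", "OUT"] <- 0.1 + 0.05 + 0.5
  D["B", "OUT"] <- 0.15 + 0.05 + 0.5
  D["C", "OUT"] <- 0.2 + 0.5
  D <- D + t(D)
  k <- kinship_from_tree(D, outgroup = "OUT")
  expect_equal(k$F["A", "B"], 0.05, tolerance = 1e-8)  # shared internal branch
  expect_equal(k$F["A", "C"], 0, tolerance = 1e-8)
  expect_equal(k$F["A", "A"], 0.15, tolerance = 1e-8)
  expect_equal(k$F["B", "B"], 0.20, tolerance = 1e-8)
  expect_equal(k$F["C", "C"], 0.20, tolerance = 1e-8)
  expect_false("OUT" %in% rownames(k$F))

  # star tree with equal branches: F = b I (midpoint rooting)
  b <- 0.08
  Ds <- matrix(2 * b, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(Ds) <- 0
  ks <- kinship_from_tree(Ds)
  expect_equal(unname(diag(ks$F)), rep(b, 4), tolerance = 1e-8)
  expect_equal(max(abs(ks$F[upper.tri(ks$F)])), 0, tolerance = 1e-8)

  # permuting population order permutes F consistently; F stays PSD
  set.seed(31)
  for (rep in 1:5) {
    n <- 5
    P <- matrix(runif(n * 40, 0.1, 0.9), n, 40,
                dimnames = list(paste0("p", 1:n), NULL))
    D2 <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      D2[i, j] <- D2[j, i] <- reynolds_distance(P[i, ], P[j, ])
    k2 <- kinship_from_tree(D2)
    expect_true(isSymmetric(k2$F))
    expect_gte(min(eigen(k2$F, symmetric = TRUE)$values), -1e-10)
    perm <- sample(rownames(P))
    k3 <- kinship_from_tree(D2[perm, perm])
    expect_equal(k3$F[rownames(k2$F), colnames(k2$F)], k2$F,
                 tolerance = 1e-10)
  }
  expect_error(kinship_from_tree(D[1:2, 1:2]), "three")
})

test_that("FLK matches its two-population closed form and symmetries", {
  f <- 0.06
  Fm <- diag(f, 2)
  rownames(Fm) <- colnames(Fm) <- c("A", "B")
  p <- c(0.7, 0.4)
  res <- flk_test(matrix(p, 2, 1, dimnames = list(c("A", "B"))), Fm)
  p0 <- mean(p)
  expect_equal(res$flk, (p[1] - p[2])^2 / (2 * f * p0 * (1 - p0)),
               tolerance = 1e-12)
  expect_equal(res$df, 1L)

  # shared frequency -> 0; ref/alt relabelling invariance
  Fm4 <- matrix(0.01, 4, 4) + diag(0.03, 4)
  same <- matrix(0.42, 4, 3)
  expect_equal(flk_test(same, Fm4)$flk, rep(0, 3), tolerance = 1e-10)
  set.seed(32)
  P <- matrix(runif(4 * 50, 0.1, 0.9), 4, 50)
  expect_equal(flk_test(P, Fm4)$flk, flk_test(1 - P, Fm4)$flk,
               tolerance = 1e-10)

  # p0 pinned at 0 or 1: statistic undefined, site skipped
  expect_true(is.na(flk_test(matrix(0, 4, 1), Fm4)$flk))
})

test_that("robust chi-square normalization recovers df and is robust", {
  set.seed(33)
  x <- rchisq(2000, df = 4)
  np <- normalize_and_pvalue(x)
  expect_lt(abs(np$df - 4) / 4, 0.1)
  expect_gt(suppressWarnings(stats::ks.test(np$p, "punif")$p.value), 0.01)

  # affine transforms preserve p-value ranks
  np2 <- normalize_and_pvalue(3 * x + 7)
  expect_equal(rank(np2$p), rank(np$p))

  # a single huge outlier barely moves the fit
  np3 <- normalize_and_pvalue(c(x, 100 * median(x)))
  common <- seq_along(x)
  expect_lt(max(abs(np3$normalized[common] - np$normalized[common])), 0.2)

  expect_error(normalize_and_pvalue(rep(2, 2000)), "scale")
})
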