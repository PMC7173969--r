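#' Haplotype-mosaic cluster model
#'
#' The local haplotype-cluster model behind hapFLK: each haplotype is a
#' hidden Markov mosaic of K ancestral clusters. Cluster k emits allele 1 at
#' site s with probability theta[k, s]; between consecutive sites the chain
#' stays in its cluster with probability 1 - r_s or jumps to a cluster drawn
#' from the stationary weights alpha, with a distance-dependent switch
#' probability r_s = 1 - exp(-rho * d_s) (r_s = 1 across scaffold breaks, so
#' scaffolds restart from alpha). Parameters are fitted by EM; several
#' independently seeded fits are retained because the likelihood surface is
#' multimodal and downstream statistics average over fits.
#'
#' @param hm a [haplotype_matrix()], or a plain 0/1/NA matrix (haplotypes x
#'   sites; unit inter-site distances assumed).
#' @param K number of clusters (>= 1).
#' @param n_fits number of independent EM fits to retain (default 20).
#' @param max_iter maximum EM iterations per fit.
#' @param tol absolute log-likelihood convergence tolerance.
#' @param seed optional RNG seed (one stream drives all fits).
#' @return object of class `cluster_model`: `K`, `fits` (each with `theta`,
#'   `alpha`, `rho`, `loglik`, `loglik_trace`, `gamma` posterior array
#'   K x H x S, `converged`), `best` (index of the best-likelihood fit),
#'   `d` (inter-site distances).
#' @export
fit_haplotype_clusters <- function(hm, K, n_fits = 20, max_iter = 200,
                                   tol = 1e-4, seed = NULL) {
  if (K < 1L) stop("K must be >= 1")
  if (inherits(hm, "haplotype_matrix")) {
    X <- hm$alleles
    d <- diff(hm$positions)
    d[hm$scaffold[-1L] != hm$scaffold[-length(hm$scaffold)]] <- Inf
    d <- as.numeric(d)
  } else {
    X <- as.matrix(hm)
    d <- rep(1, ncol(X) - 1L)
  }
  if (!is.null(seed)) set.seed(seed)
  fits <- vector("list", n_fits)
  for (e in seq_len(n_fits)) fits[[e]] <- em_mosaic(X, d, K, max_iter, tol)
  best <- which.max(vapply(fits, `[[`, numeric(1L), "loglik"))
  if (any(!vapply(fits, `[[`, logical(1L), "converged")))
    warning("EM did not converge in ", max_iter,
            " iterations for some fit(s); best-likelihood state kept")
  structure(list(K = K, fits = fits, best = best, d = d,
                 n_hap = nrow(X), n_site = ncol(X)),
            class = "cluster_model")
}

# One EM fit of the K-cluster mosaic model. X: H x S with 0/1/NA.
em_mosaic <- function(X, d, K, max_iter, tol) {
  H <- nrow(X)
  S <- ncol(X)
  if (K == 1L) {
    theta <- matrix(colMeans(X, na.rm = TRUE), nrow = 1L)
    theta[is.nan(theta)] <- 0.5
    e <- theta[rep(1L, H), , drop = FALSE]
    ll <- sum(log(ifelse(is.na(X), 1, X * e + (1 - X) * (1 - e))))
    return(list(theta = theta, alpha = 1, rho = 0, loglik = ll,
                loglik_trace = ll, gamma = array(1, dim = c(1L, H, S)),
                converged = TRUE))
  }
  # init: perturbed copies of randomly chosen seed haplotypes
  seeds <- sample.int(H, K, replace = K > H)
  theta <- matrix(0, K, S)
  for (k in seq_len(K)) {
    x <- X[seeds[k], ]
    x[is.na(x)] <- 0.5
    theta[k, ] <- 0.7 * x + 0.3 * stats::runif(S, 0.2, 0.8)
  }
  alpha <- rep(1 / K, K)
  finite_d <- is.finite(d)
  rho <- if (any(finite_d)) -log(0.9) / stats::median(d[finite_d]) else 0
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  emis <- function(s) {
    e <- matrix(1, K, H)
    xs <- X[, s]
    i1 <- which(!is.na(xs) & xs == 1L)
    i0 <- which(!is.na(xs) & xs == 0L)
    if (length(i1)) e[, i1] <- theta[, s]
    if (length(i0)) e[, i0] <- 1 - theta[, s]
    e
  }
  gamma <- array(0, dim = c(K, H, S))
  for (iter in seq_len(max_iter)) {
    r <- ifelse(is.finite(d), 1 - exp(-rho * d), 1)
    # forward (scaled per haplotype)
    fwd <- array(0, dim = c(K, H, S))
    cs <- matrix(0, H, S)
    f <- alpha * emis(1L)
    c1 <- colSums(f)
    cs[, 1L] <- c1
    f <- f / rep(c1, each = K)
    fwd[, , 1L] <- f
    for (s in seq_len(S - 1L) + 1L) {
      pred <- (1 - r[s - 1L]) * f + r[s - 1L] * alpha
      f <- pred * emis(s)
      cc <- colSums(f)
      cs[, s] <- cc
      f <- f / rep(cc, each = K)
      fwd[, , s] <- f
    }
    ll <- sum(log(cs))
    ll_trace <- c(ll_trace, ll)
    # backward + posteriors + jump expectations
    b <- matrix(1, K, H)
    gamma[, , S] <- fwd[, , S]
    land <- rep(0, K)        # expected jump landings (for alpha)
    J <- numeric(S - 1L)     # expected jumps per interval
    for (s in seq(S - 1L, 1L)) {
      u <- emis(s + 1L) * b
      ju <- colSums(alpha * u)                   # per-hap jump mass factor
      J[s] <- sum(r[s] * ju / cs[, s + 1L])
      land <- land + rowSums((r[s] * alpha) * sweep(u, 2L, cs[, s + 1L], "/"))
      b <- ((1 - r[s]) * u + r[s] * rep(ju, each = K)) /
        rep(cs[, s + 1L], each = K)
      g <- fwd[, , s] * b
      gamma[, , s] <- g / rep(colSums(g), each = K)
    }
    # M-step
    X0 <- X
    obs <- !is.na(X0)
    X0[!obs] <- 0L
    num <- matrix(0, K, S)
    den <- matrix(0, K, S)
    for (s in seq_len(S)) {
      g <- gamma[, , s]
      o <- obs[, s]
      num[, s] <- g[, o, drop = FALSE] %*% X0[o, s]
      den[, s] <- rowSums(g[, o, drop = FALSE])
    }
    upd <- den > 0
    theta[upd] <- num[upd] / den[upd]
    # tiny clamp keeps emissions non-degenerate (guards scaled FB underflow)
    theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
    alpha_new <- rowSums(matrix(gamma[, , 1L], nrow = K)) + land
    alpha <- alpha_new / sum(alpha_new)
    if (any(finite_d)) {
      dd <- d[finite_d]
      Jd <- J[finite_d]
      qfun <- function(lrho) {
        rr <- pmin(pmax(1 - exp(-exp(lrho) * dd), 1e-12), 1 - 1e-12)
        sum(Jd * log(rr) + (H - Jd) * log(1 - rr))
      }
      rho <- exp(stats::optimize(qfun, c(-35, 3), maximum = TRUE)$maximum)
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(theta = theta, alpha = alpha, rho = rho,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       gamma = gamma, converged = converged)
}

#' Per-population cluster frequencies from a fitted model
#'
#' @param model a `cluster_model`.
#' @param rows_list named list of haplotype row indices per population.
#' @param fit fit index (default: the best-likelihood fit).
#' @return array K x populations x sites of posterior-mean cluster
#'   frequencies.
#' @export
cluster_frequencies <- function(model, rows_list, fit = NULL) {
  if (is.null(fit)) fit <- model$best
  g <- model$fits[[fit]]$gamma
  K <- dim(g)[1L]
  S <- dim(g)[3L]
  out <- array(0, dim = c(K, length(rows_list), S),
               dimnames = list(NULL, names(rows_list), NULL))
  for (p in seq_along(rows_list)) {
    rs <- rows_list[[p]]
    out[, p, ] <- apply(g[, rs, , drop = FALSE], c(1L, 3L), mean)
  }
  out
}

#' Choose the number of haplotype clusters by masked-imputation
#' cross-validation
#'
#' Masks a fraction of the observed alleles, fits the mosaic model for each
#' candidate K, imputes the masked alleles from the posterior
#' (sum_k gamma * theta thresholded at 0.5) and scores imputation accuracy;
#' the K maximizing accuracy wins, ties broken toward smaller K.
#'
#' @inheritParams fit_haplotype_clusters
#' @param Ks candidate cluster numbers.
#' @param mask_frac fraction of observed entries to mask (must be > 0).
#' @return list with `K` (the winner), `accuracy` (named per candidate).
#' @export
select_K <- function(hm, Ks, mask_frac = 0.05, n_fits = 1, max_iter = 50,
                     tol = 1e-4, seed = NULL) {
  if (mask_frac <= 0) stop("mask_frac must be > 0")
  X <- if (inherits(hm, "haplotype_matrix")) hm$alleles else as.matrix(hm)
  if (!is.null(seed)) set.seed(seed)
  obs <- which(!is.na(X))
  mask <- sample(obs, max(1L, round(mask_frac * length(obs))))
  Xm <- X
  Xm[mask] <- NA_integer_
  hm2 <- hm
  if (inherits(hm, "haplotype_matrix")) hm2$alleles <- Xm else hm2 <- Xm
  Ks <- sort(Ks)
  acc <- vapply(Ks, function(K) {
    m <- fit_haplotype_clusters(hm2, K, n_fits = n_fits, max_iter = max_iter,
                                tol = tol)
    f <- m$fits[[m$best]]
    H <- nrow(X)
    pr <- matrix(0, H, ncol(X))
    for (s in seq_len(ncol(X)))
      pr[, s] <- colSums(f$gamma[, , s, drop = FALSE][, , 1L, drop = FALSE] *
                           f$theta[, s])
    mean((pr[mask] >= 0.5) == (X[mask] == 1L))
  }, numeric(1L))
  names(acc) <- Ks
  list(K = Ks[which.max(acc)], accuracy = acc)
}
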