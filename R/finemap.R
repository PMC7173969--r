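#' Candidate SNPs for fine-mapping inside an outlier region
#'
#' SNPs within the region whose scan p-value is below `p_threshold`
#' (default 1e-4, the usual cut inside genome-wide-significant regions).
#'
#' @param scan data.frame with `scaffold`, `pos` and `p` per SNP.
#' @param region list/one-row data.frame with `scaffold`, `start`, `end`
#'   (0-based half-open).
#' @param p_threshold inclusion threshold on the p-value.
#' @return integer indices into `scan`; empty (with a warning) when nothing
#'   passes.
#' @export
select_candidate_snps <- function(scan, region, p_threshold = 1e-4) {
  idx <- which(scan$scaffold == region$scaffold &
                 (scan$pos - 1L) >= region$start &
                 (scan$pos - 1L) < region$end &
                 !is.na(scan$p) & scan$p < p_threshold)
  if (!length(idx))
    warning("no SNPs below p=", p_threshold, " in region; region skipped")
  idx
}

# whitened frequency deviations: columns are per-SNP vectors
# (p0(1-p0))^(-1/2) F^(-1/2) (p - p0); rank-deficient F is ridge-regularized
whiten_deviations <- function(freqs, Fm, ridge = 0.05) {
  eg <- eigen(Fm, symmetric = TRUE)
  lambda <- 0
  if (min(eg$values) < 1e-10 * max(eg$values)) {
    lambda <- ridge
    Fm <- (1 - lambda) * Fm + lambda * mean(diag(Fm)) * diag(nrow(Fm))
    eg <- eigen(Fm, symmetric = TRUE)
  }
  Fih <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  Finv <- eg$vectors %*% (t(eg$vectors) / eg$values)
  ones <- rep(1, nrow(Fm))
  wF <- Finv %*% ones
  denom <- sum(wF)
  p0 <- as.numeric(crossprod(freqs, wF)) / denom
  Q <- freqs - matrix(p0, nrow(Fm), ncol(freqs), byrow = TRUE)
  W <- Fih %*% Q
  W <- sweep(W, 2L, sqrt(p0 * (1 - p0)), "/")
  list(W = W, p0 = p0, lambda = lambda)
}

#' FLK signal-correlation matrix for fine-mapping
#'
#' Each SNP's centred population-frequency vector is whitened by the inverse
#' square root of p0(1-p0) F — decomposing the differentiation signal onto
#' orthogonal drift components — and Sigma is the correlation of the
#' whitened vectors across SNPs. This replaces the GWAS-LD matrix in the
#' CAVIAR model. A rank-deficient kinship matrix is ridge-regularized before
#' whitening and the lambda used is recorded.
#'
#' @param freqs populations x SNPs frequency matrix.
#' @param kinship kinship matrix (rows matching `freqs`).
#' @param ridge ridge weight applied to a rank-deficient kinship matrix.
#' @return Sigma with attributes `lambda` (0 when no ridge was needed) and
#'   `z` (signed per-SNP z-scores: sqrt of per-SNP 1-df FLK along the
#'   leading whitened contrast, signed by that contrast).
#' @export
flk_signal_correlation <- function(freqs, kinship, ridge = 0.05) {
  Fm <- if (inherits(kinship, "kinship_matrix")) kinship$F else kinship
  freqs <- as.matrix(freqs)
  if (ncol(freqs) < 2L) stop("need at least two SNPs")
  wd <- whiten_deviations(freqs, Fm, ridge = ridge)
  W <- wd$W
  Sigma <- suppressWarnings(stats::cor(W))
  Sigma[!is.finite(Sigma)] <- 0
  diag(Sigma) <- 1
  u1 <- svd(W, nu = 1L, nv = 0L)$u[, 1L]
  z <- sign(as.numeric(crossprod(u1, W))) * sqrt(colSums(W^2))
  attr(Sigma, "lambda") <- wd$lambda
  attr(Sigma, "z") <- z
  Sigma
}

# log-density of z ~ N(0, V); V nudged to the nearest invertible matrix when
# numerically singular (perfectly correlated candidate SNPs)
mvn_logdens <- function(z, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch))
    ch <- chol(V + diag(1e-8 * mean(diag(V)), nrow(V)))
  q <- backsolve(ch, z, transpose = TRUE)
  -0.5 * (length(z) * log(2 * pi)) - sum(log(diag(ch))) - 0.5 * sum(q^2)
}

#' CAVIAR-style causal-configuration posterior
#'
#' Enumerates every causal configuration C with |C| <= `max_causal` over m
#' SNPs. Under configuration C the z-scores are modelled as zero-mean
#' multivariate normal with covariance Sigma + sigma_sq * Sigma_C Sigma
#' (non-centrality variance sigma_sq on the causal coordinates, propagated
#' through the signal correlation), with prior
#' gamma^|C| (1-gamma)^(m-|C|). Posteriors are normalized over all
#' configurations; per-SNP inclusion probabilities and the rho-confidence
#' causal set (smallest SNP set covering posterior mass >= rho among
#' configurations with at least one causal SNP) are derived from them.
#'
#' @param z per-SNP signed z-scores.
#' @param Sigma signal correlation matrix (m x m).
#' @param max_causal maximum causal-set size enumerated (default 2).
#' @param prior_gamma per-SNP prior causal probability (default 0.01).
#' @param sigma_sq causal non-centrality variance (default 5.2, the usual
#'   CAVIAR setting).
#' @param rho confidence level of the causal set (default 0.95).
#' @param max_snps enumeration cap on m.
#' @return list of class `finemap_result`: `configs` (data.frame of
#'   configurations with prior, loglik, posterior), `inclusion` (per SNP),
#'   `rho_set` (SNP indices), `rho`.
#' @export
caviar_posterior <- function(z, Sigma, max_causal = 2, prior_gamma = 0.01,
                             sigma_sq = 5.2, rho = 0.95, max_snps = 50) {
  m <- length(z)
  if (m > max_snps)
    stop(m, " SNPs exceed the enumeration cap (", max_snps,
         "); raise max_snps or tighten the candidate p threshold")
  Sigma <- as.matrix(Sigma)
  configs <- list(integer(0))
  for (k in seq_len(min(max_causal, m)))
    configs <- c(configs, utils::combn(m, k, simplify = FALSE))
  loglik <- vapply(configs, function(C) {
    V <- Sigma
    if (length(C))
      V <- V + sigma_sq * Sigma[, C, drop = FALSE] %*% Sigma[C, , drop = FALSE]
    mvn_logdens(z, V)
  }, numeric(1L))
  logprior <- vapply(configs, function(C)
    length(C) * log(prior_gamma) + (m - length(C)) * log(1 - prior_gamma),
    numeric(1L))
  lp <- loglik + logprior
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  inclusion <- vapply(seq_len(m), function(i)
    sum(post[vapply(configs, function(C) i %in% C, logical(1L))]),
    numeric(1L))
  # rho-set: greedy by inclusion probability, mass conditioned on >=1 causal
  nonnull <- lengths(configs) > 0L
  mass_nonnull <- sum(post[nonnull])
  ord <- order(inclusion, decreasing = TRUE)
  rho_set <- integer(0)
  covered <- 0
  for (i in ord) {
    rho_set <- c(rho_set, i)
    inset <- vapply(configs, function(C)
      length(C) > 0L && all(C %in% rho_set), logical(1L))
    covered <- sum(post[inset]) / mass_nonnull
    if (covered >= rho) break
  }
  cfg <- data.frame(
    config = vapply(configs, paste, character(1L), collapse = ","),
    size = lengths(configs), loglik = loglik, posterior = post)
  structure(list(configs = cfg, inclusion = inclusion,
                 rho_set = sort(rho_set), rho = rho, covered = covered),
            class = "finemap_result")
}
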