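#' FLK test of allele-frequency differentiation
#'
#' For each site with population frequency vector p, the ancestral frequency
#' is estimated as p0 = (1' F^-1 p) / (1' F^-1 1) and
#' FLK = (p - p0 1)' [p0 (1 - p0) F]^-1 (p - p0 1), referred to a chi-square
#' with (n_pops - 1) degrees of freedom. Sites whose estimated p0 hits 0 or 1
#' are undefined and reported NA.
#'
#' @param freqs populations x sites matrix of allele frequencies (rows must
#'   match the rows of `F`).
#' @param kinship a [kinship_from_tree()] result or a bare F matrix.
#' @return data.frame with `p0`, `flk`, `df` and `p` per site.
#' @export
flk_test <- function(freqs, kinship) {
  Fm <- if (inherits(kinship, "kinship_matrix")) kinship$F else kinship
  freqs <- as.matrix(freqs)
  if (nrow(freqs) != nrow(Fm))
    stop("frequency matrix rows must match kinship populations")
  if (!is.null(rownames(freqs)) && !is.null(rownames(Fm)))
    freqs <- freqs[rownames(Fm), , drop = FALSE]
  Finv <- solve(Fm)
  ones <- rep(1, nrow(Fm))
  denom <- as.numeric(crossprod(ones, Finv %*% ones))
  W <- Finv %*% freqs
  p0 <- colSums(W) / denom
  Q <- freqs - matrix(p0, nrow = nrow(Fm), ncol = ncol(freqs), byrow = TRUE)
  quad <- colSums(Q * (Finv %*% Q))
  v <- p0 * (1 - p0)
  flk <- ifelse(v > 0, quad / v, NA_real_)
  df <- nrow(Fm) - 1L
  data.frame(p0 = p0, flk = flk, df = df,
             p = stats::pchisq(flk, df, lower.tail = FALSE))
}

#' Robust chi-square normalization of a genome-wide scan statistic
#'
#' Fits the genome-wide empirical distribution of the raw statistic to a
#' location/scale family of chi-square distributions: sorted raw values are
#' robust-regressed (Huber M-estimation via [MASS::rlm()]) on chi-square
#' quantiles, and the degrees of freedom are chosen to minimize the robust
#' residual scale. Normalized values (raw - shift)/scale are then referred to
#' the fitted chi-square. The robust fit makes the calibration insensitive
#' to the selection outliers the scan is meant to find.
#'
#' @param stat raw statistic values (NA allowed, preserved in the output).
#' @param df_range search interval for the chi-square degrees of freedom.
#' @param min_sites fewer finite values than this triggers a warning: the
#'   normalization needs a genome-scale background to be stable.
#' @return list of class `scan_pvalues`: `raw`, `normalized`, `p`, `df`,
#'   `scale`, `shift`.
#' @export
normalize_and_pvalue <- function(stat, df_range = c(0.5, 100),
                                 min_sites = 1000) {
  x <- stat[is.finite(stat)]
  if (length(x) < 10L) stop("too few finite values to normalize")
  if (length(x) < min_sites)
    warning("normalizing on ", length(x),
            " values; >=", min_sites, " recommended")
  sx <- sort(x)
  pp <- stats::ppoints(length(sx))
  fit_df <- function(df) {
    q <- stats::qchisq(pp, df)
    f <- suppressWarnings(MASS::rlm(sx ~ q, maxit = 50))
    f
  }
  obj <- function(logdf) fit_df(exp(logdf))$s
  opt <- stats::optimize(obj, log(df_range))
  df <- exp(opt$minimum)
  f <- fit_df(df)
  a <- stats::coef(f)[["q"]]
  b <- stats::coef(f)[["(Intercept)"]]
  if (!is.finite(a) || a <= 0) stop("degenerate robust fit (non-positive scale)")
  if (f$s == 0) stop("zero robust scale")
  norm <- (stat - b) / a
  p <- stats::pchisq(norm, df, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  p[!is.finite(stat)] <- NA_real_
  structure(list(raw = stat, normalized = norm, p = p, df = df,
                 scale = a, shift = b),
            class = "scan_pvalues")
}
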