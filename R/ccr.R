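#' Relative cross-coalescence rate from recorded genealogies
#'
#' For each time bin, the coalescence rate of a class of haplotype pairs is
#' the number of pair coalescences in the bin divided by the pair-time at
#' risk (a pair is at risk until it coalesces). The relative
#' cross-coalescence rate is the between-population rate divided by the mean
#' of the two within-population rates: ~1 under panmixia, ~0 after complete
#' separation.
#'
#' @param bundle a `sim_bundle`.
#' @param popA,popB population labels.
#' @param breaks time-bin edges in generations (default: log-spaced from 100
#'   to 4e6 over 36 bins).
#' @param min_pairs minimum pairs at risk for a bin to be reported.
#' @return data.frame of class `ccr_curve`: bin edges and midpoints
#'   (generations and years), within/between rates, `rccr`, `at_risk`.
#' @export
relative_ccr <- function(bundle, popA, popB, breaks = NULL, min_pairs = 20) {
  if (is.null(breaks)) breaks <- exp(seq(log(100), log(4e6), length.out = 37))
  coal <- bundle$coal
  class_col <- function(a, b) {
    hit <- (coal$classes$a == a & coal$classes$b == b) |
      (coal$classes$a == b & coal$classes$b == a)
    if (!any(hit)) stop("no coalescence records for pair ", a, "-", b)
    which(hit)
  }
  rate_of <- function(a, b) {
    w <- coal$counts[, class_col(a, b)]
    keep <- w > 0
    tt <- coal$time[keep]
    ww <- w[keep]
    nb <- length(breaks) - 1L
    ev <- expo <- risk <- numeric(nb)
    for (i in seq_len(nb)) {
      l <- breaks[i]
      r <- breaks[i + 1L]
      inb <- tt >= l & tt < r
      ev[i] <- sum(ww[inb])
      expo[i] <- sum(ww * pmax(0, pmin(tt, r) - l))
      risk[i] <- sum(ww[tt >= l])
    }
    list(rate = ifelse(expo > 0, ev / expo, NA_real_), risk = risk)
  }
  wA <- rate_of(popA, popA)
  wB <- rate_of(popB, popB)
  bt <- rate_of(popA, popB)
  within <- (wA$rate + wB$rate) / 2
  rccr <- ifelse(is.finite(within) & within > 0, bt$rate / within, NA_real_)
  risk <- pmin(wA$risk, wB$risk, bt$risk)
  rccr[risk < min_pairs] <- NA_real_
  gt <- bundle$params$gen_time
  mid <- (breaks[-length(breaks)] + breaks[-1L]) / 2
  structure(data.frame(left = breaks[-length(breaks)], right = breaks[-1L],
                       mid = mid, mid_years = mid * gt,
                       rate_within_A = wA$rate, rate_within_B = wB$rate,
                       rate_between = bt$rate, rccr = rccr, at_risk = risk),
            class = c("ccr_curve", "data.frame"), gen_time = gt)
}

#' Population-separation time from an rCCR curve
#'
#' The most ancient upward 0.5-crossing of the rCCR curve, scanning from the
#' present into the past, linearly interpolated between bin midpoints.
#' Reported in generations and years.
#'
#' @param curve a [relative_ccr()] result.
#' @return list with `generations` and `years` (NA with a diagnostic message
#'   when the curve never crosses 0.5).
#' @export
estimate_split_time <- function(curve) {
  ok <- which(!is.na(curve$rccr))
  v <- curve$rccr[ok]
  m <- curve$mid[ok]
  cross <- which(v[-length(v)] < 0.5 & v[-1L] >= 0.5)
  if (!length(cross)) {
    message("rCCR never crosses 0.5; split time undefined")
    return(list(generations = NA_real_, years = NA_real_))
  }
  i <- cross[length(cross)]   # most ancient upward crossing
  g <- m[i] + (0.5 - v[i]) / (v[i + 1L] - v[i]) * (m[i + 1L] - m[i])
  list(generations = g, years = g * attr(curve, "gen_time"))
}

#' Onset time of a recent rise in rCCR (secondary contact / admixture)
#'
#' Scans the bins more recent than the 0.5-crossing (the post-split epoch,
#' in forward time), takes their minimum rCCR, and reports the most recent
#' bin at which rCCR exceeds that minimum by more than `delta`.
#'
#' @param curve a [relative_ccr()] result.
#' @param delta rise threshold above the post-split minimum (default 0.1).
#' @return list with `generations` and `years` (bin midpoint), NA when no
#'   rise is found.
#' @export
estimate_admixture_onset <- function(curve, delta = 0.1) {
  split <- estimate_split_time(curve)
  if (is.na(split$generations))
    return(list(generations = NA_real_, years = NA_real_))
  ok <- which(!is.na(curve$rccr) & curve$mid < split$generations)
  if (!length(ok)) return(list(generations = NA_real_, years = NA_real_))
  v <- curve$rccr[ok]
  m0 <- min(v)
  rise <- ok[v > m0 + delta]
  if (!length(rise)) return(list(generations = NA_real_, years = NA_real_))
  g <- curve$mid[min(rise)]   # most recent rising bin
  list(generations = g, years = g * attr(curve, "gen_time"))
}
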