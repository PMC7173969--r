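#' Log-transformed FST branch length
#'
#' T = -ln(1 - FST), the branch-length transform underlying PBS. FST is
#' clamped to `[0, 1 - eps]` first: negative window estimates (pure noise
#' around zero differentiation) map to T = 0, and eps keeps T finite at
#' fixed differences.
#'
#' @param fst numeric vector of FST values.
#' @param eps upper clamp margin (default 1e-6).
#' @export
log_transform_T <- function(fst, eps = 1e-6) {
  x <- pmin(pmax(fst, 0), 1 - eps)
  -log(1 - x)
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' All pairwise windowed T values for a set of populations
#'
#' @param hm a [haplotype_matrix()].
#' @param popmap population map.
#' @param pops populations to include.
#' @param windows window table.
#' @return matrix windows x pairs, columns named `"A|B"` with A < B.
#' @export
pairwise_T <- function(hm, popmap, pops, windows) {
  prs <- utils::combn(sort(pops), 2L)
  Tm <- matrix(NA_real_, nrow = nrow(windows), ncol = ncol(prs))
  colnames(Tm) <- pair_key(prs[1L, ], prs[2L, ])
  for (k in seq_len(ncol(prs))) {
    wf <- window_fst(hm, popmap, prs[1L, k], prs[2L, k], windows)
    Tm[, k] <- log_transform_T(wf$fst)
  }
  Tm
}

#' Population branch statistic from a T table
#'
#' With non-focal populations j1..jk, mode `"as_printed"` (default)
#' reproduces the generalized 4-population expression used in the scans:
#' PBS = (sum_j T(focal, j) - sum over consecutive pairs T(j_i, j_{i+1})) / k,
#' where the omitted cross-terms are keyed to the order of `nonfocal`.
#' Mode `"mean_triplet"` averages the classic three-population PBS
#' (T_fj + T_fk - T_jk)/2 over all non-focal pairs. Both modes coincide for
#' two non-focal populations.
#'
#' @param Tmat windows x pairs matrix from [pairwise_T()].
#' @param focal focal population.
#' @param nonfocal ordered vector of at least two non-focal populations.
#' @param mode `"as_printed"` or `"mean_triplet"`.
#' @return numeric vector of per-window PBS.
#' @export
pbs <- function(Tmat, focal, nonfocal, mode = c("as_printed", "mean_triplet")) {
  mode <- match.arg(mode)
  k <- length(nonfocal)
  if (k < 2L) stop("need at least two non-focal populations")
  getT <- function(a, b) {
    key <- pair_key(a, b)
    if (!key %in% colnames(Tmat)) stop("missing pair in T table: ", key)
    Tmat[, key]
  }
  if (mode == "as_printed") {
    acc <- 0
    for (j in nonfocal) acc <- acc + getT(focal, j)
    if (k >= 2L)
      for (i in seq_len(k - 1L))
        acc <- acc - getT(nonfocal[i], nonfocal[i + 1L])
    unname(acc / k)
  } else {
    prs <- utils::combn(nonfocal, 2L)
    vals <- vapply(seq_len(ncol(prs)), function(i) {
      (getT(focal, prs[1L, i]) + getT(focal, prs[2L, i]) -
         getT(prs[1L, i], prs[2L, i])) / 2
    }, numeric(nrow(Tmat)))
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = nrow(Tmat))
    rowMeans(vals)
  }
}

#' PBS for every population as focal in turn
#'
#' Convenience wrapper computing the windowed T table once and PBS per
#' population, each against the remaining populations (in `pops` order) as
#' its non-focal set — the "orthologous windows" layout delta-PBS needs.
#'
#' @inheritParams pairwise_T
#' @param mode passed to [pbs()].
#' @return matrix windows x populations of PBS values.
#' @export
pbs_all <- function(hm, popmap, pops, windows, mode = "as_printed") {
  Tmat <- pairwise_T(hm, popmap, pops, windows)
  out <- vapply(pops, function(f)
    pbs(Tmat, f, setdiff(pops, f), mode = mode), numeric(nrow(windows)))
  colnames(out) <- pops
  out
}

#' Linked-selection-corrected delta-PBS
#'
#' delta-PBS = (scaled) focal PBS minus the maximum (scaled) PBS of the
#' non-focal populations in the same window. Linked selection in a
#' low-recombination region elevates PBS in every population and therefore
#' cancels here; only focal-specific differentiation survives. Scaling
#' `"zscore"` robust-standardizes each population's PBS column
#' ((x - median) / MAD) before differencing; `"none"` (default) uses raw PBS.
#'
#' @param pbs_mat windows x populations PBS matrix (identical windows for
#'   every population).
#' @param focal focal population (a column of `pbs_mat`).
#' @param scaling `"none"` or `"zscore"`.
#' @return numeric vector of per-window delta-PBS for the focal population.
#' @export
delta_pbs <- function(pbs_mat, focal, scaling = c("none", "zscore")) {
  scaling <- match.arg(scaling)
  if (!focal %in% colnames(pbs_mat)) stop("unknown focal population: ", focal)
  M <- pbs_mat
  if (scaling == "zscore") {
    M <- apply(M, 2L, function(x) {
      md <- stats::median(x, na.rm = TRUE)
      s <- stats::mad(x, na.rm = TRUE)
      if (s == 0) stop("zero MAD in PBS column; cannot z-scale")
      (x - md) / s
    })
  }
  nonfocal <- setdiff(colnames(M), focal)
  M[, focal] - apply(M[, nonfocal, drop = FALSE], 1L, max)
}

#' Call top-quantile regions from a window statistic
#'
#' Threshold = empirical quantile of the statistic across all windows;
#' adjacent above-threshold windows (consecutive on the same scaffold) are
#' merged and each region reports its peak window value. Windows must be
#' strictly above the threshold to be called.
#'
#' @param windows window table from [make_windows()].
#' @param stat per-window statistic (same length/order as `windows`).
#' @param quantile empirical quantile for the threshold (default 0.99,
#'   i.e. top 1%).
#' @param statistic,focal labels recorded on the output regions.
#' @return data.frame of regions: scaffold, start, end, statistic, focal,
#'   peak and n_windows; attribute `threshold` records the cut-off.
#' @export
call_regions <- function(windows, stat, quantile = 0.99,
                         statistic = "stat", focal = "") {
  if (all(is.na(stat))) stop("all-missing statistic")
  if (sum(!is.na(stat)) < 100)
    warning("fewer than 100 windows; quantile threshold is unstable")
  thr <- stats::quantile(stat, quantile, na.rm = TRUE, names = FALSE)
  above <- !is.na(stat) & stat > thr
  out <- data.frame(scaffold = character(), start = integer(), end = integer(),
                    statistic = character(), focal = character(),
                    peak = numeric(), n_windows = integer())
  if (any(above)) {
    idx <- which(above)
    # merge runs of consecutive window ids on the same scaffold
    brk <- c(TRUE, diff(idx) != 1L |
               windows$scaffold[idx[-1L]] != windows$scaffold[idx[-length(idx)]])
    grp <- cumsum(brk)
    out <- do.call(rbind, lapply(split(idx, grp), function(i) {
      data.frame(scaffold = windows$scaffold[i[1L]],
                 start = windows$start[i[1L]],
                 end = windows$end[i[length(i)]],
                 statistic = statistic, focal = focal,
                 peak = max(stat[i]), n_windows = length(i))
    }))
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- thr
  out
}

#' Re-estimate delta-PBS with an island population as focal
#'
#' Validation scan for regions called in the continental residents: replace
#' the continental resident with a resident island population as focal,
#' recompute PBS/delta-PBS on the same windows, and report which of the
#' original regions fall inside the island top quantile — parallel selection
#' on a shared haplotype should re-capture them, island-private drift should
#' not.
#'
#' @inheritParams pbs_all
#' @param island island population to use as focal.
#' @param nonfocal non-focal (migrant) populations.
#' @param regions regions called on the original focal population.
#' @param quantile top quantile used for re-capture (default 0.99).
#' @param scaling passed to [delta_pbs()].
#' @return list with `pbs` (windows x populations), `delta` (island
#'   delta-PBS), `regions` (island regions) and `recaptured` (logical per
#'   input region: does it overlap an island top-quantile window?).
#' @export
island_replacement_pbs <- function(hm, popmap, windows, island, nonfocal,
                                   regions, quantile = 0.99,
                                   mode = "as_printed", scaling = "none") {
  pops <- c(island, nonfocal)
  pm <- pbs_all(hm, popmap, pops, windows, mode = mode)
  d <- delta_pbs(pm, island, scaling = scaling)
  isl_regions <- call_regions(windows, d, quantile = quantile,
                              statistic = "delta_pbs", focal = island)
  recaptured <- vapply(seq_len(nrow(regions)), function(i) {
    any(isl_regions$scaffold == regions$scaffold[i] &
          isl_regions$start < regions$end[i] &
          isl_regions$end > regions$start[i])
  }, logical(1L))
  list(pbs = pm, delta = d, regions = isl_regions, recaptured = recaptured)
}
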