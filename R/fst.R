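#' Per-site Hudson FST components
#'
#' Hudson/Bhatia estimator from observed haplotype frequencies:
#' num = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1),
#' den = p1(1-p2) + p2(1-p1). Sites with fewer than two non-missing
#' haplotypes in either population get NA components.
#'
#' @param hm a [haplotype_matrix()].
#' @param rowsA,rowsB haplotype row indices of the two populations.
#' @return data.frame with per-site `num` and `den`.
#' @export
hudson_components <- function(hm, rowsA, rowsB) {
  A <- hm$alleles[rowsA, , drop = FALSE]
  B <- hm$alleles[rowsB, , drop = FALSE]
  n1 <- colSums(!is.na(A))
  n2 <- colSums(!is.na(B))
  p1 <- colMeans(A, na.rm = TRUE)
  p2 <- colMeans(B, na.rm = TRUE)
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  bad <- n1 < 2L | n2 < 2L
  num[bad] <- NA_real_
  den[bad] <- NA_real_
  data.frame(num = num, den = den)
}

#' Windowed Hudson FST between two populations
#'
#' Ratio of sums across each window: FST = sum(num) / sum(den); windows with
#' zero (or all-missing) denominator are reported NA. The raw sums are kept
#' so pairs can be combined or re-windowed without revisiting sites.
#'
#' @param hm a [haplotype_matrix()].
#' @param popmap population map.
#' @param popA,popB population labels.
#' @param windows window table from [make_windows()].
#' @return the window table with `num_sum`, `den_sum` and `fst` columns.
#' @export
window_fst <- function(hm, popmap, popA, popB, windows) {
  rows_list <- population_rows(hm, popmap, pops = c(popA, popB),
                               drop_outgroup = FALSE)
  comp <- hudson_components(hm, rows_list[[popA]], rows_list[[popB]])
  widx <- assign_windows(hm, windows)
  ok <- !is.na(widx) & !is.na(comp$num)
  num_sum <- rep(0, nrow(windows))
  den_sum <- rep(0, nrow(windows))
  ns <- tapply(comp$num[ok], widx[ok], sum)
  ds <- tapply(comp$den[ok], widx[ok], sum)
  num_sum[as.integer(names(ns))] <- ns
  den_sum[as.integer(names(ds))] <- ds
  out <- windows
  out$num_sum <- num_sum
  out$den_sum <- den_sum
  out$fst <- ifelse(den_sum > 0, num_sum / den_sum, NA_real_)
  out
}
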