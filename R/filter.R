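#' Site filters preceding the scans
#'
#' Retains sites with pooled-ingroup minor-allele frequency at least
#' `maf_min` and at least `min_individuals` diploid samples with both
#' haplotypes called in every (non-outgroup) population. Defaults follow the
#' usual scan filters for this kind of panel: MAF 0.05 and 5 individuals per
#' phenotype. The MAF is computed on the pooled ingroup; outgroup samples are
#' never counted.
#'
#' @param hm a [haplotype_matrix()].
#' @param popmap population map.
#' @param maf_min minimum pooled minor-allele frequency (0 disables).
#' @param min_individuals minimum fully-called diploids per population
#'   (0 disables).
#' @return the filtered `haplotype_matrix`; attribute `removed` records the
#'   number of dropped sites.
#' @export
filter_sites <- function(hm, popmap, maf_min = 0.05, min_individuals = 5) {
  rows_list <- population_rows(hm, popmap, drop_outgroup = TRUE)
  ing_rows <- sort(unlist(rows_list, use.names = FALSE))
  A <- hm$alleles[ing_rows, , drop = FALSE]
  p <- colMeans(A, na.rm = TRUE)
  maf <- pmin(p, 1 - p)
  maf[is.nan(p)] <- 0
  keep <- maf >= maf_min
  if (min_individuals > 0) {
    for (r in rows_list) {
      a1 <- hm$alleles[r[seq(1L, length(r), by = 2L)], , drop = FALSE]
      a2 <- hm$alleles[r[seq(2L, length(r), by = 2L)], , drop = FALSE]
      n_called <- colSums(!is.na(a1) & !is.na(a2))
      keep <- keep & n_called >= min_individuals
    }
  }
  if (!any(keep))
    stop("all sites removed by filters; review maf_min/min_individuals")
  out <- subset_sites(hm, keep)
  attr(out, "removed") <- sum(!keep)
  out
}
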