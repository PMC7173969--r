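#' hapFLK: FLK on local haplotype-cluster frequencies
#'
#' At each site the K x n_pops matrix of posterior cluster frequencies is
#' tested with the FLK quadratic form under the multinomial covariance across
#' clusters: with per-cluster ancestral frequencies p0 (F-weighted means),
#' D = P - p0 1', A = diag(p0) - p0 p0' (rank K - 1),
#' hapFLK = tr(A^+ D F^-1 D'). For a single segregating cluster pair this
#' reduces exactly to single-SNP FLK. Degenerate clusters (frequency 0 or 1
#' everywhere) contribute nothing. The statistic is averaged over the EM
#' fits retained in the model.
#'
#' @param model a [fit_haplotype_clusters()] result.
#' @param rows_list named list of haplotype row indices per population (rows
#'   of the matrix the model was fitted to).
#' @param kinship a [kinship_from_tree()] result or bare F matrix whose rows
#'   match `names(rows_list)`.
#' @param fits fit indices to average over (default: all retained fits).
#' @return numeric vector of per-site hapFLK values.
#' @export
hapflk <- function(model, rows_list, kinship, fits = NULL) {
  Fm <- if (inherits(kinship, "kinship_matrix")) kinship$F else kinship
  pops <- names(rows_list)
  if (!is.null(rownames(Fm))) {
    if (!all(pops %in% rownames(Fm)))
      stop("kinship matrix is missing population(s): ",
           paste(setdiff(pops, rownames(Fm)), collapse = ", "))
    Fm <- Fm[pops, pops]
  }
  Finv <- solve(Fm)
  ones <- rep(1, nrow(Fm))
  wF <- Finv %*% ones
  denom <- sum(wF)
  if (is.null(fits)) fits <- seq_along(model$fits)
  S <- model$n_site
  acc <- numeric(S)
  for (e in fits) {
    freqs <- cluster_frequencies(model, rows_list, fit = e)  # K x npop x S
    for (s in seq_len(S))
      acc[s] <- acc[s] + hapflk_site(freqs[, , s, drop = FALSE], Finv, wF, denom)
  }
  acc / length(fits)
}

# quadratic form for one site; P given as K x npop (x 1) array
hapflk_site <- function(P, Finv, wF, denom) {
  P <- matrix(P, nrow = dim(P)[1L])
  p0 <- as.numeric(P %*% wF) / denom
  keep <- p0 > 1e-12 & p0 < 1 - 1e-12
  if (sum(keep) < 2L) return(0)
  p0 <- p0[keep]
  D <- P[keep, , drop = FALSE] - p0
  A <- diag(p0) - tcrossprod(p0)
  eg <- eigen(A, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos)) return(0)
  Ap <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  M <- D %*% Finv %*% t(D)
  sum(Ap * M)
}

#' Genome-wide hapFLK significance threshold by label permutation
#'
#' Shuffles population labels across individuals `n_perm` times (population
#' sizes preserved), re-estimates hapFLK and its normalized p-values under
#' each shuffle, records the per-shuffle minimum p-value, and sets the
#' genome-wide threshold to the 5th percentile of those minima. The cluster
#' model is label-free, so the EM fit — and the kinship matrix, estimated
#' once from the real labels — are held fixed across shuffles; only the
#' per-population cluster frequencies are recomputed.
#'
#' @param hm the [haplotype_matrix()] the model was fitted to.
#' @param popmap population map (non-outgroup samples are shuffled).
#' @param model a [fit_haplotype_clusters()] result.
#' @param kinship kinship matrix for the real populations.
#' @param n_perm number of label shuffles (default 100).
#' @param seed RNG seed; the same seed reproduces the same threshold.
#' @param fits fit indices passed to [hapflk()].
#' @return list with `threshold` (genome-wide p-value threshold), `min_p`
#'   (per-shuffle minima), `n_perm`, `seed`.
#' @export
permutation_threshold <- function(hm, popmap, model, kinship, n_perm = 100,
                                  seed = NULL, fits = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ing <- popmap[popmap$phenotype_class != "outgroup", , drop = FALSE]
  Fm <- if (inherits(kinship, "kinship_matrix")) kinship$F else kinship
  if (!is.null(rownames(Fm)))   # shuffle only the scanned populations
    ing <- ing[ing$population %in% rownames(Fm), , drop = FALSE]
  min_p <- vapply(seq_len(n_perm), function(i) {
    perm <- ing
    perm$population <- sample(perm$population)
    rows_list <- population_rows(hm, perm, drop_outgroup = TRUE)
    stat <- hapflk(model, rows_list, kinship, fits = fits)
    sp <- suppressWarnings(normalize_and_pvalue(stat))
    min(sp$p, na.rm = TRUE)
  }, numeric(1L))
  list(threshold = stats::quantile(min_p, 0.05, names = FALSE),
       min_p = min_p, n_perm = n_perm, seed = seed)
}

#' Assign the selected population from local vs global tree branch lengths
#'
#' Rebuilds the population NJ tree from Reynolds distances restricted to a
#' candidate region and compares terminal branch lengths with the
#' genome-wide tree: selection stretches the selected population's tip
#' branch, so the assignment is the population with the largest positive
#' tip-length excess. Populations within `tie_tol` (relative) of the top
#' excess are reported together with a tie flag; a region with fewer than
#' `min_snps` SNPs is flagged low-confidence.
#'
#' @param hm a [haplotype_matrix()].
#' @param popmap population map.
#' @param pops populations to place on the trees.
#' @param region list or one-row data.frame with `scaffold`, `start`, `end`
#'   (0-based half-open).
#' @param global_D optional precomputed genome-wide Reynolds matrix.
#' @param min_snps minimum region SNPs before flagging low confidence.
#' @param tie_tol relative tolerance for calling a tie.
#' @return list: `population` (character vector, length > 1 on ties; empty
#'   when no positive excess), `excess` (named per population), `tie`,
#'   `low_confidence`, `n_snps`.
#' @export
assign_selected_population <- function(hm, popmap, pops, region,
                                       global_D = NULL, min_snps = 10,
                                       tie_tol = 0.05) {
  if (is.null(global_D))
    global_D <- reynolds_matrix(hm, popmap, pops = pops)
  sel <- hm$scaffold == region$scaffold &
    (hm$positions - 1L) >= region$start & (hm$positions - 1L) < region$end
  n_snps <- sum(sel)
  low <- n_snps < min_snps
  if (low) warning("region has ", n_snps, " SNPs (<", min_snps,
                   "); assignment is low-confidence")
  local_D <- reynolds_matrix(hm, popmap, pops = pops, sites = sel)
  tip_lengths <- function(D) {
    tr <- ape::nj(stats::as.dist(D))
    tr$edge.length[tr$edge.length < 0] <- 0
    tip_edge <- match(seq_along(tr$tip.label), tr$edge[, 2L])
    stats::setNames(tr$edge.length[tip_edge], tr$tip.label)
  }
  gl <- tip_lengths(global_D[pops, pops])
  lo <- tip_lengths(local_D[pops, pops])
  excess <- lo[pops] - gl[pops]
  pos <- excess[excess > 0]
  if (!length(pos))
    return(list(population = character(0), excess = excess, tie = FALSE,
                low_confidence = low, n_snps = n_snps))
  top <- max(pos)
  winners <- names(pos)[pos >= top * (1 - tie_tol)]
  list(population = winners, excess = excess, tie = length(winners) > 1L,
       low_confidence = low, n_snps = n_snps)
}
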