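#' Reynolds distance between two populations
#'
#' Per-site Reynolds (1983) coancestry distance for a biallelic site,
#' d_s = (p1 - p2)^2 / (1 - p1 p2 - (1-p1)(1-p2)), averaged over sites with a
#' defined denominator. Identical frequency vectors give 0; a fixed
#' difference gives 1.
#'
#' @param p1,p2 allele-frequency vectors over a shared site set.
#' @return scalar distance.
#' @export
reynolds_distance <- function(p1, p2) {
  den <- 1 - p1 * p2 - (1 - p1) * (1 - p2)
  ok <- is.finite(den) & den > 0 & is.finite(p1) & is.finite(p2)
  if (!any(ok)) stop("no shared polymorphic sites")
  mean((p1[ok] - p2[ok])^2 / den[ok])
}

#' Pairwise Reynolds distance matrix over populations
#'
#' @param hm a [haplotype_matrix()].
#' @param popmap population map.
#' @param pops populations to include (default: all, outgroup included so it
#'   can root the tree).
#' @param sites optional site subset.
#' @return symmetric distance matrix.
#' @export
reynolds_matrix <- function(hm, popmap, pops = NULL, sites = NULL) {
  if (!is.null(sites)) hm <- subset_sites(hm, sites)
  rows_list <- population_rows(hm, popmap, pops = pops, drop_outgroup = FALSE)
  P <- population_frequencies(hm, rows_list)
  k <- nrow(P)
  D <- matrix(0, k, k, dimnames = list(rownames(P), rownames(P)))
  for (i in seq_len(k - 1L))
    for (j in seq(i + 1L, k)) {
      D[i, j] <- D[j, i] <- reynolds_distance(P[i, ], P[j, ])
    }
  D
}

#' Population kinship (co-drift) matrix from a rooted NJ tree
#'
#' Builds a neighbour-joining tree on the Reynolds distance matrix, roots it
#' (outgroup if one is named, midpoint otherwise), drops the outgroup, and
#' reads the co-drift matrix F off the tree: F_ii is the root-to-tip path
#' length of population i, F_ij the root-to-MRCA(i, j) path length. A tree
#' covariance of this form is automatically symmetric and positive
#' semi-definite. Negative NJ branch lengths are truncated to 0 with a
#' warning.
#'
#' @param D symmetric distance matrix over at least three populations.
#' @param outgroup optional outgroup label (a row of `D`) used to root; when
#'   NULL the tree is midpoint-rooted.
#' @return list of class `kinship_matrix`: `F` (populations x populations),
#'   `tree` (the rooted `phylo`, outgroup dropped), `rooting`.
#' @export
kinship_from_tree <- function(D, outgroup = NULL) {
  if (nrow(D) < 3L) stop("need at least three populations")
  tr <- ape::nj(stats::as.dist(D))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) truncated to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label) stop("outgroup not in distance matrix")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
    # keep the degree-2 root after removing the outgroup: the stem down to
    # the ingroup ancestor is drift shared by every ingroup population
    tr <- ape::drop.tip(tr, outgroup, collapse.singles = FALSE)
    rooting <- paste0("outgroup:", outgroup)
  } else {
    tr <- phangorn::midpoint(tr)
    rooting <- "midpoint"
  }
  tips <- tr$tip.label
  n <- length(tips)
  depth <- ape::node.depth.edgelength(tr)  # root-to-node path lengths
  Fm <- matrix(0, n, n, dimnames = list(tips, tips))
  mr <- ape::mrca(tr)
  for (i in seq_len(n))
    for (j in seq_len(n))
      Fm[i, j] <- depth[mr[tips[i], tips[j]]]
  diag(Fm) <- depth[seq_len(n)][match(tips, tr$tip.label)]
  structure(list(F = Fm, tree = tr, rooting = rooting),
            class = "kinship_matrix")
}
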