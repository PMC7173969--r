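#' Genetic distance from a haplotype to the ancestral sequence
#'
#' Counts the region sites at which the haplotype carries the derived allele
#' — on polarized SNP data this equals the pairwise mismatch count between
#' the haplotype and the reconstructed ancestral sequence. Undetermined
#' sites are skipped and reported.
#'
#' @param hm a [haplotype_matrix()].
#' @param ancestral ancestral table aligned to `hm` sites.
#' @param hap haplotype row index.
#' @param region optional list with `scaffold`, `start`, `end` (0-based
#'   half-open); default whole matrix.
#' @return list with `distance`, `n_polarized`, `n_skipped`.
#' @export
haplotype_ancestral_distance <- function(hm, ancestral, hap, region = NULL) {
  sel <- rep(TRUE, n_sites(hm))
  if (!is.null(region))
    sel <- hm$scaffold == region$scaffold &
      (hm$positions - 1L) >= region$start & (hm$positions - 1L) < region$end
  anc <- ancestral$ancestral[sel]
  x <- hm$alleles[hap, sel]
  polar <- anc %in% c("ref", "alt") & !is.na(x)
  derived <- ifelse(anc == "ref", x == 1L, x == 0L)
  list(distance = sum(derived[polar]),
       n_polarized = sum(polar),
       n_skipped = sum(sel) - sum(polar))
}

region_mid_mass <- function(derived, n, lo = 0.25, hi = 0.75) {
  seg <- derived >= 1 & derived <= n - 1
  if (!any(seg)) return(NA_real_)
  k <- derived[seg]
  mean(k >= lo * n & k <= hi * n)
}

#' Region SFS against a random-region null
#'
#' Compares the unfolded SFS of a focal region with SFSs of `n_random`
#' random regions of the same physical length drawn from the rest of the
#' genome. The summary statistic is the mid-frequency mass: the fraction of
#' polarized segregating sites whose derived count lies in
#' [0.25 * 2N, 0.75 * 2N]. Selection on standing variation leaves an excess
#' of mid-frequency alleles, so the empirical p-value is upper-tail:
#' p = (#null >= focal + 1) / (n_random + 1).
#'
#' @param hm a [haplotype_matrix()].
#' @param ancestral ancestral table aligned to `hm` sites.
#' @param popmap population map.
#' @param population population whose SFS is compared.
#' @param region focal region (`scaffold`, `start`, `end`, 0-based
#'   half-open).
#' @param n_random number of random regions (default 1000).
#' @param seed RNG seed.
#' @param mask optional data.frame of regions to exclude from random
#'   placement (same columns as `region`).
#' @return list of class `region_sfs_null`: `focal_stat`, `null_stats`,
#'   `p`, `focal_sfs` (an [unfolded_sfs()] object), `region`.
#' @export
region_sfs_comparison <- function(hm, ancestral, popmap, population, region,
                                  n_random = 1000, seed = NULL, mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- population_rows(hm, popmap, pops = population,
                          drop_outgroup = FALSE)[[1L]]
  n <- length(rows)
  dc <- derived_counts(hm, ancestral, rows)
  derived <- dc$derived
  derived[dc$n_obs < n] <- NA_real_   # drop incompletely-observed sites
  len <- region$end - region$start
  scs <- unique(hm$scaffold)
  avail <- vapply(scs, function(sc) max(scaffold_length(hm, sc) - len, 0L),
                  numeric(1L))
  if (sum(avail) <= 0) stop("genome too short to place random regions")
  in_region <- function(sc, a, b)
    hm$scaffold == sc & (hm$positions - 1L) >= a & (hm$positions - 1L) < b
  stat_of <- function(sc, a, b) {
    d <- derived[in_region(sc, a, b)]
    region_mid_mass(d[!is.na(d)], n)
  }
  overlaps <- function(sc, a, b, r)
    sc == r$scaffold && a < r$end && b > r$start
  focal_stat <- stat_of(region$scaffold, region$start, region$end)
  if (is.na(focal_stat)) stop("focal region has no polarized segregating sites")
  null_stats <- numeric(n_random)
  i <- 0L
  guard <- 0L
  while (i < n_random) {
    guard <- guard + 1L
    if (guard > 50L * n_random)
      stop("cannot place random regions (masks too large?)")
    sc <- sample(scs, 1L, prob = avail)
    a <- sample.int(max(avail[[sc]], 1L), 1L) - 1L
    b <- a + len
    if (overlaps(sc, a, b, region)) next
    bad <- FALSE
    if (!is.null(mask))
      for (r in seq_len(nrow(mask)))
        if (overlaps(sc, a, b, mask[r, ])) { bad <- TRUE; break }
    if (bad) next
    s <- stat_of(sc, a, b)
    if (is.na(s)) next   # empty region: redraw
    i <- i + 1L
    null_stats[i] <- s
  }
  p <- (sum(null_stats >= focal_stat) + 1) / (n_random + 1)
  focal_sfs <- unfolded_sfs(hm, ancestral, popmap, population,
                            sites = which(in_region(region$scaffold,
                                                    region$start, region$end)))
  structure(list(focal_stat = focal_stat, null_stats = null_stats, p = p,
                 focal_sfs = focal_sfs, region = region),
            class = "region_sfs_null")
}

#' Scan a sequence for an IUPAC motif on both strands
#'
#' Exact matching under IUPAC degeneracy (no mismatches) on the forward and
#' reverse-complement strands; 0-based start coordinates on the forward
#' sequence are reported for both strands.
#'
#' @param sequence a character string or `Biostrings::DNAString`.
#' @param motif motif over the IUPAC alphabet (e.g. `"GHCACGTG"`).
#' @return data.frame with `start` (0-based), `strand` (`"+"`/`"-"`) and
#'   `match` (the matched forward-strand bases), sorted by position.
#' @export
scan_iupac_motif <- function(sequence, motif) {
  if (!grepl("^[ACGTRYSWKMBDHVN]+$", toupper(motif)))
    stop("invalid IUPAC code in motif: ", motif)
  subject <- Biostrings::DNAString(toupper(as.character(sequence)))
  pat <- Biostrings::DNAString(toupper(motif))
  fwd <- Biostrings::matchPattern(pat, subject, fixed = FALSE)
  rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                  subject, fixed = FALSE)
  out <- data.frame(
    start = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    match = c(as.character(fwd), as.character(rev)))
  out[order(out$start), , drop = FALSE]
}
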