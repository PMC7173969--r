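#' Inject a selective sweep into a simulated genome
#'
#' Sweeps are implemented as haplotype-block transplants, which gives exact
#' control over the swept interval and target frequency. `"hard"` mode
#' copies the block around a single carrier haplotype onto enough focal
#' haplotypes to reach frequency `f` at the target site — one dominant
#' background, the hard-sweep signature. `"standing"` mode raises an
#' intermediate-frequency allele already present in at least two
#' populations by copying blocks drawn from multiple distinct carrier
#' backgrounds — several carrier haplotypes survive, the shared-variation
#' signature. Fixation (`f = 1`) is disallowed: a residual non-carrier
#' background always remains. No site outside the interval is touched.
#'
#' @param bundle a `sim_bundle` with haplotypes.
#' @param population focal population.
#' @param mode `"hard"` or `"standing"`.
#' @param f target derived-allele frequency at the target site in the focal
#'   population (must exceed the current frequency; otherwise no-op).
#' @param width swept interval width in bp.
#' @param scaffold,center interval placement; defaults to the middle of the
#'   first scaffold.
#' @param freq_range admissible current frequency of the target allele in
#'   the focal population.
#' @param n_backgrounds number of distinct carrier backgrounds that rise in
#'   a standing sweep (default 2, the canonical soft-sweep picture; ignored
#'   in hard mode).
#' @param seed RNG seed.
#' @return the bundle with modified haplotypes and an updated
#'   `truth$sweep` record.
#' @export
inject_sweep <- function(bundle, population, mode = c("hard", "standing"),
                         f = 0.9, width = 50000, scaffold = NULL,
                         center = NULL, freq_range = c(0.1, 0.9),
                         n_backgrounds = 2, seed = NULL) {
  mode <- match.arg(mode)
  resample <- function(x, n) x[sample.int(length(x), n)]  # scalar-safe
  if (f >= 1) stop("fixation disallowed: f must be < 1")
  if (!is.null(seed)) set.seed(seed)
  hm <- bundle$hm
  if (is.null(hm)) stop("bundle was simulated without mutations")
  if (is.null(scaffold)) scaffold <- unique(hm$scaffold)[1L]
  if (is.null(center)) center <- floor(scaffold_length(hm, scaffold) / 2)
  a <- max(0L, as.integer(center - width / 2))
  b <- a + as.integer(width)
  rows <- population_rows(hm, bundle$popmap, pops = population,
                          drop_outgroup = FALSE)[[1L]]
  n <- length(rows)
  in_iv <- hm$scaffold == scaffold & (hm$positions - 1L) >= a &
    (hm$positions - 1L) < b
  freq <- colMeans(hm$alleles[rows, , drop = FALSE], na.rm = TRUE)
  cand <- which(in_iv & freq >= freq_range[1L] & freq <= freq_range[2L])
  if (mode == "standing") {
    # allele must segregate at intermediate frequency in >= 2 populations
    other <- setdiff(unique(bundle$popmap$population[
      bundle$popmap$phenotype_class != "outgroup"]), population)
    npop_seg <- rep(0L, n_sites(hm))
    for (p in other) {
      rp <- population_rows(hm, bundle$popmap, pops = p,
                            drop_outgroup = FALSE)[[1L]]
      fp <- colMeans(hm$alleles[rp, , drop = FALSE], na.rm = TRUE)
      npop_seg <- npop_seg + (fp >= freq_range[1L] & fp <= freq_range[2L])
    }
    cand <- cand[npop_seg[cand] >= 1L]
    # a standing sweep must actually sweep: >= 2 carrier backgrounds now,
    # and enough headroom below f for a substantial frequency rise
    cand <- cand[freq[cand] * n >= 2 & freq[cand] <= f - 0.2]
  }
  if (!length(cand)) stop("no eligible target site in the interval")
  target <- cand[which.min(abs(hm$positions[cand] - center))]
  carriers <- rows[hm$alleles[rows, target] == 1L & !is.na(hm$alleles[rows, target])]
  k_now <- length(carriers)
  k_goal <- min(round(f * n), n - 1L)   # never fix the region
  if (k_goal <= k_now) {
    message("target frequency already reached; sweep is a no-op")
    return(bundle)
  }
  non_carriers <- setdiff(rows, carriers)
  recipients <- resample(non_carriers, k_goal - k_now)
  if (mode == "hard") {
    donors <- resample(carriers, 1L)
    # the single haplotype rises: existing carriers adopt its background too
    recipients <- c(recipients, setdiff(carriers, donors))
  } else {
    if (length(carriers) < 2L)
      stop("standing sweep needs >= 2 carrier backgrounds in the focal population")
    # a soft sweep: a few of the standing backgrounds rise together
    donors <- resample(carriers, min(n_backgrounds, length(carriers)))
    recipients <- c(recipients, setdiff(carriers, donors))
  }
  donor_of <- rep_len(donors, length(recipients))
  cols <- which(in_iv)
  for (r in seq_along(recipients))
    hm$alleles[recipients[r], cols] <- hm$alleles[donor_of[r], cols]
  bundle$hm <- hm
  bundle$truth$sweep <- list(population = population, mode = mode,
                             scaffold = scaffold, start = a, end = b,
                             target_pos = hm$positions[target], f = f,
                             n_donors = length(unique(donor_of)))
  bundle
}
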