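#' Demographic parameters of the simulated study system
#'
#' A blackcap-like demography: one continental resident population and three
#' medium-distance migrant populations (NW/SW/SE orientations) splitting
#' `split_time` generations ago from a common ancestor, a resident island
#' population founded from the residents `island_time` generations ago with
#' a bottleneck to `Ne_island`, a recent admixture pulse in which residents
#' receive a fraction `pulse_frac` of migrant ancestry `pulse_time`
#' generations ago, a migrant population-size increase at the same epoch,
#' and two deep outgroup species used for ancestral polarization. The
#' outgroup split is placed so that the realized per-site divergence between
#' ingroup haplotypes and the outgroup-species consensus matches `d_out`:
#' t_out = d_out / (2 mu) - 2 Ne_ancestral + 2 Ne_outgroup (1 - 1/n_h),
#' where n_h is the number of outgroup haplotypes. The second term discounts
#' the expected extra coalescent time in the ancestral population, the third
#' restores the outgroup-side drift that taking a consensus removes (the
#' consensus sits near the outgroup sample's MRCA, whose expected depth is
#' 4 Ne_outgroup (1 - 1/n_h), half of which lies on the measured path).
#'
#' Defaults reproduce the study epochs at a generation time of 2 years:
#' a split 15,000 generations (~30,000 years) ago, a pulse 2,500 generations
#' (~5,000 years) ago, mu = 3e-9 per site per generation and outgroup
#' divergence 0.026.
#'
#' @param n_per_pop diploid samples per ingroup population.
#' @param Ne_resident,Ne_migrant_recent,Ne_migrant_ancient,Ne_island
#'   population sizes (diploids); migrants step from ancient to recent size
#'   at `pulse_time`.
#' @param Ne_ancestral,Ne_outgroup ancestral/outgroup sizes.
#' @param split_time,island_time,pulse_time event times in generations.
#' @param pulse_frac admixture fraction (migrant ancestry into residents).
#' @param mu per-site per-generation mutation rate.
#' @param recombination per-site per-generation recombination rate (kept for
#'   reference; genealogies are simulated as independent blocks).
#' @param gen_time generation time in years.
#' @param d_out target ingroup-outgroup per-site divergence.
#' @param include_outgroup simulate the two outgroup species (disable for
#'   ingroup-only scans; much faster since deep branches carry most
#'   mutations).
#' @param n_out_per_species diploid samples per outgroup species.
#' @param n_scaffolds,scaffold_bp,block_bp genome layout: scaffolds are cut
#'   into `block_bp` blocks, each with an independent genealogy.
#' @return list of class `demography_params`.
#' @export
demography_params <- function(n_per_pop = 5,
                              Ne_resident = 250000,
                              Ne_migrant_recent = 500000,
                              Ne_migrant_ancient = 250000,
                              Ne_island = 10000,
                              Ne_ancestral = 250000,
                              Ne_outgroup = 250000,
                              split_time = 15000,
                              island_time = 3000,
                              pulse_time = 2500,
                              pulse_frac = 0.2,
                              mu = 3e-9,
                              recombination = 1e-8,
                              gen_time = 2,
                              d_out = 0.026,
                              include_outgroup = TRUE,
                              n_out_per_species = 2,
                              n_scaffolds = 10,
                              scaffold_bp = 1e6,
                              block_bp = 1e4) {
  if (pulse_time >= split_time) stop("admixture pulse must be after the split")
  if (island_time >= split_time) stop("island founding must be after the split")
  if (pulse_frac <= 0 || pulse_frac >= 1) stop("pulse_frac must be in (0,1)")
  if (min(split_time, island_time, pulse_time) <= 0) stop("times must be > 0")
  n_out_hap <- 2 * n_out_per_species
  t_out <- d_out / (2 * mu) - 2 * Ne_ancestral +
    2 * Ne_outgroup * (1 - 1 / n_out_hap)
  if (t_out <= split_time) stop("outgroup split must pre-date the ingroup split")
  migr <- c("mig_NW", "mig_SW", "mig_SE")
  pops <- c("resident", migr, "island")
  N0 <- c(resident = Ne_resident,
          mig_NW = Ne_migrant_recent, mig_SW = Ne_migrant_recent,
          mig_SE = Ne_migrant_recent, island = Ne_island)
  samples <- stats::setNames(rep(n_per_pop, length(pops)), pops)
  events <- list(
    list(time = pulse_time, type = "pulse", from = "resident", to = "mig_SW",
         frac = pulse_frac))
  for (p in migr)
    events <- c(events, list(list(time = pulse_time, type = "resize",
                                  pop = p, N = Ne_migrant_ancient)))
  events <- c(events,
    list(list(time = island_time, type = "merge", from = "island",
              to = "resident")),
    lapply(migr, function(p)
      list(time = split_time, type = "merge", from = p, to = "resident")),
    list(list(time = split_time, type = "resize", pop = "resident",
              N = Ne_ancestral)))
  if (include_outgroup) {
    pops <- c(pops, "out1", "out2")
    N0 <- c(N0, out1 = Ne_outgroup, out2 = Ne_outgroup)
    samples <- c(samples,
                 stats::setNames(rep(n_out_per_species, 2), c("out1", "out2")))
    events <- c(events,
      list(list(time = t_out / 2, type = "merge", from = "out2", to = "out1"),
           list(time = t_out, type = "merge", from = "out1", to = "resident")))
  }
  phen <- c(resident = "resident_continent", mig_NW = "med_NW",
            mig_SW = "med_SW", mig_SE = "med_SE", island = "island_canary",
            out1 = "outgroup", out2 = "outgroup")
  dist_code <- c(resident = NA, mig_NW = 2, mig_SW = 2, mig_SE = 2,
                 island = NA, out1 = NA, out2 = NA)
  structure(list(pops = pops, N0 = N0, samples = samples, events = events,
                 phenotype_class = phen[pops], distance_code = dist_code[pops],
                 mu = mu, recombination = recombination, gen_time = gen_time,
                 d_out = d_out, t_out = if (include_outgroup) t_out else NA,
                 split_time = split_time, island_time = island_time,
                 pulse_time = pulse_time, pulse_frac = pulse_frac,
                 include_outgroup = include_outgroup,
                 n_scaffolds = n_scaffolds, scaffold_bp = scaffold_bp,
                 block_bp = block_bp),
            class = "demography_params")
}

#' A bare star-phylogeny neutral demography for calibration experiments
#'
#' `n_pops` equal-size populations splitting simultaneously `split_time`
#' generations ago, no admixture, no outgroup. Used for null-calibration
#' runs where label exchangeability (or near-exchangeability) matters.
#'
#' @param n_pops number of populations.
#' @param Ne diploid size of every population (and the ancestor).
#' @param split_time split time in generations.
#' @param n_per_pop diploid samples per population.
#' @param mu mutation rate per site per generation.
#' @param n_scaffolds,scaffold_bp,block_bp genome layout.
#' @param gen_time generation time in years.
#' @return a `demography_params` object.
#' @export
neutral_demography <- function(n_pops = 4, Ne = 10000, split_time = 500,
                               n_per_pop = 5, mu = 1e-7, n_scaffolds = 1,
                               scaffold_bp = 1e5, block_bp = 2000,
                               gen_time = 2) {
  pops <- sprintf("pop%d", seq_len(n_pops))
  events <- lapply(pops[-1L], function(p)
    list(time = split_time, type = "merge", from = p, to = pops[1L]))
  structure(list(pops = pops,
                 N0 = stats::setNames(rep(Ne, n_pops), pops),
                 samples = stats::setNames(rep(n_per_pop, n_pops), pops),
                 events = events,
                 phenotype_class = stats::setNames(rep("neutral", n_pops), pops),
                 distance_code = stats::setNames(rep(NA, n_pops), pops),
                 mu = mu, recombination = 0, gen_time = gen_time,
                 d_out = NA, t_out = NA,
                 split_time = split_time, island_time = NA,
                 pulse_time = NA, pulse_frac = NA,
                 include_outgroup = FALSE,
                 n_scaffolds = n_scaffolds, scaffold_bp = scaffold_bp,
                 block_bp = block_bp),
            class = "demography_params")
}
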