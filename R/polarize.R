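#' Ancestral-allele calls from two outgroup species
#'
#' A site's ancestral allele is the allele for which both outgroup species
#' are homozygous (a species is homozygous iff all of its non-missing alleles
#' at the site are identical), provided that shared allele matches REF or
#' ALT. Everything else is undetermined with a reason: `outgroup_missing`
#' (a species has no data), `outgroup_heterozygous` (a species segregates at
#' the site), or `triallelic` (the outgroups introduce a third base, or the
#' two species are homozygous for different bases). Reasons are assigned in
#' that precedence order.
#'
#' @param out1,out2 character matrices of bases (rows = haploid sequences or
#'   FASTA consensus rows of each species, columns = sites). `NA` or `"N"`
#'   means missing.
#' @param ref,alt REF/ALT base per site.
#' @return data.frame with `ancestral` (`"ref"`, `"alt"` or
#'   `"undetermined"`) and `reason` (`"none"`, `"outgroup_missing"`,
#'   `"outgroup_heterozygous"`, `"triallelic"`).
#' @export
call_ancestral <- function(out1, out2, ref, alt) {
  species_state <- function(M) {
    M <- as.matrix(M)
    M[M == "N"] <- NA_character_
    counts <- vapply(c("A", "C", "G", "T"),
                     function(b) colSums(M == b, na.rm = TRUE),
                     numeric(ncol(M)))
    if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
    n_distinct <- rowSums(counts > 0L)
    allele <- c("A", "C", "G", "T")[max.col(counts, ties.method = "first")]
    allele[n_distinct != 1L] <- NA_character_
    list(n_distinct = n_distinct, allele = allele)
  }
  s1 <- species_state(out1)
  s2 <- species_state(out2)
  S <- length(ref)
  anc <- rep("undetermined", S)
  reason <- rep("none", S)
  missing <- s1$n_distinct == 0L | s2$n_distinct == 0L
  het <- !missing & (s1$n_distinct > 1L | s2$n_distinct > 1L)
  hom <- !missing & !het
  agree <- hom & s1$allele == s2$allele
  matches_ref <- agree & s1$allele == ref
  matches_alt <- agree & s1$allele == alt
  anc[matches_ref] <- "ref"
  anc[matches_alt] <- "alt"
  reason[missing] <- "outgroup_missing"
  reason[het] <- "outgroup_heterozygous"
  reason[hom & !(matches_ref | matches_alt)] <- "triallelic"
  data.frame(ancestral = anc, reason = reason)
}

#' Ancestral calls from outgroup samples carried in the haplotype matrix
#'
#' Outgroup samples are the population-map entries with
#' `phenotype_class == "outgroup"`; the two species are distinguished by their
#' `population` label. Haplotype 0/1 codes are mapped back to bases through
#' REF/ALT before applying [call_ancestral()].
#'
#' @param hm a [haplotype_matrix()] that includes the outgroup samples.
#' @param popmap population map.
#' @param species1,species2 population labels of the two outgroup species.
#' @return per-site ancestral table (see [call_ancestral()]) plus `scaffold`
#'   and `pos` columns.
#' @export
ancestral_from_outgroups <- function(hm, popmap, species1, species2) {
  to_bases <- function(rows) {
    A <- hm$alleles[rows, , drop = FALSE]
    B <- matrix(NA_character_, nrow = nrow(A), ncol = ncol(A))
    refm <- matrix(rep(hm$ref, each = nrow(A)), nrow = nrow(A))
    altm <- matrix(rep(hm$alt, each = nrow(A)), nrow = nrow(A))
    B[A == 0L] <- refm[A == 0L]
    B[A == 1L] <- altm[A == 1L]
    B
  }
  rows_list <- population_rows(hm, popmap, pops = c(species1, species2),
                               drop_outgroup = FALSE)
  calls <- call_ancestral(to_bases(rows_list[[species1]]),
                          to_bases(rows_list[[species2]]),
                          hm$ref, hm$alt)
  cbind(data.frame(scaffold = hm$scaffold, pos = hm$positions), calls)
}

#' Ancestral truth table from a simulation bundle
#'
#' The coalescent generator roots every site at the REF allele, so the true
#' ancestral call is `"ref"` everywhere.
#'
#' @param bundle a simulation bundle from [simulate_demography()].
#' @export
ancestral_from_truth <- function(bundle) {
  hm <- bundle$hm
  data.frame(scaffold = hm$scaffold, pos = hm$positions,
             ancestral = "ref", reason = "none")
}

#' Write the per-site ancestral table as TSV
#' @param ancestral table from [ancestral_from_outgroups()].
#' @param path output path.
#' @export
write_ancestral_table <- function(ancestral, path) {
  utils::write.table(ancestral, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-site derived-allele counts for a population
#'
#' @param hm a [haplotype_matrix()].
#' @param ancestral ancestral table aligned to `hm` sites.
#' @param rows haplotype row indices of the population.
#' @return list with `derived` (count per site, NA where undetermined or any
#'   haplotype is missing under `handle_missing = "drop"`), `n_obs`
#'   (non-missing haplotypes per site) and `polarized` (logical).
#' @keywords internal
derived_counts <- function(hm, ancestral, rows) {
  A <- hm$alleles[rows, , drop = FALSE]
  alt_count <- colSums(A, na.rm = TRUE)
  n_obs <- colSums(!is.na(A))
  polarized <- ancestral$ancestral %in% c("ref", "alt")
  derived <- ifelse(ancestral$ancestral == "ref", alt_count, n_obs - alt_count)
  derived[!polarized] <- NA_real_
  list(derived = derived, n_obs = n_obs, polarized = polarized)
}

#' Unfolded site-frequency spectrum of a population
#'
#' Counts of derived-allele frequency classes i = 1..2N-1 over polarized
#' segregating sites. Sites with missing haplotypes are dropped by default or
#' hypergeometrically projected down to `project_n` haplotypes.
#'
#' @param hm a [haplotype_matrix()].
#' @param ancestral ancestral table aligned to `hm` sites.
#' @param popmap population map.
#' @param population population label.
#' @param sites optional site subset (integer/logical index).
#' @param handle_missing `"drop"` (default) or `"project"`.
#' @param project_n target haplotype count for projection.
#' @return list of class `sfs`: `counts` (named vector, classes 1..2N-1) and
#'   `n` (the haplotype sample size 2N).
#' @export
unfolded_sfs <- function(hm, ancestral, popmap, population, sites = NULL,
                         handle_missing = c("drop", "project"),
                         project_n = NULL) {
  handle_missing <- match.arg(handle_missing)
  rows <- population_rows(hm, popmap, pops = population,
                          drop_outgroup = FALSE)[[1L]]
  if (!is.null(sites)) {
    hm <- subset_sites(hm, sites)
    ancestral <- ancestral[sites, , drop = FALSE]
  }
  dc <- derived_counts(hm, ancestral, rows)
  n <- length(rows)
  if (handle_missing == "drop") {
    ok <- !is.na(dc$derived) & dc$n_obs == n
    k <- dc$derived[ok]
    counts <- tabulate(k[k >= 1 & k <= n - 1], nbins = n - 1L)
  } else {
    if (is.null(project_n) || project_n < 2L)
      stop("projection needs project_n >= 2")
    m <- as.integer(project_n)
    counts <- numeric(m - 1L)
    ok <- which(!is.na(dc$derived) & dc$n_obs >= m)
    for (s in ok) {
      kk <- dc$derived[s]
      nn <- dc$n_obs[s]
      pr <- stats::dhyper(seq_len(m - 1L), kk, nn - kk, m)
      counts <- counts + pr
    }
    n <- m
  }
  if (sum(counts) == 0) warning("empty site set: all-zero SFS")
  names(counts) <- seq_len(n - 1L)
  structure(list(counts = counts, n = n), class = "sfs")
}

#' Align an ancestral table to a (possibly filtered) haplotype matrix
#'
#' Matches rows by scaffold and position so ancestral calls made on the full
#' site set can be carried through site filters.
#'
#' @param ancestral a per-site ancestral table with `scaffold` and `pos`.
#' @param hm the target [haplotype_matrix()].
#' @return the ancestral table re-indexed to the sites of `hm`.
#' @export
align_ancestral <- function(ancestral, hm) {
  idx <- match(paste(hm$scaffold, hm$positions),
               paste(ancestral$scaffold, ancestral$pos))
  if (anyNA(idx)) stop("ancestral table does not cover all sites")
  ancestral[idx, , drop = FALSE]
}
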