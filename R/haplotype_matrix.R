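#' Phased haplotype matrix
#'
#' The substrate of every scan in the package: a binary matrix of phased
#' alleles with one row per haplotype (rows come in consecutive `_a`/`_b`
#' pairs per diploid sample) and one column per segregating site. Sites are
#' ordered scaffold-major with strictly increasing physical positions within
#' each scaffold. Allele 0 is the REF allele, 1 the ALT allele, `NA` missing.
#'
#' @param alleles integer matrix, haplotypes x sites, values 0/1/NA.
#' @param positions 1-based physical position per site.
#' @param scaffold scaffold (sequence) name per site.
#' @param ref,alt REF/ALT base per site (single characters). Defaults "A"/"T".
#' @param samples diploid sample ids (one per row pair). Defaults `sample<i>`.
#' @param scaffold_lengths optional named vector of scaffold lengths in bp;
#'   when absent, the maximum observed position is used where a length is
#'   needed (e.g. when tiling windows).
#' @return an object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(alleles, positions, scaffold, ref = NULL, alt = NULL,
                             samples = NULL, scaffold_lengths = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  S <- ncol(alleles)
  if (length(positions) != S || length(scaffold) != S)
    stop("positions/scaffold must have one entry per site")
  if (nrow(alleles) %% 2L != 0L)
    stop("haplotypes must come in diploid pairs (even number of rows)")
  rng <- range(alleles, na.rm = (S > 0L && anyNA(alleles)))
  if (S > 0L && (rng[1] < 0L || rng[2] > 1L))
    stop("alleles must be 0, 1 or NA")
  scaffold <- as.character(scaffold)
  positions <- as.integer(positions)
  # scaffold-major ordering with strictly increasing positions per scaffold
  for (sc in unique(scaffold)) {
    p <- positions[scaffold == sc]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stop("positions must be strictly increasing within scaffold ", sc)
  }
  n_dip <- nrow(alleles) / 2L
  if (is.null(samples)) samples <- sprintf("sample%d", seq_len(n_dip))
  if (length(samples) != n_dip) stop("need one sample id per diploid row pair")
  if (is.null(ref)) ref <- rep("A", S)
  if (is.null(alt)) alt <- rep("T", S)
  rownames(alleles) <- paste0(rep(samples, each = 2L), c("_a", "_b"))
  structure(list(alleles = alleles, positions = positions, scaffold = scaffold,
                 ref = as.character(ref), alt = as.character(alt),
                 samples = as.character(samples),
                 scaffold_lengths = scaffold_lengths),
            class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d diploids) x %d sites on %d scaffold(s)\n",
              nrow(x$alleles), length(x$samples), ncol(x$alleles),
              length(unique(x$scaffold))))
  invisible(x)
}

#' @rdname haplotype_matrix
#' @param x a `haplotype_matrix`.
#' @export
n_sites <- function(x) ncol(x$alleles)

#' @rdname haplotype_matrix
#' @export
n_haplotypes <- function(x) nrow(x$alleles)

#' Subset a haplotype matrix by site index
#'
#' @param hm a `haplotype_matrix`.
#' @param sites integer or logical site index.
#' @return a `haplotype_matrix` restricted to `sites`.
#' @export
subset_sites <- function(hm, sites) {
  hm$alleles <- hm$alleles[, sites, drop = FALSE]
  hm$positions <- hm$positions[sites]
  hm$scaffold <- hm$scaffold[sites]
  hm$ref <- hm$ref[sites]
  hm$alt <- hm$alt[sites]
  hm
}

#' Subset a haplotype matrix to a set of diploid samples
#'
#' @param hm a `haplotype_matrix`.
#' @param samples character vector of sample ids to keep (order respected).
#' @export
subset_samples <- function(hm, samples) {
  miss <- setdiff(samples, hm$samples)
  if (length(miss)) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  rows <- hap_rows(hm, samples)
  hm$alleles <- hm$alleles[rows, , drop = FALSE]
  hm$samples <- samples
  hm
}

#' Haplotype row indices for a set of samples
#'
#' @param hm a `haplotype_matrix`.
#' @param samples sample ids.
#' @return integer vector of row indices (two consecutive rows per sample).
#' @export
hap_rows <- function(hm, samples) {
  i <- match(samples, hm$samples)
  if (anyNA(i)) stop("unknown sample(s): ",
                     paste(samples[is.na(i)], collapse = ", "))
  as.integer(rbind(2L * i - 1L, 2L * i))
}

#' Per-population haplotype row index
#'
#' @param hm a `haplotype_matrix`.
#' @param popmap a population map (see [read_population_map()]).
#' @param pops populations to index; default all populations in the map.
#' @param drop_outgroup drop populations whose `phenotype_class` is
#'   `"outgroup"` (default TRUE).
#' @return named list of integer haplotype row indices.
#' @export
population_rows <- function(hm, popmap, pops = NULL, drop_outgroup = TRUE) {
  popmap <- popmap[popmap$sample_id %in% hm$samples, , drop = FALSE]
  if (drop_outgroup && "phenotype_class" %in% names(popmap))
    popmap <- popmap[popmap$phenotype_class != "outgroup", , drop = FALSE]
  if (is.null(pops)) pops <- unique(popmap$population)
  out <- lapply(pops, function(p)
    hap_rows(hm, popmap$sample_id[popmap$population == p]))
  names(out) <- pops
  if (any(lengths(out) == 0L))
    stop("population(s) with no mapped samples: ",
         paste(pops[lengths(out) == 0L], collapse = ", "))
  out
}

#' Alternate-allele frequencies per population
#'
#' @param hm a `haplotype_matrix`.
#' @param rows_list named list of haplotype row indices (see
#'   [population_rows()]).
#' @return numeric matrix, populations x sites, of ALT-allele frequencies
#'   (missing alleles excluded from the denominator).
#' @export
population_frequencies <- function(hm, rows_list) {
  t(vapply(rows_list, function(r)
    colMeans(hm$alleles[r, , drop = FALSE], na.rm = TRUE),
    numeric(n_sites(hm))))
}

scaffold_length <- function(hm, sc) {
  if (!is.null(hm$scaffold_lengths) && sc %in% names(hm$scaffold_lengths))
    return(as.integer(hm$scaffold_lengths[[sc]]))
  max(hm$positions[hm$scaffold == sc])
}
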