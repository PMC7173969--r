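#' Read a sample-to-population map
#'
#' Tab-separated file with columns `sample_id`, `population`,
#' `phenotype_class` and optionally `distance_code` (ordinal 1-3 for
#' migratory-distance classes, NA elsewhere).
#'
#' @param path TSV path.
#' @return data.frame population map.
#' @export
read_population_map <- function(path) {
  map <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  validate_population_map(map)
  map
}

#' @rdname read_population_map
#' @param map population map data.frame.
#' @param samples optional vector of sample ids that must each appear exactly
#'   once in the map.
#' @export
validate_population_map <- function(map, samples = NULL) {
  need <- c("sample_id", "population", "phenotype_class")
  if (!all(need %in% names(map)))
    stop("population map needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(map$sample_id))
    stop("duplicated sample_id in population map")
  if (!is.null(samples)) {
    miss <- setdiff(samples, map$sample_id)
    if (length(miss))
      stop("sample(s) absent from population map: ", paste(miss, collapse = ", "))
  }
  ingroup <- map[map$phenotype_class != "outgroup", , drop = FALSE]
  if (any(table(ingroup$population) < 1L))
    stop("every non-outgroup population needs at least one sample")
  invisible(map)
}

#' Write a population map as TSV
#' @param map population map data.frame.
#' @param path output path.
#' @export
write_population_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read phased genotypes from a VCF into a haplotype matrix
#'
#' Keeps biallelic SNP records only (multi-allelic and indel records are
#' dropped and counted), restricts to the samples in the population map, and
#' splits each phased diploid GT into two haplotype rows.
#'
#' @param path VCF path (v4.x, plain or bgzipped).
#' @param population_map optional population map; when given, every mapped
#'   sample must be present in the VCF (error naming the missing sample
#'   otherwise) and only mapped samples are kept.
#' @param force_phase treat unphased separators (`/`) as phased instead of
#'   erroring. Off by default: the scans assume phased data.
#' @return list with `hm` (the [haplotype_matrix()]) and `dropped`
#'   (records removed as non-biallelic-SNP).
#' @export
read_vcf <- function(path, population_map = NULL, force_phase = FALSE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  samples <- colnames(gt)[-1L]
  if (!is.null(population_map)) {
    validate_population_map(population_map, samples = NULL)
    miss <- setdiff(population_map$sample_id, samples)
    if (length(miss))
      stop("sample(s) in population map absent from VCF: ",
           paste(miss, collapse = ", "))
    samples <- population_map$sample_id
  }
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  dropped <- sum(!keep)
  if (dropped > 0L)
    message(dropped, " non-biallelic-SNP record(s) dropped")
  fix <- fix[keep, , drop = FALSE]
  gtm <- gt[keep, samples, drop = FALSE]
  # GT is the first colon-separated field
  gtm <- sub(":.*$", "", gtm)
  unphased <- grepl("/", gtm, fixed = TRUE)
  if (any(unphased)) {
    if (!force_phase)
      stop("unphased genotype(s) found; set force_phase = TRUE to coerce")
    gtm[unphased] <- gsub("/", "|", gtm[unphased], fixed = TRUE)
  }
  S <- nrow(fix)
  n <- length(samples)
  alleles <- matrix(NA_integer_, nrow = 2L * n, ncol = S)
  a1 <- substr(gtm, 1L, 1L)
  a2 <- substr(gtm, 3L, 3L)
  to_int <- function(a) {
    out <- rep(NA_integer_, length(a))
    out[a == "0"] <- 0L
    out[a == "1"] <- 1L
    out
  }
  for (j in seq_len(n)) {
    alleles[2L * j - 1L, ] <- to_int(a1[, j])
    alleles[2L * j, ] <- to_int(a2[, j])
  }
  lens <- NULL
  meta <- v@meta
  ctg <- grep("^##contig=", meta, value = TRUE)
  if (length(ctg)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ctg)
    ln <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", ctg)))
    if (!anyNA(ln)) lens <- stats::setNames(ln, ids)
  }
  hm <- haplotype_matrix(alleles,
                         positions = as.integer(fix[, "POS"]),
                         scaffold = fix[, "CHROM"],
                         ref = ref[keep], alt = alt[keep],
                         samples = samples, scaffold_lengths = lens)
  list(hm = hm, dropped = dropped)
}

#' Write a haplotype matrix as a phased VCF
#'
#' @param hm a [haplotype_matrix()].
#' @param path output path (plain text `.vcf`).
#' @export
write_vcf <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##fileformat=VCFv4.2", con)
  scs <- unique(hm$scaffold)
  for (sc in scs)
    writeLines(sprintf("##contig=<ID=%s,length=%d>", sc, scaffold_length(hm, sc)), con)
  writeLines("##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">", con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", hm$samples), collapse = "\t"), con)
  n <- length(hm$samples)
  A <- hm$alleles
  ch <- matrix(".", nrow = nrow(A), ncol = ncol(A))
  ch[!is.na(A)] <- as.character(A[!is.na(A)])
  gts <- matrix("", nrow = n, ncol = ncol(A))
  for (j in seq_len(n))
    gts[j, ] <- paste(ch[2L * j - 1L, ], ch[2L * j, ], sep = "|")
  body <- apply(rbind(hm$scaffold, as.character(hm$positions), ".",
                      hm$ref, hm$alt, ".", "PASS", ".", "GT", gts),
                2L, paste, collapse = "\t")
  writeLines(body, con)
  invisible(path)
}

#' Write called regions as BED6
#'
#' Name is `statistic:population`; score is the peak value scaled by 1000 and
#' clamped to 0-1000, the usual BED convention for bounded scores.
#'
#' @param regions a region table from [call_regions()].
#' @param path output path.
#' @export
write_bed_regions <- function(regions, path) {
  score <- pmin(pmax(round(regions$peak * 1000), 0), 1000)
  bed <- data.frame(regions$scaffold, regions$start, regions$end,
                    paste0(regions$statistic, ":", regions$focal),
                    score, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
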