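test_that("read_vcf transcribes phased biallelic SNPs and drops the rest", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=scf1,length=1000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "scf1\t10\t.\tA\tT\t.\tPASS\t.\tGT\t0|1\t1|1",
    "scf1\t20\t.\tC\tG\t.\tPASS\t.\tGT\t0|0\t0|1",
    "scf1\t30\t.\tG\tA,T\t.\tPASS\t.\tGT\t0|1\t0|2",
    "scf1\t40\t.\tT\tC\t.\tPASS\t.\tGT\t1|0\t.|.")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  suppressMessages(res <- read_vcf(f))
  expect_equal(res$dropped, 1L)  # the triallelic record
  expect_equal(dim(res$hm$alleles), c(4L, 3L))
  expect_equal(unname(res$hm$alleles[, 1L]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(res$hm$alleles[, 3L]), c(1L, 0L, NA_integer_, NA_integer_))
  expect_equal(res$hm$positions, c(10L, 20L, 40L))
  expect_equal(unname(res$hm$scaffold_lengths["scf1"]), 1000L)

  # unphased genotype errors unless force_phase
  vcf2 <- sub("0\\|1\t1\\|1", "0/1\t1|1", vcf)
  writeLines(vcf2, f)
  expect_error(suppressMessages(read_vcf(f)), "unphased")
  suppressMessages(res2 <- read_vcf(f, force_phase = TRUE))
  expect_equal(res2$hm$alleles, res$hm$alleles)

  # a mapped sample absent from the VCF is named in the error
  bad_map <- data.frame(sample_id = c("s1", "s9"), population = "A",
                        phenotype_class = "neutral")
  writeLines(vcf, f)
  expect_error(suppressMessages(read_vcf(f, population_map = bad_map)), "s9")
})

test_that("simulator VCF round-trips through read_vcf exactly", {
  b <- small_sim()
  f <- tempfile(fileext = ".vcf")
  write_vcf(b$hm, f)
  rt <- read_vcf(f, population_map = b$popmap)
  expect_identical(rt$hm$alleles, b$hm$alleles)
  expect_identical(rt$hm$positions, b$hm$positions)
  expect_identical(rt$hm$scaffold, b$hm$scaffold)
  expect_identical(rt$hm$samples, b$hm$samples)
  expect_identical(rt$hm$ref, b$hm$ref)
  expect_identical(rt$hm$alt, b$hm$alt)
})

test_that("filter_sites applies MAF and per-population call-rate rules", {
  # 2 pops x 6 diploids each; site 1 has MAF 1/24 < 0.05 -> removed
  set.seed(5)
  A <- matrix(rbinom(24 * 10, 1, 0.4), 24, 10)
  A[, 1] <- 0L
  A[1, 1] <- 1L
  hm <- toy_hm(A)
  map <- two_pop_map(hm, split = 6)
  filt <- filter_sites(hm, map, maf_min = 0.05, min_individuals = 5)
  expect_false(10L %in% filt$positions[1])  # site 1 (pos 10) removed
  expect_true(all(filt$positions != 10L))

  # maf_min = 0 and min_individuals = 0 is the identity
  ident <- filter_sites(hm, map, maf_min = 0, min_individuals = 0)
  expect_identical(ident$alleles, hm$alleles)

  # survivors match an independent per-site recount oracle
  hm2 <- rand_hm(50, 200, seed = 6, miss = 0.05)
  map2 <- two_pop_map(hm2, split = 12)
  filt2 <- filter_sites(hm2, map2, maf_min = 0.1, min_individuals = 8)
  keep_oracle <- logical(200)
  for (s in 1:200) {
    x <- hm2$alleles[, s]
    p <- mean(x, na.rm = TRUE)
    ok <- !is.nan(p) && min(p, 1 - p) >= 0.1
    for (pp in c("A", "B")) {
      rows <- hap_rows(hm2, map2$sample_id[map2$population == pp])
      n_ind <- 0
      for (i in seq(1, length(rows), by = 2))
        n_ind <- n_ind + (!is.na(hm2$alleles[rows[i], s]) &&
                            !is.na(hm2$alleles[rows[i + 1], s]))
      ok <- ok && n_ind >= 8
    }
    keep_oracle[s] <- ok
  }
  expect_identical(filt2$positions, hm2$positions[keep_oracle])

  # idempotence
  filt3 <- filter_sites(filt2, map2, maf_min = 0.1, min_individuals = 8)
  expect_identical(filt3$alleles, filt2$alleles)

  expect_error(filter_sites(hm, map, maf_min = 0.51), "all sites removed")
})

test_that("windows tile scaffolds half-open and partition the sites", {
  hm <- toy_hm(matrix(0L, 2, 3), positions = c(2500L, 5000L, 7399L),
               lengths = c(scf1 = 7400L))
  w <- make_windows(hm, width = 2500)
  expect_equal(w$start, c(0L, 2500L, 5000L))
  expect_equal(w$end, c(2500L, 5000L, 7400L))
  # site at 1-based position 2500 (0-based 2499) is in the first window
  expect_equal(assign_windows(hm, w), c(1L, 2L, 3L))

  hm2 <- rand_hm(4, 300, seed = 7)
  w2 <- make_windows(hm2, width = 37)
  idx <- assign_windows(hm2, w2)
  expect_false(anyNA(idx))
  for (s in seq_len(300)) {
    hits <- which(w2$scaffold == hm2$scaffold[s] &
                    w2$start <= hm2$positions[s] - 1L &
                    w2$end > hm2$positions[s] - 1L)
    expect_length(hits, 1L)
    expect_equal(idx[s], w2$window[hits])
  }

  expect_error(make_windows(hm, width = 0), "width")
})

test_that("region BED output clamps scores to 0-1000", {
  reg <- data.frame(scaffold = "s", start = 0L, end = 100L,
                    statistic = "x", focal = "A", peak = 3.7, n_windows = 2L)
  f <- tempfile(fileext = ".bed")
  write_bed_regions(reg, f)
  bed <- utils::read.table(f, sep = "\t")
  expect_equal(bed$V5, 1000)
  expect_equal(bed$V4, "x:A")
})
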