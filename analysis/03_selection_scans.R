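#!/usr/bin/env Rscript
# Frequency-based selection scans on a genome with an injected hard sweep in
# the residents: windowed Hudson FST, generalized PBS, the linked-selection
# corrected delta-PBS, top-1% region calls, the island-replacement check and
# the within-population nSL scan.

suppressPackageStartupMessages(library(migrascan))
dir.create("results", showWarnings = FALSE)

b0 <- simulate_demography(
  demography_params(include_outgroup = FALSE, n_scaffolds = 1,
                    scaffold_bp = 1e6, n_per_pop = 10), seed = 20261001)
b <- inject_sweep(b0, "resident", "hard", f = 0.9, width = 50000,
                  seed = 20261002)
sw <- b$truth$sweep
cat(sprintf("injected hard sweep: %s:%d-%d (f = %.1f) in %s\n",
            sw$scaffold, sw$start, sw$end, sw$f, sw$population))

hm <- filter_sites(b$hm, b$popmap)
w <- make_windows(hm)
pops <- c("resident", "mig_NW", "mig_SW", "mig_SE")

pm <- pbs_all(hm, b$popmap, pops, w)
delta <- sapply(pops, function(p) delta_pbs(pm, p))
scan <- cbind(w, pbs = pm, dpbs = delta)
write.table(scan, "results/pbs_windows.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

reg <- call_regions(w, delta[, "resident"], statistic = "delta_pbs",
                    focal = "resident")
write_bed_regions(reg, "results/dpbs_regions.bed")
hit <- any(reg$scaffold == sw$scaffold & reg$start < sw$end & reg$end > sw$start)
cat(sprintf("resident delta-PBS top-1%% regions: %d; sweep recovered: %s\n",
            nrow(reg), hit))

# island replacement: a shared swept haplotype should be re-captured
bi <- inject_sweep(b, "island", "hard", f = 0.8, width = 50000,
                   scaffold = sw$scaffold,
                   center = (sw$start + sw$end) / 2, seed = 20261003)
isl <- island_replacement_pbs(filter_sites(bi$hm, bi$popmap), bi$popmap, w,
                              "island", c("mig_NW", "mig_SW", "mig_SE"), reg)
cat(sprintf("island replacement re-captures %d/%d resident regions\n",
            sum(isl$recaptured), nrow(reg)))

# nSL within the focal population
anc <- align_ancestral(ancestral_from_truth(b), hm)
ns <- standardize_nsl(nsl_scores(hm, anc, b$popmap, "resident"))
wn <- window_summarize_nsl(ns, w)
write.table(cbind(w, nsl = wn), "results/nsl_windows.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
rn <- call_regions(w, wn, statistic = "nsl", focal = "resident")
hit_n <- nrow(rn) > 0 &&
  any(rn$scaffold == sw$scaffold & rn$start < sw$end & rn$end > sw$start)
cat(sprintf("resident nSL top-1%% regions: %d; sweep recovered: %s\n",
            nrow(rn), hit_n))

asn <- assign_selected_population(hm, b$popmap, pops, reg[which.max(reg$peak), ])
cat(sprintf("branch-length attribution of the top region: %s\n",
            paste(asn$population, collapse = ", ")))
saveRDS(list(bundle = b, hm = hm, windows = w, regions = reg),
        "scratch/scan_state.rds")
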