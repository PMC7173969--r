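#!/usr/bin/env Rscript
# Demographic timing from recorded genealogies: relative cross-coalescence
# rate between migrants and residents, the implied population-separation
# time (rCCR 0.5-crossing) and the onset of the recent rise (the admixture
# pulse), in generations and years.

suppressPackageStartupMessages(library(migrascan))
dir.create("results", showWarnings = FALSE)

rows <- list()
curves <- list()
for (i in 1:10) {
  b <- simulate_demography(demography_params(), mutations = FALSE,
                           seed = 20260000 + i)
  cc <- relative_ccr(b, "resident", "mig_SW")
  st <- estimate_split_time(cc)
  on <- estimate_admixture_onset(cc)
  rows[[i]] <- data.frame(seed = 20260000 + i,
                          split_gen = st$generations, split_years = st$years,
                          onset_gen = on$generations, onset_years = on$years)
  curves[[i]] <- cbind(seed = 20260000 + i, as.data.frame(cc))
}
tab <- do.call(rbind, rows)
write.table(tab, "results/demography_timing.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(do.call(rbind, curves), "results/rccr_curves.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("population separation: %.0f years (mean of %d runs; truth 30,000)\n",
            mean(tab$split_years), nrow(tab)))
cat(sprintf("rCCR rise onset:       %.0f years (truth 5,000)\n",
            mean(tab$onset_years)))
cat("wrote results/demography_timing.tsv, results/rccr_curves.tsv\n")
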