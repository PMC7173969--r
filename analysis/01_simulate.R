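#!/usr/bin/env Rscript
# Simulate the study system: a blackcap-like demography with continental
# residents, three migrant orientations, a bottlenecked island population and
# two deep outgroup species. Exports the phased VCF, the population map, the
# true ancestral table and the coalescence records used downstream.

suppressPackageStartupMessages(library(migrascan))

dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

params <- demography_params(n_scaffolds = 1, scaffold_bp = 3e5)
bundle <- simulate_demography(params, seed = 20260921)
write_bundle(bundle, "results/data")
saveRDS(bundle, "scratch/bundle.rds")  # scratch cache for the later drivers

cat(sprintf("simulated %d haplotypes x %d sites over %d scaffolds\n",
            n_haplotypes(bundle$hm), n_sites(bundle$hm), params$n_scaffolds))
cat("wrote results/data/{simulated.vcf,population_map.tsv,ancestral.tsv,truth.json}\n")
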