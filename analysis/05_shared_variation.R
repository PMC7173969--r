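#!/usr/bin/env Rscript
# Shared-variation diagnostics on a standing-variation (soft) sweep:
# haplotype distances to the reconstructed ancestral sequence, the region
# SFS against a random-region null (mid-frequency excess), and IUPAC motif
# scanning of the swept sequence neighbourhood.

suppressPackageStartupMessages(library(migrascan))
dir.create("results", showWarnings = FALSE)

b0 <- simulate_demography(
  demography_params(include_outgroup = FALSE, n_scaffolds = 1,
                    scaffold_bp = 1e6, block_bp = 2500), seed = 20263001)
b <- inject_sweep(b0, "resident", "standing", f = 0.6, width = 50000,
                  seed = 20263002)
sw <- b$truth$sweep
anc <- ancestral_from_truth(b)
region <- list(scaffold = sw$scaffold, start = sw$start, end = sw$end)

# distance from one haplotype per carrier background to the ancestral state:
# standing variation predicts similar ages (distances) across backgrounds
rows <- population_rows(b$hm, b$popmap, pops = "resident")[[1]]
tgt <- which(b$hm$positions == sw$target_pos)
carriers <- rows[b$hm$alleles[rows, tgt] == 1L]
noncar <- setdiff(rows, carriers)
reps <- c(carrier = carriers[1], carrier2 = carriers[length(carriers)],
          noncarrier = noncar[1])
dist_tab <- do.call(rbind, lapply(names(reps), function(nm) {
  d <- haplotype_ancestral_distance(b$hm, anc, reps[[nm]], region)
  data.frame(haplotype = nm, row = reps[[nm]], distance = d$distance,
             n_polarized = d$n_polarized)
}))
write.table(dist_tab, "results/ancestral_distances.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(dist_tab, row.names = FALSE)

# region SFS vs 1000 random same-length regions
rs <- region_sfs_comparison(b$hm, anc, b$popmap, "resident", region,
                            n_random = 1000, seed = 20263003)
cat(sprintf("mid-frequency mass: %.3f (null mean %.3f, 95th pct %.3f), p = %.4f\n",
            rs$focal_stat, mean(rs$null_stats),
            quantile(rs$null_stats, 0.95), rs$p))
write.table(data.frame(stat = c("focal", rep("null", length(rs$null_stats))),
                       mid_mass = c(rs$focal_stat, rs$null_stats)),
            "results/region_sfs_null.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# bHLH motif scan of a synthetic sequence built from REF/ALT over the region:
# take the majority resident haplotype, spell its bases, scan GHCACGTG
iv <- which(b$hm$scaffold == sw$scaffold &
              b$hm$positions - 1L >= sw$start & b$hm$positions - 1L < sw$end)
hap <- b$hm$alleles[carriers[1], iv]
seq_bases <- ifelse(hap == 1L, b$hm$alt[iv], b$hm$ref[iv])
seqstr <- paste(seq_bases, collapse = "")
hits <- scan_iupac_motif(seqstr, "GHCACGTG")
cat(sprintf("bHLH motif (GHCACGTG) hits in the concatenated SNP sequence: %d\n",
            nrow(hits)))
write.table(hits, "results/motif_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
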