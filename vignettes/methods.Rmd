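---
title: "Models and methods behind migrascan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind migrascan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`migrascan` is a scan battery for panels of weakly differentiated
populations that differ in a focal trait — here, migratory behaviour. This
vignette explains the models, the tunable parameters and their defaults, the
numerical choices, what the synthetic-data generator does and does not
emulate, and the design decisions that were genuinely open.

## Data model and filters

All statistics run on a `haplotype_matrix`: phased 0/1 alleles (rows are
haplotypes, in `_a`/`_b` pairs per diploid), one column per biallelic SNP,
scaffold-major with strictly increasing positions. VCF positions are 1-based;
windows and BED output are 0-based half-open, so a site at 1-based position p
belongs to the window containing p − 1. Missing alleles are carried through,
never imputed; each statistic defines its own missing-data rule.

The default site filters mirror standard scan practice for panels of this
kind: pooled-ingroup minor-allele frequency ≥ 0.05 and at least 5 fully
called diploids in every population. The MAF pool excludes outgroup samples
because filtering precedes polarization. Sex scaffolds are excluded by
listing their names, never inferred.

## Windowed F_ST, PBS and ΔPBS

Window F_ST uses the Hudson/Bhatia estimator as a ratio of sums over the
2,500-bp window: per site, num = (p₁−p₂)² − p₁(1−p₁)/(n₁−1) − p₂(1−p₂)/(n₂−1)
and den = p₁(1−p₂) + p₂(1−p₁). Ratio-of-sums is robust to low-information
sites; windows with zero denominator are missing. The estimator operates on
observed haplotype frequencies: the simulator produces exact genotypes, so a
genotype-likelihood route would add machinery without adding anything
testable. Negative window estimates are clamped to zero before the branch
transform T = −ln(1 − F_ST) (T is undefined below zero; clamping is
conservative), and F_ST is capped at 1 − 10⁻⁶ to keep T finite.

PBS generalizes the three-population branch statistic. The default
`as_printed` mode reproduces the four-population expression with the omitted
cross-terms keyed to the order of the non-focal list (consecutive pairs);
`mean_triplet` averages the classic triplet form over all non-focal pairs.
Both coincide for two non-focal populations, which is the identity the test
suite checks. Whether the omitted cross-term in the four-population form is
deliberate weighting cannot be settled from the source material, hence both
modes.

ΔPBS subtracts, per window, the maximum non-focal PBS from the focal PBS:
processes that elevate differentiation in every population — linked
selection in low-recombination regions above all — cancel, so only
focal-specific differentiation survives. PBS scaling defaults to `none`
with a robust z-score option ((x − median)/MAD), since no published scaling
reproduces the printed ΔPBS magnitudes; those magnitudes are therefore not
recovery targets here. Regions are merged runs of windows strictly above the
empirical top-1% threshold; each region reports its peak window.

## FLK and hapFLK

The kinship (co-drift) matrix F comes from a neighbour-joining tree of
Reynolds distances between populations, rooted on the outgroup when one is
present and at the midpoint otherwise: F_ii is the root-to-tip path of
population i and F_ij the root-to-MRCA path, a tree covariance that is
positive semi-definite by construction. Negative NJ branch lengths are
truncated to zero with a warning. When the outgroup is removed after
rooting, the stem down to the ingroup ancestor is retained as shared drift.

FLK tests each SNP's population frequency vector p against the drift null:
p̂₀ = (1ᵀF⁻¹p)/(1ᵀF⁻¹1) and FLK = (p − p̂₀1)ᵀ[p̂₀(1−p̂₀)F]⁻¹(p − p̂₀1),
referred to χ² with (#populations − 1) df. Sites whose p̂₀ reaches 0 or 1 are
skipped.

hapFLK replaces SNP frequencies with local haplotype-cluster frequencies
from a haplotype-mosaic hidden Markov model: each haplotype is a mosaic of K
clusters; cluster k emits allele 1 at site s with probability θ_ks; between
sites the chain stays put with probability 1 − r_s or jumps to a cluster
drawn from weights α, with r_s = 1 − exp(−ρ d_s) for inter-site distance d_s
(r = 1 across scaffold breaks, restarting each scaffold). EM updates θ, α
and ρ (ρ by a one-dimensional exact maximization, so the observed-data
log-likelihood is monotone); θ is clamped to [10⁻⁶, 1 − 10⁻⁶] to keep the
scaled forward–backward recursions away from exact zeros. Defaults: 20
independent EM fits retained (the statistic averages over fits because the
likelihood surface is multimodal), convergence Δlog-lik < 10⁻⁴, at most 200
iterations; all configurable, and the examples in this package use smaller
values where the scale warrants it. K is chosen by masked-allele imputation
cross-validation, ties toward smaller K.

At each site the K × n_pops frequency matrix P is tested with the same
quadratic form under the multinomial covariance across clusters:
hapFLK = tr(A⁺ D F⁻¹ Dᵀ) with D = P − p̂₀1ᵀ and A = diag(p̂₀) − p̂₀p̂₀ᵀ
(rank K − 1, pseudo-inverted). This reduces exactly to FLK when a single
cluster pair segregates like a biallelic SNP — a reduction the tests assert —
and degenerate clusters contribute nothing.

Raw hapFLK values are normalized by robust regression (`MASS::rlm`, Huber
loss) of the sorted genome-wide values on chi-square quantiles, with the
degrees of freedom chosen to minimize the robust residual scale; normalized
values are referred to the fitted χ². The df is estimated rather than fixed
because the effective df depends on K. The robust fit is what keeps true
selection outliers from dragging their own null.

The genome-wide threshold shuffles population labels across individuals
(sizes preserved) 100 times, recomputes hapFLK and normalized p-values per
shuffle, records each shuffle's minimum p, and takes the 5th percentile.
Whether labels should be shuffled per individual or per block is not settled
by the source material; per-individual is used. The cluster model is
label-free, so the EM fit and the kinship matrix are held fixed across
shuffles; only population cluster frequencies are recomputed, which is what
makes 100 shuffles tractable and matches upstream practice. The per-scan
robust renormalization is also what makes the threshold transferable between
the permuted and observed scans.

Selected populations are attributed by rebuilding the NJ tree from
region-restricted Reynolds distances and taking the population with the
largest positive terminal-branch excess over the genome-wide tree; ties
within 5% are reported together, and regions under 10 SNPs are flagged
low-confidence.

## nSL

For a focal site, a haplotype pair's shared length is the number of
segregating sites spanned by the maximal interval containing the site over
which the pair is identical, counted inclusively — the inclusive count is
pinned by the brute-force oracle in the tests so equivalence is exact.
Missing alleles truncate the interval like mismatches; unpolarized sites are
dropped before scanning. nSL = ln(SL_A/SL_D) contrasts ancestral- and
derived-allele carriers; long derived haplotypes push it negative. Sites
need at least two haplotypes in each allele class. Scores are standardized
within derived-frequency bins (width 0.02; bins under 50 sites merge with
neighbours) because raw nSL varies with frequency, and summarized per window
as max |z| — the reduction is not fixed by the source material, and max
preserves localized signals (mean is available). The per-pair segment
arithmetic is O(pairs × mismatches) via piecewise-constant runs, which is
what makes the scan linear in practice.

## Fine-mapping

Inside an outlier region, SNPs with p < 10⁻⁴ are candidates. Each SNP's
centred frequency vector is whitened by [p̂₀(1−p̂₀)F]^(−1/2) — decomposing
differentiation onto orthogonal drift components — and the candidate-SNP
correlation matrix Σ of these whitened vectors replaces GWAS LD in the
CAVIAR model: under configuration C, z ~ N(0, Σ + σ²Σ_C Σ) with σ² = 5.2,
prior γ^{|C|}(1−γ)^{m−|C|} (γ = 0.01), all configurations of size ≤ 2
enumerated. Signed z-scores take the sign of the leading whitened contrast
(the exact decomposition used by the source adaptation is not described;
this is one faithful reading, and it squares to the per-SNP FLK quadratic
form). The ρ = 0.95 causal set is the smallest SNP set covering ≥ 95% of
the posterior mass conditional on at least one causal SNP; conditioning
avoids the degenerate case where the null configuration alone dominates. A
rank-deficient kinship matrix is ridge-regularized with the λ recorded, and
a numerically singular Σ (perfectly correlated candidates) is nudged by
10⁻⁸ on the diagonal inside the likelihood only.

## Polarization and shared-variation diagnostics

A site's ancestral allele is the allele for which both outgroup species are
homozygous (all non-missing alleles identical within a species), provided it
matches REF or ALT; otherwise the site is excluded with a reason —
outgroup_missing, outgroup_heterozygous, or triallelic, in that precedence.
Two homozygous outgroups that disagree are treated as triallelic exclusions,
the conservative reading of the exclusion rule. The unfolded SFS counts
derived classes 1..2N−1 over polarized segregating sites; incompletely
called sites are dropped by default or hypergeometrically projected to a
fixed sample size.

Haplotype-to-ancestral distance counts derived alleles in a region — on
polarized SNP data this equals the mismatch count to the reconstructed
ancestral sequence, and it is additive over disjoint regions. The
region-SFS diagnostic compares a focal region's mid-frequency mass (fraction
of polarized segregating sites with derived count in [0.25·2N, 0.75·2N] —
the operationalization of the visual mid-frequency-excess argument) with
random same-length regions; the empirical p is (#null ≥ focal + 1)/(n + 1).
Motif scanning is exact IUPAC matching on both strands via Biostrings.

## The synthetic-data generator

The generator is a structured coalescent over resize, pulse and merge
events, simulated independently per block. Defaults encode the study
conditions: continental residents (Ne 250,000, constant), three migrant
populations (Ne 500,000 recent of the pulse, 250,000 before), an island
population founded from residents 3,000 generations ago at Ne 10,000, a
common split 15,000 generations ago, an admixture pulse of 0.2 from migrants
into residents 2,500 generations ago, μ = 3×10⁻⁹ per site per generation,
generation time 2 years, and two outgroup species at per-site divergence
0.026. With these values the rCCR 0.5-crossing dates the separation at
~30,000 years and the rise-onset at ~5,000 years, the two epochs the scans
are calibrated against. The migrant size increase is a step at the pulse
time rather than a continuous growth curve, and the island founding time is
a choice (no value is printed for it); both are configuration, not claims.

Two modelling simplifications matter for interpretation. First,
recombination is approximated by independent 10-kb blocks, one genealogy
each: within-block linkage is complete and between-block linkage absent, so
LD decay, recombination-rate variation and genealogy turnover at sub-block
scale are not emulated. Passing tests therefore demonstrate detector
correctness and calibration under this linkage structure, not performance on
real LD landscapes. The region-SFS null comparison uses 2.5-kb blocks, since
a random-region null presumes genealogy turnover along the sequence — with
10-kb blocks a 50-kb region holds only five genealogies and block noise
dominates the null. Second, sweeps are haplotype-block transplants, not
forward-time selection: a hard sweep copies one carrier's block onto the
focal population until the target frequency f is reached (all carriers end
on one background; f = 1 is disallowed so a residual background always
remains), and a standing sweep raises an allele already segregating in ≥ 2
populations by expanding a small number of carrier backgrounds (default 2,
the canonical soft-sweep picture) — expanding every background
proportionally dilutes each below the mid-frequency band and produces no
sweep signature at all. A standing target must sit at least 0.2 below f;
otherwise there is nothing to sweep and the call is a no-op. Transplants
touch no site outside the stated interval, so the genealogical record stays
valid genome-wide except inside injected regions.

The outgroup split time is derived from the target divergence rather than
taken as d/(2μ): measured divergence includes the ancestral coalescent
(adding 2·Ne_anc generations of branch) and excludes outgroup-side
polymorphism below the outgroup sample's MRCA when a consensus is used
(removing 2·Ne_out(1 − 1/n_h)), so
t_out = d/(2μ) − 2·Ne_anc + 2·Ne_out(1 − 1/n_h). At the defaults the naive
formula overshoots the realized divergence by ~11%, outside the 10% the
recovery check allows; the corrected form lands within 1%.

Relative cross-coalescence rates are computed from the recorded pairwise
coalescence times, not from sequence: per time bin, rate = coalescences /
pair-time at risk, rCCR = between-rate / mean within-rate, reported only for
bins with enough pairs at risk (default 20). The separation time is the most
ancient upward 0.5-crossing, linearly interpolated between bin midpoints
(exact for a step at a shared edge of equal-width bins); the admixture onset
is the most recent bin exceeding the post-split minimum by 0.1 — the
rise-onset rule is this package's operationalization, since no formal onset
estimator exists in the source material.

## Problem sizes and calibration experiments

The test suite runs everything at desk scale, chosen so each check has the
power it needs and no more: rCCR recovery uses the default 10 × 1 Mb genome
with 5 diploids per population over several seeds; divergence recovery uses
5 Mb; FLK type-I error uses 5,000 sites drawn from the Gaussian drift model
with drift scaled so boundary truncation is negligible (truncation violates
the simulated null, not FLK); the permutation threshold is calibrated at 20
shuffles against 50 fresh neutral genomes of ~1,000 SNPs with a 3-cluster
model; and the sweep power study uses 20 replicates of a 1-Mb genome with 10
diploids per population — 5 diploids leave nSL undefined inside a 90% sweep,
since both allele classes need two haplotypes. The permutation-calibration
genomes use a shallow star demography where labels are nearly exchangeable;
under strong drift the label-shuffled null is not exchangeable with the
observed data, and the per-scan robust normalization is what absorbs most of
that mismatch.

## Known limitations

No genotype likelihoods or unphased-data support (inputs are phased by
assumption); no ancestral-recombination-graph linkage; no forward-time
selection dynamics; FLK/hapFLK assume the Gaussian drift approximation,
which degrades for very drifted or very small populations (the island
population is excluded from the scans, as in the study design); enumeration
fine-mapping is capped (default 50 SNPs, configurations of size ≤ 2); the
printed ΔPBS magnitudes of the source tables are not reproducible because
their scaling is unspecified.
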