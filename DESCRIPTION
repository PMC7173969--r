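Package: migrascan
Title: Selection Scans and Demographic Timing for Migratory-Divide Resequencing Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed Hudson FST, generalized population branch statistics (PBS)
    and the linked-selection-corrected delta-PBS, FLK and haplotype-cluster
    hapFLK with a permutation genome-wide threshold, the nSL haplotype-length
    statistic, CAVIAR-style fine-mapping from an FLK signal-correlation matrix,
    outgroup-based ancestral polarization and unfolded site-frequency spectra,
    shared-variation diagnostics, and a structured-coalescent generator of a
    songbird-like demography (population splits, an admixture pulse, island
    bottlenecks, deep outgroups and injectable selective sweeps) with relative
    cross-coalescence-rate estimation from the recorded genealogies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    BiocGenerics,
    Biostrings,
    jsonlite,
    MASS,
    phangorn,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
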