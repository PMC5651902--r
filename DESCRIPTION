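Package: epimeth
Title: Exhaustive Two-Locus Epistasis Scanning for CpG Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, quality control, and association machinery for
    exhaustive two-locus (SNP-SNP) epistasis scans on CpG methylation in
    paired discovery/replication cohorts. Implements the fast 8-df joint and
    4-df approximate interaction tests with exact factorial-ANOVA
    recalculation, adaptive per-CpG Bonferroni replication with permutation
    empirical p-values and a 9-cell sign test, LD-aware stepwise-forward
    per-CpG modeling with variance decomposition, a proximal
    main-effect-first search, and annotation/expression enrichment tests.
    Includes a synthetic-cohort generator with blockwise-LD genotypes and
    planted main, epistatic, LD-triad and probe-artifact effects so the full
    pipeline is testable without any external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    IRanges
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
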