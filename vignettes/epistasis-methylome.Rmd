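---
title: "Exhaustive two-locus epistasis scanning on CpG methylation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exhaustive two-locus epistasis scanning on CpG methylation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epimeth)
```

## The problem

Statistical epistasis is a higher-order dependency in which the effect of
the genotype at one locus depends on the genotype at another. CpG
methylation is an attractive trait for studying it: it is under close
genetic control, measured at hundreds of thousands of sites, and available
in paired cohorts, so a detected interaction can be required to replicate.
`epimeth` implements the complete analysis chain for such a study on a pair
of discovery/replication cohorts: SNP quality control and LD pruning, beta
to adjusted-M preprocessing, an exhaustive approximate-then-exact two-locus
interaction scan, a triple replication filter, per-CpG joint modeling with
LD-aware classification and variance decomposition, a cheaper proximal
main-effect-first search, and annotation/expression enrichment. Because no
individual-level cohort of this kind is freely distributable, the package
also contains a first-class synthetic-cohort generator with a registry of
planted effects, so every stage is testable against known truth.

## The statistical core

For one CpG signal $y$ (adjusted M-values) and two SNPs with genotypes
$a, b \in \{0, 1, 2\}$, the samples fall into a $3 \times 3$ table of
genotype cells with counts $n_{ij}$ and means $m_{ij}$. Three nested
models are involved:

* the **8-df joint test** compares the 9 cell means against the grand
  mean: $F_8 = \frac{\sum_{ij} n_{ij}(m_{ij} - \mu)^2 / 8}{MSE}$ with
  $MSE = SS_\text{within} / (n - 9)$;
* the **4-df approximate interaction test** subtracts the additive and
  dominance (count-weighted marginal-mean) predictions
  $p_{ij} = r_i + c_j - \mu$ from the cell means:
  $F_4 = \frac{\sum_{ij} n_{ij}(m_{ij} - p_{ij})^2 / 4}{MSE}$;
* the **exact interaction ANOVA** compares the additive model (two 3-level
  factors, 2 df each) with the saturated cell-mean model:
  $F = \frac{(RSS_\text{add} - RSS_\text{sat}) / 4}{RSS_\text{sat} / (n-9)}$,
  with the p-value from the upper tail of $F(4, n-9)$ computed on the log
  scale so thresholds near $10^{-18}$ remain meaningful; values below the
  smallest representable double are reported as that minimum with a flag.

$F_4$ is cheap and exact under orthogonality (independent SNPs, balanced
cells) but overshoots the exact statistic when the SNPs are correlated or
a large main effect is present — the package's own simulations reproduce
the near-universal overshoot on correlated additive-truth data. The scan
therefore filters on $F_4$ and recalculates every surviving pair exactly
before applying the Bonferroni correction for the full test count
$N_\text{CpGs} \cdot N_\text{SNPs}(N_\text{SNPs}-1)/2$.

### The F filter at different scan sizes

The conventional prefilter $F_4 > 22$ sits close to the Bonferroni
threshold when the test count is of order $10^{15}$. At the desk scales
this package is exercised at (for example 50 CpGs by 300 SNPs), a fixed 22
would be orders of magnitude stricter than the scan's own correction and
would dominate power. `exhaustive_scan(..., f_filter = "auto")` therefore
derives the filter from the scan's own Bonferroni threshold
(`qf(alpha / n_tests, 4, n - 9)` upper tail), which is the same design
rule expressed at any scale; the fixed default remains available.

### Replication: three filters

A hit entering replication must satisfy, in the replication cohort:

1. **Adaptive per-CpG Bonferroni** — the exact interaction p must fall
   below $\alpha / (N_\text{unique CpGs} + N_\text{hits on this CpG})$;
2. **Permutation empirical p** — the CpG signal is permuted across samples
   with genotypes fixed, the exact F recomputed each time, and the
   add-one estimator $(1 + \#\{F_\pi \ge F_\text{obs}\})/(B+1)$ compared
   with the same threshold. Permutation streams are shared across the SNP
   pairs of one CpG (one stream per CpG); a pooled per-CpG null is
   available as an option. An opt-in sequential early stop abandons a pair
   once the Clopper–Pearson lower bound of its empirical p exceeds ten
   times the threshold;
3. **Sign test** — the Pearson correlation of the 9 cell means between
   discovery and replication must exceed 0.85.

A minimal cell size strictly above 3 in both cohorts is required
throughout. Note that the sign test correlates only 9 points, so its
sampling noise is large (Fisher-z standard error about 0.41); it is a
direction-consistency filter, not a precise estimate.

### Per-CpG modeling and the LD-triad artifact

Two SNPs A and B that are each in LD with a third SNP C carrying a strong
main effect can mimic an A×B interaction: the 9 (A,B) cells partially
reconstruct C's three genotype groups. The package reproduces this
mechanism with `make_ld_triad_scenario()`, which plants an LD triad
(r²(C,A) ≈ 0.55, r²(C,B) ≈ 0.25, r²(A,B) ≈ 0.024, built from an explicit
three-locus haplotype distribution) and a main effect of C only. The
remedy is joint modeling: `forward_select()` enters candidate main effects
first (ascending discovery p), then candidate interactions, keeping a term
only when its partial F-test p is below
$\alpha / (N_\text{mains tested} + N_\text{pairs tested})$ in **both**
cohorts. Once C's main effect is in the model, the A×B interaction no
longer explains anything and is rejected.

Design choices in the selection step, where the wording of stepwise
procedures is genuinely open:

* partial tests are sequential — each candidate is tested against the
  model of all previously kept terms, which is what ordered forward entry
  implies;
* an interaction term contributes its 4 interaction contrasts on top of
  the two supporting main factors, which are added to the design silently
  if absent. Testing raw cell contrasts without the supporting mains would
  let an "interaction" absorb main-effect variance, which is exactly the
  artifact this stage exists to remove;
* the replication p of a term refits the identical term structure on
  replication data;
* rank-deficient additions are skipped.

Kept pairs are classified `ld_block` when their discovery dosage
r² exceeds the empirically calibrated LD threshold (strictly), else
`epistatic`; each pair is also labeled by cis/trans status (a SNP is cis
within 500 KB of the CpG). Variance decomposition reports the R² of the
single best main, the mains-only model, and the full model; the
interaction contribution is the difference of the last two and, because
supporting mains ride along with an interaction term, can include a small
main-effect share when a kept pair's mains were not kept on their own —
with orthogonalized planted effects this share is negligible.

### LD threshold calibration

`empirical_ld_threshold()` draws random cross-chromosome SNP pairs and
takes the 0.999 quantile of their dosage r². Under independence
$n \cdot r^2 \sim \chi^2_1$, so at $n = 533$ the expected threshold is
about $10.83 / 533 \approx 0.020$; the package's simulations land in
0.017–0.025. LD is computed throughout as squared Pearson correlation of
dosages (composite LD): the data are unphased and every consumer of the
threshold uses the same statistic, so haplotype-level r² is unnecessary.

## The synthetic cohorts

`sim_config()` fixes the study conditions: 533 discovery and 319
replication subjects, blockwise-LD genotypes (thresholded latent Gaussians
with AR(1) correlation 0.8 inside blocks of 2–10 SNPs; MAF uniform on
[0.05, 0.5]; 0.2% genotypes missing completely at random), and CpG signals
built on the M-scale as planted genetic terms + plate/batch offsets + sex
and age effects + Gaussian noise (sd 1), then mapped to beta-values
(clipped to $[10^{-6}, 1 - 10^{-6}]$ to keep the M-transform finite).
Both cohorts share maps, MAFs and effect coefficients; subject-level draws
are independent.

Planted epistatic patterns are 3×3 deviation matrices orthogonalized
against the frequency-weighted row/column margins, so they carry no main
effect by construction — the quantity the 4-df test targets. The default
pattern concentrates the deviation on the double rare-homozygote cell, the
canonical two-locus architecture in which a shift appears only when both
loci carry two minor alleles. Effect coefficients are rescaled so the
realized variance fraction tracks the target (calibration slope within
[0.8, 1.2] over 50 planted effects in the test suite); the realized values
are measured in the generated discovery cohort and recorded in the truth
registry.

What the generator does **not** emulate: recombination maps and
coalescent genealogies (LD is pairwise-realistic, not haplotype-realistic),
array chemistry (no idat-level artifacts beyond the 50-mer dosage
mechanism), cell-type composition (the PCA step stands in for it), and
phasing. Passing tests therefore demonstrate the statistical machinery
under a faithful genetic-architecture model, not robustness to every
technical artifact of real arrays.

## Preprocessing

The chain is: (1) M-transform $\log_2(\beta/(1-\beta))$; (2) z-scoring of
every CpG within every plate; (3) removal of the top principal-component
axes computed on complete-case CpGs (defaults 8 discovery / 7 replication;
at desk-scale fixture sizes 1–2 axes are appropriate, since with only tens
of CpGs additional axes begin to absorb the genetic signal itself);
(4) regression on sex and age — done jointly with the retained PC axes so
the chain is idempotent; (5) per-CpG residualization on 50-mer
probe-sequence variant dosages when they explain strictly more than 0.1%
of variance (dosage columns below MAF 0.03% dropped first). Missing
methylation entries are mean-imputed within CpG for the regression steps
and re-masked afterwards. CpGs with ≥1% missingness in either cohort, or
on the exclusion list, are dropped.

## Numerical and policy choices

* Exact Hardy–Weinberg test by full enumeration of heterozygote counts
  (log-factorial arithmetic, two-sided by summing configurations no more
  probable than the observed one) — robust at MAF 2% with genotype groups
  near 15, where the chi-squared approximation degrades.
* LD pruning uses a 50-SNP window shifted by 5 SNPs at r² 0.95 — the
  standard GWAS-toolkit parameterization; ties are broken by removing the
  later-positioned SNP, which keeps the result deterministic and
  enumeration-order-free. Pruning is decided on discovery data only.
* Per-SNP QC (MAF > 2%, exact HWE p > 0.001, missingness < 1%) must hold
  in both cohorts separately; the smallest-genotype-group ≥ 15 criterion
  applies to the scan set only.
* Boundary rules are strict where a published rule is strict: minimal
  cell size must exceed 3; probe correction triggers strictly above 0.1%
  variance; a pair exactly at the LD threshold is classified epistatic.
* All permutation and simulation seeds are explicit arguments; identical
  seeds give identical results bit for bit.

## Problem sizes used by the checks

The packaged checks exercise the chain at sizes a single core handles
comfortably while preserving the published cohort sizes (533/319):
null-calibration runs use 50 CpGs × 300 scan SNPs; parameter-recovery
runs use 10 CpGs × 80 SNPs with one planted pair at target r² 0.15 and
permutation depth B ≈ 500; the LD-triad scenario is replicated a few
hundred times. The published methylome-scale counts (for example the
404 interacting CpGs) depend on the unavailable raw cohorts and are not
recomputable; the pipeline's arithmetic on their printed inputs, and its
statistical behaviour under known synthetic truth, are.

## Known limitations

* The sign test's 9-point correlation is intrinsically noisy; near the
  0.85 bar its verdicts on borderline effects are close to coin flips,
  which any user of this filter should keep in mind.
* The forward-selection threshold counts all candidates offered, not all
  models visited; with very large candidate sets this is conservative.
* The scan is vectorized dense linear algebra over all pairs — adequate
  to a few thousand SNPs per chromosome on one core, far from the
  GPU-scale engines used for full methylome scans, and intentionally so.
* Expression coupling in the generator is linear and cis-only; trans
  networks are out of scope.
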