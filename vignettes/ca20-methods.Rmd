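---
title: "Scoring centrosome amplification from expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring centrosome amplification from expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca20)
```

# The score and its pipeline

Centrosome amplification (CA) — more than two centrosomes per cell — is hard
to measure directly in tissue, so this package works with a transcriptomic
surrogate: the CA20 metagene, a set of 20 genes (*TUBG1*, which encodes the
most abundant centrosomal protein, plus 19 genes whose overexpression
induces CA). The per-sample score is

$$\mathrm{CA20}_s \;=\; \sum_{g \in \mathrm{CA20}} \tilde{x}_{gs},$$

where $\tilde{x}_{gs}$ is the median-centred, normalized log2 expression of
gene $g$ in sample $s$. For RNA-seq counts the normalization is voom-style:
$\log_2\!\big((c_{gs}+0.5)/(L_s+1)\times 10^6\big)$ with $L_s$ the library
size, followed by quantile normalization of samples to the mean empirical
distribution (`normalize_counts()`, backed by `limma::normalizeQuantiles`
with tie averaging). Median centering subtracts every gene's across-sample
median, computed over **all loaded samples, tumours and matched normals
together** (`median_center()`). Already-normalized platforms (microarray
intensities) skip the count step and enter at the centering stage: this is
how `read_expression_table()`'s `log_quantile` state is treated by
`score_cohort()`.

Three consequences matter for interpretation:

* a score of 0 means "dataset-typical expression of every signature gene";
  per-gene additive offsets cancel, so the score is invariant to gene-wise
  calibration shifts applied before centering;
* centering is **per analysis dataset** — scores computed in separately
  centred datasets are on different scales and must not be compared.
  Per-cohort centering is available (`median_center(by =)`) but global
  centering over the loaded matrix is the default;
* signature genes missing from the data are skipped with a warning and the
  coverage is recorded on the score (`n_genes_used`), rather than failing —
  secondary scores routinely lose a few genes to platform coverage. The
  same machinery scores any signature; a hypoxia-style metagene is built
  with `build_signature()`, which drops unmeasured candidates and genes
  shared with an exclusion set (keeping, for example, a 99-gene candidate
  list at 95 after removing 3 unmeasured genes and one CA20 member, so the
  two scores share no gene).

# Association scans

All scans share one regression engine (`fit_linear_model()`, ordinary least
squares) and one multiple-testing rule: Benjamini–Hochberg, applied **per
scan over exactly the features that scan retained** (`bh_adjust()`; the FDR
procedure is an assumption — the analyses this package reproduces state only
"FDR"). Genomic-instability covariates (aneuploidy score, mutations per Mb,
CNA count, clones per tumour) enter as z-scores computed on the analysis
subset, so coefficients are comparable across cohorts with very different
alteration prevalences; cohort is included as a categorical covariate in
every pan-cancer scan to prevent between-cohort confounding. Scan runners
check covariate collinearity and warn when any variance inflation factor
reaches 2 (`variance_inflation()`).

Specific conventions:

* **Mutation scans** (`feature_scan()`) test only genes with at least
  `min_positive` mutated samples — 20 for genome-wide somatic scans, 10 for
  driver-mutation scans.
* **Arm scans** (`arm_scan()`) code each arm as two indicators (deletion
  vs none, amplification vs none) because deletions and amplifications of
  the same arm can associate in opposite directions; the reported record
  keeps the indicator with the smaller p-value and labels the direction
  `deletion-high` when deleted samples carry the higher scores. Arm calls
  come from `call_arm_alterations()`: strictly below −1 is a loss, strictly
  above +1 a gain, boundary values are no alteration.
* **Matched-normal anticipation** (`matched_normal_arm_test()`) compares
  normal-sample scores by the matched tumour's arm status, using only
  normals that are themselves intact on the tested arm, and refuses
  contaminated input rather than silently dropping it.
* **Spearman correlations** (`spearman_corr()`) use average ranks and the
  t approximation for the p-value at every sample size, for consistency
  across the scans; two dependent correlations sharing a variable are
  compared with the Williams/Steiger t on n − 3 degrees of freedom
  (`dependent_correlation_test()`).
* The amplification-vs-deletion balance per sample is reported as
  −log10 of the equal-proportions p-value, signed positive when
  amplifications dominate.

Cohort-by-feature significance profiles are clustered with Euclidean
distance and complete linkage; rows are sorted by label first so the leaf
order is reproducible under input permutation.

# Preranked enrichment

`enrichment_score()` implements the classical weighted Kolmogorov–Smirnov
running sum (weight 1 by default; hits advance by $|r|^p$ normalized over
hits, misses retreat by $1/(N-N_h)$; ES is the extremum of largest
magnitude, ties in the ranking broken by gene id). Because the input is a
preranked list (signed −log10 p from a scan, or a connectivity score),
phenotype permutation is undefined; p-values come from gene-label
permutation — random same-size sets — with the +1-corrected count on the
observed ES's sign side (`gsea_pvalue()`). Across a collection,
significance is BH over the per-set permutation p-values
(`enrichment_scan()`); this diverges from the pooled normalized-ES FDR of
the original GSEA implementation and is the more transparent choice for
small collections.

# Survival

Patients are split at the score median, ties going to the low arm
(`median_split()`; the split depends only on ranks). Kaplan–Meier curves
and the two-group log-rank test are delegated to the survival package;
`km_estimate()` reports the survival probability at a 5-year horizon and
risk-set counts every 2.5 years. The pan-cohort scan (`survival_scan()`)
drops patients with missing survival first, then keeps cohorts with
strictly more than `min_samples = 40` remaining, then BH-adjusts log-rank
p-values across cohorts. No Cox modelling: stratified log-rank is the whole
survival contract.

# Drug-sensitivity and perturbation integration

Compounds with more than 20% missing AUC values are removed (strict
inequality: exactly 20% is kept; `filter_compounds()`). The sensitivity
scan is pairwise-complete Spearman per compound (at least 4 pairs), BH
across compounds; negative rho means higher activity in high-score lines,
since AUC is inverse to activity. Calibration of the scan is checked by a
permutation Q-Q construction (`permutation_qq()`): each permutation
shuffles every compound's AUC independently across cell lines (preserving
compound marginals), all correlations are recomputed, and the expected
value at rank k is the median of the k-th sorted signed −log10 p over
permutations. The Q-Q *slope* of a single 354-compound panel is a
dispersion ratio with ≈ 0.08 sampling noise, so the package's calibration
check measures the mean slope over five replicate null panels — an
estimator that concentrates at 1 under correct calibration and retains
power against miscalibration.

Connectivity scores (in [−100, 100]; negative = the perturbation
down-regulates the query set) are averaged over the profiled cell lines
(`average_connectivity()`). `integrate_ctrp_cmap()` joins the two screens
through a compound↔perturbation id map and flags **candidates** by a pure
rule: sensitivity q < 0.05 *and* average connectivity score < −90.
`target_proliferation_assoc()` regresses each predicted target gene on
proliferation rate (with cohort), so candidates can be screened for merely
tracking proliferation.

# Microscopy quantification

A cell is amplified when it has strictly more than 4 centrioles;
`ca_fraction()` is the percentage of amplified cells per patient, and
`subtype_summary()` averages **patients, not pooled cells** within a
subtype (each patient contributes equally regardless of how many cells were
scored) with pairwise rank-sum tests. The bundled
`synthetic_centriole_factors()` list is a labelled stand-in: its 93/10
composition (93 genes, 10 in CA20) is meaningful, its synthetic member ids
are not.

# The synthetic cohort generator

`generate_cohort()` exists so that every downstream stage is testable
without controlled-access data. Each sample carries a continuous latent CA
level $z$ (CA treated as a graded property, not a binary flag):

$$z = \text{cohort offset} + \beta_\text{tumour}\,\mathbf 1\{\text{tumour}\}
      + \varepsilon,\qquad \varepsilon \sim N(0, \sigma^2).$$

Counts are negative binomial with gene-wise log-normal dispersion; the 20
CA20 genes' log-means increase with $z$ (loading 0.25 per latent unit), so
the normalization stage operates on realistic count data. Instability
covariates are linear in $z$ plus noise with the planted signs (+ for
aneuploidy, mutation burden, CNA count, clone count and hypoxia, − for
stromal infiltration); coupled arm, mutation, genome-doubling and
mutational-signature probabilities are logit-linear in the **cohort-centred**
latent, so a coupling's sign decides *who* is affected without changing the
marginal rate. Survival is exponential with log-hazard $\gamma z$ and
administrative censoring at 10 years. Matched normals inherit part
(default 0.6) of their tumour's latent residual and are intact on every
simulated arm — this is what lets the matched-normal anticipation test have
signal. The cell-line panel generator (`generate_cellline_panel()`) plants
`AUC = baseline − δ·score + noise` for designated sensitive compounds
(δ > 0 ⇒ high-score lines more sensitive), exact per-compound missingness
counts, and strongly negative connectivity (mean −95) for the
perturbations mapped to those compounds. Centriole counts
(`generate_centriole_counts()`) default to the reference patient series —
29 luminal A, 3 luminal B, 3 HER2 and 13 basal-like patients, 5–107 cells
each, prevalences 0.07/0.27/0.15/0.25; the HER2 prevalence is the one value
not fixed by the reference series and was set once between the luminal
values.

Defaults were frozen after a pre-build calibration: at these settings the
computed CA20 tracks the true latent level with Spearman ≈ 0.91–0.95
(threshold 0.8), planted effects (tumour shift, mutation signs, the
deletion-coupled arm, the sensitive-compound set, worse survival in the
high arm) are recovered in ≥ 90% of replicates, and with all couplings
zeroed every scan's FDR < 0.05 discovery rate stays at or below nominal.

What the generator deliberately does **not** emulate: per-cohort marginal
expression distributions of real tumour atlases, sub-arm copy-number
structure, mutational-signature deconvolution, batch effects, or
non-administrative censoring. Passing tests therefore demonstrate that the
statistical machinery is correct and calibrated under the stated model —
not that any biological claim transfers to a particular real dataset.
Seeds are mandatory arguments for every generator and permutation routine;
given a seed, outputs are bit-reproducible.

# Numerical choices and edge cases

* Quantile-normalization reference = column-wise mean of sorted values;
  ties within a sample receive the mean of their tied reference values.
* Arm-call and compound-filter thresholds are strict inequalities; exact
  boundary values are "no alteration" / "retained".
* Median-split ties go to the low arm.
* Missing values in TSV input are empty cells, read as absent — never zero
  — and handled complete-case per analysis, with `n` recorded per feature.
* Rank-sum comparisons where every value is identical return p = 1
  directly (the normal approximation is 0/0 there).
* Degenerate scan features are skipped with warnings (single-level arms,
  constant contributions, under-filled mutation filters), never silently
  dropped.
* Perfect covariate collinearity is an error in model fits (naming the
  aliased terms) but reported as an infinite VIF by the diagnostic.

# Problem sizes used by the test-suite

The bundled checks run on deliberately small instances: cohorts of 2–3
cohorts × 40–100 tumours with 40–60 genes, 100–200 simulation replicates
for power and calibration claims, 354 × 200 null panels with 400
permutations (×5 replicates) for Q-Q calibration, and exhaustive
enumeration for enrichment instances with N ≤ 10. These sizes were chosen
as the smallest at which the pre-build calibration showed the planted
effects are reliably detectable, so that a failing check signals a defect
rather than a power shortfall.

# Known limitations

* Gene identifiers are case-sensitive symbols with no alias resolution;
  mapping platform ids into the signature's namespace is the caller's job.
* BH is applied per scan, not across scans; analyses combining many scans
  should account for that themselves.
* The GSEA implementation reports no leading-edge sets and no
  normalized-ES-pooled FDR.
* Survival analysis is two-arm log-rank only — no adjustment, no competing
  risks.
* Cross-dataset score comparison is undefined by construction (per-dataset
  centering); the package does not try to detect it.
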