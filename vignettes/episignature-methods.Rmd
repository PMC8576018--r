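---
title: "Methods: episignature discovery, MVP scoring and DMR calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, MVP scoring and DMR calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `episignr`, the
choices made where the methodology is genuinely open, and what the
synthetic-data generator does and does not emulate.

## The measurement model

A methylation array reports, per CpG probe and sample, a beta value
β = methylated / (methylated + unmethylated) signal, in [0,1]. Beta values
are heteroskedastic (variance shrinks toward the boundaries), so all
hypothesis testing happens on the M scale, M = log₂(β′/(1−β′)), with β
clipped into [ε, 1−ε], ε = 0.001. The clip bounds |M| near 10 without
distorting the bulk of the distribution; `beta_to_m()` and `m_to_beta()`
are exact inverses away from the boundary. Effect sizes, however, are
always reported on the beta scale, because the 10% methylation-difference
threshold of the selection cascade is stated in methylation-fraction
units: tests on M, effects on β.

## Probe quality control

`qc_filter_probes()` removes, in order: probes whose detection p-value
exceeds 0.01 in *any* retained sample (the strictest reading of the
detection rule — a summary-rate alternative would keep probes that fail in
a single sample, but "fail anywhere, drop" is deterministic and
conservative); probes on chrX/chrY (sex-confounded); SNP-flagged probes;
cross-reactive probes. Each removed probe is attributed to the first
criterion it matches so the report's counts sum to the total removed. The
SNP and cross-reactivity lists vary between manifest versions, so both are
taken as user-supplied manifest flags rather than hard-coded.

## Cohort assembly

`match_controls()` selects, per case, a fixed number of same-sex controls
(default 5) by greedy nearest age without replacement; ties break to the
younger control, then lexicographic id, making the selection reproducible.
The maximum tolerated age gap defaults to 10 years and is enforced softly
(a warning), since exhausting a biobank pool is usually preferable to
failing. `pca_outlier_check()` then screens the assembled cohort: a sample
is flagged when its score on one of the top two principal components
exceeds 3 robust z-scores (median/MAD), a cutoff that flags gross
technical outliers but not biological spread.

## Cell-composition deconvolution

Whole-blood methylation is a mixture over leukocyte types, and case
status can correlate with composition; composition therefore enters the
probe-level model as a covariate. `estimate_cell_proportions()` solves,
per sample, least squares of the sample's betas at reference probes on
the cell-type reference profiles under non-negativity and an equality
sum-to-one constraint. The cited deconvolution tradition permits sums
below one, but proportions used as regression covariates should live on
the simplex — scale ambiguity would leak into the fitted group effect.
The constraint is imposed by an augmented high-weight row inside a
non-negative least-squares solve followed by exact renormalization. One
proportion column is dropped from the design matrix (simplex columns are
collinear with the intercept).

## Per-probe inference

`fit_probe_models()` fits ordinary least squares of M on [intercept, case
indicator, proportions] per probe, pooling bi- and mono-allelic carriers
as one case class for discovery (the dose contrast is available separately
for descriptive statistics). `moderate_statistics()` shrinks the residual
variances: with prior degrees of freedom d₀ and prior variance s₀²
estimated by moment matching on log s²_g (the trigamma-inversion
estimator), the posterior variance is s̃²_g = (d₀s₀² + d_g s²_g)/(d₀+d_g)
and the moderated t has d₀ + d_g degrees of freedom. d₀ → 0 recovers the
ordinary t, d₀ → ∞ the pooled-variance z; when the log-variance moments
admit no positive d₀ the fit degrades gracefully to d₀ = ∞ with a
warning. Saturated probes (clipped constant across all samples) have zero
residual variance and are floored at 1e-300 before taking logs — their
coefficient is also zero, so they never reach significance. The
multiple-testing adjustment is Benjamini–Hochberg by default (Bonferroni
and Holm are exposed); the moderated-statistics ecosystem treats BH as the
de-facto default, and nothing in the cascade depends on which is chosen
as long as it is monotone.

## The selection cascade

Four stages, each a subset of the previous:

1. **Effect size**: |Δβ| ≥ 0.10, inclusive ("at least 10%"). Δβ is the
   difference of group means on the beta scale with pairwise missing
   exclusion.
2. **Significance**: adjusted p < 0.001, strict.
3. **Discrimination**: per-probe ROC AUC, computed as the fraction of
   (case, control) pairs with case β above control β (ties half) — the
   Mann–Whitney identity. A probe passes when max(AUC, 1−AUC) > 0.9, so
   the rare hypomethylated signature probe is not discarded by a
   one-sided rule.
4. **Redundancy pruning**: a greedy sweep in ascending adjusted-p order
   keeps a probe only if it is not excessively correlated with an
   already-kept probe, keeping the most significant representative of
   each redundant block.

Correlations in stage 4 are computed separately within cases and within
controls, never pooled: pooled correlations are dominated by the
case/control separation itself and would mark every differential probe as
redundant with every other. The same argument applies one level down: in
a cohort with a methylation dose gradient (bi-allelic above mono-allelic),
all signature probes co-vary within the pooled case group because they
all track the same genotype. That is shared biology, not probe
redundancy. The default rule therefore removes a probe only when its
correlation with a kept probe exceeds the threshold in *both* sample sets
— genuine redundancy (adjacent CpGs reporting one signal, cross-hybridizing
probes) replicates in controls, dose-driven correlation does not. The
stricter remove-on-either-set variant is available
(`rule = "either"`); with small case groups it measurably prunes true
signal, because with n = 16 cases the sampling tail of a true
within-case correlation of ~0.4 crosses 0.8 for a material fraction of
probe pairs.

Degenerate inputs: zero-variance probes within a group make r undefined;
they are kept with a warning rather than silently dropped.

## MVP scoring

`train_mvp()` fits a linear-kernel SVM on the signature-probe beta values
(the scale on which heatmaps and MDS operate), with inverse-frequency
class weights to absorb the strong case/control imbalance typical of
these panels. The margin classifier's decision values are mapped to
[0,1] by a Platt sigmoid fit on the training decision values with Newton
iterations and prior-corrected targets. Calibration by internal
cross-validation was deliberately avoided: the C-level RNG it would rely
on is not reproducible across calls, and a deterministic pipeline was
judged more valuable than the modest optimism reduction — the resulting
scores are used for ordering and banding, not as literal probabilities.
The reporting bands (< 0.2 signature-negative, ≥ 0.5 signature-positive,
between: intermediate) are output conventions, not fitted thresholds.
`train_multiclass()` wraps the same binary machine in a one-against-all
scheme with a stratified per-cohort 75/25 split driven by an explicit
seed.

`mds_embed()` is classical (Torgerson) scaling of pairwise Euclidean
distances with the sign of each axis fixed by its largest-magnitude
coordinate, so embeddings are unique. `hcluster()` uses Ward linkage in
its Euclidean-consistent `ward.D2` form.

## DMR calling

`find_dmrs()` chains significant CpGs (adjusted p below the per-CpG
threshold) along each chromosome: consecutive significant CpGs at most
1 kb apart join one cluster, clusters need at least five significant
CpGs, and the candidate region spans the first to last significant CpG.
Whether the 1 kb figure constrains consecutive gaps or the total window
is ambiguous in the rule as usually stated; the chain reading is the
default (it is the behavior an enumeration oracle can verify directly)
and a total-window mode is available (`mode = "window"`). The regional
effect averages Δβ over *all* array CpGs in the span, not only the
significant ones — the conservative choice — and the Fisher combination
X² = −2Σln pᵢ ~ χ²(2k) likewise pools the raw p-values of all span CpGs.
A region is reported when |regional Δβ| ≥ 0.10 and the combined p < 0.01.
Under chaining, candidate regions are disjoint by construction, so no
overlap resolution is needed. Kernel-smoothed regional statistics (as in
dedicated DMR packages) are intentionally out of scope: the three
explicit rules above fully define a region, and they are exactly what the
brute-force test oracle checks.

Zero p-values are clipped to 1e-300 before the log; combined p of exactly
1 maps to a BED score of 0, and internal 1-based inclusive coordinates
are converted to BED's 0-based half-open on export.

## Expression comparison

Each annotated DMR maps to its highest-expressed annotated gene in the
evaluated cell type; duplicates collapse. The comparison against
background genes is a one-tailed Wilcoxon rank-sum test (alternative:
DMR genes higher). The p-value is exact by full enumeration of group
assignments when the combined sample size is at most 12 and otherwise a
normal approximation with mid-rank tie correction and 0.5 continuity
correction — the exact path exists because the DMR gene list can be very
short, where the approximation is least trustworthy.

## The synthetic-data generator

`simulate_cohort()` draws, per probe p and sample s:

M(p,s) = μ_p + δ_p(group) + γ_p·(composition_s·w_p) + ε,  ε ~ N(0, σ)

and returns β = 2^M/(1+2^M), so noise is Gaussian on the modelling scale
and β stays strictly inside (0,1). Key defaults, chosen once as a
realistic discovery-scale design and used throughout the test suite:

* **Cohort**: 8 bi-allelic + 8 mono-allelic cases, 64 controls; 20,000
  probes, 300 planted signature probes, 5 of them as co-located CpG
  clusters (6 CpGs, 150 bp spacing) annotated to synthetic TSS genes.
* **Background baselines**: μ_p ~ N(1.9, 3.0) — median β ≈ 0.79, matching
  reported whole-blood levels, with a spread wide enough to reproduce the
  U-shaped beta distribution of real arrays.
* **Signature baselines**: hypermethylated probes start essentially
  unmethylated (β₀ ~ U(0.03, 0.12)), emulating regulatory CpG-island/TSS
  sites that gain methylation in carriers; the ~1% hypomethylated probes
  mirror this at U(0.88, 0.97).
* **Planted effect**: the logit offset δ_p is calibrated so the
  beta-scale shift at the baseline equals 0.15 in bi-allelic and
  0.15 × 0.5 in mono-allelic carriers (the dose effect as a
  multiplicative factor on the planted beta shift — it reproduces the
  bi > mono > control ordering without asserting a mechanism).
* **Noise**: σ = 0.5 on the M scale per entry.
* **Composition**: 6 cell types, Dirichlet(10); 2.5% of background probes
  are composition-confounded with unit strength; 200 disjoint reference
  probes are generated as linear beta-scale mixtures of a random
  reference panel plus N(0, 0.02) noise, giving deconvolution a ground
  truth.
* **Detection failures**: injected per probe×sample at rate 1e-4.

`simulate_disorder_cohort()` reuses the per-probe baselines of an
existing cohort to generate a second syndrome affecting an arbitrary
probe set — the only way cross-cohort scoring, joint clustering and DMR
direction comparisons are meaningful. `simulate_expression()` draws
log-normal TPM with a log-scale enrichment shift for DMR genes and
derives the proportion-expressed metric as a fixed monotone transform of
TPM.

What the generator does *not* emulate: batch/chip effects beyond a label,
probe-type chemistry differences, spatial genome-wide methylation
autocorrelation outside the planted clusters, realistic gene annotation
density, or raw-intensity artifacts. Passing tests demonstrate that the
algorithms recover the structure they assume; they do not certify
performance on data whose artifacts violate those assumptions.

## Problem sizes and runtime

The reference design (20,000 probes × 80 samples) runs the full discovery
cascade in a couple of seconds; the test suite uses 3,000–5,000-probe
cohorts for replicated calibration studies (20 null cohorts for type-I
error and DMR false-call rates) and completes in well under a minute.
These sizes were chosen so distributional claims are tested with
replication rather than a single large run.

## Known limitations

* The moderated model assumes exchangeable probe variances; variance
  trends along mean methylation (probe-type effects) are not modelled.
* Greedy correlation pruning is order-dependent by design (most
  significant representative wins); a different candidate ordering can
  yield a different, equally valid signature.
* MVP scores are sigmoid-calibrated on training decision values and are
  optimistically scaled on the training cohort; interpret them as
  rankings with conventional bands, not probabilities.
* The equality-constrained deconvolution cannot represent non-blood
  contamination; residual norms are reported so such samples can be
  flagged.
* With very small case groups the within-case correlation estimates used
  by the `"either"` pruning rule are noisy; the default `"replicated"`
  rule is robust to this but will keep genuinely redundant probe pairs
  whose redundancy fails to replicate in controls by chance.
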