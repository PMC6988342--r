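---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`gutnet` integrates a host expression count table and a mucosal 16S OTU
table from the same small cohort into a mixed gene–taxon correlation
network. This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic-data generator does and
does not emulate, and where the design was genuinely open.

## 1. Contaminant screening

Reagent contaminants in low-biomass biopsy 16S data are detected by
prevalence: a taxon present in most blank-extraction controls but few true
samples is suspect. For each taxon we form the 2×2 presence table
(presence = count > 0, tightened by `min_count`) and report the one-sided
Fisher exact p-value — the hypergeometric tail probability of seeing at
least the observed number of positive controls — as the score in [0, 1].
Small scores indicate likely contaminants; `filter_contaminants()` removes
taxa scoring strictly below the threshold (0.1 by default, 0.2 as a
sensitivity setting) and drops the control columns.

Design choice: the popular prevalence classifier uses a chi-square statistic
with a Fisher fallback at small counts. With two or three controls the
chi-square approximation has no basin of validity, so we use the exact test
everywhere. Scores for taxa absent everywhere are set to 1 and flagged:
absence is not evidence of contamination.

## 2. Diversity

**Alpha.** Richness estimates depend strongly on depth, so each sample's
metric is the mean over `n_resamples = 100` independent rarefactions
(sampling without replacement) to the minimum column sum. Chao1 is
`S_obs + F1(F1−1)/(2(F2+1))`; Shannon uses natural logs. Group differences
use the two-sided Wilcoxon rank-sum test, exact when the pooled n ≤ 20
without ties, normal approximation with tie correction otherwise. The
resampling RNG derives one substream per draw from a single master seed;
without a seed policy "the mean over 100 draws" is not reproducible.

**Beta.** Bray–Curtis `Σ|x−y| / Σ(x+y)`; unweighted UniFrac as unshared over
total branch length among branches leading to tips present in either sample;
weighted UniFrac in its normalized form `Σ b_i|A_i−B_i| / Σ b_i(A_i+B_i)`
over subtree proportions. Normalization keeps the weighted variant in
[0, 1]; the raw variant is a documented alternative, not the default,
because the downstream ordination and PERMANOVA benefit from a bounded
dissimilarity. Distances are computed on the table rarefied once to minimum
depth, matching the rarefy-then-distance convention.

**Ordination and testing.** PCoA is classical scaling: eigendecomposition of
the Gower-centered `−D²/2`; negative eigenvalues are reported, not
corrected, and percent variance is taken over positive eigenvalues only.
PERMANOVA partitions the total squared distance into within- and
between-group parts and permutes labels freely (the design has no blocking
structure), with the add-one permutation p-value `(1 + #{F* ≥ F})/(1 + B)`,
`B = 999` by default.

A note on attainable p-values: permutations that preserve the group
partition reproduce the pseudo-F *exactly*. For a balanced 3v3 design, 72 of
the 720 orderings do so, which puts the smallest achievable p near 0.1
regardless of effect size. This is a property of the statistic, not an
implementation artifact, and the test suite asserts it.

## 3. Differential abundance and expression

Both the OTU and the gene tables go through the same machinery: a
negative-binomial GLM with log link,
`log μ_ij = β0 + β1·x_j + log s_j`,
fitted per feature by IRLS with a fixed dispersion.

* **Size factors** are median-of-ratios: `s_j = median_i k_ij / g_i` with
  `g_i` the geometric mean across samples of feature i, computed over
  features positive everywhere. Sparse 16S tables often have no such
  feature, so a "poscounts" fallback takes geometric means over positive
  entries (zeros still counted in the denominator n).
* **Dispersion** is a per-feature method-of-moments estimate on normalized
  counts, pooled within groups (so group mean differences do not inflate
  it), then shrunk 50/50 in log space toward a log-log linear mean–dispersion
  trend fitted across features, floored at 1e-8. Shrinkage stabilizes the
  estimate at n ≈ 20; the 50/50 weight is a deliberate, simple compromise.
* **Wald test** for the two-level condition: `z = β1/SE(β1)`, two-sided
  normal p, BH q-values; `log2FC = β1/ln 2`, reported for CF relative to
  healthy.
* **LRT** for the three CFTR genotype categories (Healthy, CF-ΔF508
  homozygous, CF-other): twice the log-likelihood difference between
  `~genotype` and `~1`, shared per-feature dispersion, against chi-square
  with 2 df.

This is an intentionally *simplified* stand-in for the standard RNA-seq NB
framework: no Cox–Reid adjusted profile likelihood, no dispersion-outlier
handling, no independent filtering, no fold-change shrinkage, no
Cook's-distance sample exclusion. Per-feature results will therefore differ
from DESeq2's on the same input, and differential-feature counts from
DESeq2-based analyses of real data should not be expected to match
numerically. What the simplification must still deliver
is calibration, and that is tested: on 2000 null NB features at n = 10/12
the empirical type-I error at nominal 0.05 must land in [0.03, 0.07], and
95% Wald intervals must cover the simulated β1 90–98% of the time.

Features that are all-zero are flagged and reported at p = 1. Features
entirely zero in one condition are refitted with a 0.5-count ridge added to
the counts, keeping the fold change finite; they carry a
`zero_group_ridge` flag.

The pathway-style Wilcoxon test takes a *relative-abundance* table (counts
are rejected with a pointer to `relative_abundance()`), filters to features
exceeding 0.1% in at least half of **all** samples — deliberately different
from the OTU filter, which uses half of the *smaller condition* — and runs
two-sided rank-sum tests with BH adjustment.

## 4. Integration: selection, CLR, Spearman, q-values

The gene-side cascade keeps genes with q < 0.05, membership in the supplied
pathway list, and |log2FC| strictly greater than 0.35. Both inequalities are
strict because the cascade is defined by exceeding thresholds; the boundary
cases are tested. Whether the fold-change cut was meant on the natural-log
scale is not decidable from the source material; we use log2 (the scale the
differential results report) and expose the threshold.

The taxon side collapses OTUs at genus — an OTU unassigned at genus joins a
group labelled by its last characterized level, e.g. `f__Ruminococcaceae` —
then applies the prevalence/abundance filter (≥ 0.1% relative abundance,
inclusive, in at least ⌈min(n_CF, n_healthy)/2⌉ samples) and the centered
log-ratio transform `clr_i = ln x_i − mean_k ln x_k` with pseudocount 1
added to counts. The pseudocount is the simplest zero-handling that is
robust across sequencing depths; it is exposed as a parameter. The pipeline
order — collapse, then filter, then CLR — matters and is fixed, because the
CLR of a sample changes whenever taxa are removed after the transform.

Every selected gene is correlated with every filtered taxon: tie-aware
Spearman rho (Pearson on mid-ranks) between size-factor-normalized
expression and CLR abundance. Since Spearman is rank-based, any per-sample
monotone normalization of expression gives identical results; normalized
counts are used rather than a variance-stabilized transform for exactly that
reason. The two-sided p comes from the t approximation
`t = ρ√((n−2)/(1−ρ²))` with n−2 df; for n ≤ 9 without ties the exact
permutation null is used instead. Pairs with a constant vector are reported
with ρ = 0, p = 1 and a flag rather than dropped, so the pair count stays
exactly `genes × taxa`.

FDR control is Storey's q-value: `π̂0(λ) = #{p > λ}/(m(1−λ))` on the grid
λ = 0.05, …, 0.95, smoothed with a cubic spline and read off at λ = 0.95,
clipped to (0, 1]; `q = π̂0 × BH`. When the spline estimate is unstable
(≤ 0 or > 1) the estimator falls back to π̂0 = 1, which reproduces BH
exactly — conservative and reproducible. Significance for network edges is
strict: q < 0.1.

## 5. SparCC

Correlating relative abundances directly is biased: closing the composition
induces negative correlation among unrelated taxa. SparCC estimates
correlations of the *basis* (unobserved absolute) abundances from pairwise
log-ratio variances `t_ij = var ln(f_i/f_j)`, which are invariant to
per-sample totals. Under the sparsity assumption (most true correlations
near zero), row sums of the variation matrix determine the basis variances
ω through a linear system; correlations follow as
`r_ij = (ω_i + ω_j − t_ij)/(2√(ω_iω_j))`, clipped to [−1, 1].

The implementation follows the published defaults, all exposed in
`sparcc_config()`: 20 estimation iterations, each drawing per-sample
fractions from Dirichlet(counts + 1); up to 10 exclusion rounds per
iteration, removing the strongest pair with |r| > 0.1 from the system and
re-solving (a pair is never excluded twice); the final estimate is the
element-wise median across iterations. If a solved basis variance is
non-positive the affected component's correlations are dropped from that
iteration; a pair unresolved in every iteration is reported as NaN, flagged,
and never becomes a network edge — silently coercing it would fabricate
edges.

Pseudo p-values use 100 randomized datasets built by independently permuting
each taxon's counts across samples — the scheme of the reference
implementation: it breaks all associations while preserving marginals. The
two-sided add-one p is `(1 + #{|r*| ≥ |r|})/(1 + 100)`, so its floor is
1/101 and its rejection rate at the 0.05 level is 5/101 ≈ 4.95% by
construction. That discreteness matters when auditing false-edge rates: a
single few-hundred-pair replicate fluctuates about ±1 percentage point
around the nominal level, which is why the recovery tests pool several
generator replicates before comparing against the 5% budget.

## 6. Network assembly

Gene–taxon edges require q strictly below 0.1; taxon–taxon edges require
|r| ≥ 0.1 (inclusive) *and* pseudo-p strictly below 0.05. The asymmetry —
inclusive on the correlation magnitude, strict on the significance — is
reproduced deliberately and tested at the boundary. Nodes are exactly the
endpoints of retained edges; an identifier appearing as both gene and taxon
is an error, not a coercion. Exports are a five-column edge list
(source, target, edge_type, weight, significance) and GraphML carrying the
same attributes; both round-trip through the package's readers.

## 7. The synthetic-data generator

The generator is the package's oracle, so its model mirrors the assumptions
of the analysis stages:

* **Gene counts**: NB with mean `s_j·μ_i·2^{log2FC_i·[CF]}`, log-normal base
  means (meanlog log 50, sdlog 1.3 — a bulk RNA-seq-like dynamic range),
  per-sample size factors from log-uniform library depths normalized to
  geometric mean 1, dispersion 0.1 by default.
* **Microbiome**: logistic-normal/multinomial — per sample, log basis
  abundances are multivariate normal with the planted correlation matrix
  (unit log-scale SD per taxon, baseline means N(0, 1.5²) for a realistic
  uneven composition), shifted by planted condition effects, then closed and
  multinomially sampled at a depth drawn from [9551, 50000]. The depth floor
  is a realistic minimum read count for mucosal biopsy 16S libraries. This is exactly SparCC's own generative
  model, which makes basis-correlation recovery well-posed.
* **Negative controls**: planted contaminants appear in each control with
  probability 0.95 (topped up to ≥ 90% prevalence) and are thinned in true
  samples to ≤ 20% prevalence; non-contaminants leak into controls at rate
  0.025 per control.
* **Gene–taxon links**: a linked gene's counts are re-drawn with NB mean
  multiplied by `exp(β·z)` where z is the linked taxon's standardized log
  basis abundance. β comes from a shipped monotone lookup
  (`inst/extdata/spearman_beta_lookup.tsv`, regenerated by
  `scripts/make_beta_lookup.R`) calibrated by Monte-Carlo at the reference
  operating point μ = 100, dispersion 0.1, so the expected Spearman matches
  the requested strength to about ±0.1 at biopsy-scale n.
* **Design**: 10 CF / 12 healthy / 2 controls by default — the scale of the
  cohort this pipeline targets — with CF samples alternating between the
  ΔF508-homozygous and other-mutation genotype categories.

What the generator does **not** emulate: batch effects, PCR/chimera
artifacts, phylogenetic signal in the effect sizes (the tree is a random
coalescent, used only to exercise UniFrac), taxon-specific dispersion in the
multinomial stage, and library-preparation covariance between the gene and
taxon tables. A green recovery test therefore establishes that the pipeline
inverts its own stated model at the planted effect sizes — not that it is
robust to every failure mode of real biopsy data. Conversely, the alpha- and
beta-diversity tests are honestly underpowered at n = 22 for moderate planted
effects; the worked example in the README shows this.

All simulation randomness flows from one integer seed through fixed derived
substreams (Mersenne-Twister, inversion normals, R ≥ 3.6 sampling), so every
artifact of a run is byte-reproducible; the determinism criterion in the
acceptance suite re-runs the full CLI pipeline and compares files byte for
byte.

## 8. Numerical details and degenerate inputs

* IRLS runs at most 100 iterations with tolerance 1e-8 and clamped linear
  predictors (|η| ≤ 30); non-convergent features are flagged and reported at
  p = 1 rather than dropped.
* p-values of exactly 0 are floored at the smallest positive double so that
  q-value machinery (which requires p ∈ (0, 1]) never rejects its own input.
* BH is implemented once (`bh_adjust()`) and verified against the step-up
  definition by brute force; the Storey estimator multiplies it by π̂0.
* Rarefaction requires depth ≤ every column sum and errors with the
  offending sample IDs; it never samples with replacement.
* All table operations align by string ID, never position; dropped IDs are
  logged. Validation rejects negative values, non-finite entries, duplicate
  IDs, and relative columns not summing to 1 (±1e-9).

## 9. Known limitations

* The NB stage is a simplified estimator (see §3); its per-feature results
  are calibrated but not numerically interchangeable with DESeq2.
* SparCC needs ≥ 4 taxa for the basis system and is noisy below ~8 samples;
  unresolved pairs are surfaced, not imputed.
* The Spearman-strength lookup is calibrated at one operating point; planted
  strengths are honored to ±0.1, which is why acceptance bands on realized
  correlations are as wide as they are.
* With two negative controls the smallest attainable contaminant score with
  10 true samples is 1/66 ≈ 0.015, so threshold 0.1 can only ever remove
  taxa absent from essentially all true samples; the screening power
  analysis in the tests uses 8 controls for that reason, and at the
  2-control design the score distribution is reported rather than asserted.
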