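---
title: "Statistical methods in padlockDM"
author: "padlockDM authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods in padlockDM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

padlockDM analyses cytosine-resolution methylation counts from targeted
bisulfite panels. This vignette records the statistical model, every
numerical convention the implementation had to fix, the design of the
synthetic-data generator, and the limits of what the test suite
demonstrates. It is the reference for choices that the function
documentation states but does not justify.

# The data and the preprocessing chain

The unit of observation is a cytosine × sample cell with `M` methylated and
`U` unmethylated read counts; the beta value is `B = M / (M + U)`. A
`MethylCountSet` keeps `M` and `U` as paired assays of a
`RangedSummarizedExperiment`; a cell is either observed in both or missing
in both. All interval inputs (genomic elements, SNP masks) are BED,
0-based half-open, converted to 1-based closed coordinates once, at the
reader boundary: a cytosine at 1-based position *p* lies in BED interval
`[s, e)` iff `s < p ≤ e`. Keeping the conversion in one seam is what the
round-trip and brute-force point-scan tests verify.

Preprocessing applies, in order:

1. **Coverage filter** — cells with `M + U < 30` become missing. Coverage 0
   and "absent" are indistinguishable after this point, by design.
2. **Technical replicates** — replicate pairs with Pearson `r ≤ 0.9`
   between their beta profiles trigger an exclusion. The member with the
   lower median coverage is dropped; this tie-break is our policy (the rule
   "one sample was excluded" does not say which member), and it is logged.
   Surviving members are collapsed by averaging `M` and `U`, rounded
   half-up.
3. **Site filters** — call rate < 70% of samples; all observed calls
   exactly 0; overlap with the user-supplied SNP mask (we deliberately do
   not bundle a population SNP set — which release and population to mask
   is a study decision, so the mask is an input); and the stable-site rule.
4. **Quantile normalization** (optional, for multi-batch cohorts) — `M` and
   `U` are normalized independently across samples and rounded half-up back
   to integers; beta values are recomputed from the normalized counts. Ties
   receive the average of their reference quantiles and missing cells are
   interpolated on the quantile scale and restored missing (the
   `limma::normalizeQuantiles(ties = TRUE)` dialect). The tie and rounding
   rules are stated here because several incompatible dialects exist.
5. **Stable-site filter** — sites where the fraction of samples at exactly
   0%, exactly 100%, or missing is ≥ 50% are removed. The boundary is
   inclusive, and the three categories count jointly. This pass runs after
   normalization: a site can become stable only once counts are on a common
   scale, which is why the site filtering is two-stage.
6. **PCA outliers** — principal components of the beta matrix (sites
   mean-imputed solely for this step; whether to run this on beta or
   M-values is configurable, beta being the default because outliers are
   artifacts of the raw scale); samples farther than 3 SD from the mean of
   PC1 or PC2 scores are removed in a single pass, with no re-iteration.

The QC report telescopes: every stage records before/removed/after, and the
tests assert the counts add up.

# The per-cytosine model

**Transform.** Extreme beta values make logits unstable, so values are first
shrunk toward the centre, `B' = (B (f − 1) + 0.5) / f`, then
`m = log2(B' / (1 − B'))`. The shrinkage factor is `f = 1000`, switched
automatically to `f = 2000` when the dataset contains CpH sites (CpH
methylation is rarer, so its beta values crowd 0 and need stronger
shrinkage). `|B' − B| ≤ 0.5/f`, so the transform is effectively lossless in
the interior; `mToBeta()` inverts it exactly on the shrunk scale.

**Robust fit.** Each cytosine's m values are regressed on the design
(diagnosis, age, sex, postmortem interval, batch, surrogates; a
diagnosis × age interaction for the aging analyses) by IRLS with the Huber
psi function. Tuning constant `c = 1.345`, scale re-estimated each
iteration as `MAD/0.6745` of the residuals, convergence when the largest
coefficient change is below 1e−6, at most 100 iterations. When every
residual sits inside `c ×` scale all weights are 1 and the fit is exactly
OLS — a fixed point the tests check against `lm()`.

The residual variance uses the Huber consistency correction:
`sigma² = Σ w r² / (K (n − p))` with `K = 2Φ(c) − 1 ≈ 0.8214`, the
expectation of `min(1, c/|z|) z²` under Gaussian residuals. Without `K` the
weighted sum underestimates the variance by ~18% and every test becomes
anticonservative; the null-calibration tests measured exactly that before
the correction was added, and type-I error at nominal 0.05 sits at ≈ 0.05
with it.

**Surrogate variables.** The number of surrogates is chosen by the stated
residual-PCA rule: regress every site on the known covariates, take
principal components of the residual matrix, and keep the `k` components
whose variance share exceeds 5%. This construction is a deliberate,
documented approximation of iterative SVA-type estimators; the selection
rule is identical, the refinement loop is not.

The *score* vectors, however, are not taken from the residual PCA directly.
Residual PCs are orthogonal to the design by construction, so a latent
factor's chance alignment with the diagnosis contrast would be absorbed
into the per-site diagnosis coefficients — a per-site bias proportional to
the factor loading that visibly inflates type-I error (we measured ≈ 0.09
at nominal 0.05 in a 40-sample null panel with a strong latent factor).
padlockDM therefore re-estimates the final scores from the centred,
covariate-*unadjusted* matrix with sites weighted by the residual-variance
share the `k` components explain — sites that carry the latent structure
vote, sites that carry design signal do not. With this reconstruction the
estimated surrogate correlates with a planted hidden batch at |r| > 0.99
and type-I error returns to ≈ 0.05. The number of surrogates is additionally
capped at `n − p − 4` so small cohorts keep residual degrees of freedom.

**Moderation.** Residual variances are shrunk by empirical Bayes assuming a
scaled inverse-chi-square prior, with hyperparameters `(d0, s0²)` from
moment matching of log variances (digamma/trigamma inversion by Newton
iterations). The moderated variance is
`s̃² = (d0 s0² + df s²)/(d0 + df)`; moderated t statistics use `df + d0`
degrees of freedom, two-sided p values. When the observed variances show no
excess dispersion over chi-square sampling noise, `d0` is capped at 1e7 and
`s0²` is set to the geometric mean variance, so that a degenerate set of
identical variances shrinks to itself. The estimates agree with
`limma::squeezeVar` on heterogeneous inputs (cross-checked in the tests)
and recover planted `(d0, s0²)` within 25%.

**Effect sizes.** "Fold change" for methylation is reported in percentage
points throughout: fitted m values are back-transformed to beta
(`B = 2^m/(2^m + 1)`), the same design is refitted to those fitted beta
values by least squares, and the contrast coefficient × 100 is reported.
This is the two-step recipe as stated, not a raw group-mean difference; the
simple group-difference alternative is available behind a switch, and the
two agree closely away from the beta boundaries. p values are adjusted per
contrast by Benjamini–Hochberg; `q < 0.05` defines significance everywhere.

# Enrichment statistics

All enrichment and overlap statistics are 2×2 constructions: the sample
odds ratio `ad/bc` (infinite when `bc = 0` with `ad > 0`), the exact
hypergeometric Fisher p (two-sided by the point-probability rule — the sum
of all tables as or less probable than the observed one — which is one of
several two-sided dialects and therefore stated), and a Woolf log-OR 95%
interval with the Haldane 0.5 correction when any cell is zero. The test
suite compares every p against exhaustive enumeration for all tables with
total ≤ 30 and a random sweep of larger tables.

Conventions fixed here:

* **Cytosine → gene assignment**: nearest panel-gene TSS among genes whose
  probed window contains the site; ties broken lexicographically by gene
  id, which makes the assignment deterministic and order-invariant.
* **TSS bins** are 20-kb, half-open on unsigned distance: a site at exactly
  20,000 bp opens bin 2. Distance is unsigned because no sign convention is
  given for upstream/downstream.
* **Per-gene statistics** use a one-sided (greater) Fisher test of the
  gene's significant-site density against all other interrogated sites (the
  gene's own sites are excluded from the comparison cells so the 2×2
  partitions cleanly — an interpretive choice, flagged). Direction is the
  majority sign of the gene's significant cytosines; ties fall back to the
  sign of the weighted mean percentage-point change over *all* the gene's
  cytosines with weights `−log10 p`. Base 10 for every log-p weight in the
  package is our convention (configurable); only "log transformed" is
  prescribed.
* **Top-site element concordance** takes the 5,000 most significant
  cytosines of two datasets and asks, per element class, whether the same
  element instances are hit in both; instances from two different
  annotations (e.g. tissue-specific enhancer calls) are matched by overlap
  within 1 kb.

# Rank aggregation

Genes are ranked within each dataset by their one-sided enrichment p value
(average ranks for ties), normalized by the dataset's gene count, and a
gene missing from a dataset receives the uninformative-worst rank 1.0 (the
alternative — dropping the list and reducing k — is available). The rho
score of a sorted rank vector `r` is `min_j P(Beta(j, k−j+1) ≤ r_j)` — the
most surprising order statistic under the null that ranks are independent
uniforms — and the reported `p_adj = min(1, rho · k)` is the published
Bonferroni-style bound, used unmodified. The tests check rho against
Monte-Carlo order-statistic probabilities (10⁶ draws), a closed form at
k = 2, monotonicity, and conservativeness of `p_adj` under shuffled ranks.

# Aging analysis

Age slopes come from the same robust engine with diagnosis, age, and
diagnosis × age terms: the control slope is the age coefficient, the case
slope adds the interaction, and BH runs within each contrast. A gene's
aging rate is the `−log10 p`-weighted mean of its cytosines' slopes
(points/year), set to zero — and flagged — when no cytosine reaches
`q < 0.05`. The age-vs-disease correlation restricts to loci nominally
significant (`p < 0.05`) in both analyses and correlates absolute effects.
Group comparisons report overlap enrichment of non-zeroed genes, a Fisher
test of sign agreement over jointly non-zeroed genes ({case +/−} ×
{control +/−} — the 2×2 construction is under-specified in the source
method and this is our reading, flagged), and a paired t test on absolute
rates over jointly non-zeroed genes (including zeroed pairs is a switch).
An old-age sensitivity re-analysis is a sample-sheet filter, not separate
code.

# Cross-dataset statistics

Kendall concordance is tau-b (tie-corrected) on paired per-gene odds
ratios; p is exact by full permutation enumeration for n ≤ 8 pairs and the
tie-corrected normal approximation otherwise. Weighted Pearson uses
weighted moments with significance from a t approximation on the effective
sample size `(Σw)²/Σw²`; with uniform weights it reduces exactly to the
ordinary test. Many-to-many homolog maps are reduced to one-to-one pairs
greedily by combined site count. The exacerbation test compares
{|effect A| > |effect B|} against {significant vs not}; "significant" means
significant in dataset A by default (union and intersection are switches,
as the source phrasing supports either).

# The synthetic-data generator

`simulatePanel()` emulates a padlock panel: genes on 5 chromosomes with
non-overlapping ±300-kb probed windows, ~20% of each gene's cytosines
placed in the promoter, element classes kept disjoint (CpG islands are
placed as "orphan" islands away from the TSS precisely so that
element-specificity tests are meaningful), baseline methylation from a
bimodal Beta mixture (30% low ~ Beta(2,10), 30% high ~ Beta(10,2), 40%
intermediate ~ Beta(5,5)), and per-cell counts that are beta-binomial over
negative-binomial coverage.

Effects are specified in percentage points and converted to the logit scale
at each cytosine's baseline using the *exact secant* at the stated shift,
so a planted 10-point effect realizes exactly 10 points; the infinitesimal
derivative would attenuate effects at extreme baselines. For the same
reason effects are only planted where they are expressible: a +10-point
shift cannot exist at a 95% baseline, so such sites are never part of the
truth (magnitudes are clipped to the available headroom in the rare
remaining cases). Planted magnitudes are lognormal around the nominal
effect (CV 0.3 by default, mean preserved) because real panels show
heterogeneous, not constant, shifts — reported average changes are
averages. The sign of a gene's shift is constant within the gene
(probability `hyper_fraction` of being positive), which has a statistical
consequence the acceptance tests respect: the null spread of the
directional odds ratio is governed by the number of affected *genes*, not
sites, so calibration sweeps use panels of many small genes, mirroring the
~500-gene shape of real designs.

Latent (cell-mixture-like) factors have loadings with nonzero mean
(default 2 points ± 3): a composition factor shifts global methylation
level as well as individual sites, which is what makes sample means vary on
a scale PCA can see. Batch offsets are per-site Gaussian (default SD 2
points); an optional `batch_confounding` parameter tilts batch assignment
by group, producing the classic confounded-batch scenario used to
demonstrate surrogate rescue. Outlier samples receive a global mean shift
calibrated, via a provisional count draw inside the outlier stream, to a
stated number of standard deviations of the *observed* sample means
(default 8), which is the scale the PCA detector sees. Technical
replicates redraw counts at identical means.

Every stage draws from its own fixed stream (a deterministic offset of the
master seed), so adding a stage never perturbs another stage's draws, and a
`noise_seed` override regenerates sampling noise while keeping the planted
truth — that is how replication datasets are simulated. Overdispersion
defaults to `rho = 0.01`; no dispersion estimate exists for the original
count data, so the default is explicitly chosen for the sensitivity of the
recovery tests, and calibration checks set their own `rho` where a
condition states one.

**What the generator does not emulate** — and what passing tests therefore
do not show about real data: read-level artifacts (bisulfite conversion
failure, probe capture bias, strand-specific hemimethylation), spatial
correlation between neighbouring cytosines, realistic linkage between
element classes (promoters and islands co-occur in real genomes; the
generator separates them on purpose), non-Gaussian batch structure, and any
form of genuine biological pathway coherence. Results on real panels
depend on those properties; the tests establish correctness and
calibration of the statistics, not field performance.

# Problem sizes and runtime choices

The packaged checks run on one CPU in well under an hour total. Sizes were
chosen as the smallest that make each property measurable: null
calibration uses ~5,000 cytosines × 40 samples over 20 seeds; effect
recovery uses the default panel at coverage 100; directional-OR calibration
uses 1,000 small genes (one affected cytosine per gene) for the gene-sign
reason above; specificity sweeps use 60-gene panels; the Monte-Carlo
rank-aggregation oracle uses 10⁶ draws; the demo pipeline (~5,000 sites, 40
samples, primary + replication) runs end-to-end twice to prove
digest-identical determinism.

# Known limitations

* The surrogate construction is the two-step residual-PCA rule with score
  reconstruction, not an iterative SVA; with many weak latent factors the
  5% rule will under-select.
* The robust fit assumes cell-level counts are exchangeable within a
  cytosine after covariate adjustment; region-level (DMR) smoothing is out
  of scope.
* Percent-change back-transformation is exact only on fitted values;
  per-sample nonlinearity at the beta boundaries is absorbed into the
  least-squares refit.
* The Woolf/Haldane interval is approximate for very sparse tables; the p
  value, not the CI, is exact.
* With interval inputs from different genome builds the package does no
  liftover; coordinates must already be consistent.
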