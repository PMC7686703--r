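---
title: "Methods: a methylation index of cervicovaginal community state"
author: "widlo authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a methylation index of cervicovaginal community state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scientific setting

A cervicovaginal smear carries two intertwined signals: the composition of
the resident microbiome and the methylome of the shed host cells. The
microbiome is summarized as a binary community state: **L-type** when the
combined relative abundance of *Lactobacillus crispatus*, *L. gasseri*,
*L. iners* and *L. jensenii* reaches at least 50% of the community, and
**O-type** otherwise. The threshold is inclusive — exactly 50% is L — and
`assignCommunityType()` applies it after renormalizing the abundance table,
with case-folded, whitespace-normalized taxon matching and an optional
synonym map.

The host methylome is a beta-value matrix (probes × samples, values in
[0, 1]). A smear is a cell mixture — mostly squamous epithelium, with
fibroblast and immune admixture — so every downstream model treats observed
methylation as a composition-weighted average of cell-type methylomes:

$$\beta_{ij} \approx \sum_k f_{ik}\, \mu_{kj},$$

with per-sample fractions $f_{ik}$ on the simplex. The summed
immune-compartment fraction IC is the single strongest nuisance covariate:
it varies widely between samples, correlates with age, and must be adjusted
for when associating methylation with community state.

## Pipeline stages and their assumptions

### Quality control

`maskAndFilter()` masks entries with detection p > 0.01 as failed, then
removes samples with strictly more than 10% failed probes, then probes
whose failure rate — recomputed over the surviving samples — strictly
exceeds 10%. The order (mask → samples → probes) is fixed; filtering is
order-sensitive and this order removes catastrophic samples before they can
drag down otherwise healthy probes. Strict (">") rather than inclusive
inequalities are used at both thresholds. `applyExclusionLists()` removes
the union of the standard exclusion sets (non-CpG probes, SNP-related
probes, chromosome-Y probes, probes with trimodal beta distributions that
betray an underlying SNP). Raw-intensity operations (background and
dye-bias correction, beta-mixture quantile normalization, intensity-based
sample exclusion) are out of scope: they need probe-level intensity data
that a beta-value pipeline does not carry.

`imputeKNN()` fills each missing entry with the mean over the k = 10
nearest probes (Euclidean distance across mutually observed samples) of
their values in that sample, skipping neighbours that are themselves
missing there; ties in distance break by probe order. Neighbours are
probes, not samples, because probe rows are long (hundreds of samples) and
co-methylation across probes is the stable structure. The function never
touches an observed value and is idempotent on complete matrices. It is
meant for the sparse missingness QC produces (~1e-5 of entries at the
default failure rate); it refuses matrices more than half missing.

### Cell-type deconvolution

`deconvolveCellFractions()` regresses each sample's beta values over the
reference probes on per-cell-type mean profiles using iteratively
reweighted least squares with Huber weights (tuning constant 1.345, no
intercept), truncates negative coefficients to zero and renormalizes to the
simplex — a robust-partial-correlation-style estimator. Robustness matters
because a minority of reference probes can be aberrant in any given sample
(local SNPs, residual artefacts); the test suite demonstrates that with 5%
corrupted reference probes the robust fit stays within 0.05 mean absolute
error while ordinary least squares does not. Reference probes missing in a
sample are dropped pairwise for that sample only. At least 50 overlapping
probes are required, and a rank-deficient reference is rejected: the
estimator is only identifiable when cell types are mutually discriminable.

### Per-CpG ranking

Five statistics, each returning a full permutation of the probes
(1 = strongest), are computed with the O class coded 1:

* `rankAdjustedLogistic()`: per probe, `logit P(O) ~ beta + age + IC`,
  ranked by the Wald p of the beta coefficient. The Wald statistic is the
  default contract; a signed likelihood-ratio variant
  (`statistic = "lrt"`) is provided because the Wald z collapses toward
  zero on probes whose effect is so strong that the classes nearly
  separate (the Hauck–Donner effect) — the LRT shares the age + IC null
  deviance across all probes, so it costs nothing extra. Probes whose fit
  fails (constant probes, non-convergence) are flagged, given p = 1, and
  sink to the bottom; a genome-scale scan must never abort on one probe.
* `rankWelch()` and `rankBartlett()`: vectorized closed forms of the
  unequal-variance t and the two-group equal-variance chi-square;
  Bartlett's direction reports which community type is more variable.
* `rankDeltaBeta()`: per group (O and L separately), ordinary least
  squares of beta on IC; the statistic is the difference of the IC = 0
  intercepts. Extrapolating to IC = 0 isolates signal in the
  non-immune (epithelial) compartment: purely immune effects vanish at the
  intercept. The statistic is an effect size in beta units, ranked by
  magnitude, with no p-value attached. A group with constant IC leaves the
  intercept unidentifiable and is an error, not a silent extrapolation.
* `rankCellDMC()`: the cell-type interaction model
  `beta ~ Σ_k f_k + Σ_k f_k × label` without a global intercept, over the
  three compartments (the seven immune subtypes a finer reference might
  distinguish are collapsed into one immune compartment, since IC enters
  every other model as a single proportion). The summary p is the smallest
  per-compartment interaction p, Bonferroni-scaled by the number of
  compartments. This scaling is valid (never anti-conservative) but not
  uniform under the null — min-p capped at 1 necessarily has an atom at 1 —
  so calibration checks assert one-sided conservativeness and the
  0.05-level rejection rate rather than two-sided uniformity.

`fdrAdjust()` is Benjamini–Hochberg. BH was chosen over a
$\pi_0$-estimating q-value procedure because it is deterministic and free
of density estimation; it is conservative when many probes carry signal,
which only makes reported q-values cautious.

`aggregateRanks()` combines methods by the geometric mean of ranks,
$\left(\prod_m r_m\right)^{1/M}$, ordered ascending. The geometric mean
rewards probes ranked consistently well by complementary statistics — mean
shifts, variability shifts, adjusted association, epithelial extrapolation
and compartment interactions — while a single discordant method (for
example a Wald collapse) only dilutes rather than destroys a strong probe.
Ties break by the adjusted-logistic rank (the anchor method) and then by
probe id, making the result independent of the order in which methods are
supplied.

### Signature training

`cvScan()` scans the ranked probe list top-down over a grid of pool sizes;
for each pool and each elastic-net mixing value α on the 11-point grid
0, 0.1, …, 1 it fits the full regularization path and measures mean
validation AUC under label-stratified k-fold cross-validation (default
tenfold). Stratification prevents single-class folds at moderate n; if a
training part still loses a class the folds are redrawn under a derived
sub-seed (at most 10 attempts). The winning (pool, α, λ) maximizes mean CV
AUC — the "max" rule rather than the one-standard-error rule, since the
goal is discrimination, with ties resolved toward the sparser model
(larger λ, then smaller pool, then smaller α) — and the model is refitted
on all training samples at that (α, λ). The default pool grid
{1000, 2000, 5000, 10000, 20000, 50000} is clipped to the number of ranked
probes. In nonlinear mode the design adds a β × IC column for *every*
pooled probe: the candidate set is deliberately a superset and the penalty
decides which interactions survive, so a CpG may carry both a linear and an
interaction weight.

Elastic-net paths are computed by coordinate descent (`glmnet`), with
features standardized internally for penalization and coefficients
reported on the original scale. The test suite verifies the solver against
an independent Newton MLE at vanishing penalty, the lasso
Karush–Kuhn–Tucker stationarity conditions along the path, and the
analytic behaviour at λ ≥ λ_max (all coefficients zero, intercept at the
logit of the prevalence).

`computeIndex()` evaluates the signature as a plain linear predictor on
the log-odds scale; higher values favour O-type. Signatures serialize to
TSV with '#'-prefixed metadata (α, λ, pool, mode, intercept) and round-trip
losslessly.

### Evaluation

`stratifiedSplit()` partitions samples 2/3–1/3 within strata of age bin ×
IC bin × label, shuffling each stratum under the seed and rounding the
training share to the nearest integer. Decade age bins and IC quartile
bins are the defaults — coarse enough that strata stay populated at a few
hundred samples, fine enough to balance the two covariates that drive
methylation heterogeneity. Singleton strata go to training.

`rocAuc()` is the Mann–Whitney statistic (ties count one half);
`aucCI()` offers both a closed-form DeLong interval (the default) and a
within-class stratified bootstrap with percentile bounds, because the two
are distinct methods that happen to be conflated in common usage; they
agree to ~0.03 at 200 samples per class on the test fixtures.
`subgroupAuc()` ships preset masks for the age < 50 / ≥ 50 and IC < 0.5 /
≥ 0.5 subgroups in which an epithelial-borne signal is expected to perform
differently.

`firthLogistic()` maximizes the Jeffreys-penalized log-likelihood
$\ell(\beta) + \tfrac{1}{2}\log\det I(\beta)$ by modified-score Newton
iterations with step-halving, giving finite estimates under complete
separation and zero table cells. Confidence intervals come from the
profile penalized likelihood (chi-square cut-off, root located by
bisection to 1e-6) and p-values from penalized likelihood-ratio tests.
Numerical safeguards, each exercised by a test: covariate columns are
scaled to unit spread internally (a pure scaling, so estimates and CIs map
back exactly); profile evaluations far from the optimum accept a looser
gradient tolerance (a residual gradient $g$ perturbs the profile value by
only about $g^2/2I$); regions where the information matrix degenerates
(fitted probabilities collapsing to 0/1) have penalized likelihood
$-\infty$ and are treated as beyond any confidence bound; and profile
walks warm-start from the previous solution with a cold-start fallback.
`associationScan()` wraps this into the standard model set — index alone,
plus age, IC, and age + IC adjustments — dropping samples with missing
covariates per model only. The index enters per unit of the linear
predictor (unstandardized), matching how such odds ratios are usually
reported.

`annotationEnrichment()` tests each CpG-island-relation category (island,
shore, shelf, open sea — distance-based annotation classes) or gene-region
category by a two-sided Fisher exact test of the selected-versus-background
2×2 table, reporting the sample odds ratio $ad/bc$ with BH adjustment
across categories; unannotated probes form an "unknown" category.

## The synthetic-cohort generator

`generateCohort()` draws, per sample, a label (L with probability 0.52,
matching a roughly balanced case–control series), an age from a truncated
normal (mean 40, sd 12, range 18–80 years — an adult screening-age
window), and cell-type fractions from a Dirichlet with concentrations
(epithelial 10, fibroblast 1.5, immune 3.5), giving epithelial-dominated
smears with median IC near 0.25 and a realistic spread into high-IC
samples. The same concentrations apply to both labels by default: in the
data this generator emulates, overall immune fraction is not itself
informative about community type, and keeping it uninformative ensures any
classifier performance comes from planted CpG effects, not composition
shortcuts. Label-dependent concentrations are available for sensitivity
experiments.

Planted effects perturb **compartment means before mixing**: an epithelial
differential CpG shifts only the epithelial reference mean, in O-labelled
samples, by ±Δ (sign mix configurable; planted probes are chosen among
those whose shifted means stay inside [0, 1], so the planted effect is
realized exactly). The observable effect therefore scales with the
sample's epithelial fraction — precisely the structure the Δβ
extrapolation and the interaction model are designed to detect, and the
property the acceptance checks exploit. Immune-compartment DMCs and
age-drift probes (slope in beta units per year, centred at the mean age)
are planted the same way on disjoint probe sets.

Measurement noise is additive Gaussian on the beta scale, truncated to
[0, 1], with sd 0.02 by default — the scale of array technical noise — and
a beta-distributed alternative (mean-matched, sd-matched) for users who
want bounded, heteroscedastic noise without truncation atoms. Planted
effect sizes default to Δ = 0.1–0.2; these are chosen for testability (a
power study can resolve them at n = 300) rather than as a claim about the
effect-size distribution in real cohorts, which the emulated data do not
pin down. Detection p-values are uniform(0, 0.01) for good entries — any
value below the masking threshold is equivalent downstream — and
uniform(0.01, 1) for failures, planted at rate 1e-5 to match the
order of magnitude of failed probes in a well-behaved array experiment.

`generateReferenceProfiles()` gives each cell type a shared bimodal
baseline (Beta(0.35, 0.35), the characteristic two-humped beta-value
distribution) plus small type-specific deviations, then forces, for every
pair of cell types, a disjoint block of ≥ 50 probes with mean difference
≥ 0.5 — the discriminating probes that make deconvolution identifiable.
`generateAbundanceTable()` draws the designated-Lactobacillus total above
(L) or below (O) the 50% threshold, with margins (0.55–0.98 for L,
0.02–0.45 for O) so labels are stable under renormalization, and splits it
among species by Dirichlet draws; re-typing the table always recovers the
input labels.

What the generator does **not** emulate: probe-type chemistry and its
normalization artefacts, batch and plate effects, correlated probe blocks
(CpG islands), genuine seven-subtype immune composition, age–microbiome
confounding unless explicitly configured, and sequencing-based abundance
noise. Passing tests therefore certify the statistical machinery and its
contracts on mixture-structured data, not performance on any real cohort.

## Determinism and problem sizes

Every stochastic stage takes an integer seed and restores the caller's RNG
state; equal seeds give byte-identical outputs, including every TSV the
package writes. The validation suite runs at sizes chosen to make its
properties sharp yet quick on a single CPU: deconvolution recovery at 100
samples × 600 probes; ranking power at 300 samples × 5000 probes with 100
planted epithelial DMCs (Δ = 0.15); null calibration pooled over 20
replicate 5000-probe cohorts (pooling across replicates is deliberate —
within one cohort p-values share the cell-fraction draw and are
correlated, so only the pooled empirical CDF is expected to be uniform);
the end-to-end run at 450 samples split 2/3–1/3; and the permutation
control at 10 re-seeded label shuffles of a 2000-probe null cohort, whose
best cross-validated AUC must stay within chance plus selection noise.

## Known limitations

* The Wald-based adjusted-logistic ranking degrades on probes with
  near-complete separation (use `statistic = "lrt"` there); the aggregated
  rank is robust to this by construction.
* The CellDMC-style summary p is conservative by design; it ranks, and
  controls error, but is not a calibrated per-probe p-value.
* Deconvolution quality is bounded by the reference: cell types missing
  from the reference are absorbed into the closest available profile.
* Δβ extrapolates to IC = 0 by a linear fit; strongly nonlinear
  β–IC relationships or IC distributions far from 0 make the intercept an
  extrapolation in the literal sense, with the usual caveats.
* The generator's independence assumptions (probes independent given
  fractions; noise homoscedastic) make power estimates optimistic relative
  to real arrays.
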