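---
title: "Methods: metabolic covariance networks and exposure-response modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic covariance networks and exposure-response modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvrnet)
library(dplyr)
```

suvrnet implements the analysis chain used in chronic-dosing imaging
studies of transgenic Alzheimer's-model mice: regional ^18^F-FDG PET uptake
is turned into cerebellum-normalized SUVr, group-level metabolic covariance
networks are built and compared through signed graph metrics, multi-resolution
consensus clustering extracts community structure that is then imposed across
groups, and a population pharmacokinetic model supplies per-animal exposure
(AUC) for linear exposure-response models of gene expression and of network
summaries. This vignette records the modeling choices, defaults, and known
limits; the worked example in the README shows the pipeline end to end.

## SUVr processing

Uptake arrives as one row per animal with one column per region. Left and
right unilateral regions (56 in the packaged mouse atlas) are averaged
arithmetically into 28 bilateral regions, and every region is then divided,
animal by animal, by that animal's cerebellum value. The order is fixed —
bilateral averaging first, then normalization — because the two operations
only commute when left and right cerebellum values are equal; a test
documents this non-property with a counterexample. Normalization is
idempotent and leaves the reference column identically 1.

### Consensus region selection

The data-reduction step ("regions that consistently explain 80% of the
variance") is genuinely under-specified as a rule, so the committed
interpretation is isolated in one function, `select_consensus_regions()`:

1. per cohort, PCA on the animal x region SUVr matrix with columns
   z-standardized (so high-mean regions do not dominate — the alternative,
   covariance-PCA, would let absolute uptake drive selection);
2. keep the leading components up to 80% cumulative explained variance;
3. score each region by the explained-variance-weighted sum of its squared
   loadings over those components, normalized to sum to 1;
4. select the smallest top-scoring set whose cumulative score reaches the
   same fraction;
5. the consensus is the strict intersection across cohorts (a
   frequency-threshold union is available via `method = "frequency"`).

Whether the original analysis used correlation- or covariance-PCA, or
rotated loadings, is not stated anywhere we could check; the choice above is
the most common default in regional-uptake work and is swappable.

## Covariance networks

For every sex x genotype x treatment group with at least 4 animals,
`covariance_matrix()` computes pairwise Pearson correlations across animals
(the reference region excluded). Correlation is invariant to per-column
affine rescaling, so z-scoring regional values first — as imaging pipelines
habitually do — changes nothing; the test suite asserts this rather than
assuming it. Edge p-values use the t transform with n − 2 degrees of
freedom, two-sided, with no multiple-testing correction at the edge level:
the thresholding rule is raw p < 0.05, and more restrictive thresholds are
known to leave these small-cohort graphs too sparse to analyze. For a fixed
group size the p-rule is equivalent to a cut on |r|; for unequal group
sizes the two rules diverge, and the p-rule is the committed one.

Zero-variance regions (possible in degenerate or truncated cohorts) degrade
to isolated nodes with a warning instead of aborting the group.

### Nodal metrics

On the thresholded signed graph, each region gets: degree (count of
surviving edges), positive strength (sum of positive weights), negative
strength (summed magnitude of negative weights, reported as a positive
number because it is plotted and compared as its own distribution), and a
clustering coefficient. The default clustering coefficient is the binary,
sign-blind Watts-Strogatz form — closed triads over k(k−1)/2, zero when
k < 2 — because the named metric has several variants in common toolboxes
and the binary form is the least parameterized; Onnela (weighted,
|w|^{1/3} geometric mean) and Zhang-Horvath (signed) variants sit behind
the `clustering` argument. Identities the implementation must satisfy
(density = mean degree / (N−1); |s_pos − s_neg| ≤ degree; edge-set nesting
in alpha) are enforced by tests against brute-force enumeration.

Global distributions of each metric (27 values per group) are compared
between groups with the two-sample Kolmogorov-Smirnov test. With 27-point
samples the asymptotic p is unreliable, so the p-value is exact — the
permutation distribution of D with ties respected — whenever both samples
have at most 30 observations, verified against full enumeration at 4 vs 4;
larger samples use the limiting Kolmogorov form.

## Community structure

`mrcc()` implements multi-resolution consensus clustering on the
positive-weight subgraph (negative covariance is excluded from community
detection but retained for nodal metrics): Louvain modularity partitions at
200 evenly spaced resolutions in γ ∈ [0.5, 3] — the source framework fixes
neither range nor sampler; this range spans from coarser-than-unit to
well past the regime where 27-node networks shatter — are pooled into a
co-classification matrix. Entries are zeroed when they do not exceed the
95th percentile of a permutation null with 10,000 replicates, and the
thresholded matrix is re-clustered until unanimous. The null is computed
from the exact probability that a uniformly random relabeling of each
ensemble partition keeps a given pair together (a function of community
sizes only), sampled as a Bernoulli mixture across the ensemble — the
marginal distribution of a co-classification entry under label
permutation, at a cost independent of network size. Where the framework's
"10,000 permutations" could parameterize either the ensemble or the null,
we commit it to the null and expose both knobs (`n_samples`, `n_null`).

Determinism: `seed` is a required argument; given it, the whole consensus
is reproducible, and on clean planted structure different seeds agree
exactly (tested). Planted 3-block cohorts at n = 200 animals are recovered
with adjusted Rand index 1.0 across seeds; two disconnected positive
cliques always return K = 2.

Reference partitions (wild-type male by default, the healthiest available
network) are imposed on every other group with `impose_partition()` —
per-animal means over community member regions — and compared community by
community with a one-way ANOVA (two groups, so F = t² of the pooled t
test) under Bonferroni correction across the K communities.

## Pharmacokinetics

The structural model is one-compartment with first-order absorption:
C(t) = D·ka / (V(ka − ke)) · (e^{−ke t} − e^{−ka t}), ke = CL/V, with the
analytic equal-rate limit when |ka − ke|/ke < 10^{−9}. CL/F and V/F are
allometrically scaled with fixed exponents 0.75 and 1.0 to a reference
weight of 0.025 kg. The dose covariate defaults to a power of dose
normalized to 30 mg/kg (the midpoint of the single-dose study levels
10/30/100 mg/kg); a proportional form is available, since the original
covariate form is not reported. Default generating values — ka = 2 /h,
CL/F = 0.010 L/h, V/F = 0.015 L — are config values, not reported
estimates: they are an allometric projection of clinical levetiracetam
kinetics to mouse scale (terminal half-life ≈ 1 h, tmax ≈ 0.8 h,
consistent with the 0.5 h sampling emphasis) and are stated in the config
rather than hard-coded as truth.

NCA follows standard conventions: linear-up/log-down trapezoid for
AUC(0–last); λ_z by log-linear regression over the best adjusted-R² window
among the last 3..6 post-Tmax points; AUC(0–∞) = AUC(0–last) + C_last/λ_z;
CL/F = dose/AUC(0–∞). Non-estimable tails (fewer than 3 positive post-Tmax
points, or a non-negative slope) are flagged, never silently imputed.

Population estimation is deliberately simplified — the original analysis
used a commercial nonlinear mixed-effects engine whose numerics are out of
scope. Two estimators are provided. The default two-stage method fits each
animal's curve by log-scale least squares (initialized from that animal's
own NCA, with the user start and a flip-flop alternative as fallback
starts), then regresses individual log CL/F and log V/F — allometry
removed — on the candidate covariates. Because the oral curve is invariant
under swapping ka and ke (with V rescaled), individual fits are
canonicalized to the conventional ka > ke representation; without this the
volume estimate is corrupted by absorption-limited mirror solutions. The
pooled method fits all observations at once; it is sharper without
between-subject variability but its covariate test treats within-animal
points as independent, which we measured to be badly anticonservative
under lognormal BSV — the reason two-stage is the default. In both,
covariates are retained by forward selection when they drop
n·log(RSS/n) by at least 3.84 (the 1-df chi-square criterion at p < 0.05).

Exposure is dose-normalized clearance: AUC = dose / (CL/F), in mg·h/L
(about 25 mg·h/L at 10 mg/kg under the defaults — a scale on which the
expression effect sizes below are realistic). Twice-daily chronic dosing
under linear kinetics gives a daily steady-state AUC of 2·dose/CL,
reported separately. The exposure-concentration screening relationship
(OLS of AUC on the 0.5 h plasma sample) is reported with R² and the slope
p-value.

## Exposure-response models

Gene-level models operate on long tibbles of log2 intensities.
`de_linear_model()` fits per-gene OLS on genotype, sex and treatment as
categorical factors, judging each factor by its marginal (drop-one) F test
so verdicts do not depend on factor order, flagging genes with any factor
p < 0.05 — raw p-values, matching the screening character of the original
analysis, with an optional Benjamini-Hochberg column.
`delta_from_vehicle()` computes the heat-map summary (treated mean minus
vehicle mean per gene and sex), with a sex-matched wild-type-vehicle
baseline variant. `gene_exposure_model()` fits log2 ~ AUC + sex per gene;
sex is coded with male as reference, so the sex coefficient is the
additive female effect and flips sign under the opposite coding (the
coding is configurable precisely because the original coding is
unstated). These models are fitted on transgenic animals only: the
exposure model's published use plots transgenic mice, and wild-type
animals have no exposure. `network_metric_exposure_model()` runs the same
regression on global network summaries; in this design the scientifically
expected outcome is a null result, so the function reports coefficients,
p-values and R² without asserting anything.

The human-module comparison step is reduced to a generic utility
(`module_signature_correlation()`) that correlates mouse deltas against a
user-supplied signature vector; enrichment itself requires external
consortium resources and is out of scope.

## Synthetic cohorts

The generator is first-class, tested code, because every downstream claim
is validated on cohorts with known structure. SUVr tables are multivariate
normal with a block-constant correlation matrix — `within_block_r` inside
planted blocks, `between_block_r` elsewhere — validated for positive
semi-definiteness before sampling (the offending eigenvalue is named on
failure). The block-constant parameterization was chosen over arbitrary
matrices so PSD is checkable analytically and planted values remain
interpretable. Group effects enter means only; correlation structure is
shared across groups by default. Per-group SUVr variances are not reported
anywhere authoritative, so the defaults (marginal SD 0.1 around a mean of
1) are config values a user can and should override. Defaults elsewhere
mirror the study design: 8–12 animals per sex x treatment arm (default
10), 27 regions plus cerebellum, PK sampling at 0.25–24 h with 3 animals
per dose per sex at 10/30/100 mg/kg, lognormal BSV and proportional
residual error (no additive floor — concentrations stay far above any
quantification limit at these doses), and Table-1-scale expression effects
(e.g. 0.00075 log2 units per mg·h/L with a −0.069 female effect).

What the generator does not emulate: PET image noise and registration
error (values are drawn at the regional level), count-level nanoString
technology noise (Gaussian on log2 intensities instead), heavier-tailed
biological outliers, and dose-dependent correlation structure (an override
exists via per-group specs but is off by default). Passing tests therefore
demonstrate correctness of the statistical machinery on well-specified
inputs, not robustness to every pathology of real scanner data.

## Numerical choices and problem sizes

All randomness flows from explicit integer seeds; the pipeline derives
per-stage streams from one master seed and two runs at the same config are
byte-identical (tested). Louvain tie-breaking follows the seeded RNG.
Degenerate inputs — zero-variance regions, graphs with no positive edges,
non-estimable NCA tails, constant-AUC designs, rank-deficient gene models
— degrade to flagged results with warnings rather than errors wherever a
partial result is scientifically meaningful, and to errors naming the
offending element where it is not.

Test and verification sizes were chosen to make Monte-Carlo conclusions
stable: planted-partition recovery uses 200-animal cohorts over 20 seeds;
PK recovery uses 50 replicates of the 18-animal design; OLS calibration
uses 500 null genes; exact-KS verification enumerates all C(8,4)
assignments. The acceptance script reruns all of these from scratch.

## Known limitations

The population PK estimators recover typical values and covariate
decisions, not random-effect variances or shrinkage-based individual
estimates; per-animal exposure uses the typical (covariate-adjusted)
clearance unless individual random effects are supplied. The consensus
null is the marginal permutation law per co-classification entry, not the
joint law across entries — adequate for entry-wise thresholding, but not a
familywise control. The 12-of-27 consensus region list reported on the
original animal data depends on that data and is not reproduced here; the
selection rule, not the list, is the tested artifact.
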