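---
title: "Moderation analysis of ROI-to-ROI functional connectivity with TFNBS"
author: "fcmod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moderation analysis of ROI-to-ROI functional connectivity with TFNBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcmod)
```

## The scientific question

Poor sleep quality and chronic musculoskeletal pain are both common in
older adults and both reshape resting-state brain networks. The analysis
this package implements asks whether chronic pain status *moderates* the
association between self-reported sleep quality (the Pittsburgh Sleep
Quality Index, PSQI, 0--21, scores of 5 or more marking a poor sleeper)
and resting-state functional connectivity (rsFC) between atlas regions
of interest. The motivating finding is a dorsostriatal--sensorimotor
network (putamen and caudate connected to precentral and postcentral
gyri) in which the PSQI slope is positive in pain-free older adults but
negative in those with chronic pain.

## The model

For every tested ROI pair ("edge") $e$, the Fisher-z connectivity
$z_{ie}$ of subject $i$ is modelled by ordinary least squares as

$$ z_{ie} = \beta_0 + \beta_A\,\mathrm{age}_i + \beta_S\,\mathrm{sex}_i
   + \beta_G\,\mathrm{grp}_i + \beta_P\,\mathrm{psqi}_i
   + \beta_{GP}\,\mathrm{grp}_i \times \mathrm{psqi}_i + \varepsilon_{ie}, $$

with sex coded 0 = male / 1 = female and group 0 = no-pain / 1 = pain,
so $\beta_{GP}$ is the change of the PSQI slope induced by chronic pain
-- the moderation effect. A *simple* model (`~ 1 + age + sex + psqi`,
no group terms) supports main-effect comparisons with earlier work.
Covariates enter in raw units; `build_design(center = TRUE)` exists
because centering changes the interpretation of lower-order terms in an
interaction model, and the choice is recorded on the design.

Assumptions: independent subjects, homoscedastic Gaussian errors per
edge, correct linear mean structure. No robust or mixed-effects
variants are offered -- the second-level model is deliberately the plain
per-edge OLS that the field's seed-to-target tools fit.

Effect sizes use Cohen's hierarchical
$f^2 = (R^2_{full} - R^2_{reduced}) / (1 - R^2_{full})$, dropping only
the tested column; 0.02 / 0.15 / 0.35 bound small / medium / large.
Scatter displays use covariate-adjusted values
$z - \hat\beta_A(\mathrm{age}-\overline{\mathrm{age}})
 - \hat\beta_S(\mathrm{sex}-\overline{\mathrm{sex}})$, computed from the
full-model coefficients (the covariates-only alternative is not used;
full-model adjustment keeps the group-wise fitted PSQI lines exactly at
their model-implied slopes).

## Connectivity and preprocessing boundary

The pipeline starts from *denoised* ROI time series; motion correction,
nuisance regression, scrubbing and similar fMRI preprocessing are out of
scope. What remains is: conversion to zero-mean percent signal
($100(x-\bar x)/\bar x$, then demeaning), a zero-phase Butterworth
band-pass (defaults 0.008--0.09 Hz at a 2 s sampling interval, order 4
per edge, forward--backward with odd-reflection padding -- zero phase is
what preserves zero-lag correlation structure), pairwise weighted
Pearson correlation, and the Fisher transform $z = \mathrm{atanh}(r)$.
Weights default to uniform: condition-weighting schemes used by some
denoising suites are not publicly specified, so the weight vector is an
explicit input rather than a reverse-engineered default. Correlations
are clamped to $|r| \le 1 - 10^{-12}$ before the transform so duplicated
columns yield a large finite z, and the matrix diagonal is stored as
`NA`, never 0, so self-connectivity can never leak into statistics.

## Hypothesis-restricted edge masks

Testing all $\binom{132}{2}$ atlas pairs would swamp the signal, so
edges are restricted by seed/target configurations built from two ROI
subsets: *sleep* ROIs (50 parcels implicated by the sleep literature)
and *pain* ROIs (parcels overlapping pain-related coordinates), whose
union holds 63 parcels. S-SP uses sleep seeds against the union, SP-SP
the union against itself, S-A sleep seeds against the whole atlas, SP-A
the union against the whole atlas. Masks are exact deduplicated
unordered-pair enumerations; `halved_pair_count()` additionally reports
the cruder `floor(seeds * targets / 2)` convention seen in published
test counts (for SP-SP both agree: $\binom{63}{2} = 1953$; for S-SP they
differ, 1875 exact vs 1575 halved, and inference always uses the exact
count).

The packaged ROI table is a transcription of the published seed list
over the Harvard-Oxford/AAL parcellation. One transcription ambiguity
deserves a loud note: reading the printed table row by row yields 51
sleep parcels, while the published per-configuration test counts require
exactly 50 (and a 63-parcel union). The shipped table is therefore
*calibrated*: the sleep flag of the midline anterior cingulate row -- a
row that also carries the pain flag, so the union is unaffected -- is
cleared, giving 50/63 and reproducing the printed factor pairs. Any
other single dual-flagged row would have served; users with their own
transcription can load it with `load_roi_table()`.

## Inference

Two complementary corrections are computed over the masked edges.

**BH-FDR.** Benjamini--Hochberg step-up adjustment (via
`stats::p.adjust`) of the per-edge GLM p-values at level $q = 0.05$,
with rejection iff the adjusted p is at most $q$. FDR is applied to the
GLM p-values, not to TFNBS scores.

**TFNBS with permutation FWE.** Threshold-free network-based statistics
removes the arbitrary cluster-forming threshold of network-based
statistics: for thresholds $T_k = k\,dT$ up to the maximum observed
statistic, each supra-threshold edge receives
$M(T) = e(T)^{E} T^{H}$, where $e(T)$ is the *extent* -- the number of
edges -- of the connected component containing it (components are
maximal sets of supra-threshold edges linked through shared ROI nodes).
Scores integrate $M(T)\,dT$ over the grid; defaults $dT = 0.1$,
$E = 0.5$, $H = 2$. Extent is counted in edges because the antecedent
network statistic defines cluster size over connections, and the grid
starts at $dT$ and ends at the smallest multiple of $dT$ covering the
maximum statistic (the integration bounds are otherwise unspecified in
the literature this follows). An isolated edge with statistic $s$ has
the closed-form limit $s^3/3$ as $dT \to 0$, with Riemann error at most
$s^2 dT$ -- a convenient worked example: $s = 3$ gives
$0.001\sum_{k=1}^{30} k^2 = 9.455$.

Familywise error control compares each edge's observed score with the
permutation distribution of the *maximum* score over the masked edges
(so control is per configuration):
$p_{FWE} = (1 + \#\{\max^{(b)} \ge \mathrm{score}\})/(1 + B)$. The
add-one convention keeps permutation p-values valid and bounds them
below by $1/(1+B)$; the default is $B = 1000$ permutations.

Permutations default to the Freedman--Lane scheme: fit the reduced
model without the tested term, permute its residuals among subjects,
add back the reduced fit, refit the full model. This preserves the
nuisance structure (age, sex, main effects) while breaking the tested
association, which a naive permutation of raw rows does not; "permuting
the original data among participants" is ambiguous, so the naive joint
permutation of the (group, psqi) rows is available as
`scheme = "simple"` and every result records its scheme. Two-tailed
analyses threshold $|t|$ against a single null of maxima (no doubling
needed); left-tailed analyses use $-t$, matching the reporting
convention for negative interactions.

## The synthetic-data generator

Subject-level data from the motivating study are available only on
request, so the generator is a first-class module that emulates the
study design: 34 pain / 14 no-pain community-dwelling older adults,
ages $72 \pm 6.78$ vs $74.5 \pm 7.31$ years truncated at the inclusion
bound of 60, PSQI $6.88 \pm 3.46$ vs $3.93 \pm 3.00$ truncated to the
0--21 instrument range (truncation by resampling), sex Bernoulli with
the observed group proportions (26/34, 7/14), and covariates independent
within group (no within-group covariances are reported to emulate).
Truncation matters for moments: with mean 3.93 and sd 3.00 the lower
bound at 0 shifts the realised no-pain PSQI mean upward by about 0.56,
so validation compares sample moments against the truncated law, not
the nominal one.

Connectivity is generated in two modes. *Direct-FC* mode evaluates the
GLM linear predictor per edge and adds i.i.d. Gaussian noise in
Fisher-z space -- the space the model is fitted in -- with an optional
exchangeable across-edge correlation (default off). *Time-series* mode
draws Gaussian series whose population correlation matches a per-subject
target built from the same linear predictor through `tanh`; targets that
are not positive definite are projected by eigenvalue clipping at
$10^{-6}$ and renormalisation, so arbitrary targets are always
factorizable, deterministically.

The planted ground truth mimics the motivating network: six edges
between two striatal and four sensorimotor stand-in ROIs with a
*negative* interaction, default $\beta_{GP} = -0.03$ z-units per PSQI
point against noise 0.15. `synthetic_roi_set()` extends the stand-ins
into a reduced-scale atlas twin: the six planted nodes are the sleep
analogs (their real counterparts are all sleep-flagged parcels), two
further pain-only stand-ins complete an 8-node union, and the standard
mask machinery then yields an S-SP analog of 27 tested edges on a
20-ROI atlas -- the restricted-hypothesis design the power suite runs
under, mirroring how the emulated study tests restricted masks rather
than all pairs. At these settings the per-edge interaction effect is
modest ($f^2 \approx 0.06$, expected $|t| \approx 1.6$), so detection
genuinely relies on the network structure, which is what makes the
fixture informative.

What the generator does *not* emulate: voxel-level fMRI, head motion,
physiological noise, hemodynamic convolution, scanner drift, or
heavy-tailed connectivity distributions. Passing tests therefore show
that the statistics behave correctly under the model's own assumptions;
they cannot certify behaviour under realistic fMRI artefacts.

## Numerical choices

* Threshold comparisons in the TFNBS integration use a $10^{-9}$
  tolerance ($s \ge T_k - 10^{-9}$) because $k \times 0.1$ is inexact in
  binary floating point; without it an edge with $t = 3$ silently misses
  its own top threshold.
* Degenerate edges (residual variance below $10^{-20}$ of the response
  scale) are flagged and carry `NaN` statistics instead of aborting the
  map; exactly-fitted noiseless responses report coefficients but no
  t-statistic.
* OLS uses QR decomposition; the permutation loop uses a precomputed
  projector (three matrix products per permutation across all edges).
* Stage seeds derive from one master seed by a fixed counter scheme, so
  cohort generation, data generation and permutation are independently
  reproducible and all outputs are byte-identical under replay.

## Validation problem sizes

The shipped suites exercise the statistics at sizes chosen to make
Monte-Carlo error small relative to the bands being checked: familywise
calibration uses 500 null datasets (n = 48, 20 ROIs, 200 permutations;
the familywise false-positive rate must land within two Monte-Carlo
standard errors of 0.05), planted-network recovery uses 100 generator
seeds with 1000 permutations each over the S-SP analog mask (at least
80% of seeds must place the smallest familywise p on a planted edge;
observed rates are near 0.88 -- under an unrestricted 190-edge mask the
same effect is found in roughly half the seeds, which is the expected
power cost of abandoning the restricted hypothesis), and the per-edge
type-I error is checked over about a thousand null edges. Component
detection is verified against breadth-first reachability on 200 random
graphs and the BH step-up against exhaustive enumeration on a fixed
p-value grid.

## Known limitations

* The weighted-correlation weights of condition-weighted denoising
  pipelines are not reproduced; uniform weights are a declared
  divergence.
* The t-test variant behind published demographic tables is not always
  stated; both Welch and pooled Student variants are exported and
  reports should name the one used (the package default is Welch).
* Permutation FWE is exact only under exchangeability; Freedman--Lane
  is approximate (and standard) for testing a single term with nuisance
  covariates.
* PSQI is generated as a continuous truncated normal, not an integer
  sum of component scores; only the total score is consumed anywhere.
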