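---
title: "Methods: network dysconnectivity, familial contrasts and clinical subtyping with cereconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network dysconnectivity, familial contrasts and clinical subtyping with cereconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cereconn)
```

## Scope and model

`cereconn` implements a multiscale graph-theoretic analysis of task-based
functional MRI for a four-group familial design in the schizophrenia
spectrum: patients (SCZ), their unaffected siblings (SCZ-SIB), healthy
controls (CON) and siblings of controls (CON-SIB), each scanned under
three N-back working-memory loads (0-back, 1-back, 2-back). The package
covers everything downstream of image preprocessing: it starts from
ROI-by-time BOLD tables and ends at group statistics, a composite
biomarker with ROC evaluation, and clinical-cognitive subtype
stratification. Image-level preprocessing, NIfTI handling and anatomical
atlas coordinates are deliberately out of scope; the atlas is a label
map of 165 ROIs assigned to six canonical networks (DMN, FP, CO, SM,
OCC, CER), in a fixed order so that feature columns are reproducible.

## Connectivity construction

For each subject and condition, the pipeline computes pairwise Pearson
correlations between ROI time series, applies the Fisher r-to-z
transform (with |r| clipped at `1 - 1e-7` so duplicate series cannot
produce infinities), zeroes the diagonal, and thresholds the matrix at
the 85th percentile of the absolute off-diagonal values. Entries at or
above the cutoff keep their signed z value; the rest become zero.

Two numerical conventions are pinned down because they change edge
counts:

* the percentile is the linear-interpolation (type-7) quantile of the
  absolute off-diagonal entries — for a 165-node matrix with distinct
  values this retains exactly 2030 of the 13530 unique edges (15.0%);
* the comparison is inclusive (`|z| >= cutoff`), so a matrix of
  identical magnitudes keeps all of its edges rather than none.

Signed weights are retained by default because the network-level
metrics average weights directly and the sign carries information about
anti-correlation; `signed = FALSE` switches to magnitudes.

Motion quality control follows the framewise-displacement rule: a run
is excluded when at least 20% of its volumes exceed 0.5 mm FD. The
boundary is inclusive (exactly 20% excludes), the conservative reading
of the rule.

## Graph metrics and the 33-feature space

Nodal metrics are the weighted strength `deg_i = sum_j |A_ij|` and the
Onnela geometric-mean local clustering coefficient computed on
`|A|/max|A|`; the Onnela form is the standard weighted default of the
graph libraries this analysis style is built on, and it is bounded in
[0, 1] with isolated and degree-1 nodes mapped to 0.

Network-level features per subject x condition:

* **Inter-network connectivity** `Inter_km`: the mean weight over all
  ordered ROI pairs between networks k and m. Self-pairs (`k = m`) are
  included in the feature set; with a zero diagonal the self-pair value
  equals `Intra_k (|N_k|-1)/|N_k|`, a redundancy accepted so that a
  6-network atlas yields the canonical 21 inter-network features.
* **Intra-network connectivity** `Intra_k`: the mean weight over the
  `|N_k|(|N_k|-1)/2` unique within-network pairs. A published variant
  of this formula mixes the two network subscripts in its denominator
  and double-counts relative to its own `j > i` summation; the mean
  over unique pairs is the only reading under which the quantity is a
  mean connectivity, and is what this package computes.
* **Network degree** `ND_k`: the sum of the five cross-network
  `Inter_km` values (self-pair excluded), the network's total
  integration with the rest of the connectome.

This gives `n(n+1)/2 + 2n` features for n networks — 33 for the
canonical six.

## Familial contrasts

Group comparisons use Welch's unequal-variance t statistic with
Welch-Satterthwaite degrees of freedom and two-sided p-values, plus
Cohen's d with the classic `(n1-1, n2-1)`-weighted pooled SD and no
small-sample correction. Benjamini-Hochberg FDR control is applied
within families; the default family is one correction per condition x
contrast x feature class (e.g. the 21 inter-network tests of one
condition), with coarser family rules available in the configuration.
The four familial contrasts — SCZ vs CON (illness), SCZ vs SCZ-SIB
(clinical state), SCZ-SIB vs CON-SIB (genetic liability), CON vs
CON-SIB (shared environment) — are the default design.

A summary-statistic one-way ANOVA (`anova_eta`) operates on printed
group means, SDs and sizes so that published demographic tables can be
re-analysed without subject-level data; partial eta squared is
`SSB/(SSB+SSW)`. Fisher's exact test uses the standard two-sided
convention (summing hypergeometric probabilities no larger than the
observed table's).

## Composite discrimination

Features significant at FDR q < 0.05 in the chosen contrast and
condition (by default, the inter-network class only) form a composite
score: the sum of each subject's raw feature values weighted by the
absolute Cohen's d of the feature. No z-scoring is applied, keeping the
score on the connectivity scale. ROC analysis uses the Mann-Whitney
rank estimator with midrank tie handling (identical, to numerical
precision, to the trapezoidal area under the empirical curve, which the
test suite asserts on random instances); the 95% CI is a stratified
percentile bootstrap with B = 2000, chosen because it is
distribution-free and reproducible under a seed. The Youden-optimal
threshold maximizes sensitivity + specificity - 1, with ties broken
toward higher specificity (an arbitrary but documented choice). When
the raw AUC is below 0.5 the score orientation is flipped and recorded.

Weights can be estimated in-sample (the default for a real-data
analysis) or planted externally; the validation simulations use planted
weights to avoid the optimism bias of in-sample weighting. For a
two-feature composite with planted standardized shifts delta, unit
variances, correlation rho and weights w, the expected AUC has the
closed form `pnorm(w'delta / (sqrt(2) sqrt(w' Sigma w)))`, which the
simulation reproduces: with shifts (1.547, 1.155) and rho = 0.25 at
group sizes 23 vs 20 the expected AUC is 0.890.

## Clinical-cognitive subtyping

The subtype stream works on a 20-feature clinical-cognitive vector: 2
global symptom scores, 4 positive-symptom domains, 5 negative-symptom
domains and 9 neuropsychological scores. (Some published descriptions
of this feature space quote 19 features while listing 20 variables; the
feature list here is configuration-driven rather than hard-coded, with
all 20 as the default.) Features are min-max normalized to [0, 1],
using theoretical bounds for symptom scales (0-5 item-mean metric) and
the observed complete-case range for cognitive scores; listwise
deletion is applied first and dropped subjects are reported. Missing
values are empty CSV cells, never sentinel numbers, so the
listwise-deletion mask is unambiguous.

Consensus clustering subsamples 80% of subjects without replacement for
100 iterations, partitions each subsample with PAM on Euclidean
dissimilarity, and aggregates co-assignments into a consensus matrix
normalized by co-sampling counts. Final labels come from PAM on
`1 - consensus`. The dimensionality-reduction step used by some
consensus frameworks is exposed as a pluggable embedding function with
identity default: the consensus machinery is embedding-agnostic, and
embedding internals are outside this package's scope. PAM itself is
exact (full enumeration) for tiny inputs, where plain BUILD + SWAP can
demonstrably stall in local optima, and BUILD + SWAP otherwise.

Stability is summarized by PAC (fraction of consensus entries strictly
inside (0.1, 0.9); pairs never co-sampled are excluded and logged),
mean silhouette width, the Calinski-Harabasz index, and mean pairwise
adjusted Rand and Jaccard similarity across iteration partitions
restricted to shared subjects. k is selected by minimum PAC over
k = 2..6. Exact PAC ties are broken toward the largest tied k, i.e. the
finest maximally stable partition. This matters for hierarchically
nested structure: when one cluster lies far from two closer ones, the
coarse two-way merge and the true three-way partition are both
perfectly consensus-stable (PAC exactly 0), and a quality-index
tie-break such as silhouette systematically prefers the coarser merge —
in simulation it under-split a perfectly recoverable three-subtype
structure in 40% of replicate cohorts, while the finest-stable rule
recovers it in all of them without affecting selection on two-cluster
or structureless data (where coarser or finer k are not exact PAC
ties). A null calibration on
structureless inputs showed that subsampled partitions of one fixed
noise dataset retain PAC around 0.4-0.7, while planted-structure data
sits below 0.1; the "no stable k" ceiling therefore defaults to
PAC > 0.3. Non-randomness of a chosen partition is testable by
permutation: each feature column is shuffled independently (destroying
inter-feature structure while preserving marginals), the statistic is
the Calinski-Harabasz index of PAM at k, and the p-value uses the
add-one rule over B = 10000 shuffles by default so it is never zero.

## The synthetic cohort generator

The generator exists so that every stage is testable without imaging
data, and its defaults are the emulated study's conditions: group sizes
23/34/20/21, three conditions, 165 ROIs in six networks (34 DMN, 21 FP,
32 CO, 33 SM, 27 OCC, 18 CER — realistic proportions with synthetic
labels), 137 volumes at TR 2.5 s.

Two modes exist deliberately:

* **Time-series mode** draws each subject x condition series from a
  zero-mean multivariate normal whose correlation matrix has a
  network-block structure (within-network 0.30, between-network 0.10
  baseline), plus `noise_sd^2` diagonal observation noise. Group x
  condition modulations raise cerebellar-sensorimotor and
  cerebellar-cingulo-opercular coupling with load in the non-patient
  groups (peaking at 1-back) and blunt it in patients (worst at
  1-back), mirroring the ordering of the emulated effects: the
  load-dependent cerebellar deficit is largest under moderate load.
  Each subject's true block correlations additionally vary around the
  group level (Gaussian, SD 0.10 by default): real cohorts differ in
  their true connectivity, and without this term between-subject
  variance would be estimation noise alone, producing implausibly
  large standardized group effects. With it, the default full-scale
  simulation yields 1-back cerebellar effect sizes near the calibrated
  values and a composite AUC near 0.9.
  Infeasible block structures are repaired by eigenvalue clipping at
  1e-6 with diagonal re-normalization — the simplest projection with a
  testable minimum-eigenvalue contract. FD traces are log-normal
  (non-negative and right-skewed like real motion), with a configurable
  fraction (default 10%) of high-motion subjects whose traces mostly
  exceed the exclusion threshold.
* **Feature mode** draws the 33-feature vector directly from a
  multivariate normal with unit variances and equicorrelation
  rho = 0.25, with group means offset by planted standardized
  differences. Because variances are 1, planted mean differences are
  Cohen's d values exactly; effects planted on the covariance scale
  would map onto the feature scale nonlinearly, which is why recovery
  targets use this mode. The default effect map plants the calibrated
  1-back deficits (CER-SM d = -1.547 and CER-CO d = -1.155 for SCZ vs
  CON; CER-SM d = -1.086 for SCZ vs SCZ-SIB) along with the smaller
  0-back and 2-back effects. Overlapping contrasts on one feature are
  resolved sequentially — the first constraint anchors both groups, a
  later constraint moves only the not-yet-anchored group — giving
  consistent means (CON = 0, SCZ = -1.547, SCZ-SIB = -0.461 for the
  1-back CER-SM feature). The between-feature correlation of real
  connectivity data is unknown; rho is a free simulation parameter with
  0.25 as a moderate default.

The clinical generator plants a three-subtype structure whose centroids
are midpoints of the emulated profile bands: a near-asymptomatic,
cognitively strong subtype of controls and control siblings (56%/44%
mix); a patient-enriched subtype (79% SCZ, 21% SCZ-SIB) with fluid
cognitive impairment and elevated negative symptoms; and a mixed
intermediate subtype with working memory relatively spared. Mixing
proportions are 36/29/33 out of 98. Within-subtype noise is Gaussian
(SD 0.07 by default) truncated to [0, 1]; symptom columns are emitted
on the 0-5 item-mean scale and cognitive columns already
unit-normalized, with the planted subtype kept in a separate truth
column for evaluation only.

What the generator does **not** emulate: hemodynamic-response
convolution, task-event timing, scanner noise spectra, spatial
autocorrelation between neighboring ROIs, or realistic missingness
patterns. Passing recovery tests therefore demonstrates that the
pipeline's statistics are correct and well calibrated under the assumed
covariance structure — not that the pipeline would reproduce any
particular result on real BOLD data.

## Reproducibility and problem sizes

Every stochastic function takes a seed, and the pipeline fans a single
master seed out to per-stage seeds by a fixed derivation, so stages can
be rerun in isolation and full reruns are byte-identical. Artifacts are
stamped with a hash of the configuration; a stage whose outputs carry
the current hash is reloaded rather than recomputed.

The validation suite uses problem sizes chosen to make Monte Carlo
error small relative to the tolerances under test: effect-size recovery
runs 200 replicate cohorts of 1000 subjects per group (standard error
of the mean estimated d about 0.004); the composite AUC simulation runs
2000 replicates at the emulated group sizes 23 vs 20; subtype recovery
runs 50 replicate cohorts of 98 subjects with 100 consensus iterations
each. Property tests (percentile conventions, AUC identities, FDR
calibration, PAM optimality at small n) run on smaller randomized
instances under fixed seeds.

## Known limitations

* The connectivity stage assumes stationary series and equal-length
  runs; no windowed or dynamic connectivity is provided.
* Thresholding at a fixed percentile guarantees equal edge density
  across subjects but makes absolute edge counts depend on the tie
  structure of the input.
* The composite score's default in-sample weighting is optimistically
  biased; out-of-sample evaluation requires planted or held-out
  weights, which the simulation mode provides.
* Consensus clustering inherits PAM's local-optimum behavior for
  realistic n; only tiny instances are solved exactly.
* The permutation test's column-shuffling null preserves marginals but
  not general dependence; it tests "no multivariate cluster structure",
  not "no structure of any kind".
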