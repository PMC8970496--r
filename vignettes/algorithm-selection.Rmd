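---
title: "Characteristics-based clustering algorithm selection: models, thresholds and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characteristics-based clustering algorithm selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clustselect)
```

## The problem and the model

Selecting a clustering algorithm purely by a quantitative score ignores most
of what makes an algorithm usable for a given analysis: whether it copes
with the dataset's size and dimensionality, with the shapes and sizes of the
clusters the data actually contains, and whether its output format,
parameter burden, determinism and cost fit the analyst's purpose.
`clustselect` makes that reasoning explicit and reproducible in four stages:
a measurement stage, a requirements stage, a qualitative down-selection
against an encoded knowledge base, and a quantitative validation stage.
This vignette records the assumptions, parameter choices and numerical
conventions behind each stage, and what the test suite does and does not
establish.

## Stage 1 — measured characteristics and their thresholds

All thresholds live in `characterize_thresholds()` and are deliberate
operationalizations of qualitative notions; none of them is a measured
constant of nature. Defaults:

| quantity | definition | flag fires when | default |
|---|---|---|---|
| small dataset | sample count | `n_samples <` | 1000 |
| high dimensional | feature count | `n_features >` | 50 |
| uneven sizes | `min(size)/max(size)` | `<` | 0.5 |
| variable density | max/min per-cluster mean NN distance | `>` | 2 |
| non-spherical | max within-cluster `sqrt(lambda1/lambda2)`, 2-PC projection | `>` | 2 |
| outliers | flagged fraction | `>` | 0.02 |

The high-dimension cutoff of 50 features follows the convention in the
cluster-analysis literature that beyond roughly 50 dimensions distance
concentration starts to bite; spectroscopy (hundreds to thousands of
wavenumber points) and expression data (tens of thousands of genes) sit far
above it, classic teaching data far below. The small-dataset cutoff of
1000 samples reflects laboratory spectroscopy practice, where collecting a
sample is expensive and datasets of tens to hundreds of rows are the norm.

**Elongation** is measured in the 2-component PCA score projection rather
than in full space, mirroring how cluster shape is in practice assessed on
score plots; a full-space measure would be dominated by noise directions in
wide data. The projection is centred but *not* scaled — scaling is a
preprocessing decision (see below), not part of measurement.

**Density** is summarized by the mean distance of each point to its nearest
same-cluster neighbour. This is scale-free across cluster sizes, works for
tiny clusters, and scales linearly with an isotropic Gaussian's standard
deviation, so the max/min ratio across clusters recovers the generating
spread ratio. Size-1 clusters are excluded from density statistics.

**Outliers.** A point is an outlier when its within-cluster
nearest-neighbour distance exceeds a robust fence of median + 3 MAD — taken
on the **log** of the distances. The log scale matters: nearest-neighbour
distances are positive and right-skewed, and the symmetric fence on the raw
scale marks 5–7% of the points of a perfectly clean two-dimensional
Gaussian cluster as outliers (verified by simulation), which would make the
2% outlier flag fire on outlier-free data. On the log scale the
false-positive rate is below 1% across the shapes we simulate while points
far outside the cluster envelope are still caught. Points already labelled
with the reserved noise sentinel `0` count as outliers directly.

**Robustness-to-noise is derived conditionally**: it is marked in an
automatic requirement profile only when outliers are present *and* no
single-point cluster exists. An algorithm that discards noise would discard
a genuine singleton class as well, so the two needs are mutually exclusive;
when singletons matter, noise-robustness cannot be demanded.

When labels are unavailable, `estimate_structure_unlabelled()` obtains
provisional labels by cutting a Ward-linkage dendrogram at a user-supplied
`k` and marks the result as estimated. Estimating `k` itself (elbow, gap
statistic) is out of scope: `k` is an input.

## Stage 2/3 — requirements, knowledge base, down-selection

The knowledge base (`inst/extdata/table3.json`) encodes one profile per
algorithm: yes/no/unknown support for eight characteristics, a determinism
level, the required parameter set, and a symbolic complexity class.
Three conventions matter:

- **Unknown is not no.** Gaps in the literature stay `unknown`, score 0,
  and are listed separately in every match report, so a knowledge gap is
  visible rather than silently penalized. The shipped KB keeps its gaps
  (BIRCH density behaviour and determinism, HDBSCAN on uneven sizes, mean
  shift and affinity propagation determinism) as `unknown`, and keeps
  entries verbatim even where they are debatable (minibatch k-means marked
  unsuitable for small data): the KB is an encoding, not a correction.
  Footnoted caveats (order-dependence of density-based results,
  hierarchy-inferable outputs, the single-point-vs-noise trade-off) are
  stored as caveat text on the cell they qualify, not as extra booleans.
- **Complexity classes** are symbolic products over `n`, `k`, `d`, `i` and
  `log n`, ranked by the exponent of `n` first and auxiliary factors
  second: `n < n log n < nkdi < n² < n²·i < n² log n < n³`. Affinity
  propagation is encoded as `n²·i`: its message passing iterates an `n²`
  computation, which places it strictly above plain `n²` — this is exactly
  what lets a "complexity at most n²" constraint keep BIRCH and minibatch
  k-means but exclude affinity propagation and spectral clustering for
  very wide data, and the encoding carries a caveat noting that the class
  is often printed as `n²`.
- **Parameter burden** is a constraint, not a support column. Requirements
  may demand `k` as the sole parameter (`hard_k_only`); asking for
  `parameter_simplicity` or `efficiency` as a *soft* characteristic is an
  error that points to the hard constraints, because neither is a yes/no
  property of the algorithm.

Matching gives weight 1 to required characteristics and 0.5 to "minor"
ones — the deliberately coarse reading of "minor consideration"; a caller
wanting finer control passes explicit weights. The majority rule keeps
algorithms scoring strictly above half the attainable weighted score; with
no soft requirements at all it keeps everything passing the hard
constraints (an empty profile expresses no preference, not a veto). Ties in
the ranking are broken by KB row order, making results reproducible.
For the two spectroscopy scenario presets a pure majority rule admits a
few algorithms beyond the historically chosen subsets (ties on the
comparative matrix are real); the engine therefore reports the full ranking
and leaves the final subset to the caller, and the tests assert that every
historically chosen algorithm clears the majority bar rather than exact set
equality. For the gene-expression and classic-ML scenarios the rule does
pin down the exact sets ({BIRCH, k-means minibatch} and the six *k*-only
algorithms).

## Preprocessing

EMSC fits each spectrum by ordinary least squares against a design of an
intercept, a reference spectrum (default: the dataset mean — the choice is
exposed because no single reference is canonical), polynomial baseline
terms in the wavenumber axis rescaled to `[-1, 1]` (conditioning; raw
wavenumbers in the thousands would make the polynomial columns nearly
collinear), and optional interferent spectra. Defaults: polynomial order 2
(offset, slope, curvature). The correction is exact to machine precision
for any spectrum in the span of the design; a spectrum whose multiplicative
coefficient `|b| < 1e-8` cannot be divided and is returned uncorrected with
a per-spectrum flag. Datasets without a wavenumber axis route to
`standardize()` (per-feature mean 0, sd 1; zero-variance features become
zeros with a warning).

## Runners

The 14 adapters are thin and registered by KB name. Ward/single linkage use
`stats::hclust`, k-means uses `stats::kmeans`, PAM uses `cluster::pam`; the
rest are compact in-package implementations because no R implementations
exist in the supported dependency set. Three are simplified variants and
documented as such: BIRCH (a leader-style clustering-feature pass followed
by Ward merging of subcluster centroids, rebuilt with a coarser threshold
on overflow), HDBSCAN (mutual-reachability single linkage, cut at the
partition maximizing the number of clusters meeting the minimum size, the
rest marked noise), and OPTICS (full reachability ordering with a flat
DBSCAN-equivalent extraction at `eps_cl`). The Gaussian-mixture EM defaults
mirror the common reference configuration — one k-means initialization,
at most 100 iterations, stopping when the mean per-sample log-likelihood
moves by less than `1e-3`, covariance ridge `1e-6` — because the benchmark
comparisons below are against runs at library defaults; a tighter, multi-
restart EM finds higher-likelihood (and on some data higher-scoring)
solutions, and all knobs are exposed as hyperparameters.

Density-based adapters default their radius-like parameters to twice the
mean 5th-nearest-neighbour distance: one NN spacing fragments a Gaussian
cluster, twice that bridges a cluster's interior while staying far below
any reasonable between-cluster gap.

Noise points keep the sentinel `0` in the run result; what they mean for
scoring is decided downstream, never silently.

`tune_to_k()` drives one numeric hyperparameter to a target cluster count
by bisection (the count is assumed monotone in the parameter, as it is for
radii, bandwidths and minimum sizes), falling back to a grid sweep within a
60-evaluation budget. An unattainable count is returned as the closest
achievable one with an explicit `inexact` flag — never a silent success —
and the result is never farther from the target than the initial spec was.

## Stage 4 — validity indices

Homogeneity, completeness and the V-measure are computed from the
class × cluster contingency table with natural-log entropies (the base
cancels in every ratio). Zero-entropy conventions follow the index's
definition: `h = 1` when the class distribution is degenerate, `c = 1` when
the cluster distribution is, `V = 0` when `beta*h + c = 0`. With `beta = 1`
the score is symmetric in its arguments and invariant to relabelling on
either side; it is 1 exactly for a bijective relabelling of the truth and 0
for a clustering carrying no class information.

**Noise convention.** How noise points enter external scoring is genuinely
underdetermined — published benchmark grids note "large number of noise"
without saying whether noise was a cluster, an error, or excluded. Both
supported conventions are explicit: `own_cluster` (default; all noise
becomes one extra cluster) and `singletons` (each noise point its own
cluster, which rewards homogeneity and penalizes completeness). The choice
is recorded in the evaluation table and both can be reported side by side.

The internal indices use their textbook definitions (silhouette with
singleton points scored 0; Davies–Bouldin flagging coincident centroids as
an error; Dunn as min single-linkage separation over max diameter).
`evaluate_grid()` never aborts on a cell: failures, excess noise (> 25%)
and unreached cluster counts degrade to annotations.

## Synthetic data: what it emulates, what it does not

`make_clusters()` draws Gaussian clusters with controllable sizes
(singletons included), per-cluster spread multipliers, anisotropic
covariances, and uniform box outliers labelled `0`. `separation` is the
*minimum pairwise* distance between the default random centres — the
generator rescales the drawn centres to guarantee it, because "separated"
presets must actually be separated for their use as ground truth.
`make_spectra()` builds per-class templates as sums of Gaussian absorption
peaks and distorts each sample with a multiplicative scatter factor, an
order-2 polynomial baseline and white noise — exactly the effect family
EMSC models, which is what makes the variance-reduction property testable.

The four archetype presets mirror the *shapes and qualitative structure* of
the validation families (73 × 3350 unbalanced spectra with a singleton
class; 120 × 448 balanced overlapping spectra; 801 × 20531 balanced
spherical data, subsamplable in features for fast runs; 150 × 4 balanced
blobs). They do not attempt to match real chemical band positions,
correlated noise, instrument drift, or the covariance structure of real
expression data. A green test on synthetic data therefore establishes that
the measurement and scoring machinery recovers known generating structure —
not that any algorithm will reach a particular score on a particular real
dataset.

## Benchmark spot-checks

The packaged classic datasets anchor the quantitative stage against
published reference scores for Ward linkage, k-means and the Gaussian
mixture model. Two preprocessing decisions are deliberate: Iris is
clustered **raw** (its four features share a physical unit, cm, and
standardizing degrades the known cluster geometry), Wine is
**standardized** (its thirteen features span alcohol percentages to
proline in the hundreds). The reference grid's own scaling is not
documented precisely, and these choices reproduce its printed cells within
±0.03 (deterministic runs) and ±0.05 (stochastic runs averaged over 10
seeds), which is the tolerance the acceptance tests assert.

## Known limitations

- The KB covers the 14 encoded algorithms only; there is no mechanism for
  deriving new profiles from literature automatically, and the default KB
  is immutable at runtime (load a modified JSON to change it).
- The simplified BIRCH/HDBSCAN/OPTICS variants trade the full tree
  machinery for transparency; on pathological data they may differ from the
  reference implementations more than the clean-data tests suggest.
- Pairwise-distance computations are dense (`O(n²)` memory), fine for the
  laboratory-scale data this workflow targets, not for `n` in the hundreds
  of thousands.
- Characterization thresholds are conventions. They are exposed precisely
  because a different field may legitimately draw the small/large or
  high-dimensional lines elsewhere.
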