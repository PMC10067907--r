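---
title: "Clustering post-transplant T cell reconstitution trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clustering post-transplant T cell reconstitution trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trecon)
```

## The problem

After allogeneic hematopoietic cell transplantation (HCT), T cell
compartments rebuild over the first year at rates and to levels that
differ widely between patients, and that heterogeneity carries
prognostic information: patients whose activated and conventional T
cell pools recover briskly tend to fare better than patients with flat,
low trajectories. Flow-cytometry monitoring, however, yields sparse and
irregular multivariate series — a handful of samples per patient,
loosely clustered around months 1, 3, 6, 9 and 12, with subsets
reported as fractions of the lymphocyte gate. `trecon` turns such data
into patient-level reconstitution phenotypes: it filters and
interpolates the series, clusters patients by the shape and level of
their four-subset trajectories using dynamic time warping (DTW), and
links the resulting clusters to overall survival and to relapse and
non-relapse mortality (NRM) as competing risks.

## The procedure

`trajectory_clusters()` runs five stages.

**Eligibility.** A patient enters the analysis with (1) at least three
distinct sampling days within the first 12 months and (2) a first
sample no later than day +45. Both bounds are inclusive; excluded
patients are logged with every rule they violate. The first rule
guarantees that a trajectory (not a point) is observed; the second
anchors all series near the transplant so that warped alignments
compare comparable phases. The filter necessarily conditions on early
survival: patients who die before their third sample cannot be
clustered, which is a selection effect any user correlating clusters
with outcomes should keep in mind.

**Counts and interpolation.** Each subset's absolute count is its
lymphocyte fraction times the absolute lymphocyte count of the same
date. Series are interpolated onto a common weekly grid
(`seq(0, 365, 7)`), clipped to each patient's observed support — we do
not extrapolate beyond the first or last sample, so series lengths
differ and the distance stage must handle that (DTW does). Seven days
is finer than any realistic sampling interval, so interpolation error,
not grid resolution, limits fidelity; a coarser grid mainly speeds up
DTW. Duplicate same-day measurements are averaged. The default
interpolant is linear; `interpolation = "smooth"` blends it with a
monotone (Fritsch–Carlson) cubic Hermite interpolant whose derivative
construction clamps overshoot, so smoothed curves keep the same
monotone segments and never leave the envelope of the bracketing
observations. The `smoothing` weight interpolates continuously between
the two, and both reproduce the observations exactly.

**Distances.** The dissimilarity between two patients is dependent
multivariate DTW: one warping path shared by all four subsets, with
local cost the L1 (default) or L2 norm of the 4-vector difference, the
symmetric three-way step pattern without weights, and no path-length
normalisation. The shared path reflects that all four subsets are
measured on the same blood sample — time distortion is a property of
the patient, not of a subset. Raw counts are the default scale;
per-subset z-scoring (pooled over the cohort) is offered as a grid
axis because subset abundances differ by orders of magnitude and raw
distances are otherwise dominated by the largest compartment. The
Sakoe–Chiba band is implemented as a slanted corridor around the
alignment diagonal with half-width `window_frac` times the longer
length, floored at one cell (scaled up with the corridor's slope when
lengths differ strongly) so that an admissible path always exists;
widening the window can therefore only decrease a distance.

**Clustering and model selection.** Two centroid methods are offered:
partition around medoids (PAM) on the precomputed distance matrix, and
k-partitioning with DTW barycenter averaging (DBA) prototypes. PAM is
the classic deterministic BUILD + SWAP: greedy seeding, then
best-improvement medoid/non-medoid exchanges until no swap lowers the
total within-cluster distance, ties always broken by the lowest
patient index. That local search matches exhaustive medoid search on
data with genuine cluster structure, but on unstructured instances it
can (like any PAM implementation, including `cluster::pam`) stop in a
swap-local optimum slightly above the global one; the test suite
checks local optimality everywhere and global optimality on structured
fixtures. DBA follows the classic formulation: members are aligned to
the current barycenter with squared-Euclidean local cost and each
barycenter point is replaced by the mean of the member points aligned
to it, which makes the alignment objective provably non-increasing;
the partitional wrapper alternates nearest-centroid assignment under
the same squared cost with barycenter refinement, warm-starting each
centroid from its previous value. Configurations are scored by the
silhouette coefficient on the full cohort and probed for robustness by
re-clustering ten random 80% subsamples; the reference grid crosses
centroid method (PAM, DBA), `k` (2–4), window fraction (0.05, 0.10,
0.20) and normalization (raw, z-scored) into 36 configurations, every
axis overridable. The working configuration is the highest-silhouette
one whose smallest cluster holds at least 10% of patients and whose
subsampling silhouette variance is at most 0.01 (falling back, with a
warning, to the best silhouette when nothing qualifies). The 10%
balance floor and the 0.01 variance ceiling are deliberate defaults on
scales the silhouette itself does not fix; both are exposed as
arguments. "Ten random subsamples" rather than ten disjoint folds is a
deliberate reading of resampling-based validation: the readout is the
variance of the silhouette across replicates, which repeated
subsampling estimates directly.

**Outcomes.** Overall survival is compared across clusters by
Kaplan–Meier estimation and the log-rank test; relapse and NRM are
treated as competing events and compared by the Aalen–Johansen
estimator and Gray's K-sample test (ρ = 0 weighting, the conventional
default). Both tests also run in a permutation mode that shuffles
cluster labels and reports a Monte-Carlo p-value — useful at the small
cohort sizes where the chi-square reference is doubtful. These are
routine estimators, so they are delegated to `survival::survfit` /
`survdiff` and `cmprsk::cuminc` behind the package's interface; the
test suite pins them to closed forms (ECDF reduction, probability
conservation, competing-exponential CIFs) rather than trusting either
package blindly.

Two fitted models (for instance the "GVHD-associated" panel of
regulatory, HLA-DR-activated, TCRαβ and TCRγδ T cells against the
"broad spectrum" panel of helper, naive helper, cytotoxic and memory
cytotoxic T cells) are compared with `cluster_agreement()`, which
matches cluster labels by exact optimal assignment on the confusion
matrix and reports the fraction of shared patients on the matched
diagonal plus the identities of re-allocated patients; the adjusted
Rand index is available as a chance-corrected alternative.

## The synthetic cohort generator

No patient-level data ship with the package; `generate_cohort()`
emulates the study design so that every stage can be validated against
a known truth. Per patient it draws a latent reconstitution phenotype
(two clusters, 65/35 by default), a visit schedule of nominal days 30,
90, 180, 270, 365 jittered by N(0, 10 d), truncated to [14, 365], with
10% per-visit dropout, and absolute counts following cluster-specific
logistic recovery curves `A / (1 + exp(-r (t - m)))` under
multiplicative lognormal noise (CV 0.25). Cluster 1 recovers slowly to
low plateaus, cluster 2 roughly 3–4× higher and earlier — an effect
size chosen to represent the clearly separated phenotypes the method
is meant to resolve. Outcomes are independent cause-specific
exponentials (defaults: cluster 1 ≈ 25%/year relapse and 23%/year NRM;
cluster 2 ≈ 7% and 2%) with administrative censoring at day 365; the
first latent event wins. For overall survival, NRM counts as death and
relapse is non-fatal by default, with an optional post-relapse death
hazard per cluster, since the clinical linkage between relapse and
death is a modelling choice, not an algorithmic one. Measurements
stop at death, as in real monitoring, so the eligibility filter's
survivorship conditioning is reproduced rather than hidden. Noise is
multiplicative lognormal because counts are positive and
right-skewed; visit days are re-drawn when jitter collides two visits
on one day.

What the generator does *not* emulate: gating error and panel drift,
correlated measurement noise across subsets sampled on the same day
(beyond the shared lymphocyte count), GVHD episodes, infections or
treatment changes that bend trajectories mid-course, and informative
(outcome-dependent) visit scheduling. Passing the recovery tests
therefore shows that the pipeline resolves level-and-shape phenotypes
of the stated effect size under sparse sampling and survivorship — not
that it would resolve subtler structure in real cohorts.

## Numerical choices and degenerate inputs

* DTW cost accumulation and the band are exact dynamic programming in
  compiled code; ties in the backtrack prefer the diagonal step.
* The DBA alignment objective uses squared-Euclidean local cost even
  when the distance grid axis says L1, because only the squared
  formulation carries the monotone-objective guarantee; silhouettes
  are always computed from the configuration's own (L1/L2) distance
  matrix.
* An emptied DBA cluster is re-seeded with the series farthest from
  every centroid and logged.
* Silhouette: members of singleton clusters score 0, as does the 0/0
  case of identical points; a single non-empty cluster is an error.
* Patients with a single observation cannot be interpolated and are
  excluded upstream with a logged reason; an all-censored outcome set
  yields flat cumulative incidences rather than an error.
* Mann–Whitney comparisons use exact enumeration up to a combined
  n of 12 without ties, and the tie-corrected normal approximation
  (without continuity correction) otherwise.
* All randomness (generator, subsampling, DBA initialisation,
  permutation tests) flows from explicit integer seeds; equal seed and
  input give bit-identical results, including the files written by
  `run_pipeline()`.

## Problem sizes used in the validation suite

The packaged tests validate DTW against exhaustive path enumeration
(series up to length 6), PAM against exhaustive medoid search (n ≤ 8),
silhouettes against a double-loop oracle, and the full pipeline on
generated cohorts of 150 patients across 20 seeds, where the
configuration search selects k = 2 and recovers the latent partition
with median adjusted Rand index 1.0. Test calibration uses 2000 null
simulations per test and 5000 permutations; these sizes keep the whole
suite within minutes on a single core while leaving Monte-Carlo error
well below the asserted margins.

## Limitations

DTW distances are not metric (the triangle inequality can fail), so
silhouette values — which only need a dissimilarity — are comparable
within one configuration grid but not against Euclidean baselines.
The configuration grid shipped here is a declared reference, not an
exhaustive search space; silhouettes from different grids or step
patterns are not directly comparable. Cox and Fine–Gray regression are
intentionally out of scope: the package's outcome surface is the
K-sample comparison (log-rank, Gray), and effect-size estimation
should be done in dedicated survival tooling on the exported cluster
assignments.
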