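# trecon

Time-series clustering of post-transplant immune reconstitution.

After allogeneic hematopoietic cell transplantation (HCT), T cell
compartments rebuild at rates and to levels that differ widely between
patients, and those differences track clinical outcome. The raw data are
unfriendly, though: a handful of flow-cytometry samples per patient,
irregularly placed around months 1, 3, 6, 9 and 12, each subset reported
as a fraction of the lymphocyte gate. `trecon` is for transplant
immunologists and biostatisticians who want to turn such sparse
longitudinal panels into patient-level reconstitution phenotypes and ask
whether those phenotypes separate survival, relapse and non-relapse
mortality (NRM).

## What it computes

Given long-format measurements (patient, day, subset, fraction,
lymphocyte count) for a four-subset T cell panel, the pipeline

1. filters patients (≥ 3 sampling days within 12 months, first sample
   ≤ day +45), converts fractions to absolute counts
   (count = fraction × ALC), and linearly interpolates each series onto
   a weekly grid clipped to its observed support;
2. computes dependent multivariate dynamic time warping distances
   between patients,

   D(i,j) = c(i,j) + min{ D(i−1,j), D(i,j−1), D(i−1,j−1) },

   with c the L1/L2 norm of the 4-vector difference and a slanted
   Sakoe–Chiba band;
3. clusters patients by partition around medoids (PAM) or DTW barycenter
   averaging (DBA) across a 36-point configuration grid
   (method × k ∈ {2,3,4} × window ∈ {0.05, 0.10, 0.20} × raw/z-scored),
   scoring each configuration by the silhouette coefficient
   s(i) = (b−a)/max(a,b) and by its variance under ten 80% subsamples;
4. selects the best balanced, robust configuration and compares clusters
   by Kaplan–Meier/log-rank for overall survival and by
   Aalen–Johansen/Gray's test for relapse and NRM as competing risks;
5. optionally compares two clustering models (e.g. a "GVHD-associated"
   vs a "broad spectrum" subset panel) by optimal label matching and the
   adjusted Rand index.

A synthetic-cohort generator with known latent phenotypes and
cluster-linked competing-risk outcomes stands in for patient data, so
every stage is testable offline.

## Worked example

```r
library(trecon)

cohort <- generate_cohort(generator_config(
  n_per_cohort = c(MUD_ATG = 80), seed = 42))
fit <- trajectory_clusters(cohort$measurements, cohort$outcomes,
                           seed = 42)
fit
```

```
Trajectory clustering fit ('gvhd_associated' panel, linear interpolation)
  patients clustered: 66 (14 excluded)
  selected configuration: 1_13 (PAM, k = 2, window 0.2, raw)
  silhouette: 0.829 (resampling variance 1.8e-05)
  cluster sizes: 40 / 26 
Cluster-outcome association (n = 66)
  OS log-rank p:       0.251 
  Gray's test relapse: 0.00354 
  Gray's test NRM:     0.251 
  cluster 1: 1-year OS 95.0%
  cluster 2: 1-year OS 100.0%
```

Of 80 simulated patients, 66 pass the eligibility filter (the rest
sampled too sparsely, started too late, or died early — see
`fit$exclusions`). The search selects a two-cluster PAM configuration
with a high, resampling-stable silhouette; the clusters split 40/26.
Cluster 2 — the fast, high-plateau reconstitution phenotype — has fewer
relapses (Gray's p = 0.0035) at this cohort size, while the OS and NRM
contrasts do not reach significance with only 66 patients. The
assignment recovers the generator's latent phenotype exactly here:

```r
truth <- setNames(cohort$truth$true_cluster, cohort$truth$patient_id)
adjusted_rand(fit$labels, truth)
#> [1] 1
```

`summary(fit)` prints the full configuration ranking, `plot(fit)` draws
per-subset trajectories coloured by cluster with prototypes overlaid,
and `run_pipeline()` executes the same workflow from a YAML config,
writing assignment, ranking and report files.

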