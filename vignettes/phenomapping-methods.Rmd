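---
title: "Methods: ECG phenogrouping of HFpEF cohorts and cardiorenal risk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG phenogrouping of HFpEF cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Heart failure with preserved ejection fraction (HFpEF) and chronic
kidney disease (CKD) interact bidirectionally: impaired diastolic
filling degrades renal perfusion, and declining renal function loads
the heart. `ecgphenomap` asks whether unsupervised phenogroups derived
from the electrocardiogram alone stratify CKD risk, using serum
creatinine (µmol/L) as the renal proxy. Four partitions of the same
patient set are built and compared:

1. **Creatinine baseline** — 1-D Ward hierarchical clustering of
   creatinine itself. Since no ground-truth CKD grouping exists in an
   unsupervised setting, this partition is the reference that the
   ECG-based partitions are scored against.
2. **All-feature k-means** — k-means on the 15 standardized tabular ECG
   variables (ventricular rate, PR interval, QRS duration, QT
   corrected, P/R/T axes, QRS count, Q/P onset and offset, T offset,
   atrial rate, QT interval).
3. **Minimal-set k-means** — k-means restricted to the features that a
   three-method consensus selects; with the default synthetic cohort
   this is the PR interval and QRS duration.
4. **DTW + Ward** — Ward hierarchical clustering on an all-pairs
   dynamic time warping (DTW) distance matrix over the raw lead-II
   waveforms.

Partitions are compared with the co-cluster Jaccard score
(`|pairs co-clustered in both| / |pairs co-clustered in either|`), the
Rand and adjusted Rand indices, and silhouette widths; per-cluster
creatinine differences are tested by one-way ANOVA with the classical
`(k - 1, n - k)` degrees of freedom; robustness is measured by
re-clustering subsets drawn without replacement and comparing each
replicate with the full-data partition restricted to the sampled items.

## The DTW distance

For sequences `x (1..n)` and `y (1..m)` the implementation computes the
cumulative alignment cost

```
D[i, j] = cost(x_i, y_j) + min(D[i-1, j], D[i, j-1], D[i-1, j-1])
D[1, 1] = cost(x_1, y_1)
```

and returns `D[n, m]`. Design choices, each tested:

* **Point cost.** The Euclidean distance between two scalar samples is
  their absolute difference; a squared-cost mode is provided because
  conventions differ. Default: absolute.
* **No normalization, no path weighting.** Raw amplitudes are compared
  and the total cost is not divided by path length, so distances grow
  with sequence length; all signals in one matrix should share a
  length and sampling rate. A z-score mode exists behind
  `dtw_config(normalization = "zscore")`.
* **Sakoe-Chiba band.** `band_radius` limits `|i - j|`; the radius is
  widened to at least `|n - m|` so the terminal cell stays reachable.
  With a radius of at least the sequence length the banded result
  equals the full dynamic program exactly.
* **Exactness.** The kernel (Rcpp, two-row sweep) is tested against an
  exhaustive enumeration of all monotone alignment paths for sequences
  up to length 6 — about a thousand random pairs per run.
* **Parallelism contract.** Each of the `n(n-1)/2` pairs is an
  independent computation, so the pairwise matrix is bitwise identical
  for any worker count and any evaluation order.

Ward linkage (`hclust(method = "ward.D2")`) formally assumes
squared-Euclidean geometry; a DTW matrix is not Euclidean, so applying
Ward to it is a pragmatic choice made for comparability with k-means,
not a metric guarantee. An average-linkage mode is provided as the
metric-agnostic alternative. The 1-D creatinine baseline uses the same
linkage, where Ward *is* proper; contiguity of the resulting intervals
on the creatinine axis is asserted at run time.

## Feature selection consensus

Three rankings are intersected at depth five:

* **Significance** — per-feature Welch t statistics between CKD-positive
  and CKD-negative patients. The p-value is one-tailed in the direction
  of the observed difference, which is an exploratory ranking device:
  because the tail is chosen after seeing the data, that directional
  p-value has twice the nominal size. The `significant` flag therefore
  compares the doubled (two-sided-equivalent) p-value against `alpha`,
  which keeps the flag's type-I error at the nominal 5% — verified by a
  permutation calibration test.
* **Resampled PCA** — 50 simulations; in each, an 80% subsample is
  standardized and decomposed; each of the first five principal
  components is assigned to the feature with the largest absolute
  loading (ties toward the lower column index), and a feature's score
  is the mean explained-variance ratio of the components assigned to
  it. Standardization is essential: the raw variables span four orders
  of magnitude (counts vs milliseconds vs degrees).
* **Lasso** — L1-penalized logistic regression of the CKD flag on the
  standardized features, with the penalty bisected (at most 60
  iterations) until exactly `target_k` coefficients are nonzero, or the
  closest achievable count is reported. A subsample probe flags
  selections whose membership is unstable. A continuous-creatinine
  response can be substituted by passing the creatinine vector through
  a gaussian-family fit upstream; the binary flag is the default
  because the clinical contrast of interest is CKD-positive versus
  CKD-negative.

The consensus is the intersection of the three top-5 lists, ordered by
mean rank; an empty intersection yields an empty set with a warning
rather than an error, and the pipeline then falls back to the
PR-interval/QRS-duration pair.

## The synthetic cohort

Access-restricted registry data cannot ship with a package, so every
downstream stage is exercised against a generator with planted ground
truth. What it emulates:

* **Five morphology phenogroups.** Group-mean profiles follow mutually
  orthogonal contrasts across groups — heart rate linear
  (63–87 bpm), PR interval quadratic (136–184 ms), QRS duration quartic
  (71–131 ms) — so that rate, PR and QRS each anchor their own
  principal component instead of collapsing into a single severity
  axis. QT is QRS plus an independent JT segment (~310 ms); QT
  corrected is Bazett-derived and therefore partially rate-driven.
  Wave amplitudes differ between groups, so waveform morphology
  separates even groups whose PR/QRS profiles coincide.
* **A planted cardiorenal link.** Group creatinine means couple to the
  group's PR and QRS deviations (0.55 µmol/L per ms each), plus a
  cubic-contrast component that splits the PR/QRS twin groups and a
  small linear term chosen so that the binary CKD flag
  (creatinine > 110 µmol/L, prevalence ≈ 0.4) is balanced with respect
  to heart rate. Consequence: CKD is predictable from PR and QRS but
  not from rate, while the creatinine baseline partition still
  separates groups that only the full waveform (not the PR/QRS plane)
  can distinguish — which is exactly the regime in which DTW
  clustering should, and in the tests does, align best with the
  creatinine baseline.
* **Waveforms.** Each beat is a sum of Gaussian bumps (P, Q, R, S, T).
  A wave spanning `[onset, offset]` has its bump scaled so the 5%-of-
  peak crossing lands exactly on the planted onset; the delineator uses
  the same 5% convention, so on noiseless input planted fiducials are
  recovered to within one sample period. White Gaussian noise
  (default sd 0.02 mV) is added; baseline wander is deliberately absent
  so that the raw-amplitude DTW comparisons are not confounded by
  drift.
* **Tabular features.** The per-record feature table carries the
  planted values plus realistic measurement noise: interval reads are
  clean (3–4 ms), the QT family is noisy (16 ms), and the fiducial
  landmarks noisier still (10–25 ms), mirroring how delineation
  accuracy degrades from R-peak-anchored intervals to P/T boundaries.
  This noise asymmetry is also what makes the tabular clusters weaker
  than the waveform clusters, as in real extracted-parameter tables.
* **Labs and eligibility.** LVEF ~ N(60, 5) %, NT-proBNP log-normal
  (median ≈ 1500 pg/mL), 2–4 laboratory panels per patient around a
  diagnosis date, and about five ECGs per patient
  (`1 + Poisson(mean - 1)`), so roughly 90% of patients pass the HFpEF
  filter (LVEF ≥ 50%, NT-proBNP > 450 pg/mL, HF flag).

What it does **not** emulate: 12-lead geometry (electrical axes are
planted tabular values and passed through extraction, since axes are
not derivable from a single lead), arrhythmia, ectopy, baseline wander,
muscle artifact, medication effects, or longitudinal disease
trajectories. Passing tests therefore demonstrate correct mechanics
and recoverability under the planted model, not clinical performance
on real ECGs; the delineator in particular is a 5%-threshold method
adequate for the synthetic morphology, with a pluggable interface
where a Pan-Tompkins-style detector would be substituted for clinical
signals.

## Numerical and procedural choices

* **HFpEF filter.** LVEF is compared with `>=` and NT-proBNP strictly
  with `>`. "Six months" is ±183 days, inclusive, anchored on the
  diagnosis date *or* any qualifying NT-proBNP laboratory date (either
  anchor suffices). Each retained ECG is paired with the creatinine
  value nearest in time within the same window; ties break toward the
  earlier laboratory. Tightening any threshold can only shrink the
  selection, and filtering is idempotent — both are property-tested.
* **QT correction.** Bazett (`QT / sqrt(RR in s)`); the conventional
  default where no formula is named.
* **Fiducial conventions.** 0-based sample indices, half-open
  `[onset, offset)` intervals, milliseconds derived via the sampling
  rate; per-record fiducial features are beat averages expressed in a
  400 ms pre-R representative-beat window.
* **R-peak detection.** Local maxima above half the global maximum
  with a 200 ms refractory window, after a 6 ms boxcar smoother.
  Records with fewer than two delineable beats raise a classed
  condition (`ecgphenomap_unusable_record`) rather than disappearing.
* **k-means.** 10 restarts, 300 iteration cap, best inertia kept,
  deterministic under the seed.
* **Elbow curves.** WCSS is k-means inertia in feature space; on a
  distance matrix it is the within-cluster sum of squared distances to
  the cluster medoid (means of warped time series are undefined
  without barycenter averaging, which is out of scope). The suggested
  k sits at the last large drop before the curve flattens — the
  maximum ratio of successive WCSS drops — because the raw
  second-difference rule systematically favours small k on
  geometric-decay curves. A suggestion whose peak ratio is below 3 is
  flagged low-confidence. The suggestion is advisory; the pipeline
  default is k = 5 throughout.
* **Degenerate conventions.** Jaccard of two all-singleton partitions
  is reported as 1 with a `degenerate` flag; singleton clusters get
  silhouette 0; an ANOVA with zero within-cluster variance reports an
  infinite F with a flag; a constant feature column yields missing
  (not zero) correlations.
* **Bootstrap stability.** Subsets are drawn *without* replacement
  (the reference design resampled subsets, not bootstrap-with-
  replacement draws); the reference partition is the full-data
  partition restricted to the sampled items. Post-hoc pairwise
  contrasts after a significant ANOVA use Welch t-tests with
  Bonferroni flags.

## Problem sizes

The package's default run (`run_config()`) uses 150 patients, 1000-
sample strips at 100 Hz (a 10 s rhythm strip at reduced resolution),
a band radius of 50 samples, and k = 5: an all-pairs matrix of ~11,000
DTW computations that completes in seconds with the compiled kernel.
The same machinery scales to 5000-sample 500 Hz records
(`n_samples = 5000, sampling_rate_hz = 500`) and larger cohorts —
cost grows linearly in the number of pairs and in `n_samples x band`.
Calibration checks run 1000–2000 simulated nulls; recovery checks run
5–10 independently seeded cohorts.

## Known limitations

* Ward on a non-Euclidean DTW matrix (see above) — inherited by
  design, flagged in the documentation.
* The delineator is built for the generator's bump morphology; real
  ECGs need a clinical-grade detector behind the same interface.
* DTW distances are length-sensitive because no path normalization is
  applied; comparing records of different durations is not meaningful
  under the default configuration.
* Electrical axes are pass-through values, never computed.
* Survival analysis (Cox, Kaplan-Meier) is out of scope.
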