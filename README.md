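# ecgphenomap

Unsupervised phenogrouping of heart-failure-with-preserved-ejection-
fraction (HFpEF) patients from lead-II electrocardiograms, with
creatinine-based assessment of chronic-kidney-disease (CKD) risk
stratification.

## Who this is for

Researchers exploring cardiorenal risk in HF cohorts who want to
compare, on one patient set, four routes to a phenogroup partition:

* **DTW + Ward** — Ward hierarchical clustering on an all-pairs
  dynamic time warping distance over the raw waveforms,
* **all-feature k-means** — k-means on the 15 standard extracted ECG
  variables (rates, intervals, axes, fiducials),
* **minimal-set k-means** — k-means on the features selected by a
  three-method consensus (resampled PCA, L1 logistic regression,
  one-tailed Welch tests), which under the planted generative model is
  the PR interval + QRS duration pair,
* **creatinine baseline** — 1-D Ward clustering of serum creatinine,
  the reference partition for CKD risk.

## The core statistic

The DTW distance between waveforms `x` and `y` is the minimum
cumulative point cost over monotone alignments,

    D[i,j] = c(x_i, y_j) + min(D[i-1,j], D[i,j-1], D[i-1,j-1]),
    D[1,1] = c(x_1, y_1),   dtw(x, y) = D[n, m],

with `c(a, b) = |a - b|` (squared-cost optional), no amplitude
normalization and no path-length weighting, optionally constrained to a
Sakoe-Chiba band. The kernel is compiled (Rcpp) and tested for exact
agreement with brute-force alignment-path enumeration. Partitions are
compared by the co-cluster Jaccard score

    J(A, B) = |pairs co-clustered in both| / |pairs co-clustered in either|,

the Rand/adjusted Rand indices and silhouettes; per-cluster creatinine
enrichment is tested by one-way ANOVA with `(k-1, n-k)` degrees of
freedom; stability by re-clustering subsets against the full-data
partition. A synthetic-cohort generator with five planted morphology
phenogroups and a planted PR/QRS -> creatinine link makes the whole
pipeline testable without restricted registry data.

## Worked example

```r
library(ecgphenomap)
rep <- run_all(run_config(seed = 7))   # 150 synthetic patients, k = 5
print(rep)
```

```
<phenomap_report: 133 patients, k = 5, seed = 7>
  minimal feature set: pr_interval_ms, qrs_duration_ms
  Jaccard vs creatinine baseline:
    dtw            0.288
    all_features   0.220
    minimal_set    0.201
  ARI vs planted archetypes:
    dtw            1.000
    all_features   0.812
    minimal_set    0.495
```

133 of 150 generated patients pass the HFpEF filter (LVEF >= 50%,
NT-proBNP > 450 pg/mL, HF flag) and have a creatinine value within the
±183-day window of one ECG. The waveform (DTW) partition recovers the
five planted phenogroups exactly (adjusted Rand 1.0 against the
generative truth) and aligns best with the creatinine baseline
(Jaccard 0.288), while the tabular partitions recover the groups only
partially and align less well — the ordering the method is designed to
expose. The selection consensus lands on exactly the planted minimal
set:

```r
top_features(rep$rankings$pca)
#> "qrs_duration_ms" "ventricular_rate_bpm" "pr_interval_ms" ...
rep$minimal_set
#> "pr_interval_ms" "qrs_duration_ms"
```

and the creatinine enrichment across DTW clusters is decisive:

```r
rep$enrichment$dtw
#> F = 171.17 (4, 128), p = 2.3e-50
#>  cluster  n   mean    sd
#>        0 27   98.0   9.9
#>        1 27  107.7   8.5
#>        2 25  117.9   7.0
#>        3 28  114.5   9.6
#>        4 26   62.6   8.1
```

A thin CLI wrapper lives at `inst/cli/phenomap.R`
(`Rscript phenomap.R run-all --seed 1 --outdir out/`).

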