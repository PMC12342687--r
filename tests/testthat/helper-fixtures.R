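# Small reusable fixtures, built in code at test time.

default_wave_params <- function(pr = 160, qrs = 90, qt = 400, rate = 60) {
  list(pr_ms = pr, qrs_ms = qrs, qt_ms = qt, rate_bpm = rate,
       amplitudes_mv = c(P = 0.15, Q = -0.1, R = 1.1, S = -0.25,
                         T = 0.35))
}

# one small tabular cohort shared across test files (no waveforms)
tab_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(300, seed = 2024, signals = FALSE)
    cache
  }
})

# per-patient feature table (first record per patient) + CKD labels
patient_features <- function(cohort) {
  feats <- cohort$features[!duplicated(cohort$features$patient_id), ]
  list(features = feats,
       ckd = cohort$truth$ckd[match(feats$patient_id,
                                    cohort$truth$patient_id)],
       archetype = cohort$truth$archetype_id[
         match(feats$patient_id, cohort$truth$patient_id)])
}
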