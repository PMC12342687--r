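test_that("delineation recovers planted fiducials on noiseless input", {
  set.seed(3)
  s <- synthesize_ecg(default_wave_params(), n_samples = 5000,
                      sampling_rate_hz = 500, noise_sd = 0)
  d <- delineate(s)
  expect_equal(attr(d, "n_r_peaks"), 10L)
  planted <- s$fiducials[d$beat, ]
  for (col in c("r_peak", "qrs_onset", "qrs_offset", "p_onset",
                "p_offset", "t_offset"))
    expect_lte(max(abs(d[[col]] - planted[[col]])), 1)
  # planted PR recovered within 2 ms
  pr_ms <- mean(d$qrs_onset - d$p_onset) * 2
  expect_lt(abs(pr_ms - 160), 2)
})

test_that("unusable records are flagged, not silently dropped", {
  expect_error(delineate(rep(0, 1000), sampling_rate_hz = 500),
               class = "ecgphenomap_unusable_record")
  expect_error(delineate(rep(1, 1000), sampling_rate_hz = 500),
               class = "ecgphenomap_unusable_record")
  # a single beat is not enough
  set.seed(4)
  s1 <- synthesize_ecg(default_wave_params(), n_samples = 500,
                       sampling_rate_hz = 500, noise_sd = 0)
  expect_error(delineate(s1), class = "ecgphenomap_unusable_record")
})

test_that("extracted features match their definitions", {
  set.seed(5)
  s <- synthesize_ecg(default_wave_params(), n_samples = 5000,
                      sampling_rate_hz = 500, noise_sd = 0)
  f <- extract_features(s, planted_axes = list(p_axis_deg = 44,
                                               r_axis_deg = 30,
                                               t_axis_deg = 41))
  expect_equal(f$ventricular_rate_bpm, 60, tolerance = 0.5 / 60)
  expect_equal(f$qrs_count, 10L)
  expect_equal(f$atrial_rate_bpm, f$ventricular_rate_bpm,
               tolerance = 0.02)
  # Bazett identity: at RR = 1 s, QTc equals QT
  expect_equal(f$qt_corrected_ms, f$qt_interval_ms, tolerance = 0.005)
  expect_equal(f$qt_interval_ms, 400, tolerance = 0.01)
  expect_equal(f$p_axis_deg, 44)
  # fiducial invariants
  expect_lt(f$p_onset_ms, f$p_offset_ms)
  expect_lt(f$q_onset_ms, f$q_offset_ms)
  expect_lte(f$q_offset_ms, f$t_offset_ms)
})

test_that("interval features are invariant to a sub-beat circular shift", {
  set.seed(6)
  s <- synthesize_ecg(default_wave_params(), n_samples = 5000,
                      sampling_rate_hz = 500, noise_sd = 0)
  shift <- 180  # samples, < 1 beat
  xs <- c(s$samples[(shift + 1):5000], s$samples[1:shift])
  f0 <- extract_features(s)
  f1 <- extract_features(ecg_signal(xs, 500))
  for (col in c("pr_interval_ms", "qrs_duration_ms", "qt_interval_ms"))
    expect_lt(abs(f0[[col]] - f1[[col]]), 2 * 2)  # < 2 sample periods
})

test_that("interval features are stable under 2x resampling", {
  p <- default_wave_params()
  set.seed(7)
  s1 <- synthesize_ecg(p, n_samples = 2500, sampling_rate_hz = 250,
                       noise_sd = 0)
  s2 <- synthesize_ecg(p, n_samples = 5000, sampling_rate_hz = 500,
                       noise_sd = 0)
  f1 <- extract_features(s1)
  f2 <- extract_features(s2)
  for (col in c("pr_interval_ms", "qrs_duration_ms", "qt_interval_ms"))
    expect_lte(abs(f1[[col]] - f2[[col]]), 4)  # one 250 Hz sample period
})

test_that("feature extraction agrees with the planted per-record table", {
  co <- generate_cohort(6, seed = 11, ecgs_per_patient = 1,
                        n_samples = 2000, sampling_rate_hz = 200,
                        noise_sd = 0)
  for (rid in names(co$signals)) {
    f <- extract_features(co$signals[[rid]])
    planted <- co$features[co$features$record_id == rid, ]
    expect_lt(abs(f$pr_interval_ms - planted$pr_interval_ms), 15)
    expect_lt(abs(f$qrs_duration_ms - planted$qrs_duration_ms), 15)
    expect_lt(abs(f$ventricular_rate_bpm -
                    planted$ventricular_rate_bpm), 6)
  }
})

test_that("feature correlation matrix has the contracted shape", {
  co <- tab_cohort()
  C <- feature_correlation(co$features)
  expect_identical(dim(C), c(15L, 15L))
  expect_identical(unname(diag(C)), rep(1, 15))
  expect_equal(C, t(C))
  # duplicated column gives off-diagonal exactly 1
  df <- co$features
  df$qt_corrected_ms <- df$qt_interval_ms
  C2 <- feature_correlation(df)
  expect_equal(C2["qt_interval_ms", "qt_corrected_ms"], 1)
  # constant column is reported missing, not zero
  df2 <- co$features
  df2$p_axis_deg <- 5
  expect_warning(C3 <- feature_correlation(df2), "constant")
  expect_true(is.na(C3["p_axis_deg", "ventricular_rate_bpm"]))
  expect_identical(unname(diag(C3)), rep(1, 15))
  expect_error(feature_correlation(co$features[1:2, ]), "3 complete")
})
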