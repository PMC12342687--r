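#' Generate a synthetic HFpEF cohort with planted phenogroups
#'
#' Emulates a heart-failure registry extract: each patient is assigned
#' one morphology archetype (balanced at random), receives patient-level
#' PQRST timing parameters drawn from the archetype distributions,
#' around five lead-II ECG recordings spread around a diagnosis date, a
#' table of 15 extracted ECG features per recording (planted values plus
#' realistic measurement noise), and laboratory panels (creatinine,
#' NT-proBNP, LVEF).  Creatinine is drawn from the archetype's
#' distribution, which in the default panel is coupled to the group's PR
#' and QRS deviations -- the planted cardiorenal link.
#'
#' Generation is a pure function of its arguments: the same call is
#' reproduced byte for byte.
#'
#' @param n_patients Number of patients (must be at least the number of
#'   archetypes).
#' @param archetypes List of [phenogroup_archetype] objects.
#' @param ecgs_per_patient Mean ECG count per patient; each patient gets
#'   `1 + rpois(mean - 1)` recordings.
#' @param seed Integer seed controlling all randomness.
#' @param n_samples,sampling_rate_hz,noise_sd Waveform parameters passed
#'   to [synthesize_ecg()].
#' @param signals If `FALSE`, skip waveform synthesis (feature tables and
#'   labs only); useful when only the tabular pipeline is exercised.
#' @param start_date First possible diagnosis date.
#' @param ckd_threshold_umol_l Creatinine threshold for the binary CKD
#'   flag attached to each patient.
#' @return A list of class `ecg_cohort` with elements `patients`,
#'   `signals`, `labs`, `features`, `truth` and `params`.
#' @examples
#' co <- generate_cohort(10, seed = 1, n_samples = 800,
#'                       sampling_rate_hz = 100)
#' table(co$truth$archetype_id)
#' @export
generate_cohort <- function(n_patients,
                            archetypes = default_archetypes(),
                            ecgs_per_patient = 5,
                            seed = 1,
                            n_samples = 5000,
                            sampling_rate_hz = 500,
                            noise_sd = 0.02,
                            signals = TRUE,
                            start_date = as.Date("2020-01-01"),
                            ckd_threshold_umol_l = 110) {
  if (!is.numeric(n_patients) || n_patients < 1)
    stop("'n_patients' must be a positive count", call. = FALSE)
  if (length(archetypes) < 1)
    stop("'archetypes' must be a non-empty list", call. = FALSE)
  if (!all(vapply(archetypes, inherits, TRUE, "phenogroup_archetype")))
    stop("'archetypes' must contain phenogroup_archetype objects",
         call. = FALSE)
  if (n_patients < length(archetypes))
    stop("'n_patients' must be at least the number of archetypes",
         call. = FALSE)
  if (!is.numeric(ecgs_per_patient) || ecgs_per_patient < 1)
    stop("'ecgs_per_patient' must be a positive count", call. = FALSE)
  n_patients <- as.integer(n_patients)
  nA <- length(archetypes)
  set.seed(as.integer(seed))

  pid <- sprintf("P%04d", seq_len(n_patients))
  # balanced random assignment so every archetype is represented
  g <- sample(rep_len(seq_len(nA), n_patients))

  draw <- function(field) {
    m <- vapply(archetypes, function(a) a[[field]]["mean"], 0)
    s <- vapply(archetypes, function(a) a[[field]]["sd"], 0)
    rnorm(n_patients, m[g], s[g])
  }
  vr  <- pmax(30, draw("ventricular_rate_bpm"))
  pr  <- pmax(60, draw("pr_interval_ms"))
  qrs <- pmax(40, draw("qrs_duration_ms"))
  qt_mean <- vapply(archetypes, function(a) a$qt_interval_ms["mean"], 0)
  qt_sd <- vapply(archetypes, function(a) a$qt_interval_ms["sd"], 0)
  qrs_sd <- vapply(archetypes, function(a) a$qrs_duration_ms["sd"], 0)
  jt_sd <- sqrt(pmax(qt_sd^2 - qrs_sd^2, 25))
  jt <- pmax(200, rnorm(n_patients, (qt_mean - vapply(
    archetypes, function(a) a$qrs_duration_ms["mean"], 0))[g], jt_sd[g]))
  qt <- qrs + jt
  p_axis <- draw("p_axis_deg")
  r_axis <- draw("r_axis_deg")
  t_axis <- draw("t_axis_deg")
  amp <- t(vapply(archetypes, function(a)
    a$wave_amplitudes_mv[c("P", "Q", "R", "S", "T")], numeric(5)))[g, ,
                                                                   drop = FALSE]
  amp <- amp * matrix(exp(rnorm(n_patients * 5, 0, 0.08)), n_patients, 5)
  colnames(amp) <- c("P", "Q", "R", "S", "T")

  creat_m <- vapply(archetypes, function(a) a$creatinine_umol_l["mean"], 0)
  creat_s <- vapply(archetypes, function(a) a$creatinine_umol_l["sd"], 0)
  creat_pat <- pmax(20, rnorm(n_patients, creat_m[g],
                              pmax(creat_s[g] - 1, 0) * 0.9))
  lvef <- rnorm(n_patients, 60, 5)
  ntp_pat <- rlnorm(n_patients, 7.3, 0.8)
  hf_flag <- rbinom(n_patients, 1, 0.97) == 1
  diag_date <- start_date + sample(0:364, n_patients, replace = TRUE)

  patients <- data.frame(patient_id = pid, hf_flag = hf_flag,
                         diagnosis_date = diag_date,
                         stringsAsFactors = FALSE)

  # laboratory panels: 2-4 draws per patient around the diagnosis date
  n_labs <- 2 + rpois(n_patients, 1)
  labs <- data.frame(
    patient_id = rep(pid, n_labs),
    lab_time = rep(diag_date, n_labs) +
      round(runif(sum(n_labs), -120, 120)),
    creatinine_umol_l = pmax(20, rep(creat_pat, n_labs) +
                               rnorm(sum(n_labs), 0, 4)),
    nt_probnp_pg_ml = pmax(10, rep(ntp_pat, n_labs) *
                             exp(rnorm(sum(n_labs), 0, 0.1))),
    lvef_percent = pmin(85, pmax(20, rep(lvef, n_labs) +
                                   rnorm(sum(n_labs), 0, 1.5))),
    stringsAsFactors = FALSE)

  # ECG records
  n_ecg <- 1 + rpois(n_patients, max(ecgs_per_patient - 1, 0))
  rec_pat <- rep(seq_len(n_patients), n_ecg)
  rec_seq <- sequence(n_ecg)
  rid <- sprintf("%s_E%02d", pid[rec_pat], rec_seq)
  rec_time <- diag_date[rec_pat] + round(rnorm(length(rid), 0, 80))
  # small per-recording physiological drift
  vr_r  <- pmax(30, vr[rec_pat] + rnorm(length(rid), 0, 1.5))
  pr_r  <- pmax(115, pr[rec_pat] + rnorm(length(rid), 0, 2))
  qrs_r <- pmax(40, qrs[rec_pat] + rnorm(length(rid), 0, 2))
  qt_r  <- qrs_r + pmax(200, jt[rec_pat] + rnorm(length(rid), 0, 3))
  # keep each beat's P-QRS-T train inside one RR interval
  vr_r <- pmin(vr_r, 60000 / (pr_r + qt_r + 30))

  dur_s <- n_samples / sampling_rate_hz
  nr <- length(rid)
  features <- data.frame(
    record_id = rid,
    patient_id = pid[rec_pat],
    record_time = rec_time,
    ventricular_rate_bpm = vr_r + rnorm(nr, 0, 2),
    pr_interval_ms = pr_r + rnorm(nr, 0, 4),
    qrs_duration_ms = qrs_r + rnorm(nr, 0, 3),
    qt_corrected_ms = qt_r * sqrt(vr_r / 60) + rnorm(nr, 0, 16),
    p_axis_deg = p_axis[rec_pat] + rnorm(nr, 0, 4),
    r_axis_deg = r_axis[rec_pat] + rnorm(nr, 0, 4),
    t_axis_deg = t_axis[rec_pat] + rnorm(nr, 0, 4),
    qrs_count = pmax(1, round((vr_r + rnorm(nr, 0, 6)) * dur_s / 60)),
    q_onset_ms = 400 - qrs_r / 2 + rnorm(nr, 0, 10),
    q_offset_ms = 400 + qrs_r / 2 + rnorm(nr, 0, 10),
    p_onset_ms = 400 - qrs_r / 2 - pr_r + rnorm(nr, 0, 25),
    p_offset_ms = 400 - qrs_r / 2 - pr_r + 100 + rnorm(nr, 0, 25),
    t_offset_ms = 400 - qrs_r / 2 + qt_r + rnorm(nr, 0, 25),
    atrial_rate_bpm = vr_r + rnorm(nr, 0, 8),
    qt_interval_ms = qt_r + rnorm(nr, 0, 16),
    stringsAsFactors = FALSE)

  sigs <- NULL
  if (isTRUE(signals)) {
    sigs <- vector("list", nr)
    for (i in seq_len(nr)) {
      params <- list(pr_ms = pr_r[i], qrs_ms = qrs_r[i], qt_ms = qt_r[i],
                     rate_bpm = vr_r[i],
                     amplitudes_mv = amp[rec_pat[i], ])
      sigs[[i]] <- synthesize_ecg(params, n_samples = n_samples,
                                  sampling_rate_hz = sampling_rate_hz,
                                  noise_sd = noise_sd,
                                  patient_id = pid[rec_pat[i]],
                                  record_id = rid[i],
                                  record_time = rec_time[i])
    }
    names(sigs) <- rid
  }

  truth <- data.frame(
    patient_id = pid,
    archetype_id = vapply(archetypes, function(a) a$id, 0L)[g],
    pr_interval_ms = pr, qrs_duration_ms = qrs, qt_interval_ms = qt,
    ventricular_rate_bpm = vr, creatinine_umol_l = creat_pat,
    ckd = creat_pat > ckd_threshold_umol_l,
    stringsAsFactors = FALSE)
  attr(truth, "seed") <- as.integer(seed)
  class(truth) <- c("synthetic_truth", "data.frame")

  structure(list(patients = patients, signals = sigs, labs = labs,
                 features = features, truth = truth,
                 params = list(seed = as.integer(seed),
                               n_patients = n_patients,
                               ecgs_per_patient = ecgs_per_patient,
                               n_samples = n_samples,
                               sampling_rate_hz = sampling_rate_hz,
                               noise_sd = noise_sd,
                               ckd_threshold_umol_l = ckd_threshold_umol_l)),
            class = "ecg_cohort")
}

#' @export
print.ecg_cohort <- function(x, ...) {
  cat(sprintf(
    "<ecg_cohort: %d patients, %d ECG records%s, %d lab panels, seed %d>\n",
    nrow(x$patients), nrow(x$features),
    if (is.null(x$signals)) " (no waveforms)" else "",
    nrow(x$labs), x$params$seed))
  invisible(x)
}
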