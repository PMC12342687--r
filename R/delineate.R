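#' Delineate a lead-II ECG signal
#'
#' Finds per-beat fiducial landmarks.  R peaks are detected as local
#' maxima above half the global maximum with a 200 ms refractory window.
#' QRS onset/offset are located by walking out from each R peak to the
#' point where the signal falls below 5% of the R amplitude; P and T
#' peaks are searched in physiologic windows relative to the QRS, and
#' their onsets/offsets by the same 5%-of-peak rule.  All positions are
#' 0-based sample indices; intervals are half-open `[onset, offset)`.
#'
#' @param signal An [ecg_signal()] or numeric vector (then
#'   `sampling_rate_hz` must be given).
#' @param sampling_rate_hz Sampling rate when `signal` is a bare vector.
#' @param smooth_ms Width of the boxcar smoother applied before landmark
#'   search (default 6 ms; set 0 to disable).
#' @return Object of class `ecg_delineation`: a data frame with one row
#'   per complete beat and columns `beat`, `p_onset`, `p_peak`,
#'   `p_offset`, `qrs_onset`, `r_peak`, `qrs_offset`, `t_offset`
#'   (0-based sample indices), plus attributes `sampling_rate_hz` and
#'   `n_r_peaks` (all detected R peaks, including incomplete beats).
#' @export
delineate <- function(signal, sampling_rate_hz = NULL, smooth_ms = 6) {
  if (inherits(signal, "ecg_signal")) {
    x <- signal$samples
    fs <- signal$sampling_rate_hz
  } else {
    x <- as.numeric(signal)
    fs <- sampling_rate_hz
    if (is.null(fs)) stop("'sampling_rate_hz' required", call. = FALSE)
  }
  n <- length(x)
  ms <- function(k) max(1L, as.integer(round(k * fs / 1000)))

  xs <- x
  if (smooth_ms > 0) {
    w <- ms(smooth_ms)
    if (w > 1) {
      kern <- rep(1 / w, w)
      xs <- as.numeric(stats::filter(x, kern, sides = 2))
      xs[is.na(xs)] <- x[is.na(xs)]
    }
  }

  # R peaks: local maxima above half the global max, 200 ms refractory
  mx <- max(xs)
  if (!(mx > 0) || stats::sd(xs) == 0)
    stop_unusable("no detectable beats (flat or non-positive signal)")
  thr <- 0.5 * mx
  cand <- which(xs > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[xs[cand] >= xs[cand - 1] & xs[cand] >= xs[cand + 1]]
  if (length(cand)) {
    cand <- cand[order(-xs[cand])]
    refr <- ms(200)
    keep <- integer(0)
    for (p in cand)
      if (!length(keep) || all(abs(keep - p) >= refr)) keep <- c(keep, p)
    r_peaks <- sort(keep)
  } else r_peaks <- integer(0)
  if (length(r_peaks) < 2L)
    stop_unusable(sprintf("only %d R peak(s) detected; need at least 2",
                          length(r_peaks)))

  walk_to_fraction <- function(peak, dir, frac_of, lim) {
    # last index moving in 'dir' where |xs| is still >= frac_of
    i <- peak
    while (i + dir >= lim[1] && i + dir <= lim[2] &&
           abs(xs[i + dir]) >= frac_of) i <- i + dir
    if (i == lim[1] || i == lim[2]) i + dir else i
  }

  rows <- list()
  for (b in seq_along(r_peaks)) {
    r <- r_peaks[b]
    lim <- c(1L, n)
    ra <- xs[r]
    q_on <- walk_to_fraction(r, -1L, ONSET_FRACTION * ra, lim)
    q_off <- walk_to_fraction(r, +1L, ONSET_FRACTION * ra, lim)
    if (q_on < 1 || q_off > n) next
    # P peak: window before QRS onset
    p_lo <- max(1L, q_on - ms(280)); p_hi <- q_on - ms(8)
    if (p_hi <= p_lo) next
    pw <- p_lo:p_hi
    p_pk <- pw[which.max(xs[pw])]
    pa <- xs[p_pk]
    if (!(pa > 0)) next
    p_on <- walk_to_fraction(p_pk, -1L, ONSET_FRACTION * pa, lim)
    p_off <- walk_to_fraction(p_pk, +1L, ONSET_FRACTION * pa, lim)
    # T peak: window after QRS offset, bounded by the next beat
    t_hi_bound <- if (b < length(r_peaks))
      r_peaks[b + 1] - ms(260) else n
    t_lo <- q_off + ms(40); t_hi <- min(n, q_off + ms(450), t_hi_bound)
    if (t_hi <= t_lo) next
    tw <- t_lo:t_hi
    t_pk <- tw[which.max(xs[tw])]
    ta <- xs[t_pk]
    if (!(ta > 0)) next
    t_off <- walk_to_fraction(t_pk, +1L, ONSET_FRACTION * ta, lim)
    if (t_off > n || p_on < 1) next
    rows[[length(rows) + 1L]] <-
      data.frame(beat = b, p_onset = p_on - 1L, p_peak = p_pk - 1L,
                 p_offset = p_off - 1L, qrs_onset = q_on - 1L,
                 r_peak = r - 1L, qrs_offset = q_off - 1L,
                 t_offset = t_off - 1L)
  }
  if (length(rows) < 2L)
    stop_unusable("fewer than 2 fully delineated beats")
  out <- do.call(rbind, rows)
  structure(out, class = c("ecg_delineation", "data.frame"),
            sampling_rate_hz = fs, n_r_peaks = length(r_peaks))
}

stop_unusable <- function(msg) {
  stop(structure(class = c("ecgphenomap_unusable_record", "error",
                           "condition"),
                 list(message = paste0("unusable record: ", msg),
                      call = sys.call(-1))))
}

#' Extract the 15 tabular ECG variables from one signal
#'
#' Intervals are averaged over delineated beats; ventricular rate is
#' `60000 / mean(RR)` and atrial rate `60000 / mean(PP)` in
#' milliseconds; `qrs_count` is the number of detected R peaks; QT is
#' corrected by Bazett's formula (`QT / sqrt(RR in s)`).  Per-record
#' fiducial positions (`q_onset_ms`, ...) are beat-averaged offsets
#' expressed in a 400 ms pre-R representative-beat window.  Electrical
#' axes cannot be computed from a single lead and are copied from
#' `planted_axes` when supplied.
#'
#' @param signal An [ecg_signal()].
#' @param planted_axes Optional named vector/list with `p_axis_deg`,
#'   `r_axis_deg`, `t_axis_deg`.
#' @param ... Passed to [delineate()].
#' @return One-row data frame with the 15 columns of
#'   [ecg_feature_names] (plus `record_id`/`patient_id` if present on
#'   the signal).
#' @export
extract_features <- function(signal, planted_axes = NULL, ...) {
  del <- delineate(signal, ...)
  fs <- attr(del, "sampling_rate_hz")
  dt <- 1000 / fs
  rr <- mean(diff(del$r_peak)) * dt
  pp <- mean(diff(del$p_peak)) * dt
  pr <- mean(del$qrs_onset - del$p_onset) * dt
  qrs <- mean(del$qrs_offset - del$qrs_onset) * dt
  qt <- mean(del$t_offset - del$qrs_onset) * dt
  origin <- 400  # representative-beat window starts 400 ms before R
  ax <- function(nm) {
    if (!is.null(planted_axes) && !is.null(planted_axes[[nm]]))
      as.numeric(planted_axes[[nm]]) else NA_real_
  }
  out <- data.frame(
    ventricular_rate_bpm = 60000 / rr,
    pr_interval_ms = pr,
    qrs_duration_ms = qrs,
    qt_corrected_ms = qt / sqrt(rr / 1000),
    p_axis_deg = ax("p_axis_deg"),
    r_axis_deg = ax("r_axis_deg"),
    t_axis_deg = ax("t_axis_deg"),
    qrs_count = attr(del, "n_r_peaks"),
    q_onset_ms = origin + mean(del$qrs_onset - del$r_peak) * dt,
    q_offset_ms = origin + mean(del$qrs_offset - del$r_peak) * dt,
    p_onset_ms = origin + mean(del$p_onset - del$r_peak) * dt,
    p_offset_ms = origin + mean(del$p_offset - del$r_peak) * dt,
    t_offset_ms = origin + mean(del$t_offset - del$r_peak) * dt,
    atrial_rate_bpm = 60000 / pp,
    qt_interval_ms = qt)
  if (inherits(signal, "ecg_signal") && !is.na(signal$record_id))
    out <- cbind(data.frame(record_id = signal$record_id,
                            patient_id = signal$patient_id,
                            stringsAsFactors = FALSE), out)
  out
}

#' Pearson correlation matrix over the 15 ECG variables
#'
#' @param features Data frame containing the [ecg_feature_names]
#'   columns (extra columns are ignored).
#' @param use_cols Columns to correlate (default the 15 canonical ones
#'   present in `features`).
#' @return Symmetric correlation matrix with unit diagonal.  Pairs
#'   involving a constant column are reported as `NA` (with a warning),
#'   not zero.
#' @export
feature_correlation <- function(features, use_cols = NULL) {
  if (is.null(use_cols))
    use_cols <- intersect(ecg_feature_names, names(features))
  X <- as.matrix(features[, use_cols, drop = FALSE])
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 3L)
    stop("need at least 3 complete rows", call. = FALSE)
  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    warning(sprintf("constant column(s): %s; correlations reported as NA",
                    paste(colnames(X)[const], collapse = ", ")),
            call. = FALSE)
  C <- suppressWarnings(stats::cor(X))
  C[const, ] <- NA_real_
  C[, const] <- NA_real_
  diag(C) <- 1
  C
}
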