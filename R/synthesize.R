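# Onset/offset convention shared by the generator and the delineator:
# every wave is a Gaussian bump whose support is defined by the points
# where it reaches ONSET_FRACTION of its peak amplitude.  A bump spanning
# [onset, offset] therefore has sd = half_width / FID_K.
ONSET_FRACTION <- 0.05
FID_K <- sqrt(2 * log(1 / ONSET_FRACTION))

#' Construct an ECG signal object
#'
#' @param samples Numeric vector of amplitudes in millivolts.
#' @param sampling_rate_hz Positive sampling rate.
#' @param patient_id,record_id Identifiers (optional).
#' @param record_time Recording date (optional, `Date`).
#' @param fiducials Optional data frame of planted per-beat fiducial
#'   sample indices (0-based), as produced by [synthesize_ecg()].
#' @return Object of class `ecg_signal`.
#' @export
ecg_signal <- function(samples, sampling_rate_hz, patient_id = NA_character_,
                       record_id = NA_character_, record_time = NA,
                       fiducials = NULL) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' contains non-finite values", call. = FALSE)
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be positive", call. = FALSE)
  structure(list(samples = as.numeric(samples),
                 sampling_rate_hz = as.numeric(sampling_rate_hz),
                 patient_id = patient_id, record_id = record_id,
                 record_time = record_time, fiducials = fiducials),
            class = "ecg_signal")
}

#' @export
print.ecg_signal <- function(x, ...) {
  cat(sprintf("<ecg_signal %s: %d samples @ %g Hz (%.1f s)>\n",
              ifelse(is.na(x$record_id), "", x$record_id),
              length(x$samples), x$sampling_rate_hz,
              length(x$samples) / x$sampling_rate_hz))
  invisible(x)
}

#' Synthesize a lead-II ECG waveform from timing parameters
#'
#' Builds a beat train in which each PQRST complex is a sum of Gaussian
#' bumps.  The bumps are placed so that the planted PR interval (P onset
#' to QRS onset), QRS duration, and QT interval (QRS onset to T offset)
#' are exactly honoured under the shared 5%-of-peak onset convention, so
#' the delineator can recover them to within a sample period on
#' noiseless input.  White Gaussian noise of sd `noise_sd` is added.
#'
#' Randomness comes from the R session RNG: two calls under an identical
#' RNG state return identical signals.
#'
#' @param params List with elements `pr_ms`, `qrs_ms`, `qt_ms`,
#'   `rate_bpm` and a named amplitude vector `amplitudes_mv`
#'   (P, Q, R, S, T).  Optional: `p_dur_ms` (default 100) and `t_dur_ms`
#'   (default 160).
#' @param n_samples Record length in samples (default 5000).
#' @param sampling_rate_hz Sampling rate (default 500 Hz, a 10 s strip).
#' @param noise_sd Additive white-noise sd in millivolts.
#' @param ... Passed to [ecg_signal()] (ids, record time).
#' @return An [ecg_signal()] whose `fiducials` element holds the planted
#'   per-beat landmarks as 0-based sample indices.
#' @export
synthesize_ecg <- function(params, n_samples = 5000, sampling_rate_hz = 500,
                           noise_sd = 0.02, ...) {
  stopifnot(is.list(params))
  pr <- params$pr_ms; qrs <- params$qrs_ms; qt <- params$qt_ms
  rate <- params$rate_bpm
  amps <- params$amplitudes_mv
  p_dur <- if (is.null(params$p_dur_ms)) 100 else params$p_dur_ms
  t_dur <- if (is.null(params$t_dur_ms)) 160 else params$t_dur_ms
  for (v in c("pr_ms", "qrs_ms", "qt_ms", "rate_bpm"))
    if (is.null(params[[v]]) || !is.finite(params[[v]]) || params[[v]] <= 0)
      stop(sprintf("'params$%s' must be a positive number", v), call. = FALSE)
  if (n_samples <= 0) stop("'n_samples' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be non-negative", call. = FALSE)
  rr <- 60000 / rate
  # fiducial consistency: P onset < QRS onset < T offset, no collision
  # with the neighbouring beat
  if (pr <= p_dur + 10)
    stop("overlapping fiducials: PR interval must exceed P duration + 10 ms",
         call. = FALSE)
  if (qt <= qrs + t_dur + 20)
    stop("overlapping fiducials: QT must exceed QRS + T duration + 20 ms",
         call. = FALSE)
  if (pr + qt + 20 >= rr)
    stop("overlapping fiducials: PR + QT does not fit in one RR interval",
         call. = FALSE)
  dur_ms <- n_samples / sampling_rate_hz * 1000
  r1 <- qrs / 2 + pr + 20
  if (dur_ms < rr || r1 >= dur_ms)
    stop("'n_samples' shorter than one cardiac cycle", call. = FALSE)
  r_ms <- seq(r1, dur_ms - 1, by = rr)

  t_ms <- (seq_len(n_samples) - 1) / sampling_rate_hz * 1000
  x <- numeric(n_samples)
  add_bump <- function(center, half_width, amp) {
    s <- half_width / FID_K
    lo <- max(1L, ceiling((center - 5 * s) * sampling_rate_hz / 1000))
    hi <- min(n_samples, floor((center + 5 * s) * sampling_rate_hz / 1000) + 1L)
    if (lo > hi) return(invisible())
    idx <- lo:hi
    x[idx] <<- x[idx] + amp * exp(-0.5 * ((t_ms[idx] - center) / s)^2)
    invisible()
  }
  fid <- vector("list", length(r_ms))
  for (b in seq_along(r_ms)) {
    r <- r_ms[b]
    q_on <- r - qrs / 2; q_off <- r + qrs / 2
    p_on <- q_on - pr; p_off <- p_on + p_dur
    t_off <- q_on + qt; t_on <- t_off - t_dur
    add_bump(r, qrs / 2, amps[["R"]])
    add_bump(q_on + 0.25 * qrs, 0.06 * qrs * FID_K, amps[["Q"]])
    add_bump(q_off - 0.25 * qrs, 0.06 * qrs * FID_K, amps[["S"]])
    add_bump((p_on + p_off) / 2, p_dur / 2, amps[["P"]])
    add_bump((t_on + t_off) / 2, t_dur / 2, amps[["T"]])
    fid[[b]] <- c(p_onset = p_on, p_peak = (p_on + p_off) / 2,
                  p_offset = p_off, qrs_onset = q_on, r_peak = r,
                  qrs_offset = q_off, t_offset = t_off)
  }
  if (noise_sd > 0) x <- x + rnorm(n_samples, 0, noise_sd)
  fd <- as.data.frame(do.call(rbind, fid))
  # 0-based sample indices of the planted landmarks
  fd_idx <- as.data.frame(lapply(fd, function(ms)
    as.integer(round(ms * sampling_rate_hz / 1000))))
  fd_idx$beat <- seq_len(nrow(fd_idx))
  fd_idx <- fd_idx[, c("beat", setdiff(names(fd_idx), "beat"))]
  ecg_signal(x, sampling_rate_hz, fiducials = fd_idx, ...)
}
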