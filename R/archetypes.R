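#' Define a phenogroup archetype
#'
#' An archetype is the latent morphology profile of one phenogroup: the
#' population mean and standard deviation of its PQRST timing parameters,
#' its electrical axes, its wave amplitudes, and the creatinine
#' distribution of patients in the group.  Interval parameters are given
#' as `c(mean, sd)` in the units of the argument name.
#'
#' @param id Small integer label for the group.
#' @param pr_interval_ms,qrs_duration_ms,qt_interval_ms Numeric
#'   `c(mean, sd)` in milliseconds.
#' @param ventricular_rate_bpm Numeric `c(mean, sd)` in beats per minute.
#' @param p_axis_deg,r_axis_deg,t_axis_deg Numeric `c(mean, sd)` in
#'   degrees.  Axes are not derivable from a single lead; they are
#'   planted tabular features.
#' @param wave_amplitudes_mv Named numeric vector with elements
#'   `P`, `Q`, `R`, `S`, `T`: mean deflection amplitudes in millivolts.
#' @param creatinine_umol_l Numeric `c(mean, sd)` in micromoles per
#'   litre.
#' @return An object of class `phenogroup_archetype`.
#' @seealso [default_archetypes()], [generate_cohort()]
#' @export
phenogroup_archetype <- function(id,
                                 pr_interval_ms,
                                 qrs_duration_ms,
                                 qt_interval_ms,
                                 ventricular_rate_bpm,
                                 p_axis_deg = c(45, 20),
                                 r_axis_deg = c(30, 25),
                                 t_axis_deg = c(40, 20),
                                 wave_amplitudes_mv = c(P = 0.15, Q = -0.1,
                                                        R = 1.1, S = -0.25,
                                                        T = 0.35),
                                 creatinine_umol_l = c(100, 10)) {
  ms2 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 2L || anyNA(x))
      stop(sprintf("'%s' must be a numeric c(mean, sd)", nm), call. = FALSE)
    if (x[2] < 0)
      stop(sprintf("'%s' has a negative sd", nm), call. = FALSE)
    c(mean = unname(x[1]), sd = unname(x[2]))
  }
  a <- list(
    id = as.integer(id),
    pr_interval_ms = ms2(pr_interval_ms, "pr_interval_ms"),
    qrs_duration_ms = ms2(qrs_duration_ms, "qrs_duration_ms"),
    qt_interval_ms = ms2(qt_interval_ms, "qt_interval_ms"),
    ventricular_rate_bpm = ms2(ventricular_rate_bpm, "ventricular_rate_bpm"),
    p_axis_deg = ms2(p_axis_deg, "p_axis_deg"),
    r_axis_deg = ms2(r_axis_deg, "r_axis_deg"),
    t_axis_deg = ms2(t_axis_deg, "t_axis_deg"),
    wave_amplitudes_mv = wave_amplitudes_mv,
    creatinine_umol_l = ms2(creatinine_umol_l, "creatinine_umol_l")
  )
  need <- c("P", "Q", "R", "S", "T")
  if (!all(need %in% names(wave_amplitudes_mv)))
    stop("'wave_amplitudes_mv' needs named elements P, Q, R, S, T",
         call. = FALSE)
  if (a$pr_interval_ms["mean"] <= 0 || a$qrs_duration_ms["mean"] <= 0 ||
      a$qt_interval_ms["mean"] <= 0 || a$ventricular_rate_bpm["mean"] <= 0)
    stop("timing means must be positive", call. = FALSE)
  if (a$qt_interval_ms["mean"] <= a$qrs_duration_ms["mean"])
    stop("QT interval mean must exceed QRS duration mean", call. = FALSE)
  if (a$creatinine_umol_l["mean"] <= 0)
    stop("creatinine mean must be positive", call. = FALSE)
  structure(a, class = "phenogroup_archetype")
}

#' @export
print.phenogroup_archetype <- function(x, ...) {
  cat(sprintf(
    "<phenogroup_archetype %d>  rate %.0f bpm, PR %.0f ms, QRS %.0f ms, QT %.0f ms, creatinine %.1f umol/L\n",
    x$id, x$ventricular_rate_bpm["mean"], x$pr_interval_ms["mean"],
    x$qrs_duration_ms["mean"], x$qt_interval_ms["mean"],
    x$creatinine_umol_l["mean"]))
  invisible(x)
}

#' Default five-archetype panel
#'
#' Five morphology phenogroups whose group-mean profiles follow mutually
#' orthogonal contrasts across groups: heart rate varies linearly, PR
#' interval follows a quadratic (U-shaped) contrast and QRS duration a
#' quartic contrast.  Group creatinine means are tied to the PR and QRS
#' deviations (the planted cardiorenal link), so chronic-kidney-disease
#' risk is predictable from PR interval and QRS duration but orthogonal
#' to heart rate.  Wave amplitudes differ between groups so that raw
#' waveform morphology separates even groups whose PR/QRS profiles are
#' twins.
#'
#' @param creatinine_coupling Strength (micromol/L per ms) of the
#'   creatinine dependence on the group's PR and QRS deviations.
#' @return List of 5 [phenogroup_archetype] objects.
#' @export
default_archetypes <- function(creatinine_coupling = 0.55) {
  rate_m <- 75 + 6 * c(-2, -1, 0, 1, 2)
  pr_m   <- 160 + 12 * c(2, -1, -2, -1, 2)
  qrs_m  <- 95 + 6 * c(1, -4, 6, -4, 1)
  qt_m   <- qrs_m + 310
  # creatinine: PR/QRS coupling plus a cubic-contrast component that
  # separates the PR/QRS twin groups, and a small linear compensation
  # keeping the thresholded CKD flag balanced with respect to heart rate
  creat_m <- 100 + creatinine_coupling * ((pr_m - 160) + (qrs_m - 95)) +
    7 * c(-1, 2, 0, -2, 1) - 3 * c(-2, -1, 0, 1, 2)
  amp_r <- c(1.1, 1.6, 0.8, 1.3, 0.95)
  amp_p <- c(0.12, 0.20, 0.15, 0.10, 0.18)
  amp_t <- c(0.30, 0.45, 0.25, 0.50, 0.35)
  amp_q <- c(-0.10, -0.15, -0.08, -0.20, -0.12)
  amp_s <- c(-0.20, -0.30, -0.15, -0.35, -0.25)
  lapply(1:5, function(g) {
    phenogroup_archetype(
      id = g,
      pr_interval_ms = c(pr_m[g], 8),
      qrs_duration_ms = c(qrs_m[g], 8),
      qt_interval_ms = c(qt_m[g], sqrt(8^2 + 20^2)),
      ventricular_rate_bpm = c(rate_m[g], 2.5),
      wave_amplitudes_mv = c(P = amp_p[g], Q = amp_q[g], R = amp_r[g],
                             S = amp_s[g], T = amp_t[g]),
      creatinine_umol_l = c(creat_m[g], 10)
    )
  })
}
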