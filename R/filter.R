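#' HFpEF selection criteria
#'
#' Thresholds defining the analysis population: left ventricular
#' ejection fraction at least `lvef_min_percent` (inclusive), NT-proBNP
#' strictly above `nt_probnp_min_pg_ml`, an HF flag, and an ECG
#' recording window of `window_days` around the diagnosis or a
#' qualifying laboratory date ("6 months" is taken as 183 days,
#' inclusive).
#'
#' @param lvef_min_percent LVEF threshold, compared with `>=`.
#' @param nt_probnp_min_pg_ml NT-proBNP threshold, compared with `>`.
#' @param window_days Half-width of the ECG pairing window in days.
#' @param require_hf_flag Require the patient-level HF flag.
#' @return Object of class `filter_criteria`.
#' @export
filter_criteria <- function(lvef_min_percent = 50,
                            nt_probnp_min_pg_ml = 450,
                            window_days = 183,
                            require_hf_flag = TRUE) {
  if (lvef_min_percent <= 0 || nt_probnp_min_pg_ml <= 0 || window_days <= 0)
    stop("all thresholds must be positive", call. = FALSE)
  structure(list(lvef_min_percent = lvef_min_percent,
                 nt_probnp_min_pg_ml = nt_probnp_min_pg_ml,
                 window_days = as.integer(window_days),
                 require_hf_flag = isTRUE(require_hf_flag)),
            class = "filter_criteria")
}

#' Select the HFpEF analysis population
#'
#' A patient qualifies when the HF flag is set (if required), any LVEF
#' measurement is `>=` the LVEF threshold, and any NT-proBNP measurement
#' is strictly `>` the NT-proBNP threshold.  Counts at each filter stage
#' are reported.
#'
#' @param patients Data frame with columns `patient_id` and (if
#'   `require_hf_flag`) `hf_flag`.
#' @param labs Data frame with columns `patient_id`, `lvef_percent`,
#'   `nt_probnp_pg_ml`.
#' @param criteria A [filter_criteria()] object.
#' @return Object of class `hfpef_selection`: list with `patient_ids`
#'   (character) and `stage_counts` (data frame).
#' @export
select_hfpef <- function(patients, labs, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  for (col in c("patient_id")) {
    if (!col %in% names(patients))
      stop(sprintf("'patients' lacks required column '%s'", col),
           call. = FALSE)
  }
  need <- c("patient_id", "lvef_percent", "nt_probnp_pg_ml")
  miss <- setdiff(need, names(labs))
  if (length(miss))
    stop(sprintf("'labs' lacks required column '%s'", miss[1]),
         call. = FALSE)

  ids <- unique(patients$patient_id)
  stages <- data.frame(stage = "all_patients", n = length(ids),
                       stringsAsFactors = FALSE)
  if (criteria$require_hf_flag) {
    if (!"hf_flag" %in% names(patients))
      stop("'patients' lacks required column 'hf_flag'", call. = FALSE)
    ids <- intersect(ids, patients$patient_id[patients$hf_flag])
    stages <- rbind(stages, data.frame(stage = "hf_flag", n = length(ids)))
  }
  lv_ok <- unique(labs$patient_id[!is.na(labs$lvef_percent) &
                                    labs$lvef_percent >=
                                    criteria$lvef_min_percent])
  ids <- intersect(ids, lv_ok)
  stages <- rbind(stages, data.frame(stage = "lvef_ge_min", n = length(ids)))
  np_ok <- unique(labs$patient_id[!is.na(labs$nt_probnp_pg_ml) &
                                    labs$nt_probnp_pg_ml >
                                    criteria$nt_probnp_min_pg_ml])
  ids <- intersect(ids, np_ok)
  stages <- rbind(stages,
                  data.frame(stage = "nt_probnp_gt_min", n = length(ids)))
  structure(list(patient_ids = ids, stage_counts = stages,
                 criteria = criteria),
            class = "hfpef_selection")
}

#' @export
print.hfpef_selection <- function(x, ...) {
  cat("<hfpef_selection>\n")
  for (i in seq_len(nrow(x$stage_counts)))
    cat(sprintf("  %-18s %d\n", x$stage_counts$stage[i],
                x$stage_counts$n[i]))
  invisible(x)
}

#' Pair ECG records with their nearest creatinine value
#'
#' Retains ECGs recorded within `window_days` (inclusive) of the
#' patient's diagnosis date or of any qualifying laboratory date
#' (NT-proBNP above the criteria threshold), and pairs each retained ECG
#' with the creatinine measurement nearest in time, provided that lab
#' lies within `window_days` of the ECG.  Nearest-in-time ties are
#' broken toward the earlier lab.  ECGs failing either condition are
#' dropped and counted.
#'
#' @param records A data frame with columns `record_id`, `patient_id`,
#'   `record_time`, or a list of [ecg_signal()] objects.
#' @param labs Lab data frame (see [select_hfpef()]) with
#'   `creatinine_umol_l` and `lab_time`.
#' @param patients Data frame with `patient_id` and `diagnosis_date`.
#' @param window_days Window half-width in days (default 183).
#' @param nt_probnp_min_pg_ml Qualifying-lab threshold used to define
#'   anchor dates.
#' @return Object of class `ecg_lab_pairs`: list with `pairs` (data
#'   frame: record_id, patient_id, record_time, creatinine_umol_l,
#'   lab_time), `n_dropped_window`, `n_dropped_no_lab`.
#' @export
pair_ecg_with_labs <- function(records, labs, patients,
                               window_days = 183,
                               nt_probnp_min_pg_ml = 450) {
  if (is.list(records) && !is.data.frame(records) &&
      all(vapply(records, inherits, TRUE, "ecg_signal"))) {
    records <- data.frame(
      record_id = vapply(records, function(s) s$record_id, ""),
      patient_id = vapply(records, function(s) s$patient_id, ""),
      record_time = as.Date(
        vapply(records, function(s) as.character(s$record_time), "")),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("record_id", "patient_id", "record_time") %in%
                  names(records)))
  window_days <- as.integer(window_days)

  anchors <- split(labs$lab_time[!is.na(labs$nt_probnp_pg_ml) &
                                   labs$nt_probnp_pg_ml >
                                   nt_probnp_min_pg_ml],
                   labs$patient_id[!is.na(labs$nt_probnp_pg_ml) &
                                     labs$nt_probnp_pg_ml >
                                     nt_probnp_min_pg_ml])
  diag_by_id <- setNames(patients$diagnosis_date, patients$patient_id)
  crea <- labs[!is.na(labs$creatinine_umol_l), ]
  crea_by_id <- split(crea[, c("lab_time", "creatinine_umol_l")],
                      crea$patient_id)

  out <- vector("list", nrow(records))
  n_drop_window <- 0L; n_drop_lab <- 0L
  for (i in seq_len(nrow(records))) {
    pidi <- records$patient_id[i]
    rt <- records$record_time[i]
    anc <- c(diag_by_id[pidi], anchors[[pidi]])
    anc <- anc[!is.na(anc)]
    if (!length(anc) || min(abs(as.numeric(rt - anc))) > window_days) {
      n_drop_window <- n_drop_window + 1L
      next
    }
    cl <- crea_by_id[[pidi]]
    if (!is.null(cl)) {
      dt <- as.numeric(cl$lab_time - rt)
      ok <- abs(dt) <= window_days
      cl <- cl[ok, ]; dt <- dt[ok]
    }
    if (is.null(cl) || nrow(cl) == 0L) {
      n_drop_lab <- n_drop_lab + 1L
      next
    }
    # nearest in time; ties broken toward the earlier lab
    ord <- order(abs(dt), cl$lab_time)
    pick <- ord[1]
    out[[i]] <- data.frame(record_id = records$record_id[i],
                           patient_id = pidi, record_time = rt,
                           creatinine_umol_l = cl$creatinine_umol_l[pick],
                           lab_time = cl$lab_time[pick],
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(pairs))
    pairs <- data.frame(record_id = character(), patient_id = character(),
                        record_time = as.Date(character()),
                        creatinine_umol_l = numeric(),
                        lab_time = as.Date(character()))
  structure(list(pairs = pairs, n_dropped_window = n_drop_window,
                 n_dropped_no_lab = n_drop_lab,
                 window_days = window_days),
            class = "ecg_lab_pairs")
}

#' @export
print.ecg_lab_pairs <- function(x, ...) {
  cat(sprintf(
    "<ecg_lab_pairs: %d paired ECGs (%d outside window, %d without creatinine)>\n",
    nrow(x$pairs), x$n_dropped_window, x$n_dropped_no_lab))
  invisible(x)
}
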