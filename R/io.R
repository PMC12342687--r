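#' Write an ECG signal to a plain-text file
#'
#' Format: a header line `# sampling_rate_hz=<value>` followed by one
#' amplitude per line.
#'
#' @param signal An [ecg_signal()].
#' @param path Output file path.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "ecg_signal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate_hz=%.10g", signal$sampling_rate_hz),
             con)
  writeLines(sprintf("%.10g", signal$samples), con)
  invisible(path)
}

#' Read an ECG signal written by [write_signal()]
#'
#' @param path Input file path.
#' @param patient_id,record_id,record_time Optional metadata to attach.
#' @return An [ecg_signal()].
#' @export
read_signal <- function(path, patient_id = NA_character_,
                        record_id = NA_character_, record_time = NA) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# sampling_rate_hz=", lines[1]))
    stop("missing '# sampling_rate_hz=' header", call. = FALSE)
  fs <- as.numeric(sub("^# sampling_rate_hz=", "", lines[1]))
  ecg_signal(as.numeric(lines[-1]), fs, patient_id = patient_id,
             record_id = record_id, record_time = record_time)
}

#' Write a cohort to a directory of delimited-text files
#'
#' Emits `patients.csv`, `labs.csv`, `features.csv`, `truth.csv` and
#' (when waveforms are present) one signal file per record under
#' `signals/`.
#'
#' @param cohort An `ecg_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ecg_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$labs, file.path(dir, "labs.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$features, file.path(dir, "features.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$truth),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  if (!is.null(cohort$signals)) {
    sdir <- file.path(dir, "signals")
    dir.create(sdir, showWarnings = FALSE)
    for (s in cohort$signals)
      write_signal(s, file.path(sdir, paste0(s$record_id, ".txt")))
  }
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @param signals Read the waveform files too?
#' @return A list with the same shape as [generate_cohort()] output.
#' @export
read_cohort <- function(dir, signals = TRUE) {
  rd <- function(f, dates = character()) {
    df <- utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE)
    for (col in intersect(dates, names(df))) df[[col]] <- as.Date(df[[col]])
    df
  }
  patients <- rd("patients.csv", "diagnosis_date")
  labs <- rd("labs.csv", "lab_time")
  features <- rd("features.csv", "record_time")
  truth <- rd("truth.csv")
  sigs <- NULL
  sdir <- file.path(dir, "signals")
  if (isTRUE(signals) && dir.exists(sdir)) {
    files <- list.files(sdir, pattern = "\\.txt$", full.names = TRUE)
    rids <- sub("\\.txt$", "", basename(files))
    meta <- features[match(rids, features$record_id), ]
    sigs <- lapply(seq_along(files), function(i)
      read_signal(files[i], patient_id = meta$patient_id[i],
                  record_id = rids[i], record_time = meta$record_time[i]))
    names(sigs) <- rids
  }
  structure(list(patients = patients, signals = sigs, labs = labs,
                 features = features, truth = truth,
                 params = list()),
            class = "ecg_cohort")
}

#' Write / read a distance matrix as CSV (ids in the header)
#'
#' @param d Symmetric distance matrix with dimnames.
#' @param path CSV path.
#' @export
write_distance_matrix <- function(d, path) {
  validate_distance_matrix(d)
  utils::write.csv(as.data.frame(d), path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  d <- as.matrix(df)
  colnames(d) <- rownames(d)
  validate_distance_matrix(d)
  d
}

#' Write a partition as CSV (`id,label,method`)
#'
#' @param part A [partition()].
#' @param path CSV path.
#' @export
write_partition <- function(part, path) {
  utils::write.csv(data.frame(id = part$ids, label = part$labels,
                              method = part$method),
                   path, row.names = FALSE)
  invisible(path)
}

#' Serialize a dendrogram as Newick-like nested text
#'
#' @param hc An `hclust` object.
#' @return A single string in Newick format (heights as branch lengths).
#' @export
hclust_to_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  lab <- hc$labels
  if (is.null(lab)) lab <- as.character(seq_along(hc$order))
  rec <- function(i, parent_h) {
    if (i < 0) {  # leaf
      sprintf("%s:%.6g", lab[-i], parent_h)
    } else {
      h <- hc$height[i]
      sprintf("(%s,%s):%.6g", rec(hc$merge[i, 1], h),
              rec(hc$merge[i, 2], h), parent_h - h)
    }
  }
  n <- nrow(hc$merge)
  h <- hc$height[n]
  paste0("(", rec(hc$merge[n, 1], h), ",", rec(hc$merge[n, 2], h), ");")
}
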