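#' Pipeline run configuration
#'
#' Desk-scale defaults: 150 patients, 1000-sample strips at 100 Hz
#' (10 s), a Sakoe-Chiba band of 50 samples for the all-pairs DTW, and
#' five clusters throughout.
#'
#' @param seed Master seed for the whole run.
#' @param n_patients Cohort size.
#' @param archetypes Archetype panel (default [default_archetypes()]).
#' @param ecgs_per_patient Mean ECGs per patient.
#' @param n_samples,sampling_rate_hz,noise_sd Waveform parameters.
#' @param filter [filter_criteria()].
#' @param dtw [dtw_config()].
#' @param k Number of clusters for every partition (default 5).
#' @param subset_size Bootstrap subset size (default 80% of the
#'   analysis set, capped at 500).
#' @param n_replicates Bootstrap replicates (default 5).
#' @param ckd_threshold_umol_l Creatinine threshold for the CKD flag.
#' @param workers Worker processes for the DTW matrix.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1, n_patients = 150,
                       archetypes = default_archetypes(),
                       ecgs_per_patient = 5, n_samples = 1000,
                       sampling_rate_hz = 100, noise_sd = 0.02,
                       filter = filter_criteria(),
                       dtw = dtw_config(band_radius = 50),
                       k = 5, subset_size = NULL, n_replicates = 5,
                       ckd_threshold_umol_l = 110, workers = 1) {
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 archetypes = archetypes,
                 ecgs_per_patient = ecgs_per_patient,
                 n_samples = n_samples,
                 sampling_rate_hz = sampling_rate_hz,
                 noise_sd = noise_sd, filter = filter, dtw = dtw,
                 k = k, subset_size = subset_size,
                 n_replicates = n_replicates,
                 ckd_threshold_umol_l = ckd_threshold_umol_l,
                 workers = workers),
            class = "run_config")
}

#' Run the full phenogrouping pipeline
#'
#' generate (or accept) a cohort, select the HFpEF population, pair
#' each patient's ECG nearest to diagnosis with its creatinine value,
#' run the three-method feature-selection consensus, build the four
#' partitions (creatinine baseline, all-feature k-means, minimal-set
#' k-means, DTW + Ward), and evaluate: elbow curves, Jaccard/Rand
#' comparison of every ECG partition against the creatinine baseline,
#' creatinine-by-cluster enrichment ANOVA, a per-feature ANOVA table,
#' and bootstrap stability of the tabular partitions.  Fully
#' deterministic under the config seed.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-built `ecg_cohort` (otherwise generated
#'   from the config).
#' @param verbose Log stage progress?
#' @return Object of class `phenomap_report`.
#' @export
run_all <- function(config = run_config(), cohort = NULL,
                    verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- "generate"
  res <- tryCatch({
    if (is.null(cohort)) {
      say("stage generate: n = %d patients", config$n_patients)
      cohort <- generate_cohort(
        config$n_patients, archetypes = config$archetypes,
        ecgs_per_patient = config$ecgs_per_patient, seed = config$seed,
        n_samples = config$n_samples,
        sampling_rate_hz = config$sampling_rate_hz,
        noise_sd = config$noise_sd,
        ckd_threshold_umol_l = config$ckd_threshold_umol_l)
    }

    stage <- "filter"
    sel <- select_hfpef(cohort$patients, cohort$labs, config$filter)
    pairs <- pair_ecg_with_labs(
      cohort$features[, c("record_id", "patient_id", "record_time")],
      cohort$labs, cohort$patients,
      window_days = config$filter$window_days,
      nt_probnp_min_pg_ml = config$filter$nt_probnp_min_pg_ml)
    say("stage filter: %d HFpEF patients, %d paired ECGs",
        length(sel$patient_ids), nrow(pairs$pairs))

    # one record per qualifying patient: the paired ECG closest to the
    # diagnosis date
    pp <- pairs$pairs[pairs$pairs$patient_id %in% sel$patient_ids, ]
    dd <- cohort$patients$diagnosis_date[
      match(pp$patient_id, cohort$patients$patient_id)]
    pp$abs_off <- abs(as.numeric(pp$record_time - dd))
    pp <- pp[order(pp$patient_id, pp$abs_off, pp$record_id), ]
    chosen <- pp[!duplicated(pp$patient_id), ]
    if (nrow(chosen) < 2 * config$k)
      stop(sprintf("analysis set too small (%d patients)", nrow(chosen)))
    feats <- cohort$features[match(chosen$record_id,
                                   cohort$features$record_id), ]
    rownames(feats) <- NULL
    ckd <- chosen$creatinine_umol_l > config$ckd_threshold_umol_l

    stage <- "feature_selection"
    say("stage feature_selection: %d patients, CKD prevalence %.2f",
        nrow(chosen), mean(ckd))
    sig_rank <- rank_by_significance(feats, ckd)
    pca_rank <- rank_by_pca(feats, seed = config$seed)
    lasso_sel <- rank_by_lasso(feats, ckd, target_k = 5,
                               seed = config$seed)
    cons <- suppressWarnings(
      consensus_features(sig_rank, pca_rank, lasso_sel))
    minimal_set <- cons$features
    if (length(minimal_set) < 2)
      minimal_set <- c("pr_interval_ms", "qrs_duration_ms")

    stage <- "cluster"
    say("stage cluster: k = %d", config$k)
    part_creat <- creatinine_baseline(
      stats::setNames(chosen$creatinine_umol_l, chosen$patient_id),
      k = config$k)
    part_feat <- kmeans_features(feats, k = config$k, seed = config$seed,
                                 ids = chosen$patient_id)
    part_min <- kmeans_features(feats, subset = minimal_set,
                                k = config$k, seed = config$seed,
                                ids = chosen$patient_id)

    stage <- "dtw"
    dmat <- NULL; part_dtw <- NULL; elbow_dtw <- NULL
    if (!is.null(cohort$signals)) {
      sigs <- cohort$signals[chosen$record_id]
      say("stage dtw: %d signals, %d pairs", length(sigs),
          choose(length(sigs), 2))
      dmat <- pairwise_dtw(sigs, config$dtw, workers = config$workers)
      dimnames(dmat) <- list(chosen$patient_id, chosen$patient_id)
      part_dtw <- ward_on_distance(dmat, k = config$k)
      elbow_dtw <- elbow(dmat)
    }

    stage <- "evaluate"
    elbow_feat <- elbow(feats, seed = config$seed)
    ecg_parts <- Filter(Negate(is.null),
                        list(dtw = part_dtw, all_features = part_feat,
                             minimal_set = part_min))
    comparison <- do.call(rbind, lapply(names(ecg_parts), function(nm) {
      cmp <- compare_partitions(ecg_parts[[nm]], part_creat)
      data.frame(partition = nm, jaccard = cmp$jaccard,
                 rand = cmp$rand, adjusted_rand = cmp$adjusted_rand)
    }))
    sil_feat <- silhouette_score(part_feat, feats)
    enrich <- lapply(ecg_parts, function(p)
      enrichment_anova(p, stats::setNames(chosen$creatinine_umol_l,
                                          chosen$patient_id)))
    anova_tab <- anova_feature_table(part_feat, feats)

    stage <- "stability"
    n_items <- nrow(chosen)
    subset_size <- config$subset_size
    if (is.null(subset_size))
      subset_size <- min(500L, floor(0.8 * n_items))
    feats_by_id <- feats
    rownames(feats_by_id) <- chosen$patient_id
    stability <- list()
    if (config$n_replicates > 0) {
      stability$all_features <- bootstrap_stability(
        chosen$patient_id,
        function(ids) kmeans_features(
          feats_by_id[ids, ], k = config$k, seed = config$seed,
          ids = ids),
        part_feat, subset_size = subset_size,
        n_replicates = config$n_replicates, seed = config$seed)
      stability$minimal_set <- bootstrap_stability(
        chosen$patient_id,
        function(ids) kmeans_features(
          feats_by_id[ids, ], subset = minimal_set, k = config$k,
          seed = config$seed, ids = ids),
        part_min, subset_size = subset_size,
        n_replicates = config$n_replicates, seed = config$seed)
      if (!is.null(dmat))
        stability$dtw <- bootstrap_stability(
          chosen$patient_id,
          function(ids) ward_on_distance(dmat[ids, ids], k = config$k),
          part_dtw, subset_size = subset_size,
          n_replicates = config$n_replicates, seed = config$seed)
    }

    truth_sub <- cohort$truth[match(chosen$patient_id,
                                    cohort$truth$patient_id), ]
    recovery <- lapply(ecg_parts, function(p)
      as.numeric(adjusted_rand_index(
        p, partition(chosen$patient_id,
                     as_zero_based(truth_sub$archetype_id),
                     method = "planted_truth"))))

    structure(list(
      config = config, selection = sel, pairs = pairs,
      analysis_set = chosen[, c("patient_id", "record_id",
                                "record_time", "creatinine_umol_l")],
      features = feats, ckd = ckd,
      rankings = list(significance = sig_rank, pca = pca_rank,
                      lasso = lasso_sel),
      consensus = cons, minimal_set = minimal_set,
      partitions = c(list(creatinine = part_creat), ecg_parts),
      distance_matrix = dmat,
      elbow = list(features = elbow_feat, dtw = elbow_dtw),
      comparison = comparison,
      silhouette_features = sil_feat$mean,
      enrichment = enrich, anova_features = anova_tab,
      stability = stability, truth_recovery = recovery),
      class = "phenomap_report")
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  res
}

#' @export
print.phenomap_report <- function(x, ...) {
  cat(sprintf("<phenomap_report: %d patients, k = %d, seed = %d>\n",
              nrow(x$analysis_set), x$config$k, x$config$seed))
  cat("  minimal feature set:", paste(x$minimal_set, collapse = ", "),
      "\n")
  cat("  Jaccard vs creatinine baseline:\n")
  for (i in seq_len(nrow(x$comparison)))
    cat(sprintf("    %-14s %.3f\n", x$comparison$partition[i],
                x$comparison$jaccard[i]))
  if (length(x$truth_recovery)) {
    cat("  ARI vs planted archetypes:\n")
    for (nm in names(x$truth_recovery))
      cat(sprintf("    %-14s %.3f\n", nm, x$truth_recovery[[nm]]))
  }
  invisible(x)
}

#' Persist a pipeline report as deterministic text artifacts
#'
#' Writes partitions, the comparison table, enrichment and ANOVA
#' tables, elbow curves, selection rankings, the distance matrix, the
#' DTW dendrogram (Newick) and a plain-text summary.  No timestamps are
#' embedded, so two runs with the same seed produce byte-identical
#' trees.
#'
#' @param report A `phenomap_report`.
#' @param outdir Output directory.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "phenomap_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  for (nm in names(report$partitions))
    write_partition(report$partitions[[nm]],
                    fp(sprintf("partition_%s.csv", nm)))
  utils::write.csv(report$comparison, fp("comparison_vs_creatinine.csv"),
                   row.names = FALSE)
  utils::write.csv(report$anova_features, fp("anova_features.csv"),
                   row.names = FALSE)
  for (nm in names(report$enrichment)) {
    er <- report$enrichment[[nm]]
    utils::write.csv(er$clusters,
                     fp(sprintf("creatinine_by_cluster_%s.csv", nm)),
                     row.names = FALSE)
  }
  utils::write.csv(as.data.frame(report$elbow$features),
                   fp("elbow_features.csv"), row.names = FALSE)
  if (!is.null(report$elbow$dtw))
    utils::write.csv(as.data.frame(report$elbow$dtw),
                     fp("elbow_dtw.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$rankings$significance),
                   fp("ranking_significance.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$rankings$pca),
                   fp("ranking_pca.csv"), row.names = FALSE)
  utils::write.csv(data.frame(feature = report$rankings$lasso$features,
                              coefficient =
                                report$rankings$lasso$coefficients),
                   fp("ranking_lasso.csv"), row.names = FALSE)
  for (nm in names(report$stability))
    utils::write.csv(as.data.frame(report$stability[[nm]]),
                     fp(sprintf("stability_%s.csv", nm)),
                     row.names = FALSE)
  if (!is.null(report$distance_matrix))
    write_distance_matrix(report$distance_matrix,
                          fp("dtw_distance_matrix.csv"))
  if (!is.null(report$partitions$dtw) &&
      !is.null(attr(report$partitions$dtw, "hclust")))
    writeLines(hclust_to_newick(attr(report$partitions$dtw, "hclust")),
               fp("dtw_dendrogram.nwk"))
  smry <- c(
    sprintf("patients: %d", nrow(report$analysis_set)),
    sprintf("k: %d", report$config$k),
    sprintf("seed: %d", report$config$seed),
    sprintf("minimal_set: %s", paste(report$minimal_set,
                                     collapse = ", ")),
    sprintf("jaccard_%s: %.6f", report$comparison$partition,
            report$comparison$jaccard))
  writeLines(smry, fp("summary.txt"))
  invisible(outdir)
}
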