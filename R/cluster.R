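#' Construct a partition object
#'
#' @param ids Character vector of item identifiers.
#' @param labels Integer cluster labels in `[0, k)`, one per id.
#' @param k Number of clusters.
#' @param method Free-text method tag.
#' @param provenance Optional list (config, seed, ...).
#' @return Object of class `partition`.
#' @export
partition <- function(ids, labels, k = length(unique(labels)),
                      method = "unknown", provenance = list()) {
  ids <- as.character(ids)
  labels <- as.integer(labels)
  if (length(ids) != length(labels))
    stop("'ids' and 'labels' must have equal length", call. = FALSE)
  if (anyNA(labels) || any(labels < 0L) || any(labels >= k))
    stop("labels must lie in [0, k)", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicated ids in partition", call. = FALSE)
  structure(list(ids = ids, labels = labels, k = as.integer(k),
                 method = method, provenance = provenance),
            class = "partition")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition '%s': %d items in %d clusters (sizes %s)>\n",
              x$method, length(x$ids), x$k,
              paste(tabulate(x$labels + 1L, x$k), collapse = "/")))
  invisible(x)
}

# relabel cluster vector to 0-based consecutive integers
as_zero_based <- function(cl) as.integer(cl) - min(as.integer(cl))

#' Restrict a partition to a subset of items
#'
#' @param x A [partition()].
#' @param ids Items to keep (order taken from `ids`).
#' @return A [partition()] over `ids` (labels unchanged).
#' @export
restrict_partition <- function(x, ids) {
  idx <- match(ids, x$ids)
  if (anyNA(idx)) stop("some ids not present in partition", call. = FALSE)
  partition(ids, x$labels[idx], k = x$k, method = x$method,
            provenance = x$provenance)
}

#' k-means clustering on extracted ECG features
#'
#' Features are standardized internally; k-means is run with multiple
#' random restarts and the best inertia kept.  Deterministic under
#' `seed`.
#'
#' @param features Data frame with the [ecg_feature_names] columns and
#'   (optionally) ids in `record_id` or `patient_id`.
#' @param subset Character vector of feature columns to use (default all
#'   15 present).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param nstart Random restarts (default 10).
#' @param iter_max Iteration cap per restart.
#' @param ids Item identifiers (default `record_id`/`patient_id` column
#'   or row numbers).
#' @return A [partition()] with an attached `wcss` (total
#'   within-cluster sum of squares in standardized space).
#' @export
kmeans_features <- function(features, subset = NULL, k = 5, seed = 1,
                            nstart = 10, iter_max = 300, ids = NULL) {
  X <- feature_matrix(features, cols = subset)
  if (!all(complete.cases(X)))
    stop("rows must be complete for the chosen feature subset",
         call. = FALSE)
  if (k > nrow(X))
    stop("'k' cannot exceed the number of rows", call. = FALSE)
  if (is.null(ids)) {
    ids <- if ("record_id" %in% names(features)) features$record_id
    else if ("patient_id" %in% names(features)) features$patient_id
    else as.character(seq_len(nrow(X)))
  }
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  set.seed(as.integer(seed))
  km <- stats::kmeans(Xs, centers = k, nstart = nstart,
                      iter.max = iter_max)
  out <- partition(ids, as_zero_based(km$cluster), k = k,
                   method = if (is.null(subset)) "kmeans_all_features"
                   else paste0("kmeans_", paste(subset, collapse = "+")),
                   provenance = list(seed = seed, nstart = nstart,
                                     subset = subset))
  attr(out, "wcss") <- km$tot.withinss
  out
}

#' Ward hierarchical clustering on a precomputed distance matrix
#'
#' Builds the agglomerative merge tree with Ward linkage
#' (`hclust(method = "ward.D2")`, which operates on the distances as
#' Euclidean) and cuts it into `k` groups.  Note that Ward linkage
#' formally assumes squared-Euclidean geometry; applying it to a DTW
#' matrix is a pragmatic choice, not a metric guarantee -- use
#' `linkage = "average"` for a metric-agnostic alternative.
#'
#' @param distances Symmetric non-negative matrix with zero diagonal
#'   (e.g. from [pairwise_dtw()]).
#' @param k Number of clusters (default 5).
#' @param linkage `"ward"` (default) or `"average"`.
#' @return A [partition()]; the full `hclust` tree is attached as
#'   attribute `"hclust"` for dendrogram output.
#' @export
ward_on_distance <- function(distances, k = 5, linkage = c("ward",
                                                           "average")) {
  linkage <- match.arg(linkage)
  validate_distance_matrix(distances)
  n <- nrow(distances)
  if (k > n) stop("'k' cannot exceed the number of items", call. = FALSE)
  ids <- rownames(distances)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  hc <- stats::hclust(stats::as.dist(distances),
                      method = if (linkage == "ward") "ward.D2"
                      else "average")
  cl <- stats::cutree(hc, k = k)
  out <- partition(ids, as_zero_based(cl), k = k,
                   method = paste0(linkage, "_on_distance"),
                   provenance = list(linkage = linkage))
  attr(out, "hclust") <- hc
  out
}

#' Baseline partition by hierarchical clustering on creatinine
#'
#' One-dimensional Ward clustering of the creatinine values; the
#' resulting clusters are contiguous intervals on the creatinine axis
#' (verified, allowing shared boundary values under ties), so cluster
#' means are strictly increasing.
#'
#' @param creatinine Positive numeric vector.
#' @param k Number of clusters (default 5).
#' @param ids Item identifiers (default names or positions).
#' @return A [partition()] with attribute `"cluster_means"` (sorted).
#' @export
creatinine_baseline <- function(creatinine, k = 5, ids = NULL) {
  x <- as.numeric(creatinine)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("creatinine values must be positive and finite", call. = FALSE)
  if (length(unique(x)) < k)
    stop(sprintf("need at least %d distinct creatinine values, have %d",
                 k, length(unique(x))), call. = FALSE)
  if (is.null(ids)) {
    ids <- names(creatinine)
    if (is.null(ids)) ids <- as.character(seq_along(x))
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  # contiguity on the value axis (intervals may share tied endpoints)
  rng <- vapply(seq_len(k), function(c)
    range(x[cl == c]), numeric(2))
  ord <- order(rng[1, ])
  for (i in seq_len(k - 1L)) {
    if (rng[2, ord[i]] > rng[1, ord[i + 1L]])
      stop("internal error: 1-D Ward clusters are not contiguous",
           call. = FALSE)
  }
  # relabel so cluster 0 has the lowest creatinine
  relab <- match(cl, ord) - 1L
  out <- partition(ids, relab, k = k, method = "creatinine_ward",
                   provenance = list())
  attr(out, "hclust") <- hc
  attr(out, "cluster_means") <- vapply(seq_len(k) - 1L, function(c)
    mean(x[relab == c]), 0)
  out
}

#' Elbow curve for choosing the cluster count
#'
#' Computes the within-cluster sum of squares (WCSS) over a range of
#' `k`.  For a feature table the WCSS is the k-means inertia in
#' standardized space; for a precomputed distance matrix it is the
#' within-cluster sum of squared distances to the cluster medoid under
#' Ward tree cuts.  The suggested `k` sits at the last large drop
#' before the curve flattens (the maximum ratio of successive WCSS
#' drops); the suggestion is advisory (the pipeline default stays
#' `k = 5`) and is flagged low-confidence when no drop dominates its
#' successor by at least a factor of 3.
#'
#' @param x Feature data frame/matrix, or symmetric distance matrix.
#' @param k_range Candidate cluster counts (default `1:10`).
#' @param seed Seed for the k-means path.
#' @param distance Set `TRUE` to force distance-matrix mode.
#' @return Object of class `elbow_curve`: data frame (`k`, `wcss`) with
#'   attributes `suggested_k` and `low_confidence`.
#' @export
elbow <- function(x, k_range = 1:10, seed = 1, distance = NULL) {
  if (is.null(distance))
    distance <- is.matrix(x) && nrow(x) == ncol(x) &&
      !is.null(rownames(x)) && identical(rownames(x), colnames(x)) &&
      all(abs(diag(x)) < 1e-12)
  k_range <- sort(unique(as.integer(k_range)))
  if (distance) {
    validate_distance_matrix(x)
    n <- nrow(x)
    if (max(k_range) > n) stop("'k_range' exceeds item count",
                               call. = FALSE)
    hc <- stats::hclust(stats::as.dist(x), method = "ward.D2")
    wcss <- vapply(k_range, function(k) {
      cl <- stats::cutree(hc, k = k)
      sum(vapply(unique(cl), function(c) {
        idx <- which(cl == c)
        if (length(idx) == 1L) return(0)
        sub <- x[idx, idx, drop = FALSE]^2
        medoid <- which.min(colSums(sub))
        sum(sub[, medoid])
      }, 0))
    }, 0)
  } else {
    X <- if (is.data.frame(x)) feature_matrix(x) else as.matrix(x)
    Xs <- scale(X)
    Xs[, apply(X, 2, stats::sd) == 0] <- 0
    n <- nrow(Xs)
    if (max(k_range) > n) stop("'k_range' exceeds item count",
                               call. = FALSE)
    set.seed(as.integer(seed))
    wcss <- vapply(k_range, function(k)
      stats::kmeans(Xs, centers = k, nstart = 30,
                    iter.max = 100)$tot.withinss, 0)
  }
  curve <- data.frame(k = k_range, wcss = wcss)
  suggested <- NA_integer_; low_conf <- TRUE
  if (length(k_range) >= 3L) {
    eps <- 1e-9 * max(wcss[1], 1)
    drops <- pmax(wcss[-length(wcss)] - wcss[-1], 0) + eps
    ratio <- drops[-length(drops)] / drops[-1]
    j <- which.max(ratio)
    suggested <- k_range[j + 1L]
    low_conf <- ratio[j] < 3
  }
  structure(curve, class = c("elbow_curve", "data.frame"),
            suggested_k = suggested, low_confidence = low_conf)
}

#' @export
print.elbow_curve <- function(x, ...) {
  cat(sprintf("<elbow_curve: k %d..%d, suggested k = %s%s>\n",
              min(x$k), max(x$k), attr(x, "suggested_k"),
              if (attr(x, "low_confidence")) " (low confidence)" else ""))
  invisible(x)
}
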