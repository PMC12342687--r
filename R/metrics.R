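align_partitions <- function(a, b) {
  stopifnot(inherits(a, "partition"), inherits(b, "partition"))
  if (!setequal(a$ids, b$ids))
    stop("partitions are over different item sets", call. = FALSE)
  list(la = a$labels, lb = b$labels[match(a$ids, b$ids)])
}

pair_counts <- function(la, lb) {
  ct <- table(la, lb)
  nij <- sum(choose(ct, 2))
  ai <- sum(choose(rowSums(ct), 2))
  bj <- sum(choose(colSums(ct), 2))
  n <- length(la)
  list(both = nij, a = ai, b = bj, total = choose(n, 2))
}

#' Co-cluster Jaccard score between two partitions
#'
#' Over all unordered item pairs: the number of pairs co-clustered in
#' both partitions divided by the number co-clustered in at least one.
#' When both partitions are all-singletons the score is undefined; 1 is
#' returned with attribute `degenerate = TRUE`.
#'
#' @param a,b [partition()] objects over the same items.
#' @return Scalar in `[0, 1]`.
#' @export
cocluster_jaccard <- function(a, b) {
  al <- align_partitions(a, b)
  pc <- pair_counts(al$la, al$lb)
  denom <- pc$a + pc$b - pc$both
  if (denom == 0)
    return(structure(1, degenerate = TRUE))
  pc$both / denom
}

#' Rand index and adjusted Rand index
#'
#' The Rand index is the fraction of item pairs on which the two
#' partitions agree (co-clustered in both or separated in both).  The
#' adjusted version corrects for chance agreement.
#'
#' @param a,b [partition()] objects over the same items.
#' @return For `rand_index` a scalar in `[0, 1]`; for
#'   `adjusted_rand_index` a scalar `<= 1` (about 0 for independent
#'   partitions).
#' @export
rand_index <- function(a, b) {
  al <- align_partitions(a, b)
  pc <- pair_counts(al$la, al$lb)
  (pc$total + 2 * pc$both - pc$a - pc$b) / pc$total
}

#' @rdname rand_index
#' @export
adjusted_rand_index <- function(a, b) {
  al <- align_partitions(a, b)
  pc <- pair_counts(al$la, al$lb)
  expected <- pc$a * pc$b / pc$total
  mx <- (pc$a + pc$b) / 2
  if (mx == expected) return(structure(1, degenerate = TRUE))
  (pc$both - expected) / (mx - expected)
}

#' Compare two partitions
#'
#' @param a,b [partition()] objects over the same items.
#' @return Object of class `partition_comparison`: list with `jaccard`,
#'   `rand`, `adjusted_rand`.
#' @export
compare_partitions <- function(a, b) {
  structure(list(jaccard = as.numeric(cocluster_jaccard(a, b)),
                 rand = rand_index(a, b),
                 adjusted_rand = as.numeric(adjusted_rand_index(a, b)),
                 methods = c(a$method, b$method)),
            class = "partition_comparison")
}

#' @export
print.partition_comparison <- function(x, ...) {
  cat(sprintf(
    "<partition_comparison %s vs %s: Jaccard %.3f, Rand %.3f, ARI %.3f>\n",
    x$methods[1], x$methods[2], x$jaccard, x$rand, x$adjusted_rand))
  invisible(x)
}

#' Silhouette score of a partition
#'
#' Standard a/b silhouette over either the Euclidean metric of a
#' feature table or a precomputed distance matrix.  Singleton clusters
#' receive silhouette 0 by convention.
#'
#' @param part A [partition()] with `k >= 2`.
#' @param x Feature data frame/matrix (rows matching `part$ids`) or a
#'   precomputed symmetric distance matrix with matching dimnames.
#' @param metric `"euclidean"` (feature input) or `"precomputed"`.
#' @return List with `mean` and per-item `widths`.
#' @export
silhouette_score <- function(part, x,
                             metric = c("euclidean", "precomputed")) {
  metric <- match.arg(metric)
  if (part$k < 2L)
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  if (metric == "precomputed") {
    validate_distance_matrix(x)
    idx <- match(part$ids, rownames(x))
    if (anyNA(idx)) stop("distance matrix lacks some partition ids",
                         call. = FALSE)
    d <- stats::as.dist(x[idx, idx])
  } else {
    X <- if (is.data.frame(x)) feature_matrix(x) else as.matrix(x)
    if (nrow(X) != length(part$ids))
      stop("feature rows must match partition items", call. = FALSE)
    d <- stats::dist(scale(X))
  }
  sil <- cluster::silhouette(part$labels + 1L, d)
  widths <- if (is.matrix(sil)) sil[, "sil_width"] else numeric(0)
  list(mean = mean(widths), widths = widths)
}

#' Bootstrap stability of a clustering procedure
#'
#' Repeatedly draws subsets of `subset_size` items without replacement,
#' re-clusters them with `cluster_fun`, and compares each replicate
#' partition with the reference partition restricted to the sampled
#' items (co-cluster Jaccard and adjusted Rand).  Replicates in which
#' clustering fails are recorded and skipped.
#'
#' @param ids Character vector of all item ids.
#' @param cluster_fun Function `(ids) -> partition` that clusters the
#'   given subset of items.
#' @param reference The full-data reference [partition()].
#' @param subset_size Items per replicate (default 500, capped at the
#'   number available).
#' @param n_replicates Number of replicates (must be positive).
#' @param seed Integer seed.
#' @return Object of class `stability_report`: data frame of
#'   per-replicate scores with attributes `mean_jaccard`, `sd_jaccard`,
#'   `mean_ari`, `sd_ari`, `n_failed`, `subset_size` and an `unstable`
#'   flag (mean Jaccard below 0.6).
#' @export
bootstrap_stability <- function(ids, cluster_fun, reference,
                                subset_size = 500, n_replicates = 20,
                                seed = 1) {
  if (n_replicates < 1)
    stop("'n_replicates' must be positive", call. = FALSE)
  if (subset_size > length(ids))
    stop("'subset_size' exceeds the number of items", call. = FALSE)
  set.seed(as.integer(seed))
  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    sub <- sample(ids, subset_size)
    part <- tryCatch(cluster_fun(sub), error = function(e) NULL)
    if (is.null(part)) { n_failed <- n_failed + 1L; next }
    ref_sub <- restrict_partition(reference, part$ids)
    rows[[r]] <- data.frame(
      replicate = r,
      jaccard = as.numeric(cocluster_jaccard(part, ref_sub)),
      adjusted_rand = as.numeric(adjusted_rand_index(part, ref_sub)))
  }
  tab <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(tab))
    tab <- data.frame(replicate = integer(), jaccard = numeric(),
                      adjusted_rand = numeric())
  structure(tab, class = c("stability_report", "data.frame"),
            mean_jaccard = mean(tab$jaccard),
            sd_jaccard = stats::sd(tab$jaccard),
            mean_ari = mean(tab$adjusted_rand),
            sd_ari = stats::sd(tab$adjusted_rand),
            n_failed = n_failed, subset_size = subset_size,
            unstable = is.finite(mean(tab$jaccard)) &&
              mean(tab$jaccard) < 0.6)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf(
    "<stability_report: %d replicates of %d items; Jaccard %.3f +/- %.3f, ARI %.3f +/- %.3f%s%s>\n",
    nrow(x), attr(x, "subset_size"), attr(x, "mean_jaccard"),
    attr(x, "sd_jaccard"), attr(x, "mean_ari"), attr(x, "sd_ari"),
    if (attr(x, "n_failed") > 0)
      sprintf("; %d failed", attr(x, "n_failed")) else "",
    if (isTRUE(attr(x, "unstable"))) " [UNSTABLE]" else ""))
  invisible(x)
}

#' Per-cluster enrichment ANOVA
#'
#' One-way fixed-effects ANOVA of a target variable across the clusters
#' of a partition, reported with the classical `(k - 1, n - k)` degrees
#' of freedom, per-cluster summaries, and Welch pairwise post-hoc tests
#' with Bonferroni flags.
#'
#' @param part A [partition()].
#' @param values Numeric target (e.g. creatinine), one per item, in the
#'   order of `part$ids` (or named by id).
#' @return Object of class `enrichment_report`: list with `clusters`
#'   (n, mean, sd per cluster), `f_statistic`, `df`, `p_value`,
#'   `degenerate` (TRUE when all within-cluster variance is zero, F
#'   reported infinite), and `posthoc`.
#' @export
enrichment_anova <- function(part, values) {
  stopifnot(inherits(part, "partition"))
  v <- as.numeric(values)
  if (!is.null(names(values)) && all(part$ids %in% names(values)))
    v <- as.numeric(values[part$ids])
  if (length(v) != length(part$ids))
    stop("'values' must have one entry per partition item", call. = FALSE)
  cl <- part$labels
  sizes <- tabulate(cl + 1L, part$k)
  if (any(sizes < 2L))
    stop("each cluster needs at least 2 items for variance estimation",
         call. = FALSE)
  k <- part$k; n <- length(v)
  cluster_tab <- data.frame(
    cluster = seq_len(k) - 1L, n = sizes,
    mean = vapply(seq_len(k) - 1L, function(c) mean(v[cl == c]), 0),
    sd = vapply(seq_len(k) - 1L, function(c) stats::sd(v[cl == c]), 0))
  ss_within <- sum((v - cluster_tab$mean[cl + 1L])^2)
  ss_between <- sum(sizes * (cluster_tab$mean - mean(v))^2)
  df1 <- k - 1L; df2 <- n - k
  degenerate <- ss_within == 0
  if (degenerate) {
    f <- if (ss_between > 0) Inf else NaN
    p <- if (ss_between > 0) 0 else NA_real_
  } else {
    f <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  combs <- utils::combn(seq_len(k) - 1L, 2L)
  ph <- data.frame(cluster_a = combs[1, ], cluster_b = combs[2, ])
  ph$p_value <- vapply(seq_len(ncol(combs)), function(i) {
    va <- v[cl == combs[1, i]]; vb <- v[cl == combs[2, i]]
    if (stats::sd(va) == 0 && stats::sd(vb) == 0)
      return(if (mean(va) == mean(vb)) 1 else 0)
    stats::t.test(va, vb)$p.value
  }, 0)
  ph$p_bonferroni <- pmin(1, ph$p_value * ncol(combs))
  ph$significant <- ph$p_bonferroni < 0.05
  structure(list(clusters = cluster_tab, f_statistic = f,
                 df = c(df1, df2), p_value = p, degenerate = degenerate,
                 posthoc = ph),
            class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat(sprintf("<enrichment_report: F = %.3f (%d, %d), p = %s%s>\n",
              x$f_statistic, x$df[1], x$df[2],
              format.pval(x$p_value, digits = 3),
              if (x$degenerate) " [degenerate]" else ""))
  print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' ANOVA of every ECG feature across a partition's clusters
#'
#' One row per feature: F statistic, degrees of freedom and p-value of
#' the one-way ANOVA of that feature across the clusters.
#'
#' @param part A [partition()].
#' @param features Feature data frame, rows matching `part$ids` order.
#' @return Data frame with columns `feature`, `f_statistic`, `df1`,
#'   `df2`, `p_value`.
#' @export
anova_feature_table <- function(part, features) {
  X <- feature_matrix(features)
  if (nrow(X) != length(part$ids))
    stop("'features' rows must match partition items", call. = FALSE)
  rows <- lapply(colnames(X), function(f) {
    er <- enrichment_anova(part, X[, f])
    data.frame(feature = f, f_statistic = er$f_statistic,
               df1 = er$df[1], df2 = er$df[2], p_value = er$p_value)
  })
  do.call(rbind, rows)
}
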