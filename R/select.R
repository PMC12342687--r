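feature_matrix <- function(features, cols = NULL) {
  if (is.null(cols)) cols <- intersect(ecg_feature_names, names(features))
  X <- as.matrix(features[, cols, drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Rank ECG features by one-tailed Welch t-tests against a CKD label
#'
#' For each feature, a Welch two-sample t statistic between the two
#' label classes with a one-tailed p-value taken in the direction of the
#' observed mean difference (exploratory ranking, not confirmatory
#' testing).  Features are ranked by ascending p.  Because the tail is
#' chosen after seeing the data, the `significant` flag compares the
#' doubled directional p (the two-sided equivalent) against `alpha`,
#' keeping the flag's type-I error at the nominal level.
#'
#' @param features Data frame with the [ecg_feature_names] columns.
#' @param labels Logical/binary vector (e.g. CKD flag), one per row.
#' @param alpha Significance threshold (default .05).
#' @return Object of class `significance_ranking`: data frame with
#'   columns `feature`, `statistic`, `p_value`, `direction`,
#'   `significant`, ordered by ascending p.
#' @export
rank_by_significance <- function(features, labels, alpha = 0.05) {
  X <- feature_matrix(features)
  lab <- as.logical(labels)
  if (length(lab) != nrow(X))
    stop("'labels' length must match rows of 'features'", call. = FALSE)
  if (length(unique(lab[!is.na(lab)])) < 2L ||
      min(table(lab)) < 2L)
    stop("both classes must be present with at least 2 members each",
         call. = FALSE)
  res <- lapply(colnames(X), function(f) {
    a <- X[lab, f]; b <- X[!lab, f]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(data.frame(feature = f, statistic = 0, p_value = 0.5,
                        direction = "none"))
    }
    tt <- stats::t.test(a, b)  # Welch
    # one-tailed in the direction of the observed difference
    p1 <- stats::pt(-abs(tt$statistic), tt$parameter)
    data.frame(feature = f, statistic = unname(tt$statistic),
               p_value = unname(p1),
               direction = if (tt$statistic >= 0) "higher_in_class"
               else "lower_in_class")
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p_value, -abs(out$statistic)), ]
  # the tail direction is chosen after seeing the data, so the
  # directional p is doubled before the significance call to keep the
  # nominal size at alpha
  out$significant <- 2 * out$p_value < alpha
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("significance_ranking", "data.frame"),
            alpha = alpha)
}

#' Rank ECG features by resampled-PCA explained variance
#'
#' In each of `n_sims` simulations an 80% subsample is drawn, features
#' are standardized (zero mean, unit variance) and a principal component
#' analysis computed.  Each of the first five components is assigned to
#' the feature carrying its largest absolute loading (ties broken toward
#' the lower column index); a feature's score is the mean
#' explained-variance ratio of the components assigned to it across
#' simulations.
#'
#' @param features Data frame with the [ecg_feature_names] columns.
#' @param n_sims Number of resampling simulations (default 50).
#' @param train_frac Subsample fraction (default 0.8).
#' @param seed Integer seed.
#' @param n_components Components considered per simulation (default 5).
#' @return Object of class `pca_ranking`: data frame with `feature`,
#'   `avg_explained_variance`, `n_assigned`, `rank` ordered by
#'   descending score.
#' @export
rank_by_pca <- function(features, n_sims = 50, train_frac = 0.8, seed = 1,
                        n_components = 5) {
  X <- feature_matrix(features)
  X <- X[complete.cases(X), , drop = FALSE]
  if (nrow(X) < 10L) stop("need at least 10 rows", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop("fewer rows than features", call. = FALSE)
  set.seed(as.integer(seed))
  p <- ncol(X)
  score_sum <- numeric(p); score_n <- numeric(p)
  for (s in seq_len(n_sims)) {
    idx <- sample(nrow(X), floor(train_frac * nrow(X)))
    pc <- stats::prcomp(X[idx, , drop = FALSE], center = TRUE,
                        scale. = TRUE)
    ev <- pc$sdev^2 / sum(pc$sdev^2)
    for (k in seq_len(min(n_components, ncol(pc$rotation)))) {
      f <- which.max(abs(pc$rotation[, k]))  # first max = lowest index
      score_sum[f] <- score_sum[f] + ev[k]
      score_n[f] <- score_n[f] + 1
    }
  }
  score <- ifelse(score_n > 0, score_sum / score_n, 0)
  out <- data.frame(feature = colnames(X),
                    avg_explained_variance = score,
                    n_assigned = as.integer(score_n))
  out <- out[order(-out$avg_explained_variance, out$feature), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("pca_ranking", "data.frame"),
            n_sims = n_sims, train_frac = train_frac, seed = seed)
}

#' @export
print.pca_ranking <- function(x, n = 5, ...) {
  cat("Feature importance by average explained variance",
      sprintf("(%d simulations, %.0f%% subsamples)\n",
              attr(x, "n_sims"), 100 * attr(x, "train_frac")))
  top <- head(x, n)
  for (i in seq_len(nrow(top)))
    cat(sprintf("  component %d  %-22s %.3f\n", i - 1L, top$feature[i],
                top$avg_explained_variance[i]))
  invisible(x)
}

#' Select features by L1-penalized logistic regression
#'
#' Fits a lasso logistic model of the binary label on the standardized
#' features and tunes the penalty by bisection until exactly `target_k`
#' coefficients are nonzero (or the closest achievable count, which is
#' then reported).  An optional stability probe refits the model on
#' five 63% subsamples and flags the selection as unstable when the
#' selected sets disagree (mean pairwise Jaccard below 0.5).
#'
#' @param features Data frame with the [ecg_feature_names] columns.
#' @param labels Logical/binary vector, one per row.
#' @param target_k Desired number of selected features (default 5).
#' @param seed Seed for the stability probe subsamples.
#' @param stability_probe Run the subsample stability check?
#' @param max_iter Bisection iteration cap (default 60).
#' @return Object of class `lasso_selection`: list with `features`
#'   (selected names ordered by |coefficient|), `coefficients`,
#'   `lambda`, `achieved_k`, `converged`, `unstable`.
#' @export
rank_by_lasso <- function(features, labels, target_k = 5, seed = 1,
                          stability_probe = TRUE, max_iter = 60) {
  X <- feature_matrix(features)
  lab <- as.numeric(as.logical(labels))
  if (length(lab) != nrow(X))
    stop("'labels' length must match rows of 'features'", call. = FALSE)
  if (length(unique(lab)) < 2L)
    stop("both classes must be present", call. = FALSE)
  target_k <- min(as.integer(target_k), ncol(X))
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0

  nnz_at <- function(lambda) {
    fit <- glmnet::glmnet(Xs, lab, family = "binomial", alpha = 1,
                          lambda = lambda, standardize = FALSE)
    beta <- as.numeric(fit$beta)
    names(beta) <- rownames(fit$beta)
    beta[is.na(beta)] <- 0
    beta
  }
  if (target_k == ncol(X)) {
    beta <- nnz_at(1e-8)
    sel <- names(beta)
    return(lasso_result(sel, beta, 1e-8, length(sel), TRUE, FALSE))
  }
  lo <- 1e-6  # dense end
  hi <- max(abs(crossprod(Xs, lab - mean(lab)))) / length(lab) * 1.1
  best <- NULL; converged <- FALSE
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    beta <- nnz_at(mid)
    k <- sum(beta != 0)
    if (is.null(best) || abs(k - target_k) < abs(best$k - target_k))
      best <- list(beta = beta, lambda = mid, k = k)
    if (k == target_k) { converged <- TRUE; break }
    if (k > target_k) lo <- mid else hi <- mid
  }
  beta <- best$beta
  sel <- names(beta)[beta != 0]
  sel <- sel[order(-abs(beta[sel]))]

  unstable <- FALSE
  if (isTRUE(stability_probe)) {
    set.seed(as.integer(seed))
    sets <- lapply(1:5, function(i) {
      idx <- sample(nrow(Xs), floor(0.63 * nrow(Xs)))
      if (length(unique(lab[idx])) < 2L) return(NULL)
      fit <- glmnet::glmnet(Xs[idx, , drop = FALSE], lab[idx],
                            family = "binomial", alpha = 1,
                            lambda = best$lambda, standardize = FALSE)
      rownames(fit$beta)[as.numeric(fit$beta) != 0]
    })
    sets <- sets[!vapply(sets, is.null, TRUE)]
    if (length(sets) >= 2L) {
      jac <- c()
      for (i in seq_along(sets)) for (j in seq_len(i - 1L)) {
        u <- length(union(sets[[i]], sets[[j]]))
        jac <- c(jac, if (u == 0) 1 else
          length(intersect(sets[[i]], sets[[j]])) / u)
      }
      unstable <- mean(jac) < 0.5
    }
  }
  lasso_result(sel, beta, best$lambda, best$k, converged, unstable)
}

lasso_result <- function(sel, beta, lambda, k, converged, unstable) {
  structure(list(features = sel, coefficients = beta[sel],
                 lambda = lambda, achieved_k = k,
                 converged = converged, unstable = unstable),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection: %d feature(s) at lambda %.4g%s%s>\n",
              x$achieved_k, x$lambda,
              if (!x$converged) " (closest achievable)" else "",
              if (x$unstable) " [UNSTABLE]" else ""))
  for (f in x$features)
    cat(sprintf("  %-22s %+0.3f\n", f, x$coefficients[f]))
  invisible(x)
}

#' Top-ranked features of a selection report
#'
#' @param x A ranking object.
#' @param n Number of features (default 5).
#' @param ... Unused.
#' @return Character vector of feature names.
#' @export
top_features <- function(x, n = 5, ...) UseMethod("top_features")

#' @export
top_features.significance_ranking <- function(x, n = 5, ...)
  head(x$feature, n)

#' @export
top_features.pca_ranking <- function(x, n = 5, ...) head(x$feature, n)

#' @export
top_features.lasso_selection <- function(x, n = 5, ...)
  head(x$features, n)

#' @export
top_features.character <- function(x, n = 5, ...) head(x, n)

#' Consensus of several feature-selection methods
#'
#' Intersects the top-`n` lists of two or more ranking reports; the
#' consensus is ordered by mean rank across methods.  An empty
#' intersection yields an empty set with a warning.
#'
#' @param ... Two or more ranking objects (or plain character vectors of
#'   ranked features).
#' @param n Depth of each top list (default 5).
#' @return Object of class `selection_consensus`: list with `features`,
#'   `mean_rank`, `method_lists`.
#' @export
consensus_features <- function(..., n = 5) {
  reports <- list(...)
  if (length(reports) == 1L && is.list(reports[[1]]) &&
      !inherits(reports[[1]], c("significance_ranking", "pca_ranking",
                                "lasso_selection")))
    reports <- reports[[1]]
  if (length(reports) < 2L)
    stop("need at least 2 method reports", call. = FALSE)
  lists <- lapply(reports, top_features, n = n)
  common <- Reduce(intersect, lists)
  if (!length(common))
    warning("empty consensus: no feature common to all top lists",
            call. = FALSE)
  mean_rank <- vapply(common, function(f)
    mean(vapply(lists, function(l) match(f, l), 0)), 0)
  common <- common[order(mean_rank[common])]
  structure(list(features = common,
                 mean_rank = sort(mean_rank),
                 method_lists = lists),
            class = "selection_consensus")
}

#' @export
print.selection_consensus <- function(x, ...) {
  cat("<selection_consensus>\n")
  for (i in seq_along(x$method_lists))
    cat(sprintf("  method %d top: %s\n", i,
                paste(x$method_lists[[i]], collapse = ", ")))
  cat(sprintf("  consensus: %s\n",
              if (length(x$features)) paste(x$features, collapse = ", ")
              else "(empty)"))
  invisible(x)
}
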