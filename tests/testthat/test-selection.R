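test_that("significance ranking behaves at the null and under signal", {
  pf <- patient_features(tab_cohort())
  rk <- rank_by_significance(pf$features, pf$ckd)
  expect_identical(nrow(rk), 15L)
  # planted PR/QRS -> CKD link puts both in the top 5
  expect_true(all(c("pr_interval_ms", "qrs_duration_ms") %in%
                    top_features(rk)))
  # a feature identical in both groups is ranked last with p ~ 0.5
  df <- pf$features
  df$p_axis_deg <- rep(7, nrow(df))  # constant: zero effect
  rk2 <- rank_by_significance(df, pf$ckd)
  expect_equal(rk2$p_value[rk2$feature == "p_axis_deg"], 0.5)
  expect_identical(rk2$feature[15], "p_axis_deg")
  expect_error(rank_by_significance(df, rep(TRUE, nrow(df))),
               "both classes")
})

test_that("significance p-values agree with a permutation oracle", {
  pf <- patient_features(tab_cohort())
  rk <- rank_by_significance(pf$features, pf$ckd)
  # permutation-test p-value for the top feature, one-tailed in the
  # observed direction, must agree within Monte-Carlo error
  f <- "p_axis_deg"  # null feature: p well inside (0, 0.5)
  x <- pf$features[[f]]
  obs <- mean(x[pf$ckd]) - mean(x[!pf$ckd])
  set.seed(42)
  perm <- replicate(2000, {
    l <- sample(pf$ckd)
    mean(x[l]) - mean(x[!l])
  })
  p_perm <- mean(abs(perm) >= abs(obs)) / 2  # one-tailed
  p_pkg <- rk$p_value[rk$feature == f]
  expect_lt(abs(p_perm - p_pkg), 3 * sqrt(p_perm * (1 - p_perm) / 2000) +
              0.002)
})

test_that("significance ranking is invariant to affine rescaling", {
  pf <- patient_features(tab_cohort())
  rk1 <- rank_by_significance(pf$features, pf$ckd)
  df <- pf$features
  df$pr_interval_ms <- df$pr_interval_ms * 37 - 1000
  df$qt_interval_ms <- df$qt_interval_ms / 250 + 3
  rk2 <- rank_by_significance(df, pf$ckd)
  expect_identical(rk1$feature, rk2$feature)
  expect_equal(rk1$p_value, rk2$p_value, tolerance = 1e-12)
})

test_that("PCA ranking is deterministic and its shares are coherent", {
  pf <- patient_features(tab_cohort())
  a <- rank_by_pca(pf$features, seed = 9)
  b <- rank_by_pca(pf$features, seed = 9)
  expect_identical(a, b)
  # per-simulation explained-variance ratios sum to 1 by construction;
  # verify on a single prcomp call of the same standardized table
  X <- scale(as.matrix(pf$features[, ecg_feature_names]))
  ev <- prcomp(X)$sdev^2
  expect_equal(sum(ev / sum(ev)), 1, tolerance = 1e-9)
  expect_true(all(a$avg_explained_variance >= 0))
  expect_true(all(diff(a$avg_explained_variance) <= 1e-12))
  expect_error(rank_by_pca(pf$features[1:5, ]), "10 rows")
})

test_that("a dominant correlated block is ranked first with its
           closed-form variance share", {
  # two strongly correlated copies of one factor among independent
  # noise: the leading eigenvalue of the standardized covariance is
  # 1 + rho, so the block's feature is ranked first with explained
  # variance share (1 + rho) / p
  set.seed(10)
  n <- 4000
  f1 <- rnorm(n)
  rho <- 0.9
  df <- data.frame(
    ventricular_rate_bpm = f1,
    pr_interval_ms = rho * f1 + sqrt(1 - rho^2) * rnorm(n),
    qrs_duration_ms = rnorm(n),
    qt_corrected_ms = rnorm(n),
    p_axis_deg = rnorm(n))
  # restrict scoring to the two leading components so the block's
  # feature is not also assigned the tiny intra-block contrast PC
  rk <- rank_by_pca(df, seed = 1, n_components = 2)
  expect_true(rk$feature[1] %in% c("ventricular_rate_bpm",
                                   "pr_interval_ms"))
  expect_equal(rk$avg_explained_variance[1], (1 + rho) / 5,
               tolerance = 0.03)
})

test_that("lasso selection hits the target count and finds planted signal", {
  pf <- patient_features(tab_cohort())
  sel <- rank_by_lasso(pf$features, pf$ckd, target_k = 5, seed = 1)
  expect_equal(sel$achieved_k, 5L)
  expect_true(sel$converged)
  expect_true(all(c("pr_interval_ms", "qrs_duration_ms") %in%
                    sel$features))
  # labels defined by a threshold on PR alone: PR selected every time,
  # and PR tops the univariate AUC ranking (oracle)
  for (s in 1:5) {
    set.seed(s)
    sub <- pf$features[sample(nrow(pf$features), 200), ]
    lab <- sub$pr_interval_ms > median(sub$pr_interval_ms)
    one <- rank_by_lasso(sub, lab, target_k = 3, seed = s,
                         stability_probe = FALSE)
    expect_true("pr_interval_ms" %in% one$features)
    auc <- vapply(ecg_feature_names, function(f) {
      r <- rank(sub[[f]])
      abs(mean(r[lab]) - mean(r[!lab]))
    }, 0)
    expect_identical(names(which.max(auc)), "pr_interval_ms")
  }
})

test_that("lasso reports all features when unconstrained and flags
           unstable null selections", {
  pf <- patient_features(tab_cohort())
  all_sel <- rank_by_lasso(pf$features, pf$ckd, target_k = 15)
  expect_setequal(all_sel$features, ecg_feature_names)
  # labels independent of all features: selection is unstable
  set.seed(77)
  lab <- sample(c(TRUE, FALSE), nrow(pf$features), replace = TRUE)
  null_sel <- rank_by_lasso(pf$features, lab, target_k = 5, seed = 77)
  expect_true(null_sel$unstable)
})

test_that("consensus is the rank-ordered intersection of top lists", {
  a <- c("A", "B", "C", "D", "E")
  b <- c("B", "C", "F", "G", "H")
  c3 <- c("B", "I", "J", "K", "C")
  cons <- consensus_features(a, b, c3)
  expect_identical(cons$features, c("B", "C"))
  same <- consensus_features(a, a, a)
  expect_identical(same$features, a)
  expect_warning(consensus_features(a, c("X", "Y", "Z", "W", "V")),
                 "empty")
  expect_error(consensus_features(a), "at least 2")
})

test_that("the three-method consensus recovers the planted minimal set", {
  pf <- patient_features(tab_cohort())
  sig <- rank_by_significance(pf$features, pf$ckd)
  pca <- rank_by_pca(pf$features, seed = 3)
  las <- rank_by_lasso(pf$features, pf$ckd, seed = 3)
  cons <- suppressWarnings(consensus_features(sig, pca, las))
  expect_setequal(cons$features, c("pr_interval_ms", "qrs_duration_ms"))
})
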