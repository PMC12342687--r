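test_that("pair-counting metrics match the enumeration oracle on small
           examples", {
  a <- make_partition(c(1, 1, 2, 2))
  b <- make_partition(c(1, 1, 1, 2))
  # co-pairs: A = {12, 34}, B = {12, 13, 23} -> intersection {12}
  expect_equal(as.numeric(cocluster_jaccard(a, b)), 1 / 4)
  expect_equal(rand_index(a, b), 3 / 6)
  expect_equal(as.numeric(cocluster_jaccard(a, a)), 1)
  expect_equal(rand_index(a, a), 1)
  expect_equal(as.numeric(adjusted_rand_index(a, a)), 1)
  # all-singletons vs non-trivial partition: empty intersection
  s <- make_partition(1:4)
  expect_equal(as.numeric(cocluster_jaccard(s, b)), 0)
  # both all-singletons: undefined, returned as 1 with a flag
  j <- cocluster_jaccard(s, make_partition(1:4))
  expect_equal(as.numeric(j), 1)
  expect_true(attr(j, "degenerate"))
  expect_error(cocluster_jaccard(a, make_partition(c(1, 1, 2))),
               "different item sets")
})

test_that("metrics agree with the oracle over every partition of up to
           5 items and random larger ones", {
  # exhaustive battery over all set partitions for n <= 5
  for (n in 2:5) {
    parts <- all_partitions(n)
    for (la in parts) for (lb in parts) {
      pa <- make_partition(la + 1L); pb <- make_partition(lb + 1L)
      orc <- pairs_oracle(la, lb)
      j <- as.numeric(cocluster_jaccard(pa, pb))
      if (is.na(orc$jaccard)) {
        expect_equal(j, 1)  # degenerate convention
      } else expect_equal(j, orc$jaccard)
      expect_equal(rand_index(pa, pb), orc$rand)
    }
  }
  # random partitions of 6-8 items
  set.seed(50)
  for (i in 1:60) {
    n <- sample(6:8, 1)
    la <- sample(1:3, n, replace = TRUE)
    lb <- sample(1:4, n, replace = TRUE)
    orc <- pairs_oracle(la, lb)
    expect_equal(as.numeric(cocluster_jaccard(make_partition(la),
                                              make_partition(lb))),
                 ifelse(is.na(orc$jaccard), 1, orc$jaccard))
    expect_equal(rand_index(make_partition(la), make_partition(lb)),
                 orc$rand)
  }
})

test_that("comparison metrics are invariant to label permutation", {
  set.seed(51)
  la <- sample(1:4, 40, replace = TRUE)
  lb <- sample(1:4, 40, replace = TRUE)
  perm <- sample(1:4)
  a1 <- make_partition(la); a2 <- make_partition(perm[la])
  b <- make_partition(lb)
  expect_equal(as.numeric(cocluster_jaccard(a1, b)),
               as.numeric(cocluster_jaccard(a2, b)))
  expect_equal(rand_index(a1, b), rand_index(a2, b))
  expect_equal(as.numeric(adjusted_rand_index(a1, b)),
               as.numeric(adjusted_rand_index(a2, b)))
})

test_that("adjusted Rand of independent random partitions centres on 0", {
  set.seed(52)
  vals <- replicate(200, {
    la <- sample(1:4, 60, replace = TRUE)
    lb <- sample(1:4, 60, replace = TRUE)
    as.numeric(adjusted_rand_index(make_partition(la),
                                   make_partition(lb)))
  })
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("silhouette behaves at its extremes", {
  # perfect two-block zero/large distance matrix: mean silhouette 1
  n <- 6
  D <- matrix(50, 2 * n, 2 * n)
  D[1:n, 1:n] <- 0; D[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0
  diag(D) <- 0
  ids <- sprintf("i%02d", 1:(2 * n))
  dimnames(D) <- list(ids, ids)
  part <- partition(ids, rep(0:1, each = n), method = "blocks")
  sil <- silhouette_score(part, D, metric = "precomputed")
  expect_equal(sil$mean, 1)
  # two distant tight blobs in feature space
  bl <- rbind(matrix(rnorm(40, 0, 0.05), 20),
              matrix(rnorm(40, 10, 0.05), 20))
  p2 <- partition(as.character(1:40), rep(0:1, each = 20))
  expect_gt(silhouette_score(p2, bl)$mean, 0.9)
  # random labels on one blob: mean near 0
  set.seed(53)
  one <- matrix(rnorm(200), 100)
  means <- replicate(30, {
    pr <- partition(as.character(1:100),
                    sample(0:1, 100, replace = TRUE))
    silhouette_score(pr, one)$mean
  })
  expect_lt(abs(mean(means)), 0.05)
  expect_error(
    silhouette_score(partition(ids, rep(0L, 2 * n), k = 1), D,
                     metric = "precomputed"),
    "at least 2")
})

test_that("bootstrap stability separates stable from unstable structure", {
  bl <- rbind(matrix(rnorm(100, 0, 0.3), 50),
              matrix(rnorm(100, 8, 0.3), 50))
  df <- as.data.frame(bl)
  names(df) <- ecg_feature_names[1:2]
  rownames(df) <- sprintf("i%03d", 1:100)
  ref <- kmeans_features(df, k = 2, seed = 1, ids = rownames(df))
  st <- bootstrap_stability(
    rownames(df),
    function(ids) kmeans_features(df[ids, ], k = 2, seed = 1,
                                  ids = ids),
    ref, subset_size = 70, n_replicates = 10, seed = 2)
  expect_gt(attr(st, "mean_jaccard"), 0.9)
  expect_false(attr(st, "unstable"))
  # pure-noise data: low stability, flagged
  set.seed(54)
  noise <- as.data.frame(matrix(rnorm(80 * 8), 80))
  names(noise) <- ecg_feature_names[1:8]
  rownames(noise) <- sprintf("i%03d", 1:80)
  ref_n <- kmeans_features(noise, k = 6, seed = 1,
                           ids = rownames(noise))
  st_n <- bootstrap_stability(
    rownames(noise),
    function(ids) kmeans_features(noise[ids, ], k = 6, seed = 1,
                                  ids = ids),
    ref_n, subset_size = 50, n_replicates = 10, seed = 3)
  expect_lt(attr(st_n, "mean_jaccard"), attr(st, "mean_jaccard"))
  expect_true(attr(st_n, "unstable"))
  expect_error(bootstrap_stability(rownames(df), identity, ref,
                                   subset_size = 70, n_replicates = 0),
               "positive")
  expect_error(bootstrap_stability(rownames(df), identity, ref,
                                   subset_size = 1000,
                                   n_replicates = 2), "exceeds")
})

test_that("failed replicates are recorded and skipped", {
  df <- data.frame(ventricular_rate_bpm = rnorm(30))
  rownames(df) <- sprintf("i%02d", 1:30)
  ref <- kmeans_features(df, k = 2, seed = 1, ids = rownames(df))
  calls <- 0
  st <- bootstrap_stability(
    rownames(df),
    function(ids) {
      calls <<- calls + 1
      if (calls %% 2 == 0) stop("synthetic failure")
      kmeans_features(df[ids, , drop = FALSE], k = 2, seed = 1,
                      ids = ids)
    },
    ref, subset_size = 20, n_replicates = 6, seed = 4)
  expect_equal(attr(st, "n_failed"), 3L)
  expect_equal(nrow(st), 3L)
})

test_that("enrichment ANOVA reports classical df and detects shifts", {
  set.seed(55)
  ids <- sprintf("i%03d", 1:500)
  part <- partition(ids, rep(0:4, each = 100), method = "test")
  v <- rnorm(500)
  er <- enrichment_anova(part, v)
  expect_identical(er$df, c(4L, 495L))
  expect_false(er$degenerate)
  # one cluster shifted by five sd: overwhelming effect
  v2 <- v; v2[1:100] <- v2[1:100] + 5
  er2 <- enrichment_anova(part, v2)
  expect_lt(er2$p_value, 0.001)
  expect_true(any(er2$posthoc$significant))
  # zero within-cluster variance: infinite F with flag
  v3 <- rep(1:5, each = 100)
  er3 <- enrichment_anova(part, v3)
  expect_true(er3$degenerate)
  expect_identical(er3$f_statistic, Inf)
  # F agrees with the stock ANOVA fit
  fit <- anova(lm(v2 ~ factor(rep(0:4, each = 100))))
  expect_equal(er2$f_statistic, fit$`F value`[1], tolerance = 1e-10)
  expect_error(enrichment_anova(
    partition(ids[1:5], c(0L, 0L, 1L, 1L, 2L), k = 3), rnorm(5)),
    "at least 2")
})

test_that("the feature-wise ANOVA table covers all 15 variables", {
  pf <- patient_features(tab_cohort())
  part <- kmeans_features(pf$features, k = 5, seed = 1)
  tab <- anova_feature_table(part, pf$features)
  expect_identical(tab$feature, ecg_feature_names)
  expect_true(all(tab$df1 == 4))
  expect_true(all(tab$df2 == nrow(pf$features) - 5))
  expect_true(all(is.finite(tab$f_statistic)))
})
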