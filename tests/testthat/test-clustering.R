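blob_features <- function(n_per, centers, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(g)
    matrix(rnorm(n_per * ncol(centers), mean = rep(centers[g, ],
                                                   each = n_per),
                 sd = sd), n_per)))
  df <- as.data.frame(X)
  names(df) <- ecg_feature_names[seq_len(ncol(X))]
  list(df = df, labels = rep(seq_len(nrow(centers)), each = n_per) - 1L)
}

test_that("k-means recovers far-separated blobs exactly", {
  bl <- blob_features(25, rbind(c(0, 0), c(10, 10)), seed = 41)
  part <- kmeans_features(bl$df, k = 2, seed = 1)
  truth <- partition(part$ids, bl$labels, method = "truth")
  expect_equal(as.numeric(adjusted_rand_index(part, truth)), 1)
  expect_error(kmeans_features(bl$df, k = 100), "exceed")
})

test_that("k = 1 gives a single label and WCSS equal to total variance", {
  bl <- blob_features(30, rbind(c(0, 0)), seed = 42)
  part <- kmeans_features(bl$df, k = 1, seed = 1)
  expect_identical(unique(part$labels), 0L)
  Xs <- scale(as.matrix(bl$df))
  expect_equal(attr(part, "wcss"), sum(scale(Xs, scale = FALSE)^2),
               tolerance = 1e-8)
})

test_that("k-means partitions are deterministic under the seed", {
  pf <- patient_features(tab_cohort())
  a <- kmeans_features(pf$features, k = 5, seed = 3)
  b <- kmeans_features(pf$features, k = 5, seed = 3)
  expect_identical(a$labels, b$labels)
})

test_that("Ward on a two-block distance matrix recovers the blocks", {
  n <- 8
  D <- matrix(10, 2 * n, 2 * n)
  D[1:n, 1:n] <- 0; D[(n + 1):(2 * n), (n + 1):(2 * n)] <- 0
  diag(D) <- 0
  dimnames(D) <- list(sprintf("i%02d", 1:(2 * n)),
                      sprintf("i%02d", 1:(2 * n)))
  part <- ward_on_distance(D, k = 2)
  expect_equal(length(unique(part$labels[1:n])), 1L)
  expect_equal(length(unique(part$labels[(n + 1):(2 * n)])), 1L)
  expect_false(part$labels[1] == part$labels[n + 1])
  # k = n gives singletons
  sing <- ward_on_distance(D, k = 2 * n)
  expect_identical(sort(sing$labels), 0:(2 * n - 1))
  # malformed inputs are rejected
  expect_error(ward_on_distance(D - 5), "negative")
  D2 <- D; D2[1, 2] <- 99
  expect_error(ward_on_distance(D2), "symmetric")
})

test_that("Ward on Euclidean distances of 1-D points equals direct 1-D
           Ward clustering", {
  set.seed(43)
  x <- c(rnorm(20, 0), rnorm(20, 6), rnorm(20, 15))
  names(x) <- sprintf("i%02d", seq_along(x))
  D <- as.matrix(dist(x))
  pa <- ward_on_distance(D, k = 3)
  pb <- creatinine_baseline(x - min(x) + 1, k = 3)  # same geometry
  expect_equal(as.numeric(adjusted_rand_index(pa, pb)), 1)
})

test_that("creatinine baseline yields ordered contiguous intervals", {
  x <- c(1, 1, 1, 100, 100, 100) + (1:6) * 1e-6
  part <- creatinine_baseline(x, k = 2)
  expect_identical(part$labels, c(0L, 0L, 0L, 1L, 1L, 1L))
  means <- attr(part, "cluster_means")
  expect_true(all(diff(means) > 0))
  co <- tab_cohort()
  part5 <- creatinine_baseline(setNames(co$truth$creatinine_umol_l,
                                        co$truth$patient_id), k = 5)
  m5 <- attr(part5, "cluster_means")
  expect_true(all(diff(m5) > 0))
  # cluster separation exceeds the pooled within-cluster sd
  wsd <- sqrt(mean(vapply(0:4, function(c)
    var(co$truth$creatinine_umol_l[part5$labels == c]), 0)))
  expect_gt(min(diff(m5)), 0.8 * wsd)
  expect_error(creatinine_baseline(c(1, 1, 1), k = 2), "distinct")
  expect_error(creatinine_baseline(c(-1, 2, 3), k = 2), "positive")
})

test_that("elbow curves find planted structure and flag its absence", {
  bl <- blob_features(30, 4 * rbind(c(0, 0), c(3, 0), c(0, 3),
                                    c(3, 3), c(6, 1.5)), sd = 0.25,
                      seed = 44)
  el <- elbow(bl$df, k_range = 1:9, seed = 1)
  expect_equal(attr(el, "suggested_k"), 5L)
  expect_false(attr(el, "low_confidence"))
  # WCSS(1) equals the total sum of squares (standardized space)
  Xs <- scale(as.matrix(bl$df))
  expect_equal(el$wcss[1], sum(Xs^2), tolerance = 1e-8)
  # non-increasing within tolerance
  expect_true(all(diff(el$wcss) <= 1e-8 + 0.02 * el$wcss[1]))
  # a single blob: no confident suggestion
  one <- blob_features(80, rbind(c(0, 0)), sd = 1, seed = 45)
  el1 <- elbow(one$df, k_range = 1:8, seed = 1)
  expect_true(attr(el1, "low_confidence"))
})

test_that("elbow on a DTW matrix of archetype waveforms suggests the
           planted group count", {
  co <- generate_cohort(40, seed = 46, ecgs_per_patient = 1,
                        n_samples = 800, sampling_rate_hz = 100,
                        noise_sd = 0.02)
  D <- pairwise_dtw(co$signals, dtw_config(band_radius = 40))
  el <- elbow(D, k_range = 1:8)
  expect_equal(attr(el, "suggested_k"), 5L)
  expect_true(all(diff(el$wcss) <= 1e-8))
})

test_that("partition objects validate their invariants", {
  expect_error(partition(c("a", "b"), c(0L, 2L), k = 2), "\\[0, k\\)")
  expect_error(partition(c("a", "a"), c(0L, 1L), k = 2), "duplicated")
  p <- partition(c("a", "b", "c"), c(0L, 1L, 1L), k = 2)
  r <- restrict_partition(p, c("c", "a"))
  expect_identical(r$labels, c(1L, 0L))
  expect_error(restrict_partition(p, "zz"), "not present")
})
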