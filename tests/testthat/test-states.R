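# Exemplar selection, validity indices, correlation k-means, assignment.

test_that("local variance maxima: hand-enumerated cases", {
  # variance series [1,5,1,2,1]: peaks at positions 2 and 4
  expect_equal(dfcstates:::local_maxima(c(1, 5, 1, 2, 1)), c(2L, 4L))
  # strictly monotone: no interior peak, fall back to the global maximum
  expect_equal(dfcstates:::local_maxima(1:7), 7L)
  expect_equal(dfcstates:::local_maxima(7:1), 1L)
  # single interior spike
  expect_equal(dfcstates:::local_maxima(c(0, 0, 3, 0, 0)), 3L)
  # plateau takes the leftmost index
  expect_equal(dfcstates:::local_maxima(c(1, 4, 4, 4, 1, 2, 1)), c(2L, 6L))
})

test_that("select_exemplars returns in-range indices for every subject", {
  cohort <- simulate_cohort(small_cohort_config())
  fsets <- small_feature_sets(cohort)
  ex <- select_exemplars(fsets)
  Wp <- nrow(fsets[[1L]]$features)
  expect_length(ex$indices, length(fsets))
  for (ix in ex$indices) {
    expect_gte(length(ix), 1L)
    expect_true(all(ix >= 1L & ix <= Wp))
  }
  expect_equal(nrow(ex$data), sum(lengths(ex$indices)))
  # pooled rows really are the flagged windows
  first <- ex$index[1L, ]
  expect_equal(unname(ex$data[1L, ]),
               unname(fsets[[1L]]$features[first$window, ]))
})

test_that("davies_bouldin matches a hand-computed Euclidean example", {
  # two clusters on a line: {0, 1} around c1 = 0.5 and {10, 12} around c2 = 11
  data <- matrix(c(0, 1, 10, 12), ncol = 1L)
  labels <- c(1L, 1L, 2L, 2L)
  centroids <- matrix(c(0.5, 11), ncol = 1L)
  # S1 = 0.5, S2 = 1, d(c1, c2) = 10.5 -> DB = (1.5 / 10.5 + 1.5 / 10.5) / 2
  expect_equal(davies_bouldin(data, labels, centroids, metric = "euclidean"),
               1.5 / 10.5, tolerance = 1e-10)
  # invariant to duplicating every point
  expect_equal(davies_bouldin(rbind(data, data), rep(labels, 2L), centroids,
                              metric = "euclidean"),
               1.5 / 10.5, tolerance = 1e-10)
  expect_error(davies_bouldin(data, c(1L, 1L, 1L, 1L), centroids,
                              metric = "euclidean"), "2 non-empty")
  expect_error(davies_bouldin(data, labels, centroids[c(1L, 1L), , drop = FALSE],
                              metric = "euclidean"), "coincident")
})

test_that("ray_turi matches a hand-computed Euclidean example and is monotone", {
  data <- matrix(c(0, 1, 10, 12), ncol = 1L)
  labels <- c(1L, 1L, 2L, 2L)
  centroids <- matrix(c(0.5, 11), ncol = 1L)
  # mean squared within = (0.25 + 0.25 + 1 + 1) / 4; min sep^2 = 10.5^2
  expect_equal(ray_turi(data, labels, centroids, metric = "euclidean"),
               0.625 / 110.25, tolerance = 1e-10)
  # pulling points toward centroids halves spreads -> RT strictly decreases
  shrunk <- matrix(c(0.25, 0.75, 10.5, 11.5), ncol = 1L)
  expect_lt(ray_turi(shrunk, labels, centroids, metric = "euclidean"),
            ray_turi(data, labels, centroids, metric = "euclidean"))
})

test_that("validity indices approach 0 for tight well-separated clusters", {
  set.seed(2)
  base <- rbind(matrix(c(1, 0, 0, 0), 1L), matrix(c(0, 0, 0, 1), 1L))
  data <- base[rep(1:2, each = 20L), ] + matrix(rnorm(160, sd = 1e-4), 40L, 4L)
  labels <- rep(1:2, each = 20L)
  centroids <- rbind(colMeans(data[1:20, ]), colMeans(data[21:40, ]))
  expect_lt(davies_bouldin(data, labels, centroids), 0.01)
  expect_lt(ray_turi(data, labels, centroids), 0.01)
})

test_that("kmeans_correlation: fixed points and affine invariance", {
  set.seed(11)
  protos <- matrix(rnorm(3L * 12L), 3L, 12L)
  data <- protos[rep(1:3, each = 5L), ]
  fit <- kmeans_correlation(data, 3L, replicates = 5L, seed = 2L)
  expect_lt(fit$model$cost, 1e-12)
  # all copies of one prototype share a label
  expect_equal(length(unique(fit$labels[1:5])), 1L)
  expect_equal(length(unique(fit$labels)), 3L)
  # affine rescaling of single rows cannot change the clustering
  data2 <- data
  data2[4L, ] <- 3 * data2[4L, ] + 7
  fit2 <- kmeans_correlation(data2, 3L, replicates = 5L, seed = 2L)
  expect_identical(fit2$labels, fit$labels)
})

test_that("kmeans_correlation cost matches exhaustive bipartition search at n = 6", {
  set.seed(21)
  data <- matrix(rnorm(6L * 8L), 6L, 8L)
  fit <- kmeans_correlation(data, 2L, replicates = 33L, seed = 3L)
  # oracle: all 2^5 - 1 = 31 non-trivial bipartitions, cost from first principles
  xs <- dfcstates:::row_standardize(data)
  part_cost <- function(grp) {
    cost <- 0
    for (g in 0:1) {
      rows <- xs[grp == g, , drop = FALSE]
      cen <- colMeans(rows)
      cen <- (cen - mean(cen)) / sqrt(sum((cen - mean(cen))^2))
      cost <- cost + sum(1 - rows %*% cen)
    }
    cost
  }
  best <- Inf
  for (code in 1:31) {
    grp <- as.integer(intToBits(code))[1:6]
    if (length(unique(grp[1:6])) < 2L) next
    best <- min(best, part_cost(grp[1:6]))
  }
  expect_equal(fit$model$cost, best, tolerance = 1e-10)
})

test_that("replicate costs: best-of never worse, prefix-stable under seed", {
  set.seed(8)
  data <- matrix(rnorm(40L * 6L), 40L, 6L)
  fit8 <- kmeans_correlation(data, 3L, replicates = 8L, seed = 5L)
  fit4 <- kmeans_correlation(data, 3L, replicates = 4L, seed = 5L)
  expect_true(all(fit8$model$cost <= fit8$model$replicate_costs + 1e-12))
  # same seed: the first 4 replicate costs coincide; more replicates never hurt
  expect_equal(fit4$model$replicate_costs, fit8$model$replicate_costs[1:4])
  expect_lte(fit8$model$cost, fit4$model$cost + 1e-12)
})

test_that("states are renumbered by descending occupancy", {
  set.seed(13)
  protos <- matrix(rnorm(2L * 10L), 2L, 10L)
  data <- protos[c(rep(1L, 4L), rep(2L, 16L)), ] +
    matrix(rnorm(200, sd = 0.01), 20L, 10L)
  fit <- kmeans_correlation(data, 2L, replicates = 5L, seed = 1L)
  occ <- tabulate(fit$labels, 2L)
  expect_true(occ[1L] >= occ[2L])
  expect_length(fit$model$relabel_map, 2L)
})

test_that("assign_states agrees with an explicit distance argmin", {
  cohort <- simulate_cohort(small_cohort_config(n_per_group = 2L))
  fsets <- small_feature_sets(cohort)
  cat_ <- concatenate_cohort(fsets)
  fit <- kmeans_correlation(cat_$features, 2L, replicates = 4L, seed = 9L)
  seqs <- assign_states(fit$model, fsets)
  for (i in seq_along(fsets)) {
    x <- dfcstates:::row_standardize(fsets[[i]]$features)
    c_ <- dfcstates:::row_standardize(fit$model$centroids)
    d <- 1 - x %*% t(c_)
    expect_equal(seqs[[i]]$states, unname(apply(d, 1L, which.min)))
  }
  # permutation equivariance of the centroid order
  perm_model <- fit$model
  perm_model$centroids <- perm_model$centroids[c(2L, 1L), ]
  seqs_p <- assign_states(perm_model, fsets)
  expect_equal(seqs_p[[1L]]$states, 3L - seqs[[1L]]$states)
  bad <- fsets[[1L]]
  bad$features <- bad$features[, -1L]
  expect_error(assign_states(fit$model, bad), "dimension")
})

test_that("estimate_k picks 2 for two well-separated blobs, deterministically", {
  set.seed(4)
  protos <- dfcstates:::row_standardize(matrix(rnorm(2L * 30L), 2L, 30L))
  data <- protos[rep(1:2, each = 25L), ] + matrix(rnorm(1500, sd = 0.05), 50L, 30L)
  ex <- list(data = data)
  curve <- estimate_k(ex, k_range = 2:6, replicates = 8L, seed = 7L)
  expect_equal(curve$chosen_k, 2L)
  expect_equal(curve$db_k, 2L)
  expect_true(all(is.finite(curve$curve$db)) && all(curve$curve$db > 0))
  expect_true(all(is.finite(curve$curve$rt)) && all(curve$curve$rt > 0))
  curve2 <- estimate_k(ex, k_range = 2:6, replicates = 8L, seed = 7L)
  expect_identical(curve$curve, curve2$curve)
  # k_range truncated with a warning when exemplars are scarce
  expect_warning(estimate_k(list(data = data[1:6, ]), k_range = 2:10,
                            replicates = 3L, seed = 1L), "truncated")
})

test_that("end-to-end state recovery on well-separated synthetics", {
  # longer dwell than the 47-volume feature support so that pure windows
  # exist; windows spanning a hidden transition are excluded from scoring
  for (k_true in c(2L, 4L)) {
    cfg <- cohort_config(n_per_group = 4L, n_components = 20L,
                         n_volumes = 225L, k_true = k_true,
                         separation = 0.9, mean_dwell_target = 60,
                         noise_sd = 0.2, seed = 100L + k_true)
    cohort <- simulate_cohort(cfg)
    fsets <- lapply(cohort$subjects, function(tc) {
      tc <- preprocess_timecourses(tc)
      zscore_feature_blocks(aswc_and_derivatives(sliding_window_correlations(tc)))
    })
    cat_ <- concatenate_cohort(fsets)
    fit <- kmeans_correlation(cat_$features, k_true, replicates = 8L,
                              max_iter = 500L, seed = 17L)
    # hidden label of each feature window; NA when the 47-volume span mixes states
    span <- 22L + 25L - 1L
    hidden <- unlist(lapply(cohort$subjects, function(su) {
      s <- cohort$ground_truth$states[[su$subject_id]]
      vapply(seq_len(175L), function(w) {
        seg <- s[(w + 3L):(w + 3L + span - 1L)]
        if (length(unique(seg)) == 1L) seg[1L] else NA_integer_
      }, integer(1))
    }), use.names = FALSE)
    pure <- !is.na(hidden)
    expect_gt(mean(pure), 0.05)
    # best label permutation (k small, enumerate)
    perms <- all_permutations(k_true)
    acc <- max(vapply(perms, function(p) {
      mean(p[fit$labels[pure]] == hidden[pure])
    }, numeric(1)))
    expect_gt(acc, 0.8)
  }
})

test_that("spread initialization reaches the same optimum on clean data", {
  set.seed(23)
  protos <- matrix(rnorm(3L * 15L), 3L, 15L)
  data <- protos[rep(1:3, each = 6L), ] + matrix(rnorm(270, sd = 0.02), 18L, 15L)
  f1 <- kmeans_correlation(data, 3L, replicates = 4L, seed = 1L)
  f2 <- kmeans_correlation(data, 3L, replicates = 4L, seed = 1L, init = "spread")
  expect_equal(f2$model$cost, f1$model$cost, tolerance = 1e-8)
})

test_that("estimate_k concentrates on k_true for well-separated cohorts", {
  # full-dimension worlds (53 components) at maximal separation; reduced
  # replicate budget and 5 consecutive seeds for runtime -- the mode over
  # seeds must equal the generating state count
  chosen <- vapply(1:5, function(s) {
    cfg <- cohort_config(seed = s, separation = 1)
    cohort <- simulate_cohort(cfg)
    fsets <- lapply(cohort$subjects, function(tc) {
      tc <- preprocess_timecourses(tc)
      zscore_feature_blocks(aswc_and_derivatives(sliding_window_correlations(tc)))
    })
    ex <- select_exemplars(fsets)
    estimate_k(ex, k_range = 2:8, replicates = 8L, max_iter = 200L,
               seed = 500L + s)$chosen_k
  }, integer(1))
  mode_k <- as.integer(names(which.max(table(chosen))))
  expect_equal(mode_k, 4L)
  # every estimate lands in the immediate neighbourhood of the truth
  expect_true(all(chosen %in% c(4L, 5L)))
})
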