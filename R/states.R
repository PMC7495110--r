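# Dynamic brain-state estimation: exemplar selection, cluster-validity
# indices (Davies-Bouldin, Ray-Turi), k-means under correlation distance,
# and window-to-state assignment.
#
# Correlation distance d(x, c) = 1 - cor(x, c) across features. Internally
# every row is centered and scaled to unit norm, after which the Pearson
# correlation is a plain dot product; k-means under this metric is then
# spherical k-means on the standardized rows, and clustering is invariant to
# per-row affine rescaling of the input.

#' Select exemplar windows at local variance maxima
#'
#' For each subject, the across-feature variance of every window is scanned
#' for strict interior local maxima (plateaus take the leftmost index;
#' endpoints are excluded). A subject with no interior peak contributes its
#' global-maximum window, so every subject yields at least one exemplar.
#'
#' @param feature_sets A single `dfc_features` object or a list of them
#'   (typically z-scored).
#' @return List with `indices` (per-subject integer vectors, 1-based),
#'   `data` (pooled exemplar matrix), and `index` (data.frame subject/window).
#' @export
select_exemplars <- function(feature_sets) {
  if (inherits(feature_sets, "dfc_features")) feature_sets <- list(feature_sets)
  idx_list <- lapply(feature_sets, function(f) {
    v <- apply(f$features, 1L, stats::var)
    if (length(v) < 3L) stopf("subject %s: need at least 3 windows", f$subject_id)
    local_maxima(v)
  })
  names(idx_list) <- vapply(feature_sets, `[[`, character(1), "subject_id")
  data <- do.call(rbind, Map(function(f, ix) f$features[ix, , drop = FALSE],
                             feature_sets, idx_list))
  index <- do.call(rbind, Map(function(f, ix) {
    data.frame(subject_id = f$subject_id, window = ix, stringsAsFactors = FALSE)
  }, feature_sets, idx_list))
  rownames(index) <- NULL
  list(indices = idx_list, data = data, index = index)
}

# Strict interior local maxima of a series; plateaus -> leftmost index;
# fallback to the global maximum when no interior peak exists.
local_maxima <- function(v) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  keep <- logical(nr)
  if (nr >= 3L) {
    for (j in 2:(nr - 1L)) {
      keep[j] <- r$values[j] > r$values[j - 1L] && r$values[j] > r$values[j + 1L]
    }
  }
  out <- starts[keep]
  if (!length(out)) out <- which.max(v)
  out
}

# Distance of every row of x to every centroid row, under the model metric.
distance_to_centroids <- function(x, centroids, metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  centroids <- as.matrix(centroids)
  if (ncol(x) != ncol(centroids)) {
    stopf("feature dimension %d does not match centroid dimension %d",
          ncol(x), ncol(centroids))
  }
  if (metric == "correlation") {
    1 - row_standardize(x) %*% t(row_standardize(centroids))
  } else {
    xx <- rowSums(x^2)
    cc <- rowSums(centroids^2)
    d2 <- outer(xx, cc, "+") - 2 * x %*% t(centroids)
    sqrt(pmax(d2, 0))
  }
}

#' Davies-Bouldin cluster validity index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / d(c_i, c_j)` where `S_i`
#' is the mean distance of cluster-i points to their centroid. Lower is
#' better.
#'
#' @param data Point matrix (rows are observations).
#' @param labels Integer cluster labels `1..k`.
#' @param centroids `k x p` centroid matrix.
#' @param metric Distance used, matching the clustering metric.
#' @return Scalar index.
#' @export
davies_bouldin <- function(data, labels, centroids,
                           metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  k <- nrow(centroids)
  if (length(unique(labels)) < 2L) stopf("need at least 2 non-empty clusters")
  if (any(tabulate(labels, k) == 0L)) stopf("empty cluster in labels")
  D <- distance_to_centroids(data, centroids, metric)
  S <- vapply(seq_len(k), function(i) mean(D[labels == i, i]), numeric(1))
  Dc <- distance_to_centroids(centroids, centroids, metric)
  if (any(Dc[upper.tri(Dc)] <= .Machine$double.eps^0.5)) {
    stopf("coincident centroids: between-centroid distance is zero")
  }
  ratios <- outer(S, S, "+") / Dc
  diag(ratios) <- -Inf
  mean(apply(ratios, 1L, max))
}

#' Ray-Turi cluster validity index
#'
#' Mean squared point-to-own-centroid distance divided by the minimum
#' squared between-centroid distance. Lower is better.
#'
#' @inheritParams davies_bouldin
#' @return Scalar index.
#' @export
ray_turi <- function(data, labels, centroids,
                     metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  k <- nrow(centroids)
  if (length(unique(labels)) < 2L) stopf("need at least 2 non-empty clusters")
  if (any(tabulate(labels, k) == 0L)) stopf("empty cluster in labels")
  D <- distance_to_centroids(data, centroids, metric)
  within <- mean(D[cbind(seq_len(nrow(D)), labels)]^2)
  Dc <- distance_to_centroids(centroids, centroids, metric)
  sep <- min(Dc[upper.tri(Dc)]^2)
  if (sep <= .Machine$double.eps) stopf("coincident centroids: zero separation")
  within / sep
}

#' K-means clustering under correlation distance
#'
#' Lloyd iterations with `d(x, c) = 1 - cor(x, c)`: assignment picks the
#' nearest centroid (ties toward the lower index); the update averages the
#' member rows after row standardization, making the fit invariant to
#' per-row affine rescaling. Each replicate starts from k distinct seeded
#' rows; an emptied cluster is re-seeded from the row farthest from its
#' centroid. The replicate with the lowest total cost wins, and states are
#' renumbered in descending occupancy (state 1 = modal state); the
#' permutation is kept in the model.
#'
#' @param data `n x p` matrix, `n >= k`, no constant rows.
#' @param k Number of clusters.
#' @param replicates Independent restarts (default 33).
#' @param max_iter Maximum Lloyd iterations per replicate (default 4000).
#' @param seed Integer seed; replicate initializations are drawn from one
#'   seeded stream, so the first `m < replicates` restarts of two runs with
#'   the same seed coincide.
#' @param init `"random"` (default): k distinct seeded rows per replicate;
#'   `"spread"`: a seeded first row followed by greedy farthest-point
#'   selection (one deterministic replicate per seeded start).
#' @return List with `model` (class `state_model`: centroids, k, cost,
#'   replicate costs, relabel map, parameters) and `labels` (length-n
#'   integer vector).
#' @export
kmeans_correlation <- function(data, k, replicates = 33L, max_iter = 4000L,
                               seed = 1L, init = c("random", "spread")) {
  init <- match.arg(init)
  data <- as.matrix(data)
  n <- nrow(data)
  if (!is_count(k, min = 1L)) stopf("k must be a positive count")
  if (n < k) stopf("cannot fit %d clusters to %d rows", k, n)
  xs <- row_standardize(data)  # errors on constant rows

  spread_init <- function(first) {
    picked <- first
    while (length(picked) < k) {
      d_min <- 1 - apply(xs %*% t(xs[picked, , drop = FALSE]), 1L, max)
      d_min[picked] <- -Inf
      picked <- c(picked, which.max(d_min))
    }
    picked
  }
  inits <- with_seed(seed, {
    starts <- lapply(seq_len(replicates), function(i) sample.int(n, k))
    if (init == "spread") lapply(starts, function(s) spread_init(s[1L])) else starts
  })

  run_one <- function(init) {
    cent <- xs[init, , drop = FALSE]
    labels <- integer(n)
    for (iter in seq_len(max_iter)) {
      sims <- xs %*% t(row_standardize(cent))
      new_labels <- max.col(sims, ties.method = "first")
      counts <- tabulate(new_labels, k)
      if (any(counts == 0L)) {
        d_own <- 1 - sims[cbind(seq_len(n), new_labels)]
        for (empty in which(counts == 0L)) {
          far <- which.max(d_own)
          new_labels[far] <- empty
          d_own[far] <- -Inf
        }
      }
      if (identical(new_labels, labels)) break
      labels <- new_labels
      cent <- rowsum(xs, labels) / tabulate(labels, k)
    }
    sims <- xs %*% t(row_standardize(cent))
    cost <- sum(1 - sims[cbind(seq_len(n), labels)])
    list(labels = labels, cost = cost)
  }

  fits <- lapply(inits, run_one)
  costs <- vapply(fits, `[[`, numeric(1), "cost")
  best <- fits[[which.min(costs)]]

  # renumber states in descending occupancy; ties keep the original order
  occ <- tabulate(best$labels, k)
  relabel <- order(-occ)                       # new position s holds old label relabel[s]
  map <- integer(k); map[relabel] <- seq_len(k)  # old label -> new label
  labels <- map[best$labels]
  centroids <- (rowsum(xs, labels) / tabulate(labels, k))
  rownames(centroids) <- paste0("state_", seq_len(k))

  model <- structure(list(
    k = as.integer(k), centroids = centroids, distance = "correlation",
    replicates = as.integer(replicates), max_iter = as.integer(max_iter),
    seed = as.integer(seed), cost = min(costs), replicate_costs = costs,
    relabel_map = map
  ), class = "state_model")
  list(model = model, labels = labels)
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, correlation distance, cost %.4f (best of %d replicates)\n",
              x$k, x$cost, x$replicates))
  invisible(x)
}

#' Estimate the number of dynamic brain states
#'
#' Clusters the pooled exemplar windows for every `k` in `k_range` and
#' records the Davies-Bouldin and Ray-Turi validity curves. The chosen `k`
#' minimizes the Ray-Turi index (the sharper ratio criterion on exemplars);
#' the Davies-Bouldin minimizer is reported alongside so disagreements are
#' visible.
#'
#' @param exemplars Result of [select_exemplars()] (or any list with a
#'   numeric `data` matrix).
#' @param k_range Candidate cluster counts (default `2:10`).
#' @param replicates,max_iter Passed to [kmeans_correlation()].
#' @param seed Integer seed (one derived stream per k).
#' @return An object of class `validity_curve`: data.frame `curve` with
#'   columns k, db, rt; `chosen_k` (Ray-Turi minimizer); `db_k`
#'   (Davies-Bouldin minimizer); `chooser` rule label.
#' @export
estimate_k <- function(exemplars, k_range = 2:10, replicates = 33L,
                       max_iter = 4000L, seed = 1L) {
  data <- exemplars$data
  n <- nrow(data)
  if (any(k_range < 2L)) stopf("k_range must start at 2 or above")
  if (max(k_range) >= n) {
    k_range <- k_range[k_range < n]
    if (!length(k_range)) stopf("pooled exemplar count %d too small for any candidate k", n)
    warnf("k_range truncated to 2..%d: only %d exemplars", max(k_range), n)
  }
  rows <- lapply(seq_along(k_range), function(ii) {
    k <- k_range[ii]
    fit <- kmeans_correlation(data, k, replicates = replicates,
                              max_iter = max_iter,
                              seed = derive_seed(seed, k))
    data.frame(k = k,
               db = davies_bouldin(data, fit$labels, fit$model$centroids),
               rt = ray_turi(data, fit$labels, fit$model$centroids))
  })
  curve <- do.call(rbind, rows)
  structure(list(curve = curve,
                 chosen_k = curve$k[which.min(curve$rt)],
                 db_k = curve$k[which.min(curve$db)],
                 chooser = "ray_turi_min"),
            class = "validity_curve")
}

#' @export
print.validity_curve <- function(x, ...) {
  cat(sprintf("<validity_curve> chosen k = %d (Ray-Turi); Davies-Bouldin minimizer k = %d\n",
              x$chosen_k, x$db_k))
  print(x$curve, row.names = FALSE)
  invisible(x)
}

#' Assign cohort windows to the nearest state centroid
#'
#' @param model A `state_model` from [kmeans_correlation()].
#' @param feature_sets A list of `dfc_features` objects (or a single one).
#' @return List of `state_sequence` objects: `subject_id`, `group`,
#'   `states` (integer labels `1..k` per window).
#' @export
assign_states <- function(model, feature_sets) {
  stopifnot(inherits(model, "state_model"))
  if (inherits(feature_sets, "dfc_features")) feature_sets <- list(feature_sets)
  lapply(feature_sets, function(f) {
    D <- distance_to_centroids(f$features, model$centroids, "correlation")
    structure(list(subject_id = f$subject_id, group = f$group,
                   states = max.col(-D, ties.method = "first")),
              class = "state_sequence")
  })
}
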