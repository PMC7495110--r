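# Windowed connectivity features: sliding-window Pearson correlations (SWC),
# averaged sliding-window correlations (ASWC) with first-order derivatives,
# per-subject block z-scoring, cohort concatenation, and static connectivity.

#' Ordered component-pair index
#'
#' Row-major upper-triangle order: (1,2), (1,3), ..., (1,C), (2,3), ...
#' For 53 components this yields 53 * 52 / 2 = 1378 pairs.
#'
#' @param C Number of components (>= 2).
#' @return Data frame with integer columns `i`, `j` (`i < j`) and a `pair`
#'   label.
#' @export
vectorize_pairs <- function(C) {
  if (!is_count(C, min = 2L)) stopf("need at least 2 components, got %s", C)
  i <- rep(seq_len(C - 1L), times = (C - 1L):1L)
  j <- unlist(lapply(seq_len(C - 1L), function(a) (a + 1L):C), use.names = FALSE)
  data.frame(i = i, j = j, pair = sprintf("c%02d-c%02d", i, j))
}

# Extract the upper triangle of a C x C matrix in vectorize_pairs() order.
ut_vector <- function(m) t(m)[lower.tri(m)]

#' Sliding-window correlations
#'
#' Window `w` (1-based) covers volumes `[w, w + window_size_tr - 1]`; the
#' number of windows is `floor((T - window_size_tr) / step_tr)`, the
#' convention under which 222 volumes with a 22-TR window give 200 windows.
#' A zero-variance component inside a window yields correlation 0 for its
#' pairs, with a warning (keeps downstream clustering total).
#'
#' @param tc A [component_timecourses()] object.
#' @param window_size_tr Window length in TR (default 22, i.e. 44 s at TR 2 s).
#' @param step_tr Window shift in TR (default 1).
#' @return An object of class `swc_series` with fields `windows`
#'   (`W x P` matrix), `pair_index`, `window_size_tr`, `step_tr`,
#'   `subject_id`, `group`, `tr_seconds`.
#' @export
sliding_window_correlations <- function(tc, window_size_tr = 22L, step_tr = 1L) {
  stopifnot(inherits(tc, "component_timecourses"))
  if (!is_count(window_size_tr, min = 3L)) stopf("window_size_tr must be >= 3")
  if (!is_count(step_tr)) stopf("step_tr must be a positive count")
  Tn <- nrow(tc$data)
  if (Tn < window_size_tr + 1L) {
    stopf("subject %s: %d volumes cannot host a %d-TR window plus one step",
          tc$subject_id, Tn, window_size_tr)
  }
  W <- (Tn - window_size_tr) %/% step_tr
  pairs <- vectorize_pairs(ncol(tc$data))
  out <- matrix(NA_real_, W, nrow(pairs))
  degenerate <- FALSE
  for (w in seq_len(W)) {
    start <- (w - 1L) * step_tr + 1L
    seg <- tc$data[start:(start + window_size_tr - 1L), , drop = FALSE]
    if (any(apply(seg, 2L, stats::sd) == 0)) {
      degenerate <- TRUE
      cm <- suppressWarnings(stats::cor(seg))
      cm[!is.finite(cm)] <- 0
    } else {
      cm <- stats::cor(seg)
    }
    out[w, ] <- ut_vector(cm)
  }
  if (degenerate) {
    warnf("subject %s: zero-variance component in at least one window; affected correlations set to 0",
          tc$subject_id)
  }
  colnames(out) <- pairs$pair
  structure(list(subject_id = tc$subject_id, group = tc$group,
                 windows = out, pair_index = pairs,
                 window_size_tr = as.integer(window_size_tr),
                 step_tr = as.integer(step_tr),
                 tr_seconds = tc$tr_seconds),
            class = "swc_series")
}

#' ASWC and first-order derivative features
#'
#' Averages `aswc_window` consecutive SWC windows (`ASWC_raw(t)` = mean of
#' windows `t .. t + aswc_window - 1`) and takes first differences as the
#' "speed" of connectivity change. The last raw ASWC window is dropped so
#' both blocks share indices: with 200 SWC windows and a 25-window average
#' this leaves 175 aligned windows of `2 P` features (ASWC block first).
#'
#' @param swc An `swc_series` from [sliding_window_correlations()].
#' @param aswc_window Number of SWC windows averaged (default 25).
#' @param drop Which raw ASWC window to discard for alignment with the
#'   derivative block: `"last"` (default) or `"first"`.
#' @return An object of class `dfc_features` with fields `aswc`,
#'   `derivatives`, `features` (`W' x 2P`), `zscored` flag and bookkeeping.
#' @export
aswc_and_derivatives <- function(swc, aswc_window = 25L,
                                 drop = c("last", "first")) {
  drop <- match.arg(drop)
  stopifnot(inherits(swc, "swc_series"))
  W <- nrow(swc$windows)
  if (!is_count(aswc_window)) stopf("aswc_window must be a positive count")
  if (W < aswc_window + 1L) {
    stopf("subject %s: %d SWC windows < required minimum %d (aswc_window + 1)",
          swc$subject_id, W, aswc_window + 1L)
  }
  P <- ncol(swc$windows)
  cs <- rbind(0, apply(swc$windows, 2L, cumsum))
  n_raw <- W - aswc_window + 1L
  raw <- (cs[(aswc_window + 1L):(W + 1L), , drop = FALSE] -
            cs[1:n_raw, , drop = FALSE]) / aswc_window
  deriv <- raw[-1L, , drop = FALSE] - raw[-n_raw, , drop = FALSE]
  aswc <- if (drop == "last") raw[-n_raw, , drop = FALSE] else raw[-1L, , drop = FALSE]
  colnames(aswc) <- colnames(swc$windows)
  colnames(deriv) <- paste0("d_", colnames(swc$windows))
  structure(list(subject_id = swc$subject_id, group = swc$group,
                 aswc = aswc, derivatives = deriv,
                 features = cbind(aswc, deriv),
                 pair_index = swc$pair_index,
                 window_size_tr = swc$window_size_tr,
                 aswc_window = as.integer(aswc_window),
                 tr_seconds = swc$tr_seconds,
                 zscored = FALSE),
            class = "dfc_features")
}

#' Z-score the ASWC and derivative blocks separately
#'
#' Standardizes each block over all of its entries (grand mean 0, grand SD 1
#' per block, per subject), so the two blocks enter clustering on the same
#' scale despite their different native magnitudes.
#'
#' @param fs A `dfc_features` object.
#' @param scope `"block"` (default): one grand mean/SD per block;
#'   `"feature"`: standardize every feature column separately within its
#'   block.
#' @return The object with standardized blocks and `zscored = TRUE`.
#' @export
zscore_feature_blocks <- function(fs, scope = c("block", "feature")) {
  scope <- match.arg(scope)
  stopifnot(inherits(fs, "dfc_features"))
  zs <- function(block, label) {
    if (scope == "feature") {
      s <- apply(block, 2L, stats::sd)
      if (any(s == 0)) stopf("subject %s: constant feature column in %s block",
                             fs$subject_id, label)
      return(sweep(sweep(block, 2L, colMeans(block)), 2L, s, "/"))
    }
    s <- stats::sd(block)
    if (s == 0) stopf("subject %s: %s block is constant, cannot z-score",
                      fs$subject_id, label)
    (block - mean(block)) / s
  }
  fs$aswc <- zs(fs$aswc, "ASWC")
  fs$derivatives <- zs(fs$derivatives, "derivative")
  fs$features <- cbind(fs$aswc, fs$derivatives)
  fs$zscored <- TRUE
  fs
}

#' Concatenate feature sets across a cohort
#'
#' Rows are stacked in the order given; an index maps each row back to its
#' subject and window so the stack can be de-concatenated exactly.
#'
#' @param feature_sets List of `dfc_features` objects sharing window count
#'   and feature dimension.
#' @return List with `features` (stacked matrix), `index` (data.frame:
#'   subject_id, group, window) and `groups` (per-subject labels).
#' @export
concatenate_cohort <- function(feature_sets) {
  if (!length(feature_sets)) stopf("no feature sets supplied")
  dims <- vapply(feature_sets, function(f) dim(f$features), integer(2))
  for (i in seq_along(feature_sets)) {
    if (any(dims[, i] != dims[, 1L])) {
      stopf("subject %s has feature shape %d x %d, expected %d x %d",
            feature_sets[[i]]$subject_id, dims[1L, i], dims[2L, i],
            dims[1L, 1L], dims[2L, 1L])
    }
  }
  mats <- lapply(feature_sets, `[[`, "features")
  idx <- do.call(rbind, lapply(feature_sets, function(f) {
    data.frame(subject_id = f$subject_id, group = f$group,
               window = seq_len(nrow(f$features)), stringsAsFactors = FALSE)
  }))
  rownames(idx) <- NULL
  list(features = do.call(rbind, mats), index = idx,
       groups = vapply(feature_sets, `[[`, character(1), "group"))
}

#' Static (full-length) functional connectivity
#'
#' Pearson correlation over the entire filtered time course, optionally on a
#' component subset (e.g. the sensorimotor components).
#'
#' @param tc A [component_timecourses()] object.
#' @param subset Optional integer vector of component indices.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
static_fc <- function(tc, subset = NULL) {
  stopifnot(inherits(tc, "component_timecourses"))
  x <- tc$data
  if (!is.null(subset)) {
    if (any(subset < 1L) || any(subset > ncol(x))) {
      stopf("subset indices out of range 1..%d", ncol(x))
    }
    x <- x[, subset, drop = FALSE]
  }
  if (any(apply(x, 2L, stats::sd) == 0)) {
    stopf("subject %s: zero-variance component in static connectivity input",
          tc$subject_id)
  }
  stats::cor(x)
}
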