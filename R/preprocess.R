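# Time-course conditioning applied before any dynamic-connectivity step:
# volume discarding, nuisance orthogonalization, despiking, zero-phase
# band-pass filtering, and framewise-displacement summaries.

#' Per-subject component time courses
#'
#' @param subject_id Subject identifier.
#' @param group Group label, `"patient"` or `"control"`.
#' @param data Numeric `T x C` matrix: rows are volumes, columns are
#'   component amplitudes (arbitrary units).
#' @param tr_seconds Repetition time in seconds.
#' @return An object of class `component_timecourses`.
#' @export
component_timecourses <- function(subject_id, group, data, tr_seconds = 2.0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stopf("time-course data must be numeric")
  if (anyNA(data)) stopf("subject %s: time courses contain missing values", subject_id)
  if (ncol(data) < 2L) stopf("subject %s: need at least 2 components", subject_id)
  group <- match.arg(group, c("patient", "control"))
  if (tr_seconds <= 0) stopf("tr_seconds must be positive")
  structure(list(subject_id = as.character(subject_id), group = group,
                 data = data, tr_seconds = tr_seconds),
            class = "component_timecourses")
}

#' @export
print.component_timecourses <- function(x, ...) {
  cat(sprintf("<component_timecourses> %s (%s): %d volumes x %d components, TR %gs\n",
              x$subject_id, x$group, nrow(x$data), ncol(x$data), x$tr_seconds))
  invisible(x)
}

#' Discard initial volumes (T1-disequilibrium dummy scans)
#'
#' @param tc A [component_timecourses()] object.
#' @param n_discard Number of leading volumes to drop (default 3).
#' @return The object with `n_discard` fewer rows.
#' @export
discard_initial_volumes <- function(tc, n_discard = 3L) {
  stopifnot(inherits(tc, "component_timecourses"))
  if (!is_count(n_discard, min = 0L)) stopf("n_discard must be a non-negative count")
  Tn <- nrow(tc$data)
  if (n_discard >= Tn) {
    stopf("subject %s: cannot discard %d of %d volumes", tc$subject_id, n_discard, Tn)
  }
  if (n_discard == 0L) return(tc)
  tc$data <- tc$data[-seq_len(n_discard), , drop = FALSE]
  tc
}

#' Orthogonalize time courses with respect to nuisance regressors
#'
#' Replaces every component signal with its least-squares residual on
#' `[intercept | regressors]`. With an empty regressor matrix this is plain
#' column demeaning.
#'
#' @param tc A [component_timecourses()] object.
#' @param regressors Numeric `T x R` matrix (may have zero columns).
#' @return The object with residualized time courses.
#' @export
regress_nuisance <- function(tc, regressors = NULL) {
  stopifnot(inherits(tc, "component_timecourses"))
  Tn <- nrow(tc$data)
  if (is.null(regressors)) regressors <- matrix(0, Tn, 0L)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != Tn) {
    stopf("regressors have %d rows but the time courses have %d volumes",
          nrow(regressors), Tn)
  }
  X <- cbind(intercept = 1, regressors)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if (is.null(dropped)) dropped <- qrX$pivot[(qrX$rank + 1L):ncol(X)]
    stopf("nuisance design is rank deficient; collinear column(s): %s",
          paste(dropped, collapse = ", "))
  }
  tc$data <- qr.resid(qrX, tc$data)
  tc
}

#' Build the 12-column motion regressor matrix
#'
#' Columns 1-6 are the six realignment parameters, columns 7-12 their first
#' backward differences (first row zero).
#'
#' @param mp `6 x T` motion-parameter matrix (3 translations in mm, 3
#'   rotations in radians).
#' @return A `T x 12` matrix.
#' @export
build_motion_regressors <- function(mp) {
  mp <- as.matrix(mp)
  if (nrow(mp) != 6L) stopf("motion parameters must have exactly 6 rows, got %d", nrow(mp))
  p <- t(mp)
  d <- rbind(0, diff(p))
  out <- cbind(p, d)
  colnames(out) <- c(paste0("mp", 1:6), paste0("mp", 1:6, "_d1"))
  out
}

#' Framewise displacement from realignment parameters
#'
#' `FD(t)` is the sum of absolute backward differences of the six rigid-body
#' parameters, with rotations converted to millimetres of arc on a sphere of
#' radius `sphere_radius_mm`. The first frame has no predecessor and is 0.
#'
#' @param mp `6 x T` motion-parameter matrix (translations mm, rotations rad).
#' @param sphere_radius_mm Rotation-to-displacement conversion radius.
#' @return List with `values` (length-T non-negative series, mm) and
#'   `mean_fd` (scalar mm).
#' @export
framewise_displacement <- function(mp, sphere_radius_mm = 50) {
  mp <- as.matrix(mp)
  if (nrow(mp) != 6L) stopf("motion parameters must have exactly 6 rows, got %d", nrow(mp))
  d <- abs(mp - cbind(mp[, 1L], mp[, -ncol(mp), drop = FALSE]))
  fd <- colSums(d[1:3, , drop = FALSE]) +
    sphere_radius_mm * colSums(d[4:6, , drop = FALSE])
  list(values = as.numeric(fd), mean_fd = mean(fd))
}

#' Despike a series with a running-median / MAD detector
#'
#' Samples whose robust z-score against an 11-point running median exceeds
#' `mad_threshold` are shrunk toward the local median through a smooth
#' `tanh` squashing, so the post-despike robust z never exceeds
#' `mad_threshold + 1`. Samples below threshold are untouched; a constant
#' series is returned unchanged.
#'
#' @param series Numeric vector, length >= 5.
#' @param mad_threshold Robust z-score threshold (default 4).
#' @return The despiked series.
#' @export
despike <- function(series, mad_threshold = 4) {
  if (length(series) < 5L) stopf("despike needs at least 5 samples")
  med <- stats::runmed(series, k = min(11L, 2L * (length(series) %/% 2L) - 1L),
                       endrule = "median")
  resid <- series - med
  scale <- stats::mad(resid)
  if (scale == 0) return(series)
  z <- resid / scale
  hot <- abs(z) > mad_threshold
  if (!any(hot)) return(series)
  zs <- z[hot]
  z[hot] <- sign(zs) * (mad_threshold + tanh(abs(zs) - mad_threshold))
  med + z * scale
}

# --- Butterworth band-pass design + zero-phase application -----------------
# The environment carries no DSP package, so the filter is designed from the
# analog prototype by pole placement, low-pass-to-band-pass transform, and
# bilinear transform (standard zpk route), then applied forward-backward.

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Design a digital Butterworth band-pass filter
#'
#' @param order Prototype order (the band-pass transfer function has
#'   `2 * order` poles).
#' @param low_hz,high_hz Band edges in Hz.
#' @param fs Sampling frequency in Hz.
#' @return List with numerator `b` and denominator `a` coefficients.
#' @export
butter_bandpass <- function(order, low_hz, high_hz, fs) {
  if (!(0 < low_hz && low_hz < high_hz && high_hz < fs / 2)) {
    stopf("band edges must satisfy 0 < low (%.4g) < high (%.4g) < Nyquist (%.4g)",
          low_hz, high_hz, fs / 2)
  }
  # analog low-pass prototype (unit cutoff)
  kk <- seq_len(order)
  p <- exp(1i * pi * (2 * kk + order - 1) / (2 * order))
  z <- complex(0)
  g <- 1
  # pre-warped band edges for the bilinear transform at internal fs = 2
  wn <- c(low_hz, high_hz) / (fs / 2)
  warped <- 4 * tan(pi * wn / 2)
  wo <- sqrt(warped[1] * warped[2])
  bw <- warped[2] - warped[1]
  # low-pass -> band-pass
  degree <- length(p) - length(z)
  p_lp <- p * bw / 2
  p_bp <- c(p_lp + sqrt(p_lp^2 - wo^2), p_lp - sqrt(p_lp^2 - wo^2))
  z_bp <- rep(0 + 0i, degree)
  g_bp <- g * bw^degree
  # bilinear transform (fs = 2 -> fs2 = 4)
  fs2 <- 4
  z_d <- c((fs2 + z_bp) / (fs2 - z_bp), rep(-1 + 0i, length(p_bp) - length(z_bp)))
  p_d <- (fs2 + p_bp) / (fs2 - p_bp)
  g_d <- g_bp * Re(prod(fs2 - z_bp) / prod(fs2 - p_bp))
  b <- Re(poly_from_roots(z_d)) * g_d
  a <- Re(poly_from_roots(p_d))
  list(b = b, a = a)
}

# Direct-form-II-transposed IIR filter over the rows of a matrix, vectorized
# across columns. `zi` is an (n-1) x C matrix of initial states (or NULL).
iir_filter <- function(b, a, x, zi = NULL) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  Tn <- nrow(x); C <- ncol(x)
  z <- if (is.null(zi)) matrix(0, n - 1L, C) else zi
  y <- matrix(0, Tn, C)
  for (t in seq_len(Tn)) {
    xt <- x[t, ]
    yt <- b[1] * xt + z[1L, ]
    if (n > 2L) {
      z[1:(n - 2L), ] <- b[2:(n - 1L)] %o% xt + z[2:(n - 1L), , drop = FALSE] -
        a[2:(n - 1L)] %o% yt
    }
    z[n - 1L, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  y
}

# Steady-state initial conditions for unit step input (companion solve),
# used so filtfilt transients vanish for constant signals.
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b))) / a[1]
  a <- c(a, rep(0, n - length(a))) / a[1]
  comp <- rbind(-a[2:n], cbind(diag(1, n - 2L), rep(0, n - 2L)))
  IminusA <- diag(1, n - 1L) - t(comp)
  B <- b[2:n] - a[2:n] * b[1]
  solve(IminusA, B)
}

# Zero-phase forward-backward filtering of each column of x, with odd
# reflection padding of length 3 * (filter order) at both ends.
filtfilt_matrix <- function(b, a, x) {
  x <- as.matrix(x)
  Tn <- nrow(x)
  npad <- 3L * max(length(a), length(b))
  if (Tn <= npad) stopf("series too short to band-pass: need more than %d samples", npad)
  pre <- 2 * matrix(x[1L, ], npad, ncol(x), byrow = TRUE) -
    x[(npad + 1L):2L, , drop = FALSE]
  post <- 2 * matrix(x[Tn, ], npad, ncol(x), byrow = TRUE) -
    x[(Tn - 1L):(Tn - npad), , drop = FALSE]
  ext <- rbind(pre, x, post)
  zi <- filter_zi(b, a)
  y <- iir_filter(b, a, ext, zi = zi %o% ext[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y <- iir_filter(b, a, y, zi = zi %o% y[1L, ])
  y <- y[nrow(y):1L, , drop = FALSE]
  y[(npad + 1L):(npad + Tn), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies a fifth-order Butterworth band-pass (0.01-0.15 Hz by default)
#' forward and backward, so no phase shift is introduced; the effective
#' magnitude order doubles. Accepts a vector or a `T x C` matrix (columns
#' filtered independently).
#'
#' @param series Numeric vector or matrix.
#' @param low_hz,high_hz Pass-band edges in Hz.
#' @param order Butterworth prototype order (default 5).
#' @param tr_seconds Sampling interval in seconds (`fs = 1/tr_seconds`).
#' @return Filtered series with the input's shape.
#' @export
bandpass <- function(series, low_hz = 0.01, high_hz = 0.15, order = 5L,
                     tr_seconds = 2.0) {
  fs <- 1 / tr_seconds
  ba <- butter_bandpass(order, low_hz, high_hz, fs)
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1L) else as.matrix(series)
  y <- filtfilt_matrix(ba$b, ba$a, x)
  if (vec) as.numeric(y) else {
    dimnames(y) <- dimnames(x)
    y
  }
}

#' Standard conditioning chain for one subject
#'
#' Enforces the fixed stage order discard -> (optional) nuisance regression
#' -> despike -> band-pass.
#'
#' @param tc A [component_timecourses()] object.
#' @param n_discard Leading volumes to drop.
#' @param motion Optional `6 x T` motion matrix (pre-discard length). When
#'   supplied and `regress_motion = TRUE`, the 12 motion regressors plus
#'   linear, quadratic and cubic trends are regressed out after discarding.
#' @param regress_motion Apply nuisance regression (default `FALSE`; real
#'   component time courses usually arrive post-cleaning).
#' @param mad_threshold Despiking threshold.
#' @param low_hz,high_hz,order Band-pass settings.
#' @return The conditioned [component_timecourses()] object.
#' @export
preprocess_timecourses <- function(tc, n_discard = 3L, motion = NULL,
                                   regress_motion = FALSE, mad_threshold = 4,
                                   low_hz = 0.01, high_hz = 0.15, order = 5L) {
  tc <- discard_initial_volumes(tc, n_discard)
  if (regress_motion) {
    if (is.null(motion)) stopf("regress_motion = TRUE requires a motion matrix")
    mr <- build_motion_regressors(motion)
    if (n_discard > 0L) mr <- mr[-seq_len(n_discard), , drop = FALSE]
    t_idx <- seq_len(nrow(tc$data)) / nrow(tc$data)
    reg <- cbind(mr, trend1 = t_idx, trend2 = t_idx^2, trend3 = t_idx^3)
    tc <- regress_nuisance(tc, reg)
  }
  tc$data <- apply(tc$data, 2L, despike, mad_threshold = mad_threshold)
  tc$data <- bandpass(tc$data, low_hz = low_hz, high_hz = high_hz,
                      order = order, tr_seconds = tc$tr_seconds)
  tc
}
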