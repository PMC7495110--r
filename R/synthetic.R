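# Synthetic cohort generator: Markov-switching multivariate-normal component
# time courses with known ground truth, emulating a resting-state recording of
# 225 volumes (TR 2 s) projected onto 53 independent components grouped into
# seven functional subdomains.

# Component counts of the seven subdomains (AUD, CER, CON, DMN, SCN, SMN, VIS).
SUBDOMAIN_SIZES <- c(AUD = 2L, CER = 4L, CON = 17L, DMN = 7L, SCN = 5L,
                     SMN = 9L, VIS = 9L)

#' Configuration for a synthetic dynamic-connectivity cohort
#'
#' Describes a two-group cohort whose per-volume component amplitudes are
#' drawn from a multivariate normal whose covariance switches among `k_true`
#' latent states according to a first-order Markov chain. The defaults mirror
#' a typical single-run resting-state acquisition: 225 volumes at TR 2 s and
#' 53 components, 17 subjects per group.
#'
#' @param n_per_group Subjects per group (patients and controls).
#' @param n_components Number of components (columns of each time course).
#' @param n_volumes Number of time points per subject before any discarding.
#' @param tr_seconds Repetition time in seconds.
#' @param k_true Number of latent covariance states.
#' @param state_covariances Optional list of `k_true` symmetric
#'   positive-definite `n_components x n_components` matrices. Defaults to
#'   [make_state_covariances()] with `separation`.
#' @param markov_matrix Optional `k_true x k_true` row-stochastic matrix
#'   (includes self-transitions). Defaults to a chain with uniform
#'   off-diagonal mass and mean dwell `mean_dwell_target`.
#' @param mean_dwell_target Expected volumes per state visit used to build
#'   the default chain (diagonal `1 - 1/mean_dwell_target`).
#' @param noise_sd Isotropic observation-noise standard deviation added on
#'   top of the state covariance.
#' @param group_effect Scalar in `[0, 1)`. For patients, moves transition
#'   mass toward state 1 (occupancy/dwell shift); 0 means the groups share
#'   one generating chain.
#' @param separation Separation in `(0, 1]` passed to
#'   [make_state_covariances()] when `state_covariances` is `NULL`.
#' @param motion_amplitude Per-volume random-walk scale for the simulated
#'   rigid-body motion traces (mm / radians).
#' @param seed Master seed; per-subject streams are derived from it, so
#'   enlarging the cohort never reshuffles existing subjects.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 17L,
                          n_components = 53L,
                          n_volumes = 225L,
                          tr_seconds = 2.0,
                          k_true = 4L,
                          state_covariances = NULL,
                          markov_matrix = NULL,
                          mean_dwell_target = 40,
                          noise_sd = 0.3,
                          group_effect = 0,
                          separation = 0.8,
                          motion_amplitude = 0.02,
                          seed = 1L) {
  if (!is_count(n_per_group)) stopf("n_per_group must be a positive count")
  if (!is_count(n_components, min = 2L)) stopf("n_components must be >= 2")
  if (!is_count(k_true)) stopf("k_true must be a positive count")
  # downstream windowing needs T > discard + swc window + aswc window
  if (!is_count(n_volumes, min = 51L) || n_volumes <= 3L + 22L + 25L) {
    stopf("n_volumes must exceed 3 + 22 + 25 = 50 for the default windowing")
  }
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (group_effect < 0 || group_effect >= 1) stopf("group_effect must be in [0, 1)")
  if (mean_dwell_target <= 1) stopf("mean_dwell_target must exceed 1 volume")

  if (is.null(state_covariances)) {
    state_covariances <- make_state_covariances(
      n_components = n_components, k_true = k_true,
      separation = separation, seed = seed
    )
  }
  if (length(state_covariances) != k_true) {
    stopf("need %d state covariances, got %d", k_true, length(state_covariances))
  }
  for (s in seq_along(state_covariances)) {
    cv <- state_covariances[[s]]
    if (!is.matrix(cv) || nrow(cv) != n_components || ncol(cv) != n_components) {
      stopf("state covariance %d is not %d x %d", s, n_components, n_components)
    }
    if (max(abs(cv - t(cv))) > 1e-8) stopf("state covariance %d is not symmetric", s)
    ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stopf("state covariance %d is not positive definite (min eigenvalue %.3g)",
            s, min(ev))
    }
  }

  if (is.null(markov_matrix)) {
    stay <- 1 - 1 / mean_dwell_target
    markov_matrix <- matrix((1 - stay) / max(k_true - 1L, 1L), k_true, k_true)
    diag(markov_matrix) <- if (k_true == 1L) 1 else stay
  }
  if (!is.matrix(markov_matrix) || any(dim(markov_matrix) != k_true)) {
    stopf("markov_matrix must be %d x %d", k_true, k_true)
  }
  if (any(markov_matrix < 0) || any(abs(rowSums(markov_matrix) - 1) > 1e-12)) {
    stopf("markov_matrix rows must be non-negative and sum to 1 (tol 1e-12)")
  }

  structure(list(
    n_per_group = as.integer(n_per_group),
    n_components = as.integer(n_components),
    n_volumes = as.integer(n_volumes),
    tr_seconds = tr_seconds,
    k_true = as.integer(k_true),
    state_covariances = state_covariances,
    markov_matrix = markov_matrix,
    mean_dwell_target = mean_dwell_target,
    noise_sd = noise_sd,
    group_effect = group_effect,
    separation = separation,
    motion_amplitude = motion_amplitude,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' Build distinct positive-definite state covariance (correlation) matrices
#'
#' Each state's matrix is a convex blend of a shared backbone pattern and a
#' state-specific pattern, both rank-one in a vector of subdomain signs:
#' `C_s = (1 - a - b) I + a u0 u0' + b u_s u_s'` with `a = strength (1 -
#' separation)` and `b = strength * separation`. Components within one
#' subdomain always share a sign, so every state shows high within-subdomain
#' connectivity with mostly negative correlations between subdomains, while
#' the sign assignment of the subdomains differs between states. At
#' `separation = 1` the shared backbone vanishes and the vectorized matrices
#' of different states are (slightly negatively) correlated; lowering
#' `separation` raises their similarity toward 1.
#'
#' @param n_components Total number of components.
#' @param k_true Number of states.
#' @param block_structure Integer vector of subdomain sizes partitioning the
#'   components; must sum to `n_components`. Default: the seven functional
#'   subdomain sizes 2, 4, 17, 7, 5, 9, 9.
#' @param separation State distinctness in `(0, 1]`.
#' @param strength Overall off-diagonal correlation magnitude.
#' @param seed Unused for the deterministic sign search; kept so callers can
#'   treat the constructor uniformly with the other generators.
#' @return List of `k_true` correlation matrices (unit diagonal, symmetric
#'   positive definite).
#' @export
make_state_covariances <- function(n_components = 53L,
                                   k_true = 4L,
                                   block_structure = NULL,
                                   separation = 0.8,
                                   strength = 0.6,
                                   seed = 1L) {
  if (is.null(block_structure)) {
    block_structure <- if (n_components == 53L) unname(SUBDOMAIN_SIZES) else {
      # spread components over 7 near-equal pseudo-subdomains
      sz <- rep(n_components %/% 7L, 7L)
      sz[seq_len(n_components %% 7L)] <- sz[seq_len(n_components %% 7L)] + 1L
      sz[sz > 0L]
    }
  }
  if (sum(block_structure) != n_components) {
    stopf("block_structure sums to %d, not n_components = %d",
          sum(block_structure), n_components)
  }
  if (separation <= 0 || separation > 1) stopf("separation must be in (0, 1]")
  if (strength <= 0 || strength >= 1) stopf("strength must be in (0, 1)")
  nb <- length(block_structure)
  block_of <- rep(seq_len(nb), times = block_structure)

  # Enumerate block-sign assignments up to a global flip (first block fixed
  # at +1) and greedily pick k_true + 1 assignments whose component-level
  # rank-one patterns are minimally correlated pairwise. Deterministic.
  n_assign <- 2L^(nb - 1L)
  signs <- matrix(1L, n_assign, nb)
  for (j in 2:nb) {
    signs[, j] <- ifelse(bitwAnd(seq_len(n_assign) - 1L, bitwShiftL(1L, j - 2L)) > 0L, -1L, 1L)
  }
  ut <- upper.tri(matrix(0, n_components, n_components))
  pat <- function(u_block) {
    u <- u_block[block_of]
    (u %o% u)[ut]
  }
  pats <- t(apply(signs, 1L, pat))
  # the all-plus assignment has a constant (degenerate) pattern; exclude it
  usable <- which(apply(pats, 1L, stats::sd) > 0)
  need <- k_true + 1L  # +1 for the shared backbone
  if (length(usable) < need) stopf("not enough distinct sign patterns for k_true = %d", k_true)
  # start from the most balanced split, then grow greedily
  balance <- abs(as.vector(signs %*% block_structure))
  balance[-usable] <- Inf
  chosen <- which.min(balance + seq_len(n_assign) / (n_assign + 1))  # ties -> lowest index
  while (length(chosen) < need) {
    cand <- setdiff(usable, chosen)
    score <- vapply(cand, function(i) {
      max(abs(stats::cor(pats[i, ], t(pats[chosen, , drop = FALSE]))))
    }, numeric(1))
    chosen <- c(chosen, cand[which.min(score)])
  }
  u0 <- signs[chosen[1L], ][block_of]
  a <- strength * (1 - separation)
  b <- strength * separation
  lapply(seq_len(k_true), function(s) {
    us <- signs[chosen[s + 1L], ][block_of]
    cv <- a * (u0 %o% u0) + b * (us %o% us)
    diag(cv) <- 0
    cv <- cv + diag(n_components)
    cv
  })
}

#' Simulate smooth rigid-body motion traces
#'
#' Six realignment parameters (3 translations in mm, 3 rotations in radians)
#' as lightly smoothed Gaussian random walks.
#'
#' @param n_volumes Number of volumes.
#' @param amplitude Innovation standard deviation per volume; 0 gives
#'   identically zero motion.
#' @param seed Integer seed.
#' @return A `6 x n_volumes` matrix with rownames
#'   `trans_x..trans_z, rot_x..rot_z`.
#' @export
simulate_motion <- function(n_volumes, amplitude = 0.02, seed = 1L) {
  if (!is_count(n_volumes, min = 2L)) stopf("n_volumes must be >= 2")
  if (amplitude < 0) stopf("amplitude must be >= 0")
  m <- with_seed(seed, {
    steps <- matrix(stats::rnorm(6L * n_volumes, sd = amplitude), 6L, n_volumes)
    walk <- t(apply(steps, 1L, cumsum))
    # 3-point smoothing keeps the walk drift-like rather than white
    sm <- walk
    if (n_volumes >= 3L) {
      sm[, 2:(n_volumes - 1L)] <- (walk[, 1:(n_volumes - 2L)] +
                                     walk[, 2:(n_volumes - 1L)] +
                                     walk[, 3:n_volumes]) / 3
    }
    sm
  })
  # rotations an order of magnitude smaller than translations, as observed
  # in practice for cooperative subjects
  m[4:6, ] <- m[4:6, ] / 10
  rownames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  m
}

simulate_state_sequence <- function(markov_matrix, n_volumes, seed) {
  k <- nrow(markov_matrix)
  with_seed(seed, {
    s <- integer(n_volumes)
    s[1L] <- sample.int(k, 1L)
    if (n_volumes > 1L) {
      u <- stats::runif(n_volumes - 1L)
      cum <- t(apply(markov_matrix, 1L, cumsum))
      for (t in 2:n_volumes) {
        s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ]) + 1L
      }
    }
    s
  })
}

# Patient-group chain: move `delta` of every row's mass toward state 1,
# which raises state-1 occupancy and dwell.
shift_markov_toward_state1 <- function(p, delta) {
  if (delta == 0) return(p)
  k <- nrow(p)
  e1 <- c(1, rep(0, k - 1L))
  out <- (1 - delta) * p + delta * matrix(e1, k, k, byrow = TRUE)
  out / rowSums(out)
}

#' Simulate a two-group cohort of component time courses
#'
#' Each subject's hidden state sequence evolves by the (group-adjusted)
#' Markov chain; volume `t` is drawn from `N(0, C_state(t) + noise_sd^2 I)`.
#' Patients additionally receive plausible clinical scores (CGI-S, BDI, BAI)
#' in the manifest. Per-subject seeds are derived deterministically from the
#' master seed, so the same config and seed reproduce the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `subjects` (list of
#'   [component_timecourses()] objects), `manifest` (data.frame with
#'   subject_id, group, cgi, bdi, bai), and `ground_truth` (list with the
#'   hidden state sequences, per-subject motion matrices, and the config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  k <- config$k_true
  C <- config$n_components
  Tn <- config$n_volumes

  # Cholesky factors of the total per-state covariance (state + noise)
  chols <- lapply(config$state_covariances, function(cv) {
    chol(cv + diag(config$noise_sd^2, C))
  })

  groups <- rep(c("control", "patient"), each = config$n_per_group)
  chains <- list(
    control = config$markov_matrix,
    patient = shift_markov_toward_state1(config$markov_matrix, config$group_effect)
  )

  n_sub <- length(groups)
  subjects <- vector("list", n_sub)
  states <- vector("list", n_sub)
  motion <- vector("list", n_sub)
  ids <- sprintf("sub-%03d", seq_len(n_sub))

  for (i in seq_len(n_sub)) {
    seed_i <- derive_seed(config$seed, i)
    s <- simulate_state_sequence(chains[[groups[i]]], Tn, seed_i)
    x <- with_seed(derive_seed(seed_i, 1L), {
      z <- matrix(stats::rnorm(Tn * C), Tn, C)
      out <- matrix(0, Tn, C)
      for (st in seq_len(k)) {
        rows <- which(s == st)
        if (length(rows)) out[rows, ] <- z[rows, , drop = FALSE] %*% chols[[st]]
      }
      out
    })
    colnames(x) <- sprintf("comp_%02d", seq_len(C))
    subjects[[i]] <- component_timecourses(
      subject_id = ids[i], group = groups[i], data = x,
      tr_seconds = config$tr_seconds
    )
    states[[i]] <- s
    motion[[i]] <- simulate_motion(Tn, config$motion_amplitude,
                                   seed = derive_seed(seed_i, 2L))
  }

  scores <- with_seed(derive_seed(config$seed, 999L), {
    n <- config$n_per_group
    data.frame(
      cgi = pmin(7L, pmax(1L, round(stats::rnorm(n, mean = 5, sd = 1.2)))),
      bdi = pmin(28L, pmax(0L, round(stats::rnorm(n, mean = 8, sd = 6)))),
      bai = pmin(38L, pmax(0L, round(stats::rnorm(n, mean = 14, sd = 10))))
    )
  })
  manifest <- data.frame(
    subject_id = ids, group = groups,
    cgi = NA_integer_, bdi = NA_integer_, bai = NA_integer_,
    stringsAsFactors = FALSE
  )
  manifest[manifest$group == "patient", c("cgi", "bdi", "bai")] <- scores

  names(states) <- ids
  names(motion) <- ids
  list(
    subjects = subjects,
    manifest = manifest,
    ground_truth = list(states = states, motion = motion, config = config)
  )
}
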