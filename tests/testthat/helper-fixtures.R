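# Small in-code fixtures shared across test files. Everything is generated
# at test time; nothing is read from disk.

# A tiny deterministic subject: sinusoid-plus-noise component time courses.
tiny_subject <- function(T = 60L, C = 4L, seed = 101L, group = "control",
                         id = "sub-tiny") {
  set.seed(seed)
  x <- matrix(rnorm(T * C), T, C)
  component_timecourses(id, group, x, tr_seconds = 2.0)
}

# A small two-state cohort at reduced dimensions for fast end-to-end tests:
# defaults chosen so preprocessing + windowing still leave enough windows.
small_cohort_config <- function(n_per_group = 4L, k_true = 2L, seed = 5L,
                                separation = 1, ...) {
  cohort_config(n_per_group = n_per_group, n_components = 14L,
                n_volumes = 120L, k_true = k_true, separation = separation,
                mean_dwell_target = 30, seed = seed, ...)
}

# Feature sets for a cohort, using the standard conditioning chain but a
# smaller SWC window so the tiny recordings still yield many windows.
small_feature_sets <- function(cohort, swc_window = 12L, aswc_window = 10L) {
  lapply(cohort$subjects, function(tc) {
    tc <- preprocess_timecourses(tc)
    swc <- sliding_window_correlations(tc, window_size_tr = swc_window)
    zscore_feature_blocks(aswc_and_derivatives(swc, aswc_window = aswc_window))
  })
}

# All permutations of 1..n (for best-permutation label matching at small k).
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  do.call(c, lapply(seq_len(n), function(i) {
    lapply(all_permutations(n - 1L), function(p) c(i, p + (p >= i)))
  }))
}

# Direct Markov-chain metrics simulation (no MVN data, no clustering):
# used for inference calibration tests where only the state sequences matter.
simulate_metric_cohort <- function(n_per_group = 17L, k = 4L, n_windows = 175L,
                                   dwell = 20, shift = 0, seed = 1L) {
  stay <- 1 - 1 / dwell
  P <- matrix((1 - stay) / (k - 1L), k, k); diag(P) <- stay
  Ppat <- if (shift > 0) {
    out <- (1 - shift) * P + shift * matrix(c(1, rep(0, k - 1L)), k, k, byrow = TRUE)
    out / rowSums(out)
  } else P
  groups <- rep(c("control", "patient"), each = n_per_group)
  chains <- list(control = P, patient = Ppat)
  lapply(seq_along(groups), function(i) {
    s <- dfcstates:::simulate_state_sequence(chains[[groups[i]]], n_windows,
                                             seed = dfcstates:::derive_seed(seed, i))
    m <- state_metrics(s, k)
    m$subject_id <- sprintf("sub-%03d", i)
    m$group <- groups[i]
    m
  })
}
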