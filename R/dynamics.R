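# State-sequence summaries (fraction of time, mean dwell time, visits,
# transitions) and group-level transition-probability models with attractor
# extraction.

#' Per-subject state-dynamics metrics
#'
#' A *visit* is a maximal run of one state; a *transition* is any change of
#' label between consecutive windows. For `k = 4` the specific-transition
#' table has 12 ordered off-diagonal cells. MDT is reported in windows and
#' is `NA` for states the subject never visits.
#'
#' @param seq A `state_sequence` (from [assign_states()]) or an integer
#'   vector of labels in `1..k`.
#' @param k Number of states.
#' @return An object of class `state_metrics`: `ft`, `mdt`, `visits`
#'   (length-k), `n_transitions`, `specific` (k x k off-diagonal change
#'   counts), `pairs` (k x k consecutive-pair counts including the
#'   diagonal), `n_windows`.
#' @export
state_metrics <- function(seq, k) {
  subject_id <- NA_character_; group <- NA_character_
  if (inherits(seq, "state_sequence")) {
    subject_id <- seq$subject_id; group <- seq$group; seq <- seq$states
  }
  seq <- as.integer(seq)
  if (!length(seq)) stopf("empty state sequence")
  if (any(seq < 1L | seq > k)) stopf("state labels outside 1..%d", k)
  W <- length(seq)
  runs <- rle(seq)
  ft <- tabulate(seq, k) / W
  visits <- tabulate(runs$values, k)
  mdt <- rep(NA_real_, k)
  for (s in seq_len(k)) {
    if (visits[s] > 0L) mdt[s] <- mean(runs$lengths[runs$values == s])
  }
  pairs <- matrix(0L, k, k)
  if (W > 1L) {
    for (t in seq_len(W - 1L)) {
      pairs[seq[t], seq[t + 1L]] <- pairs[seq[t], seq[t + 1L]] + 1L
    }
  }
  specific <- pairs
  diag(specific) <- 0L
  dimnames(specific) <- dimnames(pairs) <-
    list(paste0("from_", seq_len(k)), paste0("to_", seq_len(k)))
  structure(list(subject_id = subject_id, group = group,
                 ft = ft, mdt = mdt, visits = visits,
                 n_transitions = sum(specific), specific = specific,
                 pairs = pairs, n_windows = W, k = as.integer(k)),
            class = "state_metrics")
}

#' Pool transition counts over one group's subjects
#'
#' Transition structure has no subject-wise distribution once pooled, so the
#' model lives at the group level: counts are summed over subjects (never
#' across subject boundaries) and rows are normalized over off-diagonal
#' entries. A diagonal-inclusive probability matrix is emitted alongside.
#'
#' @param metrics_list List of `state_metrics` for the group's subjects.
#' @param k Number of states.
#' @param group Group label for bookkeeping.
#' @return An object of class `transition_model`: `counts`, `probs`
#'   (off-diagonal, rows sum to 1 where defined), `probs_with_self`,
#'   `undefined_rows` (states with no outgoing transitions), `group`.
#' @export
pool_transitions <- function(metrics_list, k, group = NA_character_) {
  if (!length(metrics_list)) stopf("no subjects supplied")
  counts <- Reduce(`+`, lapply(metrics_list, `[[`, "specific"))
  pairs <- Reduce(`+`, lapply(metrics_list, `[[`, "pairs"))
  out_deg <- rowSums(counts)
  probs <- counts / ifelse(out_deg > 0, out_deg, NA_real_)
  probs_self <- pairs / ifelse(rowSums(pairs) > 0, rowSums(pairs), NA_real_)
  structure(list(group = group, counts = counts, probs = probs,
                 probs_with_self = probs_self,
                 undefined_rows = which(out_deg == 0),
                 n_subjects = length(metrics_list), k = as.integer(k)),
            class = "transition_model")
}

#' Extract the attractor of a transition model
#'
#' Follows each state's maximal-probability successor (ties toward the lower
#' index). The successor map restricted to states that lie on a cycle forms
#' the attractor -- the recurring loop of state transitions; off-cycle
#' states are reported with their path into it. States without outgoing
#' transitions are excluded.
#'
#' @param tm A `transition_model` from [pool_transitions()].
#' @return List with `successor` (named integer vector, `NA` for excluded
#'   states), `cycles` (list of integer vectors, each rotated to start at
#'   its smallest state), `on_cycle` (integer vector of attractor states),
#'   `paths` (per off-cycle state, the path to the first cycle state).
#' @export
extract_attractor <- function(tm) {
  stopifnot(inherits(tm, "transition_model"))
  k <- tm$k
  successor <- rep(NA_integer_, k)
  for (s in seq_len(k)) {
    row <- tm$probs[s, ]
    if (all(is.na(row))) next
    successor[s] <- which.max(row)  # ties -> lower index
  }
  names(successor) <- paste0("state_", seq_len(k))

  on_cycle <- logical(k)
  cycles <- list()
  for (s in which(!is.na(successor))) {
    path <- s
    cur <- s
    repeat {
      nxt <- successor[cur]
      if (is.na(nxt)) break
      if (nxt %in% path) {
        cyc <- path[which(path == nxt):length(path)]
        if (!any(on_cycle[cyc])) {
          cyc <- c(cyc[which.min(cyc):length(cyc)], cyc[seq_len(which.min(cyc) - 1L)])
          cycles[[length(cycles) + 1L]] <- cyc
        }
        on_cycle[cyc] <- TRUE
        break
      }
      path <- c(path, nxt)
      cur <- nxt
    }
  }
  paths <- list()
  for (s in which(!is.na(successor) & !on_cycle)) {
    path <- s
    cur <- s
    while (!is.na(successor[cur]) && !on_cycle[cur]) {
      cur <- successor[cur]
      path <- c(path, cur)
    }
    paths[[paste0("state_", s)]] <- unname(path)
  }
  list(successor = successor, cycles = lapply(cycles, unname),
       on_cycle = which(on_cycle), paths = paths)
}

#' Tabulate per-subject metrics as a data frame
#'
#' One row per subject: `ft_1..k`, `mdt_1..k`, `visits_1..k`,
#' `n_transitions`, and the `k*(k-1)` specific-transition counts.
#'
#' @param metrics_list List of `state_metrics`.
#' @return A data.frame.
#' @export
metrics_table <- function(metrics_list) {
  k <- metrics_list[[1L]]$k
  off <- which(row(diag(k)) != col(diag(k)))
  rows <- lapply(metrics_list, function(m) {
    spec <- as.vector(m$specific)[off]
    names(spec) <- sprintf("t_%d_to_%d", row(diag(k))[off], col(diag(k))[off])
    c(stats::setNames(m$ft, paste0("ft_", seq_len(k))),
      stats::setNames(m$mdt, paste0("mdt_", seq_len(k))),
      stats::setNames(m$visits, paste0("visits_", seq_len(k))),
      n_transitions = m$n_transitions, spec)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(data.frame(subject_id = vapply(metrics_list, `[[`, character(1), "subject_id"),
                          group = vapply(metrics_list, `[[`, character(1), "group"),
                          stringsAsFactors = FALSE),
               out)
  rownames(out) <- NULL
  out
}
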