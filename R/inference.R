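# Two-group permutation inference with Benjamini-Hochberg FDR control,
# Hedges' g effect sizes, and Spearman clinical correlations.

#' Two-tailed permutation test on a difference of group means
#'
#' The statistic is `mean(values_a) - mean(values_b)`; group labels are
#' permuted `n_perm` times and the two-tailed p-value is
#' `(1 + #{|perm| >= |obs|}) / (n_perm + 1)`, so p is never 0 and never
#' below `1 / (n_perm + 1)`.
#'
#' @param values_a,values_b Numeric vectors (non-finite values dropped);
#'   each group needs at least 2 finite values.
#' @param n_perm Number of label permutations (default 100000).
#' @param seed Integer seed.
#' @param statistic `"mean_diff"` (default) or `"t"` (Welch t statistic);
#'   under balanced exchangeable designs the two give the same rejection
#'   ordering.
#' @return List with `p` (two-tailed), `observed` (mean difference a - b),
#'   `n_a`, `n_b`, `n_perm`.
#' @export
permutation_test <- function(values_a, values_b, n_perm = 100000L, seed = 1L,
                             statistic = c("mean_diff", "t")) {
  statistic <- match.arg(statistic)
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 2L || n_b < 2L) {
    return(list(p = NA_real_, observed = NA_real_, n_a = n_a, n_b = n_b,
                n_perm = n_perm,
                reason = sprintf("group sizes %d and %d after exclusions; need >= 2 each",
                                 n_a, n_b)))
  }
  pooled <- c(values_a, values_b)
  n <- n_a + n_b
  welch_t <- function(xa, xb) {
    (mean(xa) - mean(xb)) /
      sqrt(stats::var(xa) / length(xa) + stats::var(xb) / length(xb))
  }
  observed <- mean(values_a) - mean(values_b)
  obs_stat <- if (statistic == "t") welch_t(values_a, values_b) else observed
  total <- sum(pooled)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (i in seq_len(n_perm)) {
      ia <- sample.int(n, n_a)
      stat <- if (statistic == "t") {
        welch_t(pooled[ia], pooled[-ia])
      } else {
        sa <- sum(pooled[ia])
        sa / n_a - (total - sa) / n_b
      }
      if (abs(stat) >= abs(obs_stat) - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  list(p = (1 + exceed) / (n_perm + 1), observed = observed,
       n_a = n_a, n_b = n_b, n_perm = n_perm, statistic = statistic)
}

#' Hedges' g standardized mean difference
#'
#' Cohen's d on the pooled SD, shrunk by the small-sample factor
#' `J = 1 - 3 / (4 (n_a + n_b) - 9)`.
#'
#' @param values_a,values_b Numeric vectors (non-finite values dropped).
#' @return Scalar g (sign follows `mean_a - mean_b`).
#' @export
hedges_g <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n_a <- length(values_a); n_b <- length(values_b)
  if (n_a < 2L || n_b < 2L) stopf("each group needs at least 2 finite values")
  s2 <- ((n_a - 1) * stats::var(values_a) + (n_b - 1) * stats::var(values_b)) /
    (n_a + n_b - 2)
  if (s2 <= 0) stopf("pooled SD is zero; effect size undefined")
  d <- (mean(values_a) - mean(values_b)) / sqrt(s2)
  J <- 1 - 3 / (4 * (n_a + n_b) - 9)
  J * d
}

#' Benjamini-Hochberg FDR step-up procedure
#'
#' @param p_values Vector of raw p-values in `[0, 1]` (`NA` allowed;
#'   excluded from the family).
#' @param alpha FDR level (default 0.05).
#' @return List with `reject` (logical), `adjusted` (BH-adjusted values,
#'   monotone and capped at 1), `m` (family size).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  ok <- !is.na(p_values)
  p <- p_values[ok]
  m <- length(p)
  adjusted <- rep(NA_real_, length(p_values))
  reject <- rep(NA, length(p_values))
  if (m > 0L) {
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    adj_full <- numeric(m)
    adj_full[o] <- adj
    # step-up rejection: largest i with p_(i) <= i/m * alpha, reject all below
    crit <- which(p[o] <= seq_len(m) / m * alpha)
    rej <- logical(m)
    if (length(crit)) rej[o[seq_len(max(crit))]] <- TRUE
    adjusted[ok] <- adj_full
    reject[ok] <- rej
  }
  list(reject = reject, adjusted = adjusted, m = m)
}

#' Spearman rank correlation with mid-ranks
#'
#' Pearson correlation of average (mid) ranks; p from the large-sample
#' t approximation `t = rho sqrt((n - 2) / (1 - rho^2))`, with an optional
#' seeded permutation p for small samples.
#'
#' @param x,y Paired numeric vectors; pairs with non-finite entries are
#'   dropped; needs `n >= 3` and non-constant inputs.
#' @param method `"approx"` (default) or `"permutation"`.
#' @param n_perm,seed Permutation settings when `method = "permutation"`.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y, method = c("approx", "permutation"),
                          n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3L) stopf("need at least 3 complete pairs, got %d", n)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stopf("constant input: rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  p <- if (method == "approx") {
    if (abs(rho) >= 1) {
      0
    } else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
  } else {
    with_seed(seed, {
      cnt <- 0L
      for (i in seq_len(n_perm)) {
        if (abs(stats::cor(rx, sample(ry))) >= abs(rho) - 1e-12) cnt <- cnt + 1L
      }
      (1 + cnt) / (n_perm + 1)
    })
  }
  list(rho = rho, p = p, n = n)
}

#' Full two-group comparison of state-dynamics measures
#'
#' Tests, with patients minus controls as the sign convention: fraction of
#' time per state (BH family of size k), mean dwell time per state (BH
#' family of size k; subjects with an undefined MDT are excluded pairwise
#' from that state's test), total transitions, visits per state, and every
#' specific transition (uncorrected, as exploratory trends). Hedges' g
#' accompanies each test. When the manifest carries clinical scores,
#' Spearman correlations between each score and the dynamic measures are
#' computed within the patient group, BH-corrected per score.
#'
#' @param metrics_list List of `state_metrics` with group labels.
#' @param k Number of states.
#' @param n_perm Permutations per test (default 100000).
#' @param alpha Two-tailed level (default 0.05).
#' @param seed Master seed; each test gets a derived stream.
#' @param manifest Optional data.frame with `subject_id` and clinical score
#'   columns (`cgi`, `bdi`, `bai`) for the patient group.
#' @param mdt_absent `"exclude"` (default): subjects who never visit a
#'   state are dropped pairwise from that state's MDT test; `"zero"`:
#'   their dwell is treated as 0 windows.
#' @return An object of class `group_report`: `tests` (data.frame with
#'   measure, family, means/SDs, observed difference, p, q, g, n per
#'   group), `clinical` (data.frame or NULL), `params`.
#' @export
run_group_analysis <- function(metrics_list, k, n_perm = 100000L,
                               alpha = 0.05, seed = 1L, manifest = NULL,
                               mdt_absent = c("exclude", "zero")) {
  mdt_absent <- match.arg(mdt_absent)
  groups <- vapply(metrics_list, `[[`, character(1), "group")
  if (!all(c("patient", "control") %in% groups)) {
    stopf("metrics for both groups (patient, control) are required")
  }
  tab <- metrics_table(metrics_list)
  if (mdt_absent == "zero") {
    for (col in paste0("mdt_", seq_len(k))) tab[[col]][is.na(tab[[col]])] <- 0
  }
  pat <- tab$group == "patient"

  measure_cols <- c(paste0("ft_", seq_len(k)), paste0("mdt_", seq_len(k)),
                    "n_transitions", paste0("visits_", seq_len(k)),
                    grep("^t_\\d+_to_\\d+$", names(tab), value = TRUE))
  families <- c(rep("ft", k), rep("mdt", k), "transitions",
                rep("visits", k),
                rep("specific", k * (k - 1L)))

  test_idx <- 0L
  rows <- lapply(seq_along(measure_cols), function(ii) {
    col <- measure_cols[ii]
    a <- tab[[col]][pat]        # patients
    b <- tab[[col]][!pat]       # controls
    pt <- permutation_test(a, b, n_perm = n_perm, seed = derive_seed(seed, ii))
    g <- tryCatch(hedges_g(a, b), error = function(e) NA_real_)
    data.frame(measure = col, family = families[ii],
               mean_patient = mean(a[is.finite(a)]),
               sd_patient = stats::sd(a[is.finite(a)]),
               mean_control = mean(b[is.finite(b)]),
               sd_control = stats::sd(b[is.finite(b)]),
               observed_diff = pt$observed, p = pt$p, g = g,
               n_patient = pt$n_a, n_control = pt$n_b,
               stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$q <- NA_real_
  tests$reject_fdr <- NA
  for (fam in c("ft", "mdt")) {
    sel <- tests$family == fam
    bh <- fdr_bh(tests$p[sel], alpha = alpha)
    tests$q[sel] <- bh$adjusted
    tests$reject_fdr[sel] <- bh$reject
  }

  clinical <- NULL
  if (!is.null(manifest) && any(c("cgi", "bdi", "bai") %in% names(manifest))) {
    scores <- intersect(c("cgi", "bdi", "bai"), names(manifest))
    ptab <- merge(tab[pat, , drop = FALSE], manifest[, c("subject_id", scores)],
                  by = "subject_id")
    dyn_cols <- c(paste0("ft_", seq_len(k)), paste0("mdt_", seq_len(k)),
                  "n_transitions")
    crows <- list()
    for (sc in scores) {
      for (dc in dyn_cols) {
        res <- tryCatch(spearman_corr(ptab[[sc]], ptab[[dc]]),
                        error = function(e) list(rho = NA_real_, p = NA_real_, n = NA_integer_))
        crows[[length(crows) + 1L]] <- data.frame(
          score = sc, measure = dc, rho = res$rho, p = res$p, n = res$n,
          stringsAsFactors = FALSE)
      }
    }
    clinical <- do.call(rbind, crows)
    clinical$q <- NA_real_
    for (sc in scores) {
      sel <- clinical$score == sc
      clinical$q[sel] <- fdr_bh(clinical$p[sel], alpha = alpha)$adjusted
    }
  }

  structure(list(tests = tests, clinical = clinical,
                 params = list(n_perm = n_perm, alpha = alpha, seed = seed,
                               k = k, mdt_absent = mdt_absent)),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat(sprintf("<group_report> %d tests, n_perm = %d, alpha = %g\n",
              nrow(x$tests), x$params$n_perm, x$params$alpha))
  sig <- x$tests[!is.na(x$tests$p) & x$tests$p < x$params$alpha, ]
  if (nrow(sig)) {
    cat("uncorrected p <", x$params$alpha, "\n")
    print(sig[, c("measure", "p", "q", "g")], row.names = FALSE)
  } else {
    cat("no test below alpha uncorrected\n")
  }
  invisible(x)
}
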