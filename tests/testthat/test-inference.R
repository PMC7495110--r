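# Permutation tests, Hedges' g, Benjamini-Hochberg, Spearman, group report.

test_that("permutation test: degenerate and symmetric cases", {
  r <- permutation_test(rep(1, 5), rep(1, 5), n_perm = 500L, seed = 1L)
  expect_equal(r$p, 1)
  a <- c(1, 2, 3, 5); b <- c(2, 4, 6, 7)
  r1 <- permutation_test(a, b, n_perm = 2000L, seed = 3L)
  r2 <- permutation_test(b, a, n_perm = 2000L, seed = 3L)
  # same distribution either way; Monte-Carlo draws differ, so allow a few SEs
  expect_lt(abs(r1$p - r2$p), 0.05)
  expect_equal(r1$observed, -r2$observed)
  expect_gte(r1$p, 1 / 2001)
  # groups emptied by exclusions are flagged, not errored
  r3 <- permutation_test(c(1, NA, NA), c(1, 2, 3), n_perm = 100L)
  expect_true(is.na(r3$p))
  expect_match(r3$reason, "exclusions")
})

test_that("permutation p agrees with exhaustive enumeration at n = 3 + 3", {
  a <- c(0.1, 0.5, 0.9); b <- c(1.2, 1.4, 2.0)
  pooled <- c(a, b)
  obs <- mean(a) - mean(b)
  # oracle: all choose(6, 3) = 20 label splits
  splits <- combn(6L, 3L)
  stats <- apply(splits, 2L, function(ix) mean(pooled[ix]) - mean(pooled[-ix]))
  p_exact <- mean(abs(stats) >= abs(obs) - 1e-12)
  n_perm <- 20000L
  r <- permutation_test(a, b, n_perm = n_perm, seed = 11L)
  se <- sqrt(p_exact * (1 - p_exact) / n_perm)
  expect_lt(abs(r$p - p_exact), 2 * se + 2 / n_perm)
})

test_that("hedges_g matches the direct formula and its invariances", {
  expect_equal(hedges_g(c(1, 2, 3), c(2, 3, 1)), 0)
  a <- c(0, 1); b <- c(1, 2)
  # d = -1 / sqrt(0.5), J = 1 - 3/7
  expect_equal(hedges_g(a, b), (1 - 3 / 7) * (-1 / sqrt(0.5)), tolerance = 1e-12)
  set.seed(2)
  x <- rnorm(10); y <- rnorm(12, mean = 1)
  expect_equal(hedges_g(3 * x, 3 * y), hedges_g(x, y), tolerance = 1e-12)
  expect_gt(hedges_g(y, x), 0)  # sign follows mean_a - mean_b
  expect_error(hedges_g(rep(1, 4), rep(1, 4)), "pooled SD")
})

test_that("fdr_bh matches stats::p.adjust and the hand-applied step-up rule", {
  p <- c(0.001, 0.02, 0.03, 0.2)
  r <- fdr_bh(p, alpha = 0.05)
  expect_equal(r$adjusted, stats::p.adjust(p, "BH"), tolerance = 1e-12)
  # hand rule: p_(i) <= i/4 * 0.05 -> thresholds 0.0125, 0.025, 0.0375, 0.05
  # largest i satisfied is i = 3 -> reject the three smallest
  expect_equal(r$reject, c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_bh(rep(0.01, 4L))$reject))
  set.seed(6)
  q <- runif(10)
  rr <- fdr_bh(q)
  expect_true(all(rr$adjusted >= q))
  expect_equal(rr$adjusted, stats::p.adjust(q, "BH"), tolerance = 1e-12)
  # NA handling keeps family size at the non-missing count
  rna <- fdr_bh(c(0.01, NA, 0.04))
  expect_equal(rna$m, 2L)
  expect_true(is.na(rna$adjusted[2L]))
})

test_that("spearman_corr: monotone cases and hand-ranked ties", {
  x <- c(1, 3, 7, 9, 15)
  expect_equal(spearman_corr(x, exp(x))$rho, 1)
  expect_equal(spearman_corr(x, -x^3)$rho, -1)
  # mid-rank oracle: x = (1,2,2,4) -> ranks (1, 2.5, 2.5, 4)
  x2 <- c(1, 2, 2, 4); y2 <- c(3, 1, 5, 2)
  hand <- cor(c(1, 2.5, 2.5, 4), rank(y2))
  expect_equal(spearman_corr(x2, y2)$rho, hand, tolerance = 1e-12)
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  # permutation option agrees with the approximation in direction
  r <- spearman_corr(x, c(2, 1, 5, 7, 20), method = "permutation",
                     n_perm = 2000L, seed = 5L)
  expect_gt(r$rho, 0)
  expect_lte(r$p, 1)
})

test_that("permutation p is calibrated under the exchangeable null", {
  # direct Markov-chain cohorts with no group effect: the FT(1) permutation
  # p-value must be super-uniform; check the rejection rate and uniformity
  reps <- 120L
  pvals <- vapply(seq_len(reps), function(r) {
    ms <- simulate_metric_cohort(n_per_group = 8L, k = 3L, n_windows = 120L,
                                 dwell = 15, shift = 0, seed = 1000L + r)
    tab <- metrics_table(ms)
    permutation_test(tab$ft_1[tab$group == "patient"],
                     tab$ft_1[tab$group == "control"],
                     n_perm = 400L, seed = r)$p
  }, numeric(1))
  alpha <- 0.05
  rate <- mean(pvals <= alpha)
  # binomial 99% envelope around alpha for 120 replicates
  expect_lt(rate, alpha + 3 * sqrt(alpha * (1 - alpha) / reps))
  # Monte-Carlo p-values are discrete, hence tied; the KS warning is expected
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("injected occupancy shift is detected with positive g", {
  # patients' chain pushes mass toward state 1: FT(1) should flag often
  hits <- vapply(1:15, function(r) {
    ms <- simulate_metric_cohort(n_per_group = 17L, k = 4L, n_windows = 175L,
                                 dwell = 20, shift = 0.25, seed = 300L + r)
    tab <- metrics_table(ms)
    a <- tab$ft_1[tab$group == "patient"]; b <- tab$ft_1[tab$group == "control"]
    p <- permutation_test(a, b, n_perm = 1000L, seed = r)$p
    (p < 0.05) && (hedges_g(a, b) > 0)
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})

test_that("run_group_analysis produces the full report schema", {
  ms <- simulate_metric_cohort(n_per_group = 6L, k = 4L, n_windows = 100L,
                               dwell = 12, shift = 0.2, seed = 77L)
  man <- data.frame(
    subject_id = vapply(ms, `[[`, character(1), "subject_id"),
    group = vapply(ms, `[[`, character(1), "group"))
  man$cgi <- ifelse(man$group == "patient", sample(1:7, nrow(man), TRUE), NA)
  rep_ <- run_group_analysis(ms, k = 4L, n_perm = 500L, seed = 9L, manifest = man)
  tests <- rep_$tests
  # families: ft x4, mdt x4, transitions, visits x4, 12 specific transitions
  expect_equal(nrow(tests), 4L + 4L + 1L + 4L + 12L)
  expect_equal(sum(tests$family == "specific"), 12L)
  # FDR families are ft and mdt only (m = k each); others uncorrected
  expect_true(all(!is.na(tests$q[tests$family == "ft"])))
  expect_true(all(is.na(tests$q[tests$family %in% c("transitions", "visits", "specific")])))
  expect_true(all(c("measure", "family", "p", "q", "g", "n_patient",
                    "n_control", "observed_diff") %in% names(tests)))
  ok <- !is.na(tests$p)
  expect_true(all(tests$p[ok] > 0 & tests$p[ok] <= 1))
  # clinical correlations exist for the patient group only, per-score FDR
  expect_false(is.null(rep_$clinical))
  expect_true(all(rep_$clinical$score == "cgi"))
  expect_equal(nrow(rep_$clinical), 9L)  # ft x4, mdt x4, transitions
  # determinism under the same seed
  rep2 <- run_group_analysis(ms, k = 4L, n_perm = 500L, seed = 9L, manifest = man)
  expect_identical(rep_$tests, rep2$tests)
})

test_that("MDT tests exclude non-visiting subjects pairwise", {
  # force some subjects to never visit state 3
  ms <- lapply(1:8, function(i) {
    s <- if (i <= 2L) rep(c(1L, 2L), 20L) else sample.int(3L, 40L, replace = TRUE)
    m <- state_metrics(s, 3L)
    m$subject_id <- sprintf("s%02d", i)
    m$group <- if (i %% 2L == 0L) "patient" else "control"
    m
  })
  rep_ <- run_group_analysis(ms, k = 3L, n_perm = 200L, seed = 1L)
  row3 <- rep_$tests[rep_$tests$measure == "mdt_3", ]
  expect_lt(row3$n_patient + row3$n_control, 8L)
})

test_that("t-statistic option matches mean-difference ordering when balanced", {
  set.seed(19)
  a <- rnorm(8L); b <- rnorm(8L, mean = 0.8)
  r_m <- permutation_test(a, b, n_perm = 3000L, seed = 2L)
  r_t <- permutation_test(a, b, n_perm = 3000L, seed = 2L, statistic = "t")
  expect_equal(r_t$observed, r_m$observed)
  expect_lt(abs(r_t$p - r_m$p), 0.05)  # same rejection ordering, MC noise only
})

test_that("mdt_absent = 'zero' keeps all subjects in the MDT tests", {
  ms <- lapply(1:8, function(i) {
    s <- if (i <= 2L) rep(c(1L, 2L), 20L) else sample.int(3L, 40L, replace = TRUE)
    m <- state_metrics(s, 3L)
    m$subject_id <- sprintf("s%02d", i); m$group <- if (i %% 2L == 0L) "patient" else "control"
    m
  })
  rep_ <- run_group_analysis(ms, k = 3L, n_perm = 200L, seed = 1L,
                             mdt_absent = "zero")
  row3 <- rep_$tests[rep_$tests$measure == "mdt_3", ]
  expect_equal(row3$n_patient + row3$n_control, 8L)
})
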