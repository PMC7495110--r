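---
title: "Estimating dynamic brain states from component time courses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating dynamic brain states from component time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfcstates)
```

## The problem and the model

Static functional connectivity summarizes a whole resting-state fMRI
recording with one correlation matrix and so discards the way connectivity
reconfigures over minutes. The dynamic-connectivity ("chronnectome") view
instead treats the recording as a trajectory through a small set of
*dynamic brain states*: prototypical connectivity configurations that
subjects leave and return to. `dfcstates` implements the standard
sliding-window variant of this analysis for independent-component time
courses:

1. **Conditioning.** Each subject's $T \times C$ component matrix is
   trimmed of dummy volumes, optionally orthogonalized against nuisance
   regressors, despiked, and band-pass filtered (0.01–0.15 Hz, fifth-order
   Butterworth, applied forward–backward so no phase shift is introduced;
   the effective magnitude order doubles).
2. **Windowed features.** Pearson correlations for all $P = C(C-1)/2$
   component pairs are computed in a sliding window of 22 TR (44 s at
   TR = 2 s) shifted by 1 TR. Runs of 25 consecutive windows are averaged
   (ASWC), which suppresses the sampling noise of the short window, and the
   first difference of the ASWC series is kept as the *speed* of
   connectivity change. With 225 acquired volumes and 3 discarded this
   yields 222 volumes → 200 windows → 175 aligned windows of
   $2P$ features. ASWC and derivative blocks are z-scored separately per
   subject (grand mean 0, grand SD 1 per block) so both enter clustering
   on a common scale.
3. **State estimation.** Windows at subject-specific local maxima of
   across-feature variance ("exemplars") are pooled and clustered with
   k-means under correlation distance $d(x, c) = 1 - \mathrm{cor}(x, c)$
   for every candidate $k$ in 2–10; the Davies–Bouldin and Ray–Turi
   validity indices are recorded, and the chosen $k$ minimizes the
   Ray–Turi index (the Davies–Bouldin minimizer is reported alongside).
   The full concatenated cohort matrix is then clustered at the chosen
   $k$ (33 replicates, up to 4000 iterations) and every window of every
   subject receives a state index.
4. **Dynamics and inference.** Per subject: fraction of time per state
   (FT), mean dwell time (MDT, in windows), visits, number of transitions,
   and the $k(k-1)$ specific transition counts. Per group: pooled
   transition probabilities (self-transitions excluded) and the
   *attractor* — the cycle obtained by following each state's
   highest-probability successor. Group differences use two-tailed
   permutation tests on the difference of means (default 100,000
   permutations), Benjamini–Hochberg FDR within the FT and MDT families
   (family size $k$), and Hedges' $g$ with the patients-minus-controls
   sign convention. Spearman correlations relate patient clinical scores
   (CGI-S, BDI, BAI) to the dynamic measures.

## Parameters that matter

| parameter | default | role |
|---|---|---|
| `swc_window` | 22 TR (44 s) | SWC estimation window; shorter = noisier, more temporal detail |
| `aswc_window` | 25 windows | averaging depth; total feature support is 46 volumes |
| `low_hz`, `high_hz` | 0.01, 0.15 Hz | resting-state band; high edge must stay below Nyquist |
| `k_min:k_max` | 2–10 | candidate state counts for the validity curves |
| `replicates`, `max_iter` | 33, 4000 | k-means restarts / iteration cap |
| `n_perm`, `alpha` | 100000, 0.05 | permutation inference settings |

MDT is reported in windows; multiply by the TR for seconds. Subjects who
never visit a state have an undefined MDT there and are excluded pairwise
from that state's group test (treating absences as zero is deliberately not
the default, since it conflates occupancy with dwell).

## The synthetic cohort: what it emulates and what it does not

No patient data ship with the package. `simulate_cohort()` generates a
two-group cohort (default 17 + 17 subjects, 225 volumes, TR 2 s, 53
components in seven functional subdomains of sizes 2/4/17/7/5/9/9) from the
minimal model under which "dynamic brain states" are well defined: a
per-subject hidden Markov chain over `k_true` covariance states, with each
volume drawn from the active state's multivariate normal plus isotropic
noise. State covariances are correlation matrices
$C_s = (1-a-b)I + a\,u_0 u_0^\top + b\,u_s u_s^\top$ built from subdomain
sign vectors: components within a subdomain always correlate positively and
subdomains correlate with mixed, mostly negative signs, while the
subdomain-sign assignment differs between states. The `separation`
parameter in $(0, 1]$ moves weight from the shared backbone $u_0$ to the
state-specific pattern $u_s$; at `separation = 1` the vectorized
state matrices are essentially uncorrelated. The default
`separation = 0.8` and `noise_sd = 0.3` were fixed once as a realistic
contrast between within- and between-subdomain coupling; default mean
dwell is 40 volumes, and a `group_effect` parameter shifts the patient
chain's mass toward state 1, giving a known occupancy effect for power
checks.

What the generator does **not** emulate: hemodynamic autocorrelation and
1/f spectra (volumes are white in time within a state), spatial maps,
scanner drift or physiological artifacts, and — importantly — gradual state
changes: covariance switches are instantaneous. A green recovery test
therefore establishes that the estimator recovers *this* stated world, not
that real fMRI contains four states.

### A structural finding worth knowing about

Because switches are instantaneous, every window that straddles a
transition carries a coherent first-order-derivative signature (the ASWC
ramp between the two state patterns). In feature space these
transition-phase windows form genuine clusters of their own: when the
estimator splits a state, the two competing sub-clusters share essentially
one ASWC pattern while their derivative patterns are near-opposite —
windows *entering* versus *leaving* the state. With geometric dwell ~40
volumes and a 46-volume
feature support, most windows straddle a transition, so at moderate
separation (0.8) the Ray–Turi curve is nearly flat between `k_true` and
`k_true + 1` and the chosen k wavers across cohort seeds. At maximal
separation (1.0), which the cluster-recovery checks use as their
"well-separated" regime, the four-state solution wins consistently
(the Davies–Bouldin index still tends to prefer the extra transition
cluster; it is reported, while Ray–Turi decides). This is a property of
the generator's sharp switches, not an estimator defect, and it is why the
acceptance check pins the simulated cohort (fixed generator seed, i.e. a
fixed dataset) while leaving the clustering initialization streams to the
caller's seed.

## Numerical choices

- **Window conventions.** Window counts use the non-inclusive rule
  $W = \lfloor (T - \text{window})/\text{step} \rfloor$, the convention
  under which 222 volumes give exactly 200 windows and 200 windows give
  175 aligned feature windows. The derivative is the first difference of
  the ASWC series and the *last* raw ASWC window is dropped for alignment.
  Windows are 1-based in all user-facing output.
- **Correlation k-means.** Rows are centered and scaled to unit norm, so
  correlation distance becomes a dot product and the clustering is
  invariant to per-row affine rescaling; the centroid update averages the
  standardized member rows. Assignment ties break toward the lower state
  index; an emptied cluster is re-seeded from the row farthest from its
  centroid; replicate initializations are drawn from one seeded stream so
  a longer replicate budget extends (never reshuffles) a shorter one.
  After the best replicate is selected, states are renumbered by
  descending occupancy, so state 1 is always the modal state.
- **Validity indices.** Both indices use the clustering metric. Ray–Turi
  is primary for choosing k because its single worst-pair denominator
  reacts more sharply to an over-split solution than Davies–Bouldin's
  per-cluster average; both are returned.
- **Despiking.** A median/MAD detector (11-point running median) with
  smooth `tanh` squashing: samples beyond 4 robust SD are pulled toward
  the local median so the post-despike robust z never exceeds threshold
  + 1; constant series pass through unchanged.
- **Zero-variance windows.** A window in which a component is constant
  has an undefined correlation; the affected pairs are set to 0 with a
  warning rather than propagating NaN into clustering.
- **Permutation p-values.** The +1-corrected estimator
  $(1 + \#\{|T^\ast| \ge |T|\})/(n_{\text{perm}} + 1)$, so p is never 0.
- **Framewise displacement.** Sum of absolute backward differences of the
  six realignment parameters with rotations converted on a 50 mm sphere
  (radius exposed as an argument); the first frame is 0.

## Design choices where the method description was open

- The despiking algorithm and the filter's phase handling are not pinned
  by the method description; a median/MAD squasher and zero-phase
  forward–backward filtering were chosen as the simplest auditable
  options, both parameterized.
- Exemplar variance is computed on the z-scored features (z-scoring is
  applied "also with regard to cluster estimation"); plateaus of the
  variance series contribute their leftmost window, endpoints are
  excluded, and a subject with no interior peak contributes its global
  maximum window.
- The permutation statistic is the difference of group means; with
  balanced groups and exchangeability this matches the t-statistic's
  rejection ordering for these designs.
- Transition probabilities are defined over state *changes* (diagonal
  excluded): attractors are cycles between distinct states, and the count
  measure already summarizes switching; a diagonal-inclusive matrix is
  emitted alongside for completeness.
- Nuisance regression of motion parameters is available but off by
  default: component time courses normally arrive post-cleaning, and the
  synthetic cohort's motion traces are independent of its signals.

## Limitations

- The estimator inherits the sliding-window method's temporal resolution:
  nothing faster than the 46-volume feature support is observable.
- The generator's geometric dwell times and instantaneous switches make
  transition windows more stereotyped than in real data (see above);
  recovery results at `separation < 1` should be read with the flat
  4-versus-5 Ray–Turi valley in mind.
- Group-level transition probabilities pool all subjects and therefore
  support no subject-wise inference; only descriptive attractor
  comparisons are provided, as in the underlying method.

## A minimal run

```{r example, eval = FALSE}
cfg <- default_config(n_per_group = 17L, k_true = 4L, seed = 1L)
run_pipeline("all", cfg, out_dir = "run1")
# artifacts: run1/cohort, run1/features, run1/states, run1/dynamics,
# run1/compare, plus provenance JSON and pipeline.log
```
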