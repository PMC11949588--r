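---
title: "Modality generalization of connectome-based attention models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modality generalization of connectome-based attention models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmod)
```

This vignette is the package's own account of the statistical machinery it
implements: the model, the choices that were genuinely open and how they
were settled, what the synthetic-data generator does and does not emulate,
and the numerical details a careful user should know.

## The model

A *connectome* for one task run is the symmetric matrix of Pearson
correlations between the activity time courses of `n` parcellated brain
regions; its strict upper triangle, flattened in row-major order, is the
*edge vector* of length `n(n-1)/2` (35,778 for the 268-node parcellation
the defaults assume). Connectome-based predictive modeling (CPM) proceeds
in three steps:

1. **Feature selection.** Each edge is correlated (Pearson) with the
   behavioral score across training runs. Edges with two-tailed
   `p < alpha` (default 0.01, from the t distribution on `n - 2` degrees
   of freedom) form the *positive* (high-attention) mask if `r > 0` and
   the *negative* (low-attention) mask if `r < 0`. With a covariate, the
   partial Pearson correlation is used and a degree of freedom is
   subtracted per covariate — this is how networks are retrained while
   partialing out the other modality's performance.
2. **Summary.** *Network strength* of a run is the mean edge value inside
   the positive mask minus the mean inside the negative mask.
3. **Calibration.** Ordinary least squares of behavior on training
   strength gives `predicted = m * strength + b`. Because this map is
   monotone for `m > 0`, every rank-based validation statistic is
   identical whether computed on raw strength or calibrated predictions;
   the calibration only matters when predictions must live on the
   behavior scale.

External validation correlates strength with observed behavior in an
independent dataset using the **partial Spearman correlation**: all
variables are rank-transformed (average ranks at ties), the two rank
vectors of interest are residualized on the covariate ranks by least
squares, and the Pearson correlation of the residuals is reported with a
t-based two-tailed p on `n - 2 - q` degrees of freedom. Rank
transformation makes the statistic robust to outliers and invariant to
any strictly increasing transform of either variable — which also makes
it indifferent to whether edges were Fisher-z transformed.

**Modality specificity** is the within-modality partial rho minus the
cross-modality partial rho for the same evaluation runs. Its null
distribution shuffles the two *prediction* vectors independently while
holding observed behavior and the motion covariate fixed, recomputing the
difference each time; the test is one-tailed, asking whether the observed
advantage exceeds the shuffled ones.

**Network overlap** between two masks of sizes `K` and `N` among `M`
edges is tested against the upper-tail hypergeometric probability
`p = P(X > x)`. The strict inequality (the observed count itself is
excluded) matches the `1 - hygcdf(x, M, K, N)` convention; it makes the
test slightly conservative in the other direction — `p = 0` exactly when
the overlap is maximal.

**Canonical-network contributions** count, per pair of node groups, the
positive-mask edges minus negative-mask edges in that block, normalized
by the number of possible edges in the block. Significance comes from
redrawing both masks (sizes preserved) uniformly from all edges and
recomputing each cell; the per-cell empirical p is two-sided with the
add-one correction and is deliberately left uncorrected across cells,
mirroring how such matrices are usually displayed.

## Parameters that matter

| Parameter | Default | Units / meaning |
|---|---|---|
| `alpha` (selection) | 0.01 | two-tailed p-threshold per edge |
| `fd_max` | 0.15 | mm; mean framewise displacement cutoff (strict `>` excludes) |
| `disp_max` | 4 | mm; maximum head displacement cutoff |
| `censor_max` | 0.5 | fraction of censored frames tolerated |
| `k` (SD rule) | 2.5 | low-outlier multiplier for hit rate and performance |
| `n_perm` | 5000 | specificity-test permutations |
| `n_perm` (contributions) | 1000 | mask shuffles per contribution matrix |
| `n_draw` | 5000 | matched-size subset draws |

Two points deserve emphasis. First, the exclusion cascade applies motion
rules *before* the SD rules, and each SD reference (mean, SD) is computed
once over the runs surviving the earlier stages — no re-iteration. The
order matters: a 2.5-SD rule computed over a set that still contains
motion-contaminated runs can have a shifted reference and keep (or drop)
different runs; the test suite pins this behavior with a fixture. The
hit-rate rule is referenced within modality; the performance rule across
all surviving runs of a dataset. Second, no multiple-comparison correction
is applied to generalization tests: each external validation tests a
single directed hypothesis, and this is surfaced as a documented default
rather than hidden.

## The synthetic cohort generator

`cohort_config()` + `generate_cohort()` define the study conditions every
test runs under. Per subject, a supramodal trait `g` and modality-specific
traits `e_m` are standard normal, and behavior in modality `m` is
`b_m = sqrt(w) * g + sqrt(1 - w) * e_m`, so the cross-modal behavior
correlation converges to `w`. The default `w = 0.55` places the
cross-modal Spearman correlation near 0.53, inside the 0.50–0.59 range
reported for the three empirical datasets the package's defaults emulate.
Default mask sizes (581 positive / 659 negative per modality, 25 / 41
shared) are the reported visual network and overlap sizes; runs per
modality default to 50.

Edges are generated as `baseline_k + s_k * effect_size * b_m + noise`,
with per-edge baselines drawn once from N(0, 0.3) so matrices resemble
Fisher-z-transformed correlations, `s_k = +1` for positive and `-1` for
negative planted edges, and Gaussian run noise (default SD 0.3). With the
default `effect_size = 0.15`, a planted edge's population correlation
with behavior is `0.15 / sqrt(0.15^2 + 0.3^2) ≈ 0.45` — comfortably
detectable at p < 0.01 with ~50 runs, which is what a usable CPM training
set looks like. The motion surrogate is a mean-FD-scaled variable with a
configurable behavior correlation; published characterizations of this
magnitude are scarce, so the default is a mild `-0.2` (worse performers
tend to move more), configurable to zero for clean nulls.

One run per subject is the default; `runs_per_subject > 1` adds runs
around the subject trait with `run_noise_sd`, acknowledging that pooled
run-level training (the default here, as in practice) treats repeated
runs of a subject as exchangeable observations. A subject-aware analysis
is out of scope; the option exists so users can probe the sensitivity of
their conclusions.

The generator also simulates press streams: hits occur on frequent trials
with probability `pnorm(1 + trait)` and false alarms on rare trials with
probability `pnorm(-1 - trait)`, with press latencies placed inside the
gradCPT response window. This emulates the monotone trait→performance
link the scoring stage assumes — it does *not* emulate vigilance
decrements within a run, response-time autocorrelation, or lapses, and
the connectome generator does not emulate BOLD autocorrelation, scanner
artifacts, or spatial edge dependence. Passing tests therefore certify
the *statistical machinery* (selection recovers planted truth, permutation
tests are calibrated, scoring implements the stated rules), not that real
fMRI data will behave this tamely.

External-validation cohorts should be drawn with
`generate_cohort(cfg, truth = training_cohort$truth)` so the new sample
shares the planted predictive edges — that is what "generalization to an
independent dataset" means under the generative model.

## Scoring rules and their edge cases

**gradCPT.** Stimuli cross-fade every 1.6 s. The response window of a
trial runs from 70 % presented to 40 % disappeared; with the ramp
interpreted on the time axis this is `[onset + 0.7 * 1.6,
onset + 1.6 + 0.4 * 1.6]`, boundaries inclusive. (The alternative —
defining the window on stimulus *opacity* — would require the cosine ramp
shape, which is not specified; the time-fraction reading is used.)
Assignment is two-pass: in-window presses go to their trial; remaining
presses, in ascending time order, go to an adjacent unanswered trial —
the frequent one if the other neighbor is a rare trial, otherwise the
closer one, with exact ties broken toward the earlier trial (the causal
reading: a press more plausibly answers the stimulus already seen).
Presses before the first trial or after the last window are logged as
unassigned. RT is measured from trial onset.

**avCPT.** Presses are binned into 1.2-s trial windows. The first press
of a frequent trial is reassigned to the previous frequent trial iff the
trial received more than one press, the first press came under 100 ms
after trial start, and the previous frequent trial is unanswered — an
accounting for reaction times longer than the trial.

**d′.** Rates of 0 and 1 are replaced by `1/(2N)` and `1 - 1/(2N)`
(N = trials of that type) before the normal quantile — standard
signal-detection practice that keeps d′ finite at ceiling (empirical
values run up to ~5) while preserving order. Negative d′ is legal.
**Inverse RT variability** is `mean(rt)/sd(rt)` with the sample SD, over
hit RTs only, and errors rather than guessing when fewer than two RTs
exist.

## Numerical choices

- Correlations of magnitude 1 are clipped to `1 - 1e-7` before Fisher z,
  keeping z finite while preserving edge order.
- Edge/node indices are 1-based throughout; published masks distributed
  as 1-based `(i, j)` pair lists are ingested by `read_edge_pairs()`.
- Ties at `p == alpha` are *not* selected (strict inequality), and ties
  in ranks use average ranks.
- All permutation p-values use the add-one estimator
  `(#extreme + 1) / (n + 1)` and can never be exactly zero.
- Every stochastic routine takes an explicit integer seed; cohort stages
  derive sub-seeds deterministically from the master seed so any stage
  can be re-run in isolation. Results are bit-reproducible given
  `(seed, n_perm)`.
- Degenerate inputs error early and loudly: constant behavior or
  covariates, empty masks (strength undefined), single-run normalization,
  sub-minimum sample sizes. A constant *edge* is merely warned about and
  never selected, since one dead edge should not abort a 35,778-edge
  selection.

## Problem sizes used in the checks

The package's own verification uses deliberately compact cohorts: most
unit tests run 30-node cohorts (435 edges) with 10 + 10 planted edges and
40–120 runs; the selection-calibration check uses a 160-node null cohort
(12,720 edges); permutation-test calibration uses 200 replicate null
cohorts of 50 runs with 199 permutations each; and parameter recovery
uses a 100-node cohort (4,950 edges) with 200 runs. These sizes give the
Monte-Carlo bands quoted in the tests while keeping the full suite in the
tens of seconds; the statistics themselves are size-agnostic, and the
defaults reproduce the full 268-node geometry.

For the recovery check the selection threshold is `alpha = 1e-4` rather
than the training default 0.01: over ~5,000 null edges an α of 0.01
*correctly* admits ~50 false edges (that is what the threshold means), so
exact mask recovery is only a fair demand when the expected number of
false discoveries over the whole edge pool is below one.

## Known limitations

- Run-level pooling ignores within-subject dependence; between-subject
  SEs from pooled runs are optimistic. The `runs_per_subject` option lets
  users quantify the effect, but no mixed-effects machinery is provided.
- The hypergeometric overlap test assumes masks are drawn uniformly —
  anatomical clustering of predictive edges makes it anti-conservative as
  a test of "meaningful" overlap; it is reported as the field reports it.
- The contribution-matrix normalizer is ambiguous in the source
  descriptions ("divided by network size"); the per-block possible-edge
  count is the default, the total-mask-size alternative is available via
  `normalizer = "mask"`.
- Preprocessing (parcellation, nuisance regression, censoring) is out of
  scope: the package starts from node time series or edge matrices.
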