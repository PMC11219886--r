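---
title: "Modeling REM sleep from resting-state connectomes: methods and design notes"
author: "remcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling REM sleep from resting-state connectomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remcpm)
```

# Overview

`remcpm` implements an end-to-end analysis relating rapid-eye-movement (REM)
sleep to whole-brain resting-state functional connectivity in a split-night
sleep-deprivation design with three groups:

* **FS** — full night of sleep, in bed 23:00–08:00;
* **early_dep** — early-night deprivation, awake until 03:00, sleeps
  03:00–07:30 (REM-rich late-night sleep retained);
* **late_dep** — late-night deprivation, sleeps 23:00–03:30, then kept awake
  (REM-rich sleep lost).

The stages are: polysomnographic sleep scoring from hypnograms; Fisher-z
functional connectivity (FC); connectome-based predictive modeling (CPM) of
REM duration; multi-level characterization of the predictive connectome; and
a three-group comparison of connectome strengths. Because clinical recordings
of this kind are rarely shareable, the package includes a synthetic cohort
generator that reproduces the statistical structure the analysis assumes, so
every stage is testable.

# Sleep metrics

Hypnograms are sequences of 30-second epochs over the AASM alphabet
{W, N1, N2, N3, R}, spanning lights-off to lights-on. Scoring conventions
vary across laboratories, so the package fixes them explicitly:

* **Sleep onset** is the first epoch of any non-wake stage.
* **SL** (sleep latency) is lights-off to sleep onset, in minutes.
* **WASO** counts wake strictly between onset and the final sleep epoch.
  Terminal wake is reported separately, so time in bed decomposes exactly:
  `TIB = SL + TST + WASO + terminal wake`.
* **SE** (sleep efficiency) uses the full lights-off-to-lights-on span as
  denominator. A sleep-period-time denominator is a common alternative; the
  components to compute it are all returned.
* Stage percentages are fractions of total sleep time (TST) and close to
  100 exactly. An all-wake record yields `TST = 0` with percentages reported
  as `NA`, not zero.

`segment_hypnogram()` splits a night at a clock time (03:30 by default
downstream), snapping to the nearest epoch boundary; every duration metric
is additive across the split, which the test suite asserts on generated
nights.

# Synthetic cohorts

## Hypnograms

The generator is a semi-Markov cycle model: an initial wake run (latency),
then sleep cycles of roughly 90 minutes (Gaussian, SD 10 min), each composed
of N1/N2/N3 blocks followed by a REM block, with brief awakenings inserted
after onset and an occasional terminal wake run. Two choices matter:

* **REM ramp.** The REM fraction of a cycle rises linearly from 10%
  (cycle 1) to 35% (cycle 5). This reproduces the early/late-night REM
  asymmetry that motivates the split-night design without claiming
  physiological fidelity.
* **Circadian anchoring.** The cycle index is computed from clock time
  elapsed since 23:00 (habitual onset), not from each subject's own sleep
  onset. A subject who starts sleeping at 03:00 therefore enters the night
  in REM-rich cycles. Anchoring to per-subject onset instead would give the
  early-deprivation group cycle-1-like REM-poor sleep and invert the
  groups' observed REM ordering.

Deep NREM (N3) is front-loaded (its within-cycle share decays across
cycles), and per-group mean latency and WASO parameters (FS 8/23 min,
early_dep 5/6.5, late_dep 10/10) match the scale of a manipulation-night
sleep table.

## Behavior and its reconciliation

Per-group REM durations are drawn from normal laws. The defaults
(FS 102.2 ± 28.6 min, early_dep 61.3 ± 16.5, late_dep 38.2 ± 13.4) are
back-computed from group-level total sleep time and REM percentage
(TST × REM%/100) — they are approximations, since only percentage summaries
are typically published, and they can be overridden in `cohort_config()`.
The drawn duration is *reconciled* into the subject's hypnogram by
converting randomly chosen REM epochs to N2 (or NREM epochs to REM) until
the hypnogram-derived duration matches the draw to within one epoch. Wake
epochs are never touched, so TST, SL and WASO are preserved and the recorded
behavior always equals what `score_sleep_parameters()` recomputes. This is
O(1) per subject; rejection sampling would be wasteful and would distort the
schedule constraints.

## Connectivity

Each subject's edge vector (upper triangle, row-major, `n(n-1)/2` edges; for
227 nodes, 25,651) is

$$z_e = \mathrm{base}_e + \beta\,\tilde b\,[e \in \mathcal{P}] + \varepsilon_e,$$

where the baseline is `atanh(0.25)` for within-network and `atanh(0.08)` for
between-network edges (typical resting-state FC levels on the Fisher-z
scale), $\tilde b$ is the cohort-standardized REM duration, $\mathcal{P}$ is
the planted edge set, and $\varepsilon_e$ is independent Gaussian noise of
SD `edge_noise_sd`. The linear coupling on the z scale with Gaussian noise
matches CPM's linear-regression assumption, so parameter recovery is a fair
test of the estimator rather than of a model mismatch. The 40 default
planted edges are split evenly over the DMN-DMN, DMN-VIS, VIS-SUB and
CON-CON network pairs, mirroring where predictive edges concentrate in this
literature. `dmn_group_delta` subtracts a constant from the planted DMN-DMN
edge means of late-deprivation subjects, modeling a group-level deficit.
`realize_timeseries()` can back-convert any target z matrix into node time
series (multivariate normal with the target correlation; non-positive
definite targets are repaired by eigenvalue clipping and reported).

What the generator does **not** emulate: EEG waveforms, BOLD hemodynamics,
head motion, spatially correlated noise, heavy-tailed FC distributions, or
site/scanner effects. Passing tests therefore demonstrate correctness of the
estimators under the stated generative model, not robustness to every
artifact of real recordings.

# Connectome-based predictive modeling

`cpm()` follows the standard protocol. Within each leave-one-out fold:

1. every edge is Pearson-correlated with behavior over the n−1 training
   subjects; edges with `r > 0` and two-sided `p < alpha` form the positive
   mask, `r < 0` analogously the negative mask (default `alpha = 0.01`, the
   most common choice; exposed in the interface because published analyses
   often leave it unstated);
2. each subject's positive/negative *strength* is the sum of its z-values
   over the corresponding mask;
3. ordinary least squares of behavior on the strength is fit on training
   subjects only, and applied to the held-out subject's strength computed
   under the training-derived mask.

Three models are reported — positive, negative, and a combined two-feature
model — because the literature is ambiguous about whether the tails enter
jointly or separately; the positive model is the conventional headline.
Significance is a one-tailed permutation test: behavior is permuted, the
*entire* pipeline (selection included) is re-run, and
`p = (1 + #{r_perm >= r_obs}) / (n_perm + 1)` (default 1000 permutations,
floor p ≈ 0.001).

Numerical notes:

* The per-fold correlations are computed by downdating full-sample cross
  products, so each fold costs O(edges) and the permutation test is
  feasible in plain R; the test suite proves exact equivalence to a
  brute-force per-fold reimplementation (`cor.test` + `lm`).
* Selection thresholds are applied via the critical |r| equivalent to
  `p < alpha` at the training df — identical decisions, no per-edge p-value
  evaluation in the inner loop.
* A fold whose masks are empty predicts the training mean (counted and
  reported, never an error). If *every* fold is empty the cross-validated
  predictions are an affine decreasing function of the held-out values and
  `r_obs` is exactly −1 — the extreme case of LOOCV's negative bias under
  the null. The permutation test is built from the same pipeline and is
  therefore calibrated despite this bias (asserted by a uniformity test and
  a type-I-rate test on null cohorts).
* Correlation is clipped at |r| ≤ 0.999999 before `atanh`, keeping z finite
  on degenerate inputs. Matrix diagonals are stored as 0 and excluded
  everywhere.

The **consensus connectome** merges per-fold masks: an edge is retained if
selected with the same sign in at least `consensus_fraction` of folds
(default 1.0, the intersection — the strictest, most reproducible choice;
smaller fractions interpolate toward the union).

## A detectability limit worth knowing

With independent per-edge noise, a *fixed* total signal spread over $k$
planted edges pins the per-edge population correlation: if the summed
strength over the planted set explains a fraction $R^2$ of behavioral
variance, each edge's correlation is $\sqrt{R^2/(k(1-R^2) + R^2)}$
(≈ 0.053 for $R^2 = 0.10$, $k = 40$) irrespective of the absolute noise
scale. At n ≈ 110 the selection threshold `p < 0.01` corresponds to
|r| > 0.245, so such a diffuse signal is invisible to CPM's univariate
screen even though an oracle that knew the planted set would predict
behavior at r ≈ 0.32. Detection requires the signal to be concentrated
(few edges, or correlated noise that summation cancels). This is a property
of the method, not a bug; the test suite exercises both regimes, and the
diffuse one fails to reach r ≥ 0.2 for exactly this reason.

# Characterization

The consensus mask is profiled at three levels; all "normalized" quantities
are divide-by-total (each distribution sums to 1) and all variances are
population variances (divide by the count) — printed concentration values
depend on both conventions, so they are fixed and documented.

* **Network pairs** (55 with ten networks): edge counts, shares, and the
  variance of the 55 shares (concentration of edges into few pairs).
* **Pair contributions**: for each pair with at least one mask edge, the
  absolute Pearson correlation between behavior and the per-subject sum of
  that pair's edge strengths; absolute, so positive- and negative-tail
  edges are comparable. Pairs with zero mask edges are excluded from the
  contribution normalization but kept (as zeros) in the share distribution.
* **Large-scale networks**: endpoint shares (a within-network edge counts
  twice for its network) and analogous contributions.
* **Regions**: per-node degree and contribution, plus their similarity
  `cor(degree, contribution)` over nodes.

Conservation identities (shares sum to 1, Σ degree = 2 × edge count) hold
exactly and are asserted on random fixtures.

# Group comparison

Subject-level strength of a network pair is the **mean** (not sum) Fisher-z
over the pair's consensus edges, making strengths comparable across pairs
with different edge counts. Each pair is tested by classical one-way
fixed-effects ANOVA across the three groups (df = (2, N−3)); p-values are
corrected across pairs with Benjamini–Hochberg FDR by default (Bonferroni
available). Post-hoc Welch t contrasts and an edge-level ANOVA follow-up run
only for pairs surviving correction (gatekeeping). Cohen's d is reported in
two conventions — pooled-SD d and t/√N — because published effect sizes mix
both standardizers; neither is used as a decision criterion. The degenerate
all-constant case is reported as F = 0, p = 1. `welch_t_from_summary()`
computes the same Welch t directly from published mean/SD/n triplets and is
verified to match the raw-sample computation to 1e−12.

One caution established while validating the group stage: consensus pairs
are *not* usable as negative controls for the group test, because consensus
edges were selected for correlation with behavior and behavior differs
strongly between groups — a chance-selected edge therefore carries a real
group effect. Calibration of the correction is instead demonstrated with
probe edges drawn outside the planted pairs.

# Problem sizes and reproducibility

Simulation-based validation uses a reduced connectome — 46 nodes
(1035 edges, network sizes rescaled by largest remainder with a floor of
two nodes per network) with the full cohort size of 110–113 subjects —
chosen so properties that are scale-free in the edge count (selection
calibration, LOOCV equivalence, recovery, type-I rates) can be replicated
hundreds of times; results at 227 nodes differ only in multiple-testing
burden. Every stochastic stage is reproducible from an integer seed:
`generate_cohort()` seeds all draws from `config$seed`, `cpm()` seeds its
permutation stream, and `run_pipeline()` writes byte-identical artifacts on
re-run.

A note on the default parcellation: the ten-network composition over 227
nodes approximates the relative network sizes of widely used functional
atlases (one published figure describes the matrix as "227×277", an evident
typo for 227×227 — the edge count 25,651 corresponds to 227 nodes). The
parcellation is consumed purely as a node→network table; any labeling over
the ten canonical networks and any node count is accepted.

# Known limitations

* No covariate adjustment (age, sex, motion) in the CPM stage; the paper
  trail for such adjustments is design-specific and the hook would invite
  silent misuse. No k-fold or split-half CV variants; LOOCV only.
* The hypnogram model makes no claim to physiological realism beyond the
  schedule, cycle, and ramp constraints stated above.
* Group labels are fixed to the three-arm split-night design; other designs
  would need their own schedule table.
* The characterization's concentration variances depend on the
  normalization conventions above; values computed under other conventions
  are not comparable.
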