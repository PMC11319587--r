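---
title: "Models and methods behind boxtask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind boxtask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boxtask)
```

## The task and its data model

The Box Task is a self-ordered search test: boxes at random screen
locations are opened one at a time to find a hidden target; a found target
stays in its box, a new target is hidden in a box that has not yet held
one, and the trial ends when every box has yielded its target. A session
is two practice trials of 3 boxes followed by two trials each at set sizes
4, 6 and 8. The engine (`build_session_spec()`, `start_trial()`,
`open_box()`) enforces this structure and records every open event with a
timestamp, so a session log is a loss-free account of behaviour. Box
indices are 0-based everywhere, including the JSON/CSV file formats; trial
and search indices are 1-based in reports.

Two structural commitments deserve mention because the task description
alone does not fix them:

* **Target placement.** Each trial's targets are a seeded random
  permutation of the boxes, fixed before the first open. This follows from
  the requirements that every box eventually yields a target and that found
  targets persist; an adaptive or adversarial placement mode is deliberately
  not implemented.
* **Practice trials** are generated and logged but excluded from all
  scoring and analysis, matching the convention of reporting only the
  4/6/8-box scores.

Coordinates live on an abstract 100 x 100 canvas with a minimum box
separation of 15 units; they matter for log fidelity only and never enter
scoring. The engine imposes no response deadline.

## Scoring

Four measures are computed per trial (`score_trial()`):

* **Between-search errors**: every open of a box that holds a target found
  in a strictly earlier search of the same trial. Repeated re-opens each
  count.
* **Within-search errors**: every open of a box already opened *and found
  empty* earlier in the current search. An open of a past-target box is
  always classified as a between-search error and never additionally as a
  within-search error; this precedence rule makes the two counters disjoint
  and well defined. The first open of a trial can never be an error.
* **Completion time**: the timestamp of the final `target_found` event.
* **Strategy score**: for each search $k \ge 2$, let $\mathrm{ref}$ be the
  path of search $k-1$ with *all* occurrences of that search's target box
  removed and $\mathrm{cur}$ the full path of search $k$; the per-search
  score is
  $\mathrm{lev}(\mathrm{ref}, \mathrm{cur}) / \max(|\mathrm{ref}|, |\mathrm{cur}|)$
  (0 when both are empty) and the trial score is the unweighted mean over
  $k = 2..n$. Removing every occurrence of the previous target, not only
  the terminal one, keeps known-error opens out of the reference path. The
  max-length denominator gives the standard normalised Levenshtein range
  [0, 1]; lower scores mean consecutive searches retrace similar paths,
  i.e. a more systematic strategy.

Per set size, `score_session()` reports the mean of the two trials for each
measure and additionally the trial-1 + trial-2 *sum* of the two error
counts, which are the decision tree's inputs. The
`emulate_missing_4box_t1_time` flag makes the 4-box time aggregate use
trial 2 only, replicating the handling of a recording fault in the original
study data.

## The generative agent

No generative model of participant behaviour exists in the source
literature, so the simulator is this package's own modelling commitment,
chosen as the simplest recency mechanism whose two memory parameters map
onto the two error types:

At every choice point the agent assembles a believed-eligible set. Each
past-target box is remembered independently with probability
$\rho_B^{\,d}$, where $d$ counts the opens elapsed since that target was
found; each box opened during the current search is remembered with
probability $\rho_W^{\,d}$ since its most recent open. Remembered boxes
are excluded; if nothing remains eligible the agent resets to all boxes
except the one just opened. With probability $\sigma$ the agent opens the
lowest-indexed eligible box (a canonical scan order), otherwise one
uniformly at random. Per-open latencies are log-normal
$(\mu_\ell, \sigma_\ell)$ and timestamps cumulate.

Geometric decay per intervening open makes forgetting load-dependent: the
same $\rho_B$ produces far more between-search errors at 8 boxes than at 4,
reproducing the set-size effect without any extra parameter. A
perfect-memory, fully systematic agent ($\rho_B = \rho_W = \sigma = 1$)
provably makes zero errors, which the test suite asserts as a hard
invariant.

### Severity and covariates

Each simulated participant carries a latent severity scalar
$s \sim N(0, \text{severity\_sd}^2)$. Severity shifts the retention
probabilities down on the logit scale (`sev_rho_slope` per unit) and the
latency location up (`sev_latency_slope`), and simultaneously shifts every
neuropsychological covariate through per-test coupling weights:
$x = \text{mean} + \text{coupling} \cdot s + \varepsilon$, with the
residual SD chosen so the marginal SD matches the target and the result
truncated to the instrument range (ACE-III /100, RCF /36, Spatial Span /16,
times in seconds). Trails B is floored at Trails A + 1 s so the executive
difference score B − A stays non-negative. One scalar driving both task
and covariates is what creates covariate–error correlations; the
*group-specific* coupling weights are how the published dissociation is
built in: the AD model couples RCF 3-min recall strongly to severity
(−3 points per SD) with Trails A only moderate (+12 s), whereas the bvFTD
model zeroes the recall coupling and keeps a Trails A coupling (+15 s).
Consequently recall predicts 6-box between-search errors in simulated AD
but not bvFTD cohorts — by construction, which is exactly what a
generator-recovery test can and cannot demonstrate (see *Limitations*).

### Calibration

Group presets were calibrated once by coarse grid search over
$(\rho_B, \rho_W, \sigma)$ against the published group-level anchors (mean
between-search errors per set size, mean completion times, covariate
means/SDs), then refined with larger Monte-Carlo runs measured through the
same cohort generator the analyses use. Shipped values:

| group   | $\rho_B$ | $\rho_W$ | $\sigma$ | mean latency (s) | sev_rho_slope |
|---------|---------:|---------:|---------:|-----------------:|--------------:|
| control | 0.973    | 0.985    | 0.45     | 2.5              | 0.5           |
| bvFTD   | 0.87     | 0.98     | 0.55     | 4.0              | 0.5           |
| AD      | 0.52     | 0.98     | 0.30     | 4.7              | 1.0           |

These reproduce the anchor means (bvFTD 6-box between-search errors ~3.9,
AD 6-box ~6.4, control 8-box ~3.6, AD 8-box time ~168 s, AD ACE-III 68.3)
to within a few percent of the published values at the study sample sizes.
The steeper AD severity slope is needed because at low $\rho_B$ the
expected-error curve flattens, and without the steeper slope severity would
barely move AD task errors, leaving the covariate couplings with nothing
to correlate with.

Trails A and B means/SDs are not available in the published group table;
the shipped values (controls 35/85 s, bvFTD 55/170 s, AD 70/210 s, with
clinically plausible SDs) are the implementers' choice, set once from
typical clinic ranges for these populations. Demographics are not
generated: the groups were reported age- and sex-comparable, and no
analysis in the package consumes them.

A single log-normal latency per open cannot reproduce the published 4-box
times (which imply ~6–9 s per open) and 6/8-box times (~4–5 s per open)
simultaneously; the presets are calibrated to the 6- and 8-box rows, so
simulated 4-box times run low. Real patients presumably slow down
disproportionately on early, sparse trials — a deliberation effect the
constant-latency model omits.

## Classification

`classify_published_tree()` is the fixed published tree: root on ACE-III
total at 70 with a score of exactly 70 taking the lower branch ("above 70"
is strict); then 6-box within-search error sum ≥ 1 ⇒ AD on the high branch
and 4-box between-search error sum ≥ 2 ⇒ AD on the low branch. The tree is
shipped as a constant so that replication of the published rule does not
depend on the tree fitter.

`fit_chaid()` is a simplified CHAID: continuous predictors are discretised
at candidate cut-points (all distinct values when ≤ 20, else 20
quantile-based cuts); adjacent categories are merged while the most similar
adjacent pair's 2 x 2 chi-square test has p > `alpha_merge`; the winning
predictor minimises the Bonferroni-adjusted p of the final labels x
categories table, with multiplier $\binom{c_0 - 1}{c - 1}$ (the number of
ways of reducing $c_0$ ordered categories to $c$); the split is accepted if
that adjusted p ≤ `alpha_split`. Recursion stops at `max_depth`, at nodes
below `2 * min_node_size`, or when no acceptable split remains. A
`forced_first` predictor is always split first at the root — its merged
categories are used even when its adjusted p fails `alpha_split`, mirroring
the "forced into the model" design. Leaf ties go to AD, the clinically
costlier miss to soften; this is configurable. The exact internals of the
commercial CHAID implementation (exhaustive vs classic merging, its
Bonferroni variants, its binning) are not public, so this algorithm is a
documented simplification; a recovery test shows it reconstructs the
70/1/2 cut-offs from data generated off the fixed tree's own partition.

`roc_auc()` computes AUC as the Mann–Whitney probability with ties counted
1/2 via midranks — exact under ties, unlike trapezoidal integration over an
interpolated curve — and returns the full step curve. An orientation flag
reverses scores for measures where *higher* values indicate the positive
class (errors, times), so AUC ≥ 0.5 always means discrimination in the
stated direction. `evaluate_classifier()` reports the confusion matrix,
per-class and overall percent correct, the risk estimate $r$ (training
misclassification proportion) and its standard error $\sqrt{r(1-r)/n}$.

## Supporting statistics

`benjamini_hochberg()` implements the step-up rule directly (reject the
largest prefix of sorted p-values with $p_{(k)} \le kQ/m$), returning the
per-rank critical values; `standardized_regression()` z-scores response and
predictors and fits OLS with all predictors entered simultaneously,
reporting standardised betas and classical t-test p-values with
$n - k - 1$ degrees of freedom. The executive predictor enters as the
Trails B − A difference, avoiding the collinearity of Trails B with
Trails A. Rank-deficient designs are rejected with the collinear columns
named.

The repeated-measures model used for the original group x set-size
inference (generalised estimating equations with a Poisson link) is
deliberately out of scope: it is off-the-shelf machinery rather than a
contribution, and its estimated means are handled as simulator calibration
anchors instead. In its place `group_setsize_contrasts()` provides
permutation tests of group mean differences per set size
(two-sided, $p = (1 + \#\{|T_\pi| \ge |T_{obs}|\})/(1 + B)$, default
$B = 9999$), BH-corrected across the family.

## Problem sizes and numerical choices

The shipped test-suite and acceptance runs use: full study cohorts
(32/28/28) for calibration checks; 200 participants per patient group for
the regression-dissociation check; 100 replicates for the CHAID and
permutation type-I checks; Levenshtein/AUC/BH oracle comparisons on
exhaustive small instances (sequence length ≤ 8, n ≤ 12, m ≤ 10). These
sizes make every Monte-Carlo assertion stable at the stated thresholds
while keeping a full run in the low minutes on one core. All stochastic
tests fix their seeds. Ties in the BH procedure are handled by stable
sort; 0/0 strategy comparisons are defined as 0; chi-square tests on
tables with empty margins are treated as uninformative (p = 1) during
merging.

## Limitations

* The agent is a stand-in, not a fitted model: no parameter was estimated
  from patient logs (none are public), so agreement with the published
  group means shows calibration, not mechanism discovery.
* Passing the regression-dissociation check demonstrates that the analysis
  chain *recovers structure the generator encodes*; it is not evidence
  about real bvFTD or AD cohorts.
* Within-search error rates and strategy scores were not calibration
  targets; they land in plausible ranges (within-search means below ~0.7,
  strategy means 0.6–0.8) but are emergent rather than matched.
* Covariates are conditionally independent given severity; real test
  batteries have richer correlation structure (shared motor speed,
  education effects) that only marginals cannot constrain.
* The fixed decision tree's published classification accuracy concerns the
  original patient sample; applied to simulated cohorts it performs
  according to the simulator's own error distributions, not the printed
  percentages.
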