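---
title: "Matched subgroup discovery for heterogeneous treatment effects: methods and design choices"
author: "mcart"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Matched subgroup discovery: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Secondary analyses of randomized trials increasingly search for
heterogeneous treatment effects (HTEs): subgroups of participants whose
benefit or harm differs systematically from the trial average. Randomization
balances covariates between arms *overall*, but it does not guarantee
balance *within* every data-driven subgroup a search procedure may carve
out. A subgroup selected because its treated members did conspicuously
better than its controls may owe that contrast to a covariate imbalance
inside the subgroup — confounding reintroduced by the search itself — rather
than to genuine effect modification. Regression with treatment
interactions and forest-based effect estimators, followed by partitioning
of the estimated individual effects, are particularly prone to this: the
estimated effect surface is a deterministic function of the covariates, so
a partitioning tree will happily slice a large trial into hundreds of tiny
"subgroups", most of them imbalanced and spurious.

`mcart` implements a matching-first alternative. Treated and control
participants are pair-matched on their baseline covariates *before any
outcome contrast is examined*; the subgroup search then operates on matched
pairs, so every candidate subgroup is balanced between arms by
construction.

## The algorithm

For a two-arm trial with binary adverse outcome \(Y\), treatment
\(Z \in \{0,1\}\), and \(K\) prognostic baseline covariates:

1. Select the \(K\) prognostic covariates \(P = (X_1, \dots, X_K)\)
   (continuous or categorical) and store each participant's vector
   \(P_i\).
2. With \(T\) treated and \(C\) controls, form the rank-based Mahalanobis
   distance matrix between arms (smaller arm as rows). Each encoded
   covariate column is replaced by its ranks over all \(N\) participants
   (average ranks for ties); with \(S\) the covariance of the ranked
   columns, \(d(i,j) = \sqrt{(r_i - r_j)^\top S^{-1}(r_i - r_j)}\).
   Ranking caps outlier leverage and makes distances invariant to monotone
   transforms of continuous covariates.
3. Pair-match: an optimal bipartite assignment yields \(G = \min(C, T)\)
   disjoint treated–control pairs minimizing the total matched distance.
4. Exact-filter: any pair whose members disagree on a categorical
   covariate (binary 0/1 covariates included by default) is discarded,
   leaving \(G_2 \le G\) pairs.
5. Average: per pair \(g\), the pair-level effect
   \(\delta_g = Y^t_g - Y^c_g \in \{-1, 0, 1\}\) and covariates
   \(P_g = (P^t_g + P^c_g)/2\) (categoricals are equal within a pair after
   step 4 and are carried).
6. Grow a single conditional inference tree for \(\delta_g\) given
   \(P_g\): permutation-test split selection with Bonferroni multiplicity
   adjustment.
7. Project: every trial participant is routed down the tree; within each
   terminal node the subgroup treatment effect is estimated on the original
   data as the risk difference between arms with a 95% interval, and the
   node's \(\Pr[\delta_i = k]\), \(k \in \{-1,0,1\}\), are estimated by the
   node's pair-level frequencies (the only \(\delta\) information the tree
   retains).

```r
library(mcart)
trial <- simulate_trial(make_scenario("2B"), seed = 7)
model <- mcart_fit(trial)
mcart_report(model, trial)
```

## The tree: split selection by permutation tests

At each node, every candidate covariate \(X_j\) is tested against the
response with the linear statistic \(T_j = \sum_i g_j(x_{ij})\,y_i\)
(\(g_j\): identity for numeric, level indicators for categorical
covariates), standardized by its exact conditional mean and covariance
under permutation of \(y\) and summarized as a quadratic form referred to a
chi-square distribution with rank-of-covariance degrees of freedom. For
nodes of at most 10 observations the reference distribution is instead
computed exactly, by enumerating every distinct rearrangement of the
response. The smallest Bonferroni-adjusted p-value (\(p \cdot K\), capped
at 1) selects the split variable; the node stays terminal if that p-value
exceeds `alpha`. Only then is the cut point sought: every midpoint between
consecutive distinct values (numeric) or every binary level partition
(categorical, refused above 10 levels) is scored by the standardized
two-sample statistic, subject to both children holding at least `min_leaf`
rows. Separating variable selection from cut-point search is what keeps
the false-split rate at `alpha` per node and avoids the classical
variable-selection bias toward many-valued covariates.

Tunable parameters (`tree_control()`), following the conditional-inference
framework's conventional defaults — the benchmark designs do not prescribe
them:

| parameter    | default | meaning |
|--------------|---------|---------|
| `alpha`      | 0.05    | adjusted significance level a split must reach |
| `min_split`  | 20      | smallest node in which a split is attempted |
| `min_leaf`   | 7       | smallest admissible child |
| `adjust`     | Bonferroni | multiplicity adjustment over the K candidates |
| `response_scale` | numeric | \(\delta_g\) as a score (mean-shift tests); a nominal treatment is available |

Treating \(\delta_g \in \{-1,0,1\}\) as numeric matches the use of node
means as effect estimates; the ordering benefit < none < harm is real and
a mean-shift test is the natural target.

## Matching: design choices

* **Optimal vs greedy.** The pair-matching step is an exact optimal
  assignment (successive shortest augmenting paths, implemented in C++).
  It is deterministic for a given matrix; among exactly cost-tied optimal
  matchings the scan order, not a lexicographic rule, fixes the result —
  total distance, which is what the method consumes, is unaffected. A
  greedy nearest-neighbour variant is available (`match_method =
  "greedy"`) for sensitivity analysis.
* **Singular rank covariance.** Indicator blocks can be collinear in small
  trials; a Moore–Penrose pseudo-inverse is then used in place of
  \(S^{-1}\).
* **Encoding.** Categorical variables enter the distance as \(L-1\)
  indicators (lexicographically first level as reference); all columns,
  indicators included, are ranked uniformly. Zero-variance columns are
  dropped with a warning.
* **Binary covariates** count as categorical for the exact filter
  (`default_categorical_vars()`); the list is user-configurable. Averaging
  unequal categorical values is refused rather than guessed, so disabling
  the filter on disagreeing pairs is an explicit error.

## Effect estimates, balance, and bias

Within a projected subgroup the risk difference is
\(\widehat{RD} = e_t/n_t - e_c/n_c\). The default 95% interval is the
normal approximation with the Yates continuity correction (equivalently,
what `prop.test()` reports); `correct = FALSE` gives the plain Wald
interval. The corrected form is the default because it reproduces the
printed intervals of the classical two-proportion analyses this package's
benchmark designs are calibrated to; on the trial scale the two differ by
\((1/n_t + 1/n_c)/2\) in half-width.

Balance is quantified by absolute standardized differences:
\(|\bar x_t - \bar x_c| / \sqrt{(s_t^2 + s_c^2)/2}\) for continuous
covariates (sample variances; the \(n-1\) convention is adopted — the
published two-decimal tables cannot distinguish it from \(n\)) and
\(|p_t - p_c| / \sqrt{(p_t q_t + p_c q_c)/2}\) for proportions, reported
per level for multi-level categoricals with the variable summarized by the
maximum level ASD. A subgroup's balance is *acceptable* iff every ASD is
strictly below 0.2 (the order of a small effect size; configurable).

When the truth is known (simulation), a subgroup's bias is its estimated
risk difference minus its true average treatment effect — the mean of the
true \(\delta_i\) over the participants it contains.

The two-proportion sample size (`required_sample_size()`) uses the
pooled-variance normal approximation without continuity correction,
\(n = \left(z_{1-\alpha/2}\sqrt{2\bar p\bar q} + z_{\rm power}\sqrt{p_0q_0 + p_1q_1}\right)^2 / (p_1-p_0)^2\),
rounded up.

## The simulator

`make_scenario()` / `simulate_trial()` generate five benchmark randomized
trials with known potential outcomes: a phase II oncology trial
(\(n = 200\), 6 covariates) with no HTE ("1A") or two age-defined
subgroups ("1B"), and a phase III CVD trial (\(n = 6000\), 10 covariates)
with no HTE ("2A"), four aspirin-by-eGFR subgroups and a negative overall
effect ("2B"), or the same four subgroups with zero overall effect
("2C"). Within each subgroup cell \(\delta\) is multinomial on
\(\{-1,0,1\}\); participants with \(\delta = 0\) have both potential
outcomes equal to 1 in the oncology setting and 0 in the CVD setting — the
latter is implicit in the designs but forced by the stated arm-level event
rates (e.g. a 6.8% control rate equals the \(\Pr[\delta=-1]\) cell, which
requires \(\delta = 0\) to mean "no event either way"). The zero-effect
overall average in "2C" follows from subgroup multipliers \((-3, -7, 7,
3)\) of the base effect, which sum to zero. Randomization is complete
(exactly \(n/2\) per arm, a seeded permutation), covariates are drawn
column-by-column in schema order then \(\delta\) then the arm (R's default
Mersenne–Twister; one seed, byte-identical reruns). Continuous covariates
are not truncated: extreme draws can be clinically implausible (negative
creatinine) with negligible probability and are left as drawn. The eGFR
subgroup boundary places the value 72 in the "\(\le 72\)" cell, and the
age boundary in "1B" places 65 in the younger group (a continuous draw
ties with probability zero).

What the simulator does *not* emulate: missing data, measurement error,
unmeasured confounders, correlated covariates, informative dropout, or
non-1:1 allocation. Passing the benchmark suite therefore demonstrates
correct mechanics and the imbalance phenomenon under clean conditions, not
robustness to the messiness of real trial data.

## Comparators

`lr_backward_aic()` fits the classical interaction model (all covariates,
treatment, and every treatment-by-covariate interaction) and eliminates
terms backwards by AIC via `stats::step()`, which respects marginality (an
interaction leaves before its main effects — the criterion alone does not
pin this down, and hierarchy is the standard reading). Individual effects
are \(p_1 - p_0\) from the final model. `forest_effects()` provides a
classification-forest adapter (500 trees, \(\sqrt{p}\) variables per
split; difference of majority-vote predictions with treatment forced to 1
vs 0) and a gradient-forest slot that delegates to an external
honest-estimation implementation when one is installed and otherwise
reports itself skipped. `partition_effects()` applies the same conditional
inference tree to the estimated effects — the step that fragments null
trials into hundreds of imbalanced subgroups and motivates matching first.
Comparator subgroup *counts* are realizations of unstated seeds and
library versions; only their order of magnitude relative to the matched
pipeline is a stable property.

## Numerical choices and degenerate inputs

* Exact permutation enumeration below \(n = 11\); chi-square otherwise
  (tests confirm 0.02 agreement with a 50,000-draw Monte-Carlo oracle at
  \(n = 200\)).
* Zero-variance response or covariate: association p-value 1, flagged.
* Numeric thresholds are midpoints of consecutive distinct values;
  boundary values route left (`x <= c`).
* Ties: first-minimum variable selection (schema order), smallest
  threshold, lexicographically first level set, assignment scan order.
* Quadratic forms use eigenvalue pseudo-inversion with a relative
  tolerance; degrees of freedom equal the covariance rank.
* Nodes with an empty arm after projection have an undefined risk
  difference: flagged with a warning, never silently dropped.

## Problem sizes in the test suite

The distributional checks run the full pipeline on 20 seeded replicates of
each \(n = 6000\) scenario (and 20 of each \(n = 200\) scenario), 200
null replicates for the type-I split rate, and a pooled \(3 \times
10^5\)-participant draw for simulator calibration — sizes chosen to hold
Monte-Carlo error well inside each asserted band while keeping a full run
in minutes on one core.

## Known limitations

* **Cut-point variance.** Variable selection is protected by permutation
  tests, but once a variable is selected its cut point is the argmax of a
  maximally selected statistic with no multiplicity control of its own
  (the framework's standard construction). When the true within-node
  signal is modest (standardized effect around 3–4), a chance cluster of
  pairs in a covariate tail can occasionally out-score the true boundary,
  yielding a cut far from it and a small, imbalanced projected subgroup.
  Across 20 seeded replicates of the four-subgroup CVD benchmark this
  affects a noticeable minority of runs on either response scale; single
  clean runs are typical but not guaranteed. Inspecting per-node sizes and
  ASDs (the report does both) flags such nodes immediately.
* Small trials: with \(n = 200\) and ~50–70 pairs surviving the exact
  filter, the tree rarely reaches significance — the benchmark "1B"
  subgroups are genuine false negatives of the method at that size.
  Matching discards up to half the sample and the filter more; power is
  the price of enforced balance.
* Only 1:1 pair matching is implemented (no calipers, 1:k, full, or
  propensity matching).
* Inference within discovered subgroups uses large-sample intervals and no
  multiplicity correction across subgroups.
* Balance is enforced on *observed* covariates only; imbalance in
  unmeasured covariates remains possible.
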