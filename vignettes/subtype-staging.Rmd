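---
title: "Subtype and stage inference for regional biomarker z-scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype and stage inference for regional biomarker z-scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

sustainz fits the linear z-score variant of Subtype and Stage Inference
(SuStaIn) to cross-sectional and longitudinal regional biomarker data —
the setting it was written for is tau-PET SUVR quantified in lobar
composite regions, but nothing in the model is specific to PET.

Disease progression is modelled as an ordered sequence of discrete
**events**. An event is a region `i` crossing a severity threshold
`z_ir` expressed in control-referenced z-score units. With `B` regions
and `R_i` thresholds per region the model has `N = sum(R_i)` events; the
default geometry (10 regions x 2 thresholds) gives the 20-event model
used throughout the package's tests.

A **subtype** `c` is a permutation `S_c` of the `N` events, constrained
so that each region's lower threshold precedes its higher ones. A
subject at **stage** `k` of subtype `c` has completed the first `k`
events of `S_c`. The expected z-score of region `i` at stage `k`,
`g_i(k)`, is the piecewise-linear interpolant through the knots

```
(0, 0), (p(i,1), z_i1), ..., (p(i,R), z_iR), (N, z_max_i)
```

where `p(i,r)` is the position of event `(i, r)` in `S_c` and `z_max_i`
is a per-region ceiling. When a region's top event occupies the final
position `N`, the ceiling segment vanishes and the trajectory ends at
`z_iR`. This knot set makes every trajectory non-decreasing in stage,
which the test suite asserts property-style over random valid sequences.

Observed z-scores are the trajectory plus Gaussian noise:

```
x_ij ~ Normal(g_i(k_j), sigma_i)        [default sigma_i = 1]
```

Since the data are control-referenced z-scores, unit noise is the
natural default; `sigma` is configurable per region. Stages carry a
uniform prior over `0..N`, the standard choice for z-score event models,
so the per-subtype marginal likelihood of a scan is the average of the
`N + 1` stage likelihoods, and the cohort likelihood is the mixture over
subtypes with fractions `f_c`. All likelihood work happens in log space
with log-sum-exp reductions; a naive double-sum oracle in the tests
confirms agreement to 1e-10.

## Preparing inputs

`fit_zscore_reference()` estimates per-region control means and SDs
(n-1 denominator) from **control baseline scans only**; follow-up
control scans and patients never touch the reference. `apply_zscore()`
then standardizes every scan. Controls are used solely for this step —
they are excluded from model fitting.

Event thresholds come from `prep_event_set()`, which pools control and
patient baseline z-scores per region and fits a two-component Gaussian
mixture (`fit_2gmm()`) by EM with a deterministic median-split
initialization, relabeled so `m1 < m2`. The mapping from mixture to
thresholds is a policy, because more than one reasonable rule exists:

* `"gmm"` (default): `z_1` is the equal-posterior decision boundary
  between the components, floored at 1.0 (below one control SD a
  "severity" threshold is not meaningful); `z_2` is the abnormal
  component mean `m2`; the ceiling is `m2 + 2 sd2`. If flooring breaks
  the ascending order the triple is repaired with 0.5-unit gaps and a
  warning — thresholds must be strictly ascending under every policy.
* `"fixed"`: `z = (2, 5)` with ceiling 10, a conventional fixed-grid
  choice for z-scored PET data. The synthetic-data generator uses this
  geometry as its ground truth, so end-to-end recovery tests run with
  the fixed policy.

When the mixture components overlap so much that the posterior boundary
is not bracketed between the means, the midpoint `(m1 + m2)/2` is used
and a warning is logged.

## Fitting

`optimize_sequence()` maximizes the weighted marginal log-likelihood of
a single sequence by greedy reinsertion: events are swept in a
seeded-random order, each is removed and re-inserted at the valid
position that maximizes the objective, and sweeps repeat until no move
improves. Ties keep the earliest position and only strict improvements
move, so the objective never decreases and termination is guaranteed.
The sweep itself is implemented in C++ (`src/sweep.cpp`); on six-event
problems the result matches exhaustive enumeration over all valid
permutations on at least 95% of seeded random datasets, and the
acceptance run reports the realized agreement rate.

`fit_em()` alternates subtype responsibilities (E) with per-subtype
sequence optimization and fraction updates (M), from `n_startpoints`
random valid initializations (default 10); the best restart wins. The
observed-data log-likelihood is non-decreasing across iterations (EM
with an ascent M-step), stopping at relative change `1e-6` or 100
iterations. A subtype whose fraction collapses below `1/(10 n)` aborts
that restart.

`hierarchical_fit()` grows the model divisively: subjects are
hard-assigned to their maximum-likelihood subtype, each subtype with at
least `2C` members is split by a 2-subtype fit on its members, and each
candidate (split sequences plus the remaining ones) is refined by EM on
the full data. Two design choices are worth recording:

* the **top two distinct** split solutions per parent are refined, not
  just the best — the extra candidates close most of the gap to
  oracle-initialized EM that we observed in recovery experiments;
* if every refined candidate falls below the previous model's
  log-likelihood, a duplicate-subtype candidate (largest subtype
  duplicated, fraction halved — which reproduces the previous
  likelihood exactly) is refined instead, so the returned training
  log-likelihood is provably non-decreasing in `C`.

Ordering uncertainty is quantified by `run_mcmc()`, a Metropolis
sampler over sequences: per iteration one subtype and one event are
drawn uniformly, the event is proposed at a uniformly-random valid
position, and the move is accepted on the total-data likelihood ratio.
Fractions stay at their EM estimates — a sequence-only sampler is
simpler and makes the acceptance rule deterministic given the seed;
samplers that also perturb fractions exist and this is a documented
divergence from them. Positional-variance matrices (rows sum to 1)
summarize the retained samples.

`cross_validate()` partitions subjects into seeded folds, fits the
divisive path on each training portion and evaluates held-out
log-likelihood with the training fractions;
`CVIC(C) = -2 * sum(held-out log-likelihood)`. The held-out likelihood
uses the EM point estimate rather than an MCMC average — a deliberate
simplification, recorded here. No automatic selection happens; the
curve is reported, and `cvic_elbow()` offers one transparent rule
(smallest `C` beyond which no gain exceeds 10% of the largest
single-step gain).

## Assignment, exclusion and deviation

`assign_scan()` computes the subtype posterior
`P(c|x) = f_c P(x|S_c) / sum f_c' P(x|S_c')`, assigns the
maximum-posterior subtype (ties to the lowest index), then the
maximum-probability stage within it (ties to the lowest stage). A scan
whose maximum posterior falls **below** the probability threshold
(default 0.5, sensitivity values 0 and 0.8) is flagged excluded but its
assignment is still recorded. Stage-0 scans keep their posterior —
which reduces to the fraction prior, since all trajectories start at
zero — and are flagged `stage_zero` so reports can treat them
separately.

`sequence_deviation()` reconstructs the "event imperfection" statistic:
each event is binarized as achieved iff `x_i >= z_ir` (closed
comparison, configurable in principle but fixed here), and the
deviation is the Hamming distance between the achieved set and the
first-`k` prefix of the assigned sequence. It is zero exactly when the
achievement vector is a prefix of the sequence.

## Longitudinal stability

`restage_followups()` assigns every scan independently with the frozen
baseline-trained model and baseline z-score reference; no information
flows between a subject's visits. `stability_report()` builds the
baseline-vs-last-visit confusion matrix over subjects with at least one
follow-up and non-excluded baseline and last scans (subjects failing
the threshold at either end are dropped and counted), unweighted
Cohen's kappa with the asymptotic standard error
`sqrt(p_o(1-p_o)/(n(1-p_e)^2))`, and the retention proportion with a
Wald interval. `annual_stage_change()` restricts to subjects retaining
their baseline subtype, computes `(stage_last - stage_first)/dt`, and
summarizes per subtype (one-sample t-test against zero) and across
subtypes (one-way ANOVA; an exactly-constant rate vector short-circuits
to `F = 0` rather than relying on a 0/0 float ratio).

Proportions are reported with Wald intervals
`p +/- 1.96 sqrt(p(1-p)/n)`, clamped to `[0,1]` and rounded to integer
percent — chosen because this convention reproduces the standard
`k/n (..%, 95% CI: ..-..%)` reporting style exactly on the reference
count triples in the regression tests. Wilson intervals were considered
and rejected only because they do not match that style.

## The synthetic cohort generator

`generate_truth()` + `simulate_cohort()` + `simulate_followups()`
define the study conditions under which the pipeline is validated:

* control z-scores are `Normal(0, 1)`; patient scans are
  `g_c(k) + Normal(0, sigma)` with `sigma = 1`, subtype drawn from the
  mixing fractions and stage uniform on `0..N`;
* raw-value mode maps z back through per-region SUVR-like references
  (`mu ~ U(1.0, 1.4)`, `s ~ U(0.08, 0.15)`) so z-scoring is exercised
  end-to-end;
* follow-ups advance the true stage by `round(rate * dt)` clamped to
  `0..N`, with per-subject rates `Normal(0.56, 0.70)` stages/year and
  one follow-up at `|Normal(1.90, 0.94)|` years (floored at 0.25) —
  stage advance is rounded because the model's stage space is discrete;
  the continuous rate is retained in the ground truth;
* an optional `mixed_frac` generates scans from the average of two
  subtypes' trajectories to exercise the poor-fit exclusion logic, and
  `switch_prob` can switch generating subtypes at follow-up to exercise
  the stability metrics (both default to 0).

What the generator does **not** emulate: site and scanner effects,
age/covariate structure, spatially correlated noise across regions,
measurement floors, attrition correlated with severity, or deviations
from piecewise-linear trajectories. Passing recovery tests therefore
demonstrates the estimator's correctness under its own generative
assumptions, not robustness to the full messiness of real PET data.

## Scoring recovery

`match_subtypes()` finds the label bijection maximizing agreement
(exhaustive over permutations, `C <= 8`); `sequence_recovery()` is
Kendall's tau between position maps. Two scoring choices are
deliberate: the headline accuracy is computed over scans that pass the
poor-fit exclusion — stage-0 scans carry no subtype signal at all and
sit at the posterior prior, so including them measures the stage
distribution, not the estimator (the all-scan accuracy is also
reported); and fraction errors compare against the cohort's *realized*
subtype proportions, because the generating fractions are only the
expectation of a multinomial draw whose own SD is ~0.027 at `n = 300`.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: the full-scale
recovery study at `B = 10`, `R = 2`, `C = 3`, `n = 300` patients, 85
controls, `sigma = 1`; 5-fold cross-validation over `C = 1..4` with 6
EM start points per fold (10 for the main fit); 2000 MCMC iterations;
100 seeded six-event datasets for the enumeration check. EM tolerance
is `1e-6` relative with a 100-iteration cap; strict-improvement
epsilon in the sweep is `1e-12`; ties break to the first candidate in
canonical enumeration order everywhere. Degenerate inputs (constant
GMM samples, zero-variance controls, empty folds, all-zero weights)
either error with a pointed message or return flagged results, as the
reference pages document.

## Known limitations

Sequences are point estimates refined by local search; for large `N`
and heavily overlapping subtypes the greedy sweep can settle in local
optima (restarts and the dual-split refinement mitigate but do not
eliminate this). The stage space is discrete, so stage-change rates
inherit rounding noise of order `1/dt`. The sampler explores orderings
only, so positional-variance matrices understate joint uncertainty in
(sequence, fractions). Covariate adjustment (w-scores) is not
implemented; the reference is age-matched controls by construction of
the input cohort.
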