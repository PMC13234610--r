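# sustainz

Subtype and Stage Inference (SuStaIn, linear z-score variant) for
regional biomarker data in R.

## What problem this solves

Neurodegenerative diseases are heterogeneous: different patients
accumulate pathology in different spatial patterns, and cross-sectional
cohorts mix people at every point of those trajectories. Given one scan
per subject — say average tau-PET SUVR in 10 unilateral lobar regions —
sustainz jointly infers:

* **subtypes**: groups of subjects sharing an ordering in which regions
  cross severity thresholds, and
* **stages**: how far along its subtype's ordering each subject is,

from cross-sectional data alone, and then evaluates whether those
assignments hold up longitudinally when follow-up scans are restaged
with the frozen baseline model. It is aimed at neuroimaging and
biomarker researchers who have region-level quantification (not images)
and want a tested, scriptable implementation of the full
subtype-and-stage workflow: z-scoring, data-driven thresholds, model
fitting and selection, per-scan assignment, and longitudinal stability
metrics.

## The model

Regional values are z-scored against controls. An **event** is region
*i* crossing threshold *z<sub>ir</sub>* (z-score units); with *B*
regions and *R* thresholds each, the model has *N = B·R* events
(default 10 × 2 = 20). Subtype *c* is a valid permutation
*S<sub>c</sub>* of the events (lower thresholds first within each
region). The expected value of region *i* at stage *k* is the
piecewise-linear function through

> (0, 0), (p(i,1), z<sub>i1</sub>), …, (p(i,R), z<sub>iR</sub>), (N, z<sub>max,i</sub>)

with p(i,r) the position of event (i,r) in *S<sub>c</sub>*. Scans are
trajectory plus unit Gaussian noise; stages carry a uniform prior and
are marginalized, so the data likelihood is a mixture over subtypes
with fractions *f<sub>c</sub>*:

> P(x) = Σ<sub>c</sub> f<sub>c</sub> · (N+1)<sup>−1</sup> Σ<sub>k=0..N</sub> Π<sub>i</sub> 𝒩(x<sub>i</sub>; g<sub>i</sub><sup>c</sup>(k), σ<sub>i</sub>)

Sequences are optimized by greedy event reinsertion (C++ inner loop)
inside EM, subtypes are grown by divisive splitting, ordering
uncertainty comes from a Metropolis sampler, and the number of subtypes
is compared by cross-validation information criteria (CVIC). See the
methods vignette (`vignettes/subtype-staging.Rmd`) for the full
account, including every numerical policy.

## Worked example

A complete synthetic study: simulate a 3-subtype cohort with known
ground truth, fit, assign, and restage follow-ups with the frozen
model.

```r
library(sustainz)

# simulate a 3-subtype cohort with known ground truth
truth <- generate_truth(B = 10, R = 2, C = 3, seed = 42)
sim <- simulate_cohort(truth, n_patients = 300, n_controls = 85,
                       sigma = 1, seed = 142)

# z-score against the controls, fix the 20-event geometry
ref <- fit_zscore_reference(sim$table)
Z <- apply_zscore(sim$table, ref)[sim$table$group == "patient", ]
es <- prep_event_set(Z, policy = "fixed")$event_set

# fit 1..3 subtypes by EM with divisive splitting
models <- hierarchical_fit(Z, 3, es, run_config(seed = 42))
models[[3]]
#> Linear z-score subtype model: 3 subtype(s), 20 events
#>   subtype 1: fraction 0.355
#>   subtype 2: fraction 0.345
#>   subtype 3: fraction 0.300
#>   log-likelihood: -5599.067

# assign every scan, score against the truth
asg <- assign_cohort(Z, models[[3]], prob_threshold = 0.5)
rec <- recovery_metrics(models[[3]], asg, sim$truth)
round(c(accuracy = rec$accuracy, tau = rec$kendall_tau), 3)
#> accuracy     tau1     tau2     tau3
#>    0.936    0.958    0.968    0.926

# follow-up visits at 0.56 +/- 0.70 stages/year, restaged frozen
lon <- simulate_followups(sim, seed = 242)
fu <- restage_followups(lon$table, models[[3]], ref)
stability_report(fu, n_subtypes = 3)
#> Subtype stability over 276 subjects
#>         last
#> baseline S1 S2 S3
#>       S1 99  2  3
#>       S2  0 90  5
#>       S3  4  3 70
#> retention: 93.8% (95% CI 91-97%)
#> Cohen's kappa: 0.91 (95% CI 0.86-0.95)
round(annual_stage_change(fu)$overall_mean, 2)
#> [1] 0.55
```

Reading the numbers: the fitted mixing fractions (0.355/0.345/0.300)
recover the uniform generating fractions; subtype assignment agrees
with the ground truth for 93.6% of confidently-assigned scans and the
fitted event orderings correlate with the true ones at Kendall τ ≥
0.93. When follow-up scans are assigned independently with the frozen
baseline model, 93.8% of subjects keep their subtype (κ = 0.91) and the
estimated progression rate of 0.55 stages/year matches the generating
rate of 0.56.

A thin command-line wrapper over the same functions ships in
`inst/cli/sustainz.R` (`simulate`, `prep`, `fit`, `assign`, `restage`,
`evaluate`, `report` subcommands with `--seed`/`--out-dir` flags).

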