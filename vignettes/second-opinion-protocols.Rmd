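---
title: "AI-triggered second opinions: models, calibration and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AI-triggered second opinions: models, calibration and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(secondopinion)
```

## The problem and the protocol

When a clinician plans treatment for a tooth with an advanced (pulpal-quarter)
carious lesion, the key binary judgement is whether excavation will expose the
pulp. Individual readers are only moderately accurate at this, and AI
classifiers trained on preoperative radiographs can outperform them — yet
clinicians distrust visible machine advice, and a fully automated system
carries the risk of acting on its errors.

The protocol studied here sidesteps both problems by keeping the AI hidden.
For each case the first reader records a decision. In the background the AI
prediction is compared with it: on agreement the reader's decision is final;
on disagreement a second reader, drawn uniformly at random from the rest of
the panel, is consulted and *their* recorded answer becomes final. The AI
never contributes a final answer — it only decides *when* a human second
opinion is requested. The benchmark alternative is three-reader majority
voting, in which the first reader is always supplemented by two other readers
drawn without replacement.

`secondopinion` implements both protocols as Monte-Carlo engines over a
recorded response matrix (cases × readers plus one AI vector), together with
the scoring, calibration, inference and validation machinery needed to study
them end to end.

## The rater model

Simulated readers and the synthetic AI are parameterised by a
(sensitivity, specificity) pair: the probability of calling a true exposure
(class 1) and of clearing a true non-exposure (class 0). Responses are drawn
independently across cases and readers given the true outcome. This
*conditional independence* is the default generative model; an optional shared
per-case difficulty effect (`difficulty_sd` in `generate_rater_responses()`)
adds a normal logit shift common to all readers, which induces the positive
between-reader error correlation that real reading panels display. It
defaults off, so the default synthetic data represent the most favourable
regime for arbitration protocols (see "What the generator does not emulate").

The headline score is the macro-averaged F1: the harmonic mean of precision
and recall computed once with exposure as the positive class and once with
non-exposure as the positive class, averaged with equal weight. Degenerate
denominators are scored as 0 (a precision or recall with no eligible cases,
or a class F1 with precision + recall = 0), which keeps every simulated trial
scoreable; results are insensitive to this convention away from pathological
inputs.

## The synthetic study

Because the original response matrix is not public, the generator reproduces
the study's *design*:

* **Cohort**: 290 cases in two randomised arms — 142 stepwise-excavation (SW)
  and 148 non-selective/complete-excavation (NSE) cases — with exactly 24 and
  42 pulp exposures respectively. Outcome labels are assigned by exact count
  per arm rather than Bernoulli draws, reproducing the study's fixed margins
  for every seed. (The study reports the exposure counts inconsistently,
  24/42 in its cohort table and 25/43 in its running text; the tabulated
  counts are the default and both are overridable.)
* **Covariates**: age from a shifted, discretised gamma distribution
  (median ≈ 29 years, truncated to 18–89), preoperative-pain prevalence
  103/290, tooth classes 161/118/8/3 (molar/premolar/incisor/canine). These
  match the published cohort composition; the skewed-gamma shape is our
  choice, as only the median is published.
* **Panel**: 25 readers whose pool-mean macro-F1 is calibrated to the
  published 0.586, heterogeneous via per-reader uniform jitter (half-width
  0.08) around a common operating point.
* **AI**: a single profile calibrated to the published macro-F1 of 0.71.

`calibrate_pool()` finds the common operating point by a coarse grid scan
(step 0.005) of the analytic plug-in macro-F1 at the cohort's prevalence,
followed by root refinement; the plug-in score is monotone in the operating
point, so the root is unique. Targets outside the achievable range at the
given prevalence raise a calibration error with the range in the message. The
achieved *expected* pool mean is within 0.02 of the target by construction;
one realised 290-case draw adds sampling noise of roughly ±0.01 to the
panel mean (±0.04 for a single reader's F1).

## Reproducibility and seeding

Every generator and engine takes an integer seed and is bit-reproducible
given it. `run_simulation()` derives one sub-stream per (reader, protocol)
from the master seed by counter-based mixing, so adding readers to a run, or
running the majority-vote protocol alongside, never perturbs an existing
reader's trial stream. The AI-accuracy sweep reuses the same master seed for
every target (common random numbers), which makes the sweep monotone in the
AI's balanced accuracy up to Monte-Carlo noise rather than only in
expectation.

## Validation oracles

Two independent oracles check the engine:

* `expected_second_opinion_rates()` gives the closed-form probability that
  the final response is 1 in each true class under conditional independence;
  `plugin_macro_f1()` turns such rates into the large-n limit of the mean
  Monte-Carlo macro-F1. (It is *not* the finite-n expectation — macro-F1 is a
  nonlinear function of the confusion counts — so agreement is asserted at
  large case counts only.) Because the second reader enters the rates
  linearly, the arithmetic pool mean is exactly equivalent to averaging
  rates reader-by-reader; for majority voting, where pair products appear,
  `expected_majority_rate_pool()` implements the exact over-pairs mixture.
* `enumerate_second_opinion()` enumerates all (|D|−1)^k equiprobable
  assignments of second readers to the k disagreement cases of a tiny
  instance and returns the exact outcome distribution and mean macro-F1.

The test suite asserts engine–oracle agreement (within three standard errors
of the Monte-Carlo mean) on batteries of random tiny instances, and agreement
of the analytic rates with a direct one-million-case simulation of the
protocol rule.

## Design choices

* **Second reader per case, not per trial.** The protocol draws the second
  reader independently for each disagreement case within a trial, matching
  the per-case description of the experiment; a `fixed_b` flag provides the
  one-consultant-per-trial variant for study.
* **Majority voters without replacement, excluding the primary.** Sampling
  with replacement could duplicate a voter and silently produce two-reader
  decisions.
* **Confidence intervals** are t-based with n−1 degrees of freedom on the
  per-reader (or per-trial) sample. Applied to the packaged per-participant
  table this reconstructs the published interval for the panel mean
  (0.567–0.605), which is how the construction was validated — the study
  does not state its CI method.
* **Significance testing** operates on per-reader mean F1 values (n = 25
  pairs, paired by participant), not on per-trial values, matching how the
  published table is organised. Tests are two-sided at α = 0.05 with
  Bonferroni multiplier equal to the number of pairwise comparisons.
* **Agreement stratification** uses a strict threshold (agreement > 0.70 for
  the high-agreement group), following the "more than 70%" rule.
* **Group comparisons** use Student's two-sample t for age and two-proportion
  z-tests (chi-squared without continuity correction) for shares; the study
  names only a t-test, so the proportion-test choice is ours.
* **Switch-accounting denominators.** The published "altered", "correctly
  switched" and "incorrectly switched" percentages do not state their
  denominator. `switch_analysis()` defaults to consulted cases (under which
  correct + incorrect ≤ altered holds) and offers cases-initially-called-
  positive as the alternative; under the alternative the fractions can exceed
  one when consultations outnumber positive calls.
* **Reading load.** 25 readers × 290 cases would give 7250 readings, yet the
  published agreement/disagreement subset sizes sum to 3624; the per-reader
  case load is not recoverable. Simulations therefore run over all cases by
  default, with a `cases` argument to restrict the universe when emulating
  partial reading loads.

## What the generator does not emulate

Passing the directional checks on synthetic data shows that the protocols,
scoring and inference behave correctly — not that the synthetic effect sizes
equal the study's. The main gap is error correlation: under conditional
independence a consulted second reader errs independently of the first, which
makes second opinions (and a perfect AI trigger) *more* valuable than in real
panels, where readers tend to fail on the same difficult cases. Consequently
the synthetic uplift from 0.586-calibrated panels exceeds the published
0.586 → 0.645, the synthetic perfect-AI ceiling exceeds the published 0.729,
and fewer cases reach high panel–AI agreement than the published 171/290.
Enabling `difficulty_sd` moves all of these toward the published values at
the cost of an extra unidentified parameter; the package's standard
conditions keep it off and assert directions, orderings and significance
rather than magnitudes. Radiograph content, reader fatigue and the two
case-presentation formats are not modelled at all.

## Problem sizes used in the packaged checks

The packaged tests validate the engine with 10^5-trial runs on ≤ 6-case
instances, one-million-case rate simulations, 1000-trial simulations of the
full 25-reader × 290-case synthetic study, and 10^4-replication coverage
checks of the t-interval; the whole suite runs in well under a minute. These
sizes were chosen so that the three-standard-error agreement bands are a few
multiples of 10^-3 — tight enough to catch systematic protocol errors.

## A worked run

```{r, eval = FALSE}
cohort <- generate_cohort(142, 148, 24, 42, seed = 1)
pool <- calibrate_pool(0.586, 25, cohort, seed = 2)
ai <- calibrate_pool(0.71, 1, cohort, seed = 3)[[1]]
m <- generate_rater_responses(cohort, pool, seed = 4)
m <- set_ai_predictions(m, generate_ai_predictions(cohort, ai, seed = 5))

so <- run_simulation(m, "second_opinion", n_trials = 1000, seed = 6)
summarize_by_rater(so)

baseline <- vapply(raters(m), function(r) macro_f1(m$responses[, r], m$truth),
                   numeric(1))
so_mean <- vapply(split(so$f1, so$rater_id), mean, numeric(1))[raters(m)]
paired_t_bonferroni(list(baseline = unname(baseline),
                         second_opinion = unname(so_mean)))
pearson(unname(baseline), unname(so_mean - baseline))
```
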