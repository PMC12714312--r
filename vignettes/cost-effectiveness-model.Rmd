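---
title: "A decision-tree + Markov model of toxicity-risk-guided radiation therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree + Markov model of toxicity-risk-guided radiation therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostoxcea)
```

## The question the model answers

Men treated curatively for prostate cancer receive stereotactic body
radiation therapy (SBRT), conventionally fractionated radiotherapy (CFRT) or
a prostatectomy. All three can cause late genitourinary (GU) toxicity —
urinary frequency, urgency, incontinence appearing more than 90 days after
treatment — which is long-lasting, costly to manage, and reduces quality of
life. A germline microRNA assay (PROSTOX *ultra*) classifies a patient as
high or low risk for late GU toxicity from SBRT before the modality is
chosen. This package implements a payer-perspective health-economic model of
using that assay to steer treatment, against standard of care (SOC) in which
modality choice ignores individual toxicity risk: a 5-year cost-impact
comparison and a lifetime cost-effectiveness analysis in QALYs.

## Model structure

**Decision tree.** Tested patients split into a high-risk fraction
(`p_high = 0.1872`) and its complement. Each stratum has a modality mix;
combined with the assay arm's strata and the SOC literature mix this yields
nine *tracks* T1–T9 (risk stratum x modality x arm). Two behavioural
assumptions shape the assay arm:

* `radiation_adherence` (default 1): every tested radiation patient follows
  the recommended modality, so no high-risk patient receives SBRT (T1 = 0)
  and no low-risk patient receives CFRT (T5 = 0). The model generalises to
  partial adherence — a non-adherent patient stays on the modality SOC would
  have favoured — because the sensitivity analysis varies this knob.
* `surgery_diversion` (default 0.80): among low-risk tested patients the
  prostatectomy share falls by 80% relative to SOC (49.35% to 9.87%);
  diverted patients use SBRT, the modality they were just cleared for.

```{r tree}
compute_track_weights(model_parameters(), "PROSTOX")
```

**Markov cohort model.** Each track feeds a three-state annual-cycle cohort
model (no-toxicity, toxicity, death). Everyone enters in no-toxicity at age
67, the average age at diagnosis. Each cycle applies background mortality
first (the same age-specific probability in both living states — the model
deliberately carries no toxicity effect on survival, so the arms never
differ in life-years), then toxicity development among surviving
no-toxicity patients. Toxicity is absorbing among the living: once late
toxicity develops, its management cost ($5,774.58/year vs $2,914.90) and
utility decrement (0.70 vs 0.90) persist until death.

Track-specific hazards: radiation tracks keep their cycle-1 toxicity
probability through cycle 4, after which an annual development taper applies
geometrically (`p1 * 0.7013^(t-4)`). Prostatectomy tracks admit toxicity
only in cycle 1 — surgical GU complications are fully manifest within the
first year. Within-cycle ordering (death before toxicity) is a
competing-risk convention the source material leaves open; it makes the
one-cycle hand example well defined and is cross-checked against a
patient-level microsimulation oracle in the tests.

**Numerical choices.** No half-cycle correction: costs and QALYs accrue on
end-of-cycle state membership, consistent with the magnitude of the
published per-track values. Treatment costs accrue once at T0 and are never
discounted; the assay cost ($4,000 list price) accrues once at T0 in the
tested arm. The horizon runs to a terminal age of 110 with a forced final
death probability of 1, so the cohort is always fully absorbed.

**Discounting.** The source material is internally contradictory: its
methods prose says discounting was not applied, while its input table lists
3% discount rates for costs and utilities and its lifetime QALY magnitudes
(≈11.6 against ≈16.5 expected life-years) are only consistent with
discounting applied. The package defaults to `discounting_enabled = TRUE`
at 3% and exposes the flag rather than resolving the contradiction.

## Background mortality: a calibrated synthetic life table

The published analysis states no mortality source, so its per-track
lifetime values cannot be reproduced exactly. The package bundles a
*synthetic* life table generated from a Gompertz–Makeham hazard
$h(x) = \lambda + a e^{bx}$ with $\lambda = 0$ and $b = 0.095$ fixed, and
the scale $a$ found by deterministic root-finding so that undiscounted life
expectancy at age 67 equals 16.5 years — a round calibration target
approximating US male period life expectancy at that age. One free
parameter makes the calibration a well-posed monotone root-finding problem
while keeping realistic old-age hazard growth.

```{r lifetable}
lt <- default_life_table()
life_expectancy(lt)
```

What this stand-in does *not* emulate: cause-specific (prostate-cancer)
mortality, cohort trends, or any real tabulated schedule. Consequently the
full-pipeline per-track lifetime QALYs approximate the published scale to
within about 7% rather than matching it, and the lifetime incremental
results are validated as a *dominance property* (lower cost, higher QALYs)
rather than as point reproductions. Users with a real life table can pass
it via `load_life_table()`.

## Two aggregation paths

The published per-track outcome table has a structural quirk: its annual
clinical cost cells are per-patient costs *already multiplied by the track
weight*, while its T0 and lifetime columns are per-patient. The published
arm totals are then sum-products of those cells with the weights — a
double-weighting. The package exposes both computations separately:

* `aggregate_printed_table()` — the worked-example path, which applies the
  published arithmetic to the printed cells verbatim and reproduces the
  published totals to the dollar ($1,109 year-5 SOC cost; $47,683 vs
  $67,298 five-year totals; $19,615 savings; 11.63 lifetime QALYs).
* `evaluate_arms()` — the genuine pipeline, which computes per-patient
  streams from the Markov traces. Its 5-year savings (≈$22,200 under the
  calibrated life table) feed the sensitivity analyses.

The published lifetime arm costs ($82,337 / $107,114) are not recoverable
from the printed per-track lifetime values under any weighting we examined
(weighted sums disagree by ≈0.5%) and are therefore not bound as targets.

## Sensitivity analyses

**One-way DSA.** Each parameter is varied alone by ±20%, with probabilities
and utilities clipped to [0, 1] (warned, as the 0.90 utility exceeds 1 at
+20%). Rows are varied *independently, spreadsheet-style*: perturbing the
SOC prostatectomy utilization leaves the other utilization rows at their
printed values (the arm mix is used unnormalized) and does not propagate
into the tested strata, whose prostatectomy shares are their own input
rows. This independence is what reproduces the published tornado ordering —
the SOC prostatectomy share first, the prostatectomy cost close behind;
under re-normalized or propagated semantics the cost row would dominate
instead, contradicting the published ranking. When a custom outcome
evaluator is supplied, SOC shares fall back to renormalization so the
evaluator always sees a valid parameter set.

**PSA.** 10,000 iterations; every varied parameter is drawn independently
from a moment-matched distribution — gamma for costs
(`shape = (m/se)^2`, `scale = se^2/m`), beta for probabilities, shares,
utilities and the taper — with a 10% standard error wherever no error datum
exists. The adherence knob (mean 1, no feasible beta variance) and the
discount rates are held fixed; the life table is held at the base case.
Draws are parameter-major from one seeded generator, so a seed reproduces
the full analysis bit-for-bit.

A known consequence of drawing the two utilities independently at 10% SE:
in roughly 5–6% of iterations the drawn no-toxicity utility falls below the
toxicity utility, flipping the sign of the QALY difference and placing the
iteration in the southwest quadrant. The southeast (dominant) share is
therefore ≈94–95% rather than ≈100%; the acceptability curve is unaffected
(≥0.99 across willingness-to-pay 0–$150,000) because incremental costs are
negative in essentially every iteration. Order-preserving alternatives
(drawing the disutility, or correlated draws) would remove these
inversions, but the package keeps the stated independent-draw design.

```{r psa}
psa <- run_psa(model_parameters(), n = 1000, seed = 7)
psa
head(ceac(psa, seq(0, 150000, 50000)))
```

**Price sweep.** `price_threshold_sweep()` re-runs the pipeline at each
candidate assay price; because the price enters once at T0, savings are
affine in it with slope −1 (an emergent property, verified in the tests,
not a shortcut), and remain positive beyond a $10,000 price.

## Problem sizes and testing

The test suite exercises the cohort engine against three independent
oracles: a one-cycle hand recursion, the closed form $1-(1-p)^t$ for
constant hazard without mortality, and a 100,000-patient microsimulation
compared within three binomial standard errors per cycle. Distribution
calibration is checked on 100,000 draws against the stated mean/SE;
property tests sweep randomized parameter sets (occupancy conservation,
weight normalization, monotonicity of the diversion knob). The PSA runs at
its full 10,000 iterations in the acceptance checks; unit tests use smaller
draws (40–2,000 iterations) chosen to keep the default suite under a
minute while leaving every code path exercised.

## Limitations

* Cohort-average model: no patient-level heterogeneity beyond the risk
  strata, no toxicity grades, no recovery from late toxicity, no
  cancer-progression or cancer-specific mortality states.
* The mortality schedule is synthetic and calibrated, so lifetime-scale
  outputs are approximations; short-horizon (5-year) results are driven by
  the printed inputs and are insensitive to it.
* PSA draws are independent; no correlation structure or expected value of
  perfect information is computed.
* Costs are taken as already inflated 2024 USD; there is no
  inflation/deflation engine.
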