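---
title: "Model and methods behind btcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind btcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`btcea` implements a probabilistic Markov cohort model comparing standard
therapy, bronchial thermoplasty (BT), and omalizumab in adults with
moderate-to-severe allergic asthma that remains uncontrolled on high-dose
inhaled corticosteroids. This vignette records the model, the assumptions,
and the design decisions taken where the published description of this class
of model leaves room, so that a maintainer can tell deliberate choices from
accidents.

## States, cycles, and transitions

Five states: exacerbation-free; exacerbations requiring oral
corticosteroids (OCS), an emergency-department (ED) visit, or
hospitalization; and death (absorbing). The cycle length is one week — short
enough that an exacerbation can be represented as a *state* lasting exactly
one cycle rather than as an instantaneous event, which is what lets unit
costs and state utilities attach to exacerbations cleanly. Occupants of an
exacerbation state return to exacerbation-free after their week unless they
die.

Annual exacerbation rates under standard therapy, λ_s in
events/person-year, convert to weekly scale via `1 − exp(−λ_s/52)`.
Treatment acts multiplicatively on the rate (relative rates RR_s). Within a
cycle the three exacerbation causes and background death compete. The
published marginal formula says nothing about joint allocation, so we use
the standard multistate discretization: sum the weekly cause-specific
hazards into H, compute the total event probability `1 − exp(−H)`, and split
it across causes in proportion to their hazards. This is exactly the
constant-hazard cause-specific cumulative incidence
∫₀¹ h_s·exp(−H·t) dt, which the test suite verifies against an independent
numerical integration. The residual mass stays exacerbation-free.

Three mortality channels:

* background mortality from an age-indexed life table, converted to weekly
  probabilities as `1 − (1 − q_x)^(1/52)`, with age advancing as
  `baseline + week/52` and the whole-year bracket selected by `floor()`;
* the 30-day case-fatality risk after an asthma hospitalization (0.02),
  applied in full on the single cycle spent hospitalized — the model has no
  30-day construct, and charging it once per hospitalization preserves the
  per-event risk;
* no excess mortality from OCS- or ED-level exacerbations, because the
  input set specifies a death risk only for hospitalization.

## Accrual and discounting

Per cycle, each alive state accrues its annual utility divided by 52, and
drug costs accrue per alive person-week (treatment is assumed to continue
through exacerbation weeks — stopping therapy during a one-week flare would
be clinically odd and the source description is silent). Each incident entry
into an exacerbation state adds that event's unit cost. The BT upfront cost
($14,900) is charged once at week 0, undiscounted. Both costs and QALYs are
discounted at 3%/year with per-week compounding, `1.03^(−week/52)`; at a
weekly cycle length the difference from annual-step discounting or from a
half-cycle correction is well below the rounding of the published results,
so no half-cycle correction is applied.

Strategies are modelled as add-ons to standard therapy: the $2,610/year
standard drug cost continues under BT and omalizumab; omalizumab adds
$22,700/year; BT adds only its one-time cost. The 8% post-procedure
hospitalization risk and 10% re-scheduling risk of BT are *cost-only*
components already folded into the $14,900 (0.08×$9,900 and 0.1×$66); they
generate no modelled events or QALY decrements.

## The input set and its distributions

`default_parameters()` rebuilds the published parameter table in code:
rates, relative rates, costs (2013 US$), utilities, and the hospitalization
death risk, each with a point estimate and a sampling distribution
(log-normal for rates and RRs, gamma for unit costs, beta for utilities and
the death risk, normal for the utility differences; treatment costs are
fixed and vary only in the deterministic analyses).

Two calibration notes:

* **Log-normal spreads.** The published table's second log-normal parameter
  reproduces the published 95% credible intervals only when read as a
  log-scale *SD* for the baseline rates but as a log-scale *variance* for
  the relative rates (e.g. BT OCS RR 0.48 with CrI 0.26–0.88 implies
  sdlog ≈ 0.30 = √0.09). The bundled fixture therefore stores
  `sdlog = y` for rates and `sdlog = √y` for RRs, which reproduces every
  printed interval to two decimals. This choice is load-bearing for the
  probabilistic analysis and is asserted in the tests.
* **Death-risk beta.** Beta(1.10, 43.22) has mean 0.0248 but median 0.018;
  the published point estimate 0.02 tracks the median of this strongly
  right-skewed distribution, not its mean. The audit test checks the
  analytic mean against the point estimate for every other entry and the
  median for this one.

In a PSA draw, exacerbation-state utilities are clamped at the drawn
exacerbation-free utility of the same strategy: the utility distributions
are wide enough that a raw draw can make an exacerbation week *better* than
an exacerbation-free week, which would flip the sign of the treatment
benefit for no clinical reason.

The base-case omalizumab utility difference is 0.04 (its sampling
distribution N(0.04, 0.004)); the 0.03–0.05 range appears only in the
one-way sensitivity analysis, mirroring how the alternative values are
presented alongside the main table.

## The life table

The published model cites US life tables without printing them, and over a
5-year horizon from age 40 background mortality contributes on the order of
1% of deaths-adjusted outcomes. `default_life_table()` is therefore an
explicit, documented *synthetic stand-in*: 0.0008/year at age 18 rising
linearly to 0.002 at 40, flat 0.002 across ages 40–44 (the bracket the
base-case cohort traverses), then Gompertz-like doubling every 8 years
anchored at age 42, and q = 1 at the terminal age 100. It approximates 2013
US adult period rates to the precision that matters here and is swappable
through every `life_table` argument.

## Treatment-effect waning

Long horizons need an assumption about BT's effect beyond its evidence
base. With `waning_exponential(onset, half_life)`, the log relative rate
decays geometrically toward zero strictly after the onset week:
`log RR_t = log(RR) · 2^(−(t−onset)/half_life)`, so RR_t → 1 (no effect).
`half_life → 0` removes the effect immediately after onset;
`half_life → ∞` recovers the constant-effect model; both limits are tested.
The published description names an "exponentially declining effect after the
fifth year" without a rate, so the half-life default is one year (52 weeks)
— a deliberately conservative choice exposed as configuration, and the
reason the lifetime-horizon ICER is treated as an order-of-magnitude check
rather than a target. Waning applies to the BT arm by default
(configurable), as omalizumab is dosed continuously.

## Probabilistic analysis

`run_psa()` draws all uncertain parameters independently from their marginal
distributions (the input table specifies no correlations), one joint draw
per iteration shared across the three strategies. Sharing the draw is what
makes the cost-effectiveness plane clouds and the acceptability curves
meaningful — between-strategy increments are computed within iterations.
The cohort engine is vectorized over draws, so the full 10,000-iteration
analysis takes seconds.

Acceptability curves count, at each willingness-to-pay, the fraction of
iterations in which a strategy has the strictly largest net monetary
benefit, splitting exact ties equally (a measure-zero event under continuous
sampling, but the deterministic rule keeps degenerate test cases
well-defined); probabilities sum to one across strategies by construction.
EVPI is per individual, `E[max_s NMB_s] − max_s E[NMB_s]`, with no
population scaling. Credible intervals are empirical 2.5/97.5 percentiles
with linear interpolation (R's default quantile type).

### Where the model's uncertainty differs from the published one

Running the shipped input set exactly as printed, the base-case costs,
QALYs, exacerbation counts, all pairwise ICERs, the cost sweep and the
threshold costs land within a few percent of the published values, and the
acceptability probability for BT at $100,000/QALY (~64%) is within Monte
Carlo distance of the published 67%. The *level* of decision uncertainty is
larger, however: we obtain EVPI ≈ $390 and ≈ $2,300 per individual at
$50,000 and $100,000/QALY, versus the published $155 and $1,530, and
P(BT optimal) ≈ 16% versus 9% at $50,000.

A decomposition (reproducible by fixing single distributions and re-running
`run_psa()`) shows the BT exacerbation-free utility difference,
N(0.03, 0.02), carries essentially *all* of this: fixing it at 0.03
collapses EVPI at $100,000/QALY from ~$2,300 to ~$2. The published
uncertainty summaries behave as if that parameter's SD were roughly 25%
smaller than printed — plausibly an artefact of the unprinted
questionnaire-to-utility mapping step used upstream. We keep the printed
distribution rather than calibrating it to the published curves; users
comparing against the published EVPI should bear this sensitivity in mind.

## Deterministic analyses

One-way scenarios re-run the point-estimate model at a low and a high value
per parameter: ±25% for costs and baseline rates (the published figure does
not tabulate its exact ranges), the 95% CrI bounds for relative rates, and
the published alternative ranges for the utility differences (0–0.06 for
BT, 0.03–0.05 for omalizumab). The threshold BT cost inverts the
cost-to-ICER map by bisection to a $100/QALY tolerance on the ICER — the
map is affine in the cost, so bisection is guaranteed to converge, and
dominance at a bracket end is mapped to a signed infinity to keep the
bracket valid. ICERs are reported only in the northeast/southwest quadrants;
otherwise the comparison is labelled dominant/dominated, and strategies with
equal cost order by QALYs.

Displayed money follows the published convention — model cost outputs to the
nearest $1,000, ICERs to the nearest $100 below $1M and three significant
figures above — applied strictly at the report layer; stored CSV/JSON keep
full precision.

## Meta-analysis module

The RR inputs descend from pooled trial evidence, so the package ships the
poolers: inverse-variance fixed-effect, DerSimonian–Laird random-effects
(moment estimator of τ², truncated at zero, then 1/(se²+τ²) weights), and
pooling with an *externally borrowed* τ² — the published device for
constructing BT's intervals when only a few heterogeneous trials exist.
Because the unrounded per-trial effects behind the published pools are not
printed, no invented "real" trial table is shipped: the pooled results enter
the model through the parameter fixture, and the poolers are exercised on
synthetic trial sets with known truth (`simulate_trial_set()`: true effects
~ Normal(μ, τ²), observed effects ~ Normal(effect, se²)). The DL
implementation is cross-checked against `metafor::rma(method = "DL")` in the
tests. For the borrowed-τ² pooler both variants are exposed — re-weighting
the point estimate with the external τ² (default) or keeping the
fixed-effect point and widening only the interval — since the published
account does not say which was used.

## What the synthetic data do and do not establish

The bundled fixtures (parameter table, life table, synthetic trial sets) are
deterministic functions of code and seeds; nothing is downloaded. Passing
tests therefore demonstrate that the *model machinery* reproduces the
published analysis from the published inputs — they cannot validate the
inputs themselves (trial efficacy, costing, utility mapping), nor how the
synthetic life table compares with any specific national table, nor the
behaviour of BT's effect beyond its 5-year evidence base.

Problem sizes used in the checks are chosen to make Monte Carlo error small
relative to the tolerances: 10,000 PSA iterations (matching the published
analysis), 200,000 individuals for the microsimulation-versus-cohort
agreement checks (three draws, three-SE criterion), and 50-trial synthetic
sets for τ² recovery.

## Known limitations

* Single-cohort entry age (40); no age/sex heterogeneity.
* Exacerbation states last one week by construction; multi-week
  hospitalizations are not represented beyond their unit cost and utility.
* No correlation between input parameters; no EVPPI.
* The published uncertainty summaries are not fully recoverable from the
  printed distributions (see the decomposition above).
* The lifetime ICER depends on an unprinted waning rate and should be read
  as order-of-magnitude.
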