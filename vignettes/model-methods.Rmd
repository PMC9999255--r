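---
title: "A Markov cohort model for diabetic retinopathy telemedicine screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for diabetic retinopathy telemedicine screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retscreen)
```

## The question the model answers

Community telemedicine screening for diabetic retinopathy (DR) photographs
the fundus at a local health centre and sends the image away for grading.
The grading step can be done by ophthalmologists reading images remotely
("manual grading") or by a deep-learning classifier ("AI-assisted").  The AI
reads cheaper and returns results immediately, but it misses a fifth of
sight-threatening disease (sensitivity about 80%) where expert double
reading is taken as the diagnostic reference.  In a setting with low labour
costs the money saved by replacing graders is small, so whether the switch
is worthwhile is a genuine economic question.  `retscreen` answers it with a
decision-analytic Markov cohort model: lifetime discounted costs,
quality-adjusted life years (QALYs) and years without blindness for each
grading strategy, their incremental ratios, and deterministic plus
probabilistic sensitivity analyses.

## Model structure

A closed cohort of people with diabetes enters at age 65 and is followed for
30 one-year cycles through eight states:

* `no_dr` — diabetic, free of retinopathy (utility 0.87, not 1.0, because
  everyone in the cohort has diabetes);
* `non_stdr` — non-sight-threatening retinopathy (utility 0.79);
* `stdr_undetected` / `stdr_treated` — sight-threatening retinopathy
  (severe non-proliferative or proliferative), before and after detection;
* `dme_undetected` / `dme_treated` — diabetic macular oedema, a parallel
  severe branch; all four severe states share utility 0.70;
* `blind` (utility 0.55) and `dead` (utility 0).

Severity can only increase — there is no regression to a milder state, even
with treatment; treatment multiplies the annual progression-to-blindness
probability by a factor below one (default 0.43).  Death is reached from
every state: a background age-specific probability is adjusted on the odds
scale by a state-specific odds ratio, `q = OR·o/(1 + OR·o)` with
`o = p/(1 − p)`.  The residual row mass stays in the current state.

Within each annual cycle the order of events is

1. **screening** — every alive, non-blind resident attends (people already
   diagnosed are re-screened by the programme); undetected severe disease
   moves to the treated state with probability
   `sensitivity × compliance`; screen-negative severe disease and
   detected-but-noncompliant cases stay undetected and are re-screened next
   year; false-positive referrals arise from the two mild states at rate
   `(1 − specificity) × compliance` and cost a confirmatory examination
   without changing state;
2. **accrual** — utilities and state-membership costs accrue from the
   cycle-start occupancy, event costs from the screening tallies;
3. **transition** — the post-screening vector is multiplied by the
   age-specific transition matrix.

Screening results feed treatment within weeks, which is why detection
precedes accrual and transition inside the same annual cycle.

Multi-year cumulative incidences are converted to annual probabilities with
the constant-hazard pair `r = −log(1 − p)/t` and `p = 1 − exp(−rt)`
(`annual_rate_from_cumulative()`, `probability_from_rate()`), which
round-trip to 1e−12.

## Costing

Costs are societal and in USD (a single exchange-rate field, 6.90 CNY/USD,
converts configurations entered in yuan at load time).  Every flow is split
into direct-medical / direct-nonmedical / indirect components:

* screening: a per-attendee aggregate, $10.10 (manual) vs $9.60 (AI);
* referral examination: charged per completed referral, true or false
  positive; participant and family wage loss is zero by assumption (the
  cohort is past retirement age), though the fields exist;
* treatment: first detection year — 3 anti-VEGF injections for macular
  oedema, photocoagulation or vitrectomy for severe NPDR/PDR; follow-up
  years — one injection plus an annual outpatient review;
* blindness: a first-year burden of $8,920 split 53.2% / 6.4% / 40.4%
  into the three components, and indirect costs only thereafter.

First-year versus continuing treatment and blindness are distinguished by
one-cycle *tunnel bookkeeping on inflows* rather than extra Markov states:
the expected values are identical and the state space stays small; the test
suite verifies the decomposition against direct matrix bookkeeping
(`blindness_tunnel()`).

Costs and QALYs are discounted at 3.5% per year by cycle index.  Years
without blindness are accrued **undiscounted** by default
(`settings$discount_effects` turns discounting on): the effectiveness
denominator of a screening comparison is conventionally left undiscounted
when the source presentation does not state otherwise, and the choice is
exposed rather than hidden.  There is no half-cycle correction by default
(`settings$half_cycle` enables a midpoint-occupancy accrual variant);
cycle-start accrual is the simplest convention consistent with
within-cycle screening.

## Parameters and provenance

Every input is one row of `parameter_table()`: base value, deterministic
range, distribution family, units and provenance.  Two provenance classes
matter:

* `paper-text` — headline values of the Shanghai programme this model
  represents: utilities 0.87/0.79/0.70/0.55; AI sensitivity 80.47% and
  specificity 97.96%; manual grading 100% accurate at base (its range for
  sensitivity analysis reflects trained non-expert graders); referral
  compliance 50.4%; screening costs above; the $8,920 blindness burden and
  its split; 3.5% discounting; GDP-per-capita thresholds $22,600 and
  $67,800.
* `supplement-placeholder` — transition probabilities, initial prevalence
  split, the mortality table and odds ratios, and the referral/treatment
  cost components.  These were **not published** with the programme
  description; the shipped values are stand-ins of plausible magnitude,
  chosen once so that base-case outputs land at a realistic scale
  (per-person lifetime cost around $3,200 and about 6.75 QALYs).  Any
  result that depends on them demonstrates the machinery, not a
  reproduction of the original numbers.

Default sensitivity ranges follow the class conventions: ±10% for
probabilities and utilities, ±50% for costs, ±25% for the AI compliance
multiplier; `cfg$ranges` overrides per parameter.  Validation
(`load_parameters()`) is total — probabilities and utilities in [0, 1],
ordered utilities, nonnegative costs, consistent ranges, blindness shares
summing to one, outgoing transition mass at most one, mortality coverage of
every modelled age — and reports every violation at once.

One validation subtlety is deliberate: the cross-field utility ordering
(0.87 ≥ 0.79 ≥ 0.70 ≥ 0.55) is enforced for *base* configurations but
relaxed to per-field bounds for one-way sensitivity excursions and PSA
draws (`check = "draw"`), because independently perturbing adjacent
utilities by ±10% legitimately crosses the ordering (the low end of 0.87 is
0.783, below 0.79), and suppressing those excursions would silently shrink
the published ranges.

## Economic outcomes

With manual grading as baseline, differences are AI minus manual, scaled to
100,000 people screened.  The ICER is ΔCost/ΔYearsWithoutBlindness and the
ICUR ΔCost/ΔQALY, both reported at full precision; zero denominators flag
the ratio undefined and classification falls back to the cost comparison.
WHO willingness-to-pay classification (`who_classify()`) uses 1× and 3×
GDP per capita, with the reversed rule for utility-reducing, cost-saving
interventions: savings per QALY lost above 3×GDP are highly
cost-effective, between 1× and 3× cost-effective, below 1× not
cost-effective.  Ratios exactly on a threshold take the more favourable
class by default (`boundary_favorable = FALSE` closes the boundary the
other way); the source rule says "less than" / "1–3 times" without closing
the boundary, so the convention is explicit and configurable.

```{r}
res <- run_base_case(default_config())
res$comparison
```

Under the shipped defaults the AI arm saves money but loses a little
effectiveness, and the savings per QALY lost fall below GDP per capita —
the switch is classified not cost-effective, the same regime the Shanghai
comparison reported.  The magnitudes of the increments depend on the
placeholder inputs and are not a reproduction.

## Sensitivity analyses

**Deterministic.**  `run_dsa()` sweeps every ranged parameter to its low
and high end with everything else at base (side-effect-free; endpoints are
reproducible from independent single runs) and sorts by ICUR spread.
Entries whose endpoint ratios are undefined or change sign — typically the
AI compliance multiplier, which can flip the effect difference — are
flagged and reported separately instead of being drawn as tornado bars.
`compliance_threshold_scan()` applies the multiplier grid (0.75–1.25) to
the AI arm only, since the swept quantity is the change in referral
compliance after adopting AI, and reports the first multiplier reaching
each classification.

**Probabilistic.**  `run_psa()` fits method-of-moments distributions per
parameter — beta for probabilities and utilities, gamma for costs,
log-normal for odds ratios and the compliance multiplier — matching
`mean = base` and `sd = (high − low)/(2 × 1.96)`, i.e. the deterministic
range treated as a 95% interval (the standard convention when only ranges
are published; configurable by overriding `cfg$ranges`).  The log-normal
is parameterised to match the mean and sd of the ratio itself, not of its
logarithm, because only a point value and range are available.  Each of
the 10,000 seeded draws is shared between the two arms, so incremental
differences reflect strategy structure rather than sampling noise;
invalid draws are rejected, redrawn and counted.  `ceac()` computes, per
willingness-to-pay threshold, the fraction of draws in which each strategy
attains the maximal net monetary benefit (`λ·QALY − Cost`), splitting
exact ties equally; the default grid spans 0 to 3×GDP in 200 steps with
both WHO thresholds forced onto the grid.

## The synthetic generator and the microsimulation oracle

`generate_scenario(seed)` draws every placeholder parameter uniformly
within its admissible interval while keeping the published headline values
fixed, and only returns configurations that pass full validation.  It
emulates the *structure* of the study's parameter set — not its values —
so passing tests demonstrate that the machinery (conservation, costing,
ratio arithmetic, classification) is correct across the plausible parameter
space.  What the generator does not emulate: parameter correlation (draws
are independent), age-dependence of progression, secular trends in costs,
and real compliance behaviour; conclusions about the actual Shanghai
programme require the unpublished appendix values.

`microsim_oracle()` is the independent check on the cohort engine: it
simulates individual state paths by categorical sampling from the *same*
transition matrices, with Bernoulli detection and false-positive events and
the same event order, and returns means with Monte Carlo standard errors.
Because the microsimulation replaces expectation propagation with sampling
while sharing every numeric input, agreement isolates the cohort engine's
bookkeeping.  The test suite checks 3-standard-error agreement for cost,
QALYs and years without blindness on twenty 200,000-individual runs over
random scenarios, plus exact equality in the degenerate (event-free) case.

## Numerical choices and problem sizes

* Occupancy conservation is asserted at 1e−10 across 1,000 random
  scenarios; transition rows are stochastic at 1e−12.
* The event-free cohort reproduces the closed-form discounted annuity
  `u·Σ(1.035)^{−k}` to 1e−10.
* Distribution fits are verified by sampling: 10⁶ draws per fitted
  parameter recover the target mean within 3 standard errors and the sd
  within 5%.
* The CEAC is verified against hand-enumerated fractions on a constructed
  10-draw set including an exact tie.
* Exports are byte-identical under identical configuration and seed; the
  rounded report tables print money and ratios to 2 decimals and
  probabilities to 4, with a parallel full-precision export.

## Limitations

The cohort engine is deterministic expectation propagation: no
individual-level heterogeneity (the microsimulation exists only as an
oracle), no treatment-induced regression, no age-dependence in progression
probabilities, and no correlation between PSA parameters.  Supplement-level
inputs are placeholders, so absolute outputs are demonstrations of scale;
the published headline inputs, all of the arithmetic, and every structural
property are exact.
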