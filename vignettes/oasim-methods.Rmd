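---
title: "Modelling osteoarthritis burden reduction with oasim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling osteoarthritis burden reduction with oasim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`oasim` is a discrete-time microsimulation of osteoarthritis (OA) in an
open adult population. Each simulated individual carries demographics
(age, sex, education, income, region, smoking), a continuous body mass
index (BMI), an absorbing OA diagnosis with onset year, an
eight-attribute Health Utilities Index Mark 3 (HUI3) health state
(vision, hearing, speech, mobility, dexterity, emotion, cognition,
pain), current analgesic use (acetaminophen, oral NSAIDs, coxibs,
opioids), chronic comorbidity flags (diabetes, hypertension,
cardiovascular disease, stroke, ulcer, and remitting non-ulcer
dyspepsia), and a joint-replacement-surgery (JRS) history capped at four
primary replacements. The population is open: people enter by turning 20
or immigrating, and leave by death or emigration, with exogenous entry
counts so population composition does not depend on within-scenario
events.

Each simulated year applies, in a fixed order: (1) aging, background
mortality and migration; (2) the autoregressive log-BMI update; (3) the
preventive BMI reduction when a prevention scenario is active; (4) OA
incidence; (5) analgesic sampling from point-prevalence tables, with
scenario odds modifiers; (6) medication side effects, including lethal
opioid overdose and case fatality for serious gastrointestinal (GI)
bleeds, cardiovascular (CVD) events, and strokes; (7) JRS sampling with
perioperative mortality and surgical improvement of the pain and
mobility attributes; (8) the hierarchical HUI3 update, pain last,
followed by the same year's drug effects on pain; and (9) an accounting
snapshot. Treatment therefore responds to current pain, and the year's
utility reflects the year's treatment. Decedents contribute half a
person-year at their pre-update utility; emigrants contribute none in
the exit year.

Key modelling assumptions, each of which is a deliberate choice where
the underlying design was open:

* **Annual time step.** Coefficients are interpreted as per-year
  effects. The BMI and HUI3 models that inspired this structure were
  estimated on a two-year survey cadence; the per-year reinterpretation
  is an approximation and is the main reason the default coefficient
  values are calibration targets rather than estimates.
* **Treated pain is the carried state.** A drug-induced pain improvement
  feeds the next year's lagged pain, medication eligibility, and JRS
  odds. The alternative (treating relief as a transient overlay) would
  decouple treatment from care-seeking behaviour, which we found less
  coherent.
* **Medication is re-sampled annually from point prevalence.** There is
  no adherence or persistence state; annual re-sampling reproduces
  cross-sectional use patterns by age, sex, OA stage and pain level,
  which is what the point-prevalence parameterization describes. The
  four drug classes are sampled independently and act independently on
  pain and side effects; co-use is allowed.
* **OA is absorbing**, staged as diagnosis <5 years, >=5 years,
  post-JRS <5 years, post-JRS >=5 years (surgery stages take
  precedence).
* **BMI affects OA burden through incidence only.** The BMI terms in
  the HUI3 models are kept near zero so that weight loss does not
  change health utility directly; prevention scenarios act by lowering
  OA incidence via the BMI-category relative risks. This mirrors the
  scope of an OA-specific burden analysis, which excludes the many
  non-OA pathways between BMI and health.

## Random numbers and scenario coupling

All randomness flows through a counter-based generator (splitmix64):
every draw is a pure function of `(master seed, person id, process
stream, calendar year)`. Draw values are independent of call order and
of other individuals' histories, so two scenario runs from the same
initial population are coupled by *common random numbers*: a person
never touched by an intervention predicate has a bit-identical
trajectory in every scenario, and a null intervention reproduces the
base case byte for byte. This makes between-scenario differences (DALYs
averted, QALY differences) far less noisy than independent replicates
would be, which is essential at desk-scale population sizes.

## Outcomes

Burden is tallied per scenario, calendar year, sex, and age group
(20-69, 70+):

* **Disability weight**: mean utility of the non-OA group minus mean
  utility of the OA group, recomputed per scenario and year (treatment
  changes the OA group's utility, so weights are scenario-specific).
* **YLD** = OA prevalence x disability weight x person-time (crude,
  not age-standardized).
* **ΔYLL** = scenario person-time minus base-case person-time; forced
  to zero for BMI scenarios, which are assumed to have no effect on
  OA-related mortality.
* **DALYs averted** = ΔYLD + ΔYLL, with exact running cumulative sums;
  positive values mean burden averted.
* **QALYs** are undiscounted utility-weighted person-years; the
  effectiveness ratio divides the cumulative QALY difference by the
  cumulative number of additional surgeries.
* **Total OA DALYs** (the denominator for percentage-averted
  reporting) add base-case YLD to the person-time difference between a
  suppressed-treatment counterfactual (all drug and surgery effects
  off) and the base case.

## The synthetic default parameter set

The default parameters (`build_default_parameters()`) are synthetic:
the model structure mirrors analyses of national health surveys and
administrative data, but no survey microdata are distributed, so every
coefficient here was chosen, once, to make the base case resemble a
plausible aging Western population and then frozen. The calibration
targets were: adult OA prevalence around 15% and rising; OA incidence
around 8-13 per 1000 person-years; a 70+ population share in the low
teens rising over two decades; NSAID point prevalence among OA near
38%, acetaminophen near 20%, coxibs and opioids in single digits;
primary JRS rates of 40-55 per 1000 OA person-years; a pain
distribution among OA dominated by level 1; mean HUI3 among OA near
0.78; and an age-standardized OA prevalence drift below half a
percentage point over the first five years (the steady-state
requirement). These are reproduced by the test suite and the acceptance
script, not asserted here.

The harm/benefit balance of the analgesics is the most delicate part of
the default set, because the scenario design depends on its sign
pattern: targeted uptake must help every targeted group and harm the
excluded ones (NSAIDs and coxibs in people 70+ with mild pain; opioids
in anyone with mild pain). Pain relief is modelled as per-drug
distributions over one- and two-level pain improvements; harms flow
through age-graded excess GI bleeding, CVD and stroke relative risks,
remitting dyspepsia (a three-year disutility state, the dominant diffuse
harm channel), and lethal opioid overdose. The defaults place each
drug's net effect on the intended side of zero with the widest margins
the structure allows; some boundary cells (notably coxibs at 70+ with
mild pain) are intentionally near zero, which is precisely why the
targeting excludes them. Tests assert these signs with Monte Carlo
tolerances derived from per-person QALY-difference variance.

Where a quantity is published and well known we use it directly: BMI
category cut-offs (18.5/25/30, half-open), the HUI3 attribute list and
its published utility floor of -0.36, WHO-style 5-year age bands. The
multiplicative utility map over collapsed attribute levels (three
levels per non-pain attribute, five pain levels) is a stand-in
consistent with the published multi-attribute form, not a re-derivation
of HUI3 scoring; it is anchored at 1 for full health and -0.36 for the
worst state and is strictly monotone.

The hierarchical HUI3 update order is vision, hearing, speech,
cognition, emotion, mobility, dexterity, pain: sensory and cognitive
attributes first, pain last so that same-year treatment can act on it.
The order is configurable; only "pain last" is structural.

## Scenarios

Nine scenarios are built in: a base case; `Medication x2`/`x3`
(analgesic odds multiplied in the targeted groups only); `Surgery
x2`/`x3` (JRS hazard multiplied for OA with pain >= 2; revisions are
unaffected by default, with a configurable flag); and
`BMI-0.1/0.3/0.5/1.0` (annual BMI reduction while BMI >= 25, with
re-entry if a person drifts back above the threshold). Interventions
start in 2020 and are implemented instantly; a gradual ramp-up is out
of scope. A suppressed-treatment counterfactual supports the
total-burden denominator.

## Sensitivity analysis

Seventeen parameters are registered with means and 95% bounds: the four
BMI-to-OA relative risks, four per-drug pain-effect probabilities, four
cardiovascular/cerebrovascular relative risks, NSAID GI excess, opioid
overdose death, the JRS pain-improvement probability, perioperative
mortality, and a log-odds scale on the JRS pain-odds profile.
`run_one_way()` reruns selected scenarios at each parameter's mean,
lower, and upper value under common random numbers and orders results
by tornado range. The registry CIs encode a deliberate design: drug
effects are given meta-analysis-like precision while the obesity
relative risks are wide, so that obesity risk dominates uncertainty in
prevention scenarios — the qualitative pattern the analysis is meant to
exhibit. Probabilistic sensitivity analysis is out of scope.

## Numerical choices

* Proportional-odds sampling inverts the cumulative logit with a single
  uniform; cutpoints are validated to be strictly increasing.
* The odds multiplier uses `p' = mp / (1 - p + mp)` with the limit
  convention `p' = 0` when `m = 0`.
* Event probabilities derived from hazards use `1 - exp(-h)`; scenario
  multipliers scale the hazard, not the probability.
* Steady-state prevalence is computed by accumulating the BMI-averaged
  incidence hazard over age (OA is absorbing and background mortality
  does not depend on OA status, so prevalence at age a is
  `1 - exp(-H(a))`); the initial OA assignment is tilted by current BMI
  category and rescaled to match the calibrated marginal.
* New populations run a 15-year burn-in of the HUI3, medication, and
  surgery-history processes (demography and incidence frozen) so the
  joint health-state distribution starts near stationarity.
* Rate titration is by bisection with a tolerance of 5% of the target
  or 2 events, whichever is larger.
* BMI is clamped to [12, 70] with a clamp counter; attained age uses a
  top band of 90+.

## Problem sizes

Simulations in the test suite use 2,000-100,000 individuals depending
on what a check needs to resolve: exact identities (coupling,
accounting, person-time conservation) hold at any size and use small
populations; distributional checks use 10^5 draws; the
strategy-ordering comparison uses 100,000 individuals over 2020-2100;
the targeting analysis uses 80,000 over 2020-2050; the acceptance
script reports a 30,000-person, 20-year comparison. These sizes are the
package's chosen desk scale; the model itself has no size limit, and
Monte Carlo error columns are reported where relevant.

## What the synthetic data do and do not show

Passing tests demonstrate that the machinery is correct (accounting
identities, sampling distributions, calibration, common-random-number
coupling, parameter recovery by regression) and that the default
parameter set reproduces the intended qualitative epidemiology:
medication effects arrive fastest, expanded surgery overtakes them
within the horizon, and sufficient population weight loss dominates
over decades. They do not validate the default coefficients against any
real population: absolute DALY counts, crossover years, and percentage
reductions depend on a calibration that real survey and administrative
data would have to supply through the JSON parameter file.

Known limitations: no topical NSAIDs or non-pharmacological therapy; no
joint-specific OA; no costs; no waiting-list dynamics; immigrant health
states are fresh draws from the initial-covariate generator; and BMI is
modelled as self-reported-style continuous values without
measurement-error correction.
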