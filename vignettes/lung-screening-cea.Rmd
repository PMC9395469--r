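---
title: "A Markov cohort model for the cost-effectiveness of LDCT lung cancer screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for the cost-effectiveness of LDCT lung cancer screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcscreen)
```

## The decision problem

Low-dose CT (LDCT) screening detects lung cancer earlier than clinical
presentation. Earlier detection means earlier stages at diagnosis, more access
to curative surgery instead of palliative systemic therapy, longer survival —
and also the recurring cost of screening an entire high-risk population every
year. Whether a national programme is worth funding is a classic
health-economic question: per 100,000 heavy (ex-)smokers, what do different
start/stop-age strategies cost, how many quality-adjusted life years (QALYs)
do they gain, and which strategies are efficient?

`lcscreen` answers this with an annual-cycle Markov cohort model evaluated
over a lifetime horizon from the healthcare perspective, followed by
incremental cost-effectiveness analysis (efficiency frontier with strict and
extended dominance) and probabilistic sensitivity analysis (CEAC/CEAF).

## Health-state space

The state space (`build_state_space()`) has five non-cancer states — *well*,
*post-treatment*, *recurrence*, *death from lung cancer*, *death from other
causes* — plus one cancer state per (histology, stage) pair, split into a
clinically detected and a screen-detected variant. Histology distinguishes
small-cell lung cancer (SCLC) from four non-small-cell types
(adenocarcinoma, squamous-cell, large-cell, other NSCLC); stages are the
seven TNM groups IA–IV. With the defaults that is
5 + 2·5·7 = 75 states.

Internally the engine appends one *undiagnosed preclinical* compartment per
histology. This keeps detection dynamics inside a single row-stochastic
transition matrix, so person conservation and the matrix-product oracle hold
exactly for the whole simulation, screening included. The undiagnosed
compartments carry the well-state utility and no cost: they represent
asymptomatic disease before any diagnosis.

### Within-cycle event order

Events in a cycle are applied in a fixed, documented order: screening
detection (if the scenario schedules a round at the cohort's current age),
then clinical presentation of undiagnosed disease, then disease transitions
(cancer death, cure, stage progression) and other-cause death. Formally the
cycle matrix is the product `S %*% D` of a detection matrix and a disease
matrix; with no round scheduled it is `D` alone.

### Detection and the stage shift

New cancers arise from *well* at an age-dependent onset probability and enter
the undiagnosed pool with a histology drawn from the registry-style mix.
From there:

* at a screening round, a fraction `sens` (LDCT sensitivity; the PET → biopsy
  confirmation chain is assumed to add no false positives) is detected and
  enters the *screen-detected* cancer states with the trial-style,
  early-shifted stage distribution;
* every cycle, screened or not, undiagnosed disease presents clinically with
  probability `p_present` and enters the *clinically detected* states with
  the registry-style, late-heavy stage distribution.

This design has three consequences we consider essential and test:

1. **False negatives carry over.** Cases missed at one round (probability
   `1 - sens`) remain undiagnosed and are screened again next round, giving
   the geometric carry-over of missed cases.
2. **Zero sensitivity is a pure-cost programme.** With `sens = 0` the
   detection matrix is exactly the identity, so the disease dynamics are
   bit-for-bit those of no screening; costs differ by exactly the
   accumulated programme costs and QALYs by exactly zero.
3. **The stage shift is the only screening benefit.** Survival is applied by
   stage and histology identically to screen- and clinically-detected cases,
   so screening helps only by moving diagnoses to earlier stages — there is
   no modelled lead-time artefact beyond the stage shift itself.
   `apply_stage_shift()` exposes the counterfactual rule (default: the
   late-stage target IV with weight 1, configurable to a IIIB/IV split) for
   directional analyses.

A deliberate simplification: undiagnosed preclinical disease carries no
lung-cancer mortality and no stage label; the stage is assigned at detection
from the appropriate distribution. This mirrors the prevalence-based use of
registry and trial stage distributions and keeps the undiagnosed sojourn
(mean `1/p_present` years, default about 1.7) short.

### Cure and recurrence

Cure probability depends on histology and stage and leads to a pooled
*post-treatment* state; from there an annual recurrence probability leads to
the dedicated *recurrence* state, parameterised with stage-IV-like cancer
mortality and utility. We route recurrence through this explicit state rather
than back into a specific (histology, IV) cancer state because histology
identity is deliberately pooled away at cure; the recurrence state is the
structural way to keep the five-state non-cancer layout while preserving a
late-stage-like prognosis after relapse.

## Cohorts, ages and horizon

The screened population is a set of closed cohorts, one per entry age
(default: entry ages 50, 55, …, 95, with 10,000 persons each, 100,000 in
total). Each cohort is simulated separately with transitions indexed by
current age = entry age + cycle, then pooled; results are normalised per
100,000 persons. The horizon runs to age 100; the synthetic life table closes
with a terminal death probability of 1, so cohorts are essentially fully
absorbed at the horizon.

Scenarios schedule annual rounds at integer ages in `[start_age, stop_age)`.
The half-open convention makes a `start == stop` scenario perform zero rounds
and reproduce the no-screening trace exactly, which is the natural null. The
default grid crosses start ages {50, 60, 70} with stop ages {60, 70,
lifetime}, the six strategies evaluated alongside no screening.

## Economics

* **Discounting** — end-of-cycle convention: cycle *t* is divided by
  `(1 + r)^t`, with costs at 4%/year and effects at 1.5%/year (Dutch
  guideline rates); both rates and a begin-of-cycle switch are configurable.
* **QALYs** — state utilities are age-invariant (SF-36-style), death states
  carry 0, and occupancy is valued at cycle end. A half-cycle correction is
  available (`half_cycle = TRUE`) but off by default.
* **Costs** — four categories, each with a per-cell oracle test:
  LDCT per person screened per round (every eligible, alive, undiagnosed
  participant; full adherence is assumed, so invitees and attendees
  coincide); PET + biopsy confirmation per screen-detected case; a treatment
  lump sum at detection by histology and stage (surgery for operable stages,
  chemotherapy and immunotherapy for late stages; a per-cycle chronic-cost
  hook exists and defaults to zero); and a palliative cost for the terminal
  six months, charged to each lung-cancer death at its death cycle — annual
  cycles cannot resolve half-years, so the whole amount is discounted at the
  death cycle rather than spread.

## Cost-effectiveness analysis

`efficiency_frontier()` sorts scenarios by increasing discounted cost,
removes strictly dominated entries (no cheaper-or-equal entry with at least
as many QALYs may exist), then iteratively removes extended-dominated
entries until sequential ICERs strictly increase. Ties on cost keep the
higher-QALY entry; full ties keep the first label and warn. The iterative
algorithm is tested against a brute-force segment oracle (every point against
every connecting segment) on a thousand randomized instances, and the
published seven-scenario table reproduces its published labelling: three
strategies excluded by extended dominance, four on the frontier, all
sequential ICERs below the EUR 20,000/QALY willingness-to-pay reference.

CERs versus the no-screening reference, a Table-1-style report
(`table1_report()`, with asterisks on extended-dominated rows) and
undiscounted budget-impact streams (standard budget-impact convention)
complete the deterministic analysis.

## Probabilistic sensitivity analysis

Every probability and utility receives a beta distribution, every cost a
gamma distribution, moment-matched so the mean equals the base value. A
stated `(lo, hi)` range is read as a 95% central interval via the normal
approximation `sd = (hi - lo)/3.92`; the default synthetic specification uses
±10% of the base value, clipped to the support. A zero-width range is a point
mass, and a fully degenerate specification short-circuits to the base
parameter set so the 10-draw PSA reproduces the deterministic totals
bit for bit — a limit we test, together with the convergence of CEAF
switch-points to the deterministic frontier ICERs.

Draws are seeded per draw index from the top-level seed (reproducible and
resumable), and one parameter draw is evaluated under *all* scenarios
(common random numbers), which is what makes CEAC/CEAF coherent. After
perturbation, simplex-valued parameters (histology mix, stage distributions)
are renormalised proportionally; a draw violating a structural invariant
(e.g. the stage-monotone death ladder or the utility ordering) is redrawn
and counted. Because rejection is driven by the ordering constraints,
marginal means of the *constrained* leaves can shift slightly; the
mean-centering consistency checks therefore target unconstrained leaves.
The registry-style life table and discount rates are treated as fixed inputs
and not varied.

The default WTP grid spans EUR 0–50,000 in steps of 100 (configurable); CEAC
probabilities are tie-split and sum to one at every grid point, and the CEAF
reports, at each WTP, the CEAC value of the expected-net-benefit maximiser.

## The synthetic input generator

No registry or trial microdata ship with the package. `generator_config()` /
`generate_parameter_set()` produce complete, internally consistent synthetic
inputs whose *structure* matches the real parameter tables:

* onset probability logistic in age (scale 0.006, midpoint 72, slope 9);
* clinical stage distribution tilted late (log-linear tilt 0.55 per stage
  index — roughly 45% of clinical diagnoses in stage IV), screened
  distribution tilted early by an exponential likelihood-ratio factor
  controlled by `stage_shift` in [0, 1] (default 0.8), which guarantees
  first-order stochastic dominance toward early stages and exact equality at
  strength 0;
* annual cancer mortality a geometric ladder over stage (strictly
  increasing by construction), cure probability geometrically decreasing,
  utilities decreasing with stage and bounded by the well utility;
* euro costs with surgery (22,000) < chemotherapy (35,000) < immunotherapy
  (75,000), LDCT 150 per scan, confirmation workup 2,500, palliative
  terminal phase 12,000;
* a Gompertz life table (`qx = 2.8e-5 * exp(0.102 * age)`, closed at 1 by
  age 99), somewhat heavier than a general-population table, as befits heavy
  smokers.

Magnitudes are the package's own synthetic defaults — chosen once as
plausible for a western-European smoking population and *not* calibrated to
any registry — and a seeded log-normal jitter (4%) varies them across seeds
while every structural invariant holds by construction. The generator
records every leaf value in a `truth` vector, which the uncertainty
specification covers exactly and which round-trips through the CSV input
tree (`write_parameter_dir()` / `read_parameter_dir()`), so file-based and
in-memory pipelines are the same code path.

What passing tests on these fixtures shows is that the *machinery* is
correct: conservation, oracle equivalence, dominance labelling, discounting
arithmetic, distributional limits, and the directional economics of
screening (wider age windows cost weakly more and gain weakly more QALYs;
zero-sensitivity screening is pure cost). What it cannot show is agreement
with any published absolute totals, ICER point values or CEAF switch-points:
those depend on registry- and trial-derived parameter values that are not
public, and the package makes no claim to reproduce them. Published results
enter only as *inputs* to arithmetic-consistency checks of the incremental
and dominance operations.

## Numerical choices

* Row sums of transition matrices are checked to 1e-9; entry ranges allow a
  1e-12 float tolerance for composed matrices; person conservation is
  checked to 1e-6 of cohort size.
* Validation reports (`validate_parameters()`, `validate_transitions()`)
  enumerate all violations with state labels instead of failing fast;
  constructors validate by default, readers construct first and let the
  calling command validate and report.
* Problem sizes used by the test-suite: unit tests run 3 cohorts of 1,000
  (and a 2-histology × 3-stage space for sampling-heavy checks); the
  directional end-to-end sweep runs the full study conditions over 100
  generator seeds; the shipped analysis script uses 100 PSA draws over the
  full scenario grid. The study-scale PSA default remains 5,000 draws
  (`cmd_psa()`).

## Known limitations

* Cohort-level (Markov) dynamics only: no individual-level microsimulation,
  no smoking cessation/relapse dynamics, no tumour-growth model.
* Screening adherence, radiation harm, overdiagnosis and lead-time
  correction are out of scope by design.
* The undiagnosed compartment is immortal with respect to lung cancer and
  histology-pooled; with long `1/p_present` sojourns this would understate
  preclinical mortality.
* Utilities are age-invariant; indirect/societal costs and price-year
  inflation machinery are not modelled (healthcare perspective only).

## A worked run

```{r example, eval = FALSE}
cfg <- generator_config(seed = 1)
params <- generate_parameter_set(cfg)$params
fit <- lc_cea(params)
print(fit)       # Table-1-style report with dominance labels
plot(fit)        # efficiency frontier

spec <- generate_uncertainty_spec(params, cfg$uncertainty_width)
psa <- run_psa(params, spec, n_draws = 200, seed = 1)
plot(psa)        # CEAC curves and the acceptability frontier
ceaf_switchpoints(ceaf(psa))
```
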