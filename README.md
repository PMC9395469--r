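# lcscreen

Decision-analytic modelling of **low-dose CT (LDCT) lung cancer screening**
in high-risk smokers and ex-smokers: an annual-cycle Markov cohort model of
lung cancer natural history, screening scenarios with stage shift, discounted
cost and QALY accumulation, efficiency-frontier analysis with extended
dominance, and probabilistic sensitivity analysis (CEAC/CEAF).

The package is written for health economists and modellers who want a
tested, configurable implementation of the standard screening
cost-effectiveness pipeline — from parameter tables to a Table-1-style
report — without any proprietary registry data: a synthetic generator
emulates the structure of registry- and trial-derived inputs so every stage
of the pipeline is runnable and testable out of the box.

## The model in brief

**States.** Five non-cancer states (well, post-treatment, recurrence, death
from lung cancer, death other cause) plus one cancer state per
(histology × stage), each split into screen-detected and clinically detected
variants: 5 histologies (SCLC + 4 NSCLC types) × 7 TNM stages (IA–IV) gives
5 + 2·5·7 = 75 states. An internal undiagnosed-preclinical compartment per
histology keeps detection inside one row-stochastic matrix.

**Dynamics.** Closed cohorts enter at ages 50–95 (10,000 per entry age,
100,000 total) and run in annual cycles to age 100. Onset is logistic in
age; undiagnosed disease is screen-detected with sensitivity *s* at annual
rounds in `[start_age, stop_age)` (early-shifted stage distribution) or
presents clinically (late-heavy distribution). Detected cancer faces
stage-monotone annual cancer mortality, histology/stage-dependent cure, and
progression; cure can relapse into a stage-IV-like recurrence state.

**Economics.** Costs (LDCT per screen, PET+biopsy per detection, treatment
lump sum at detection, palliative terminal phase at death) discounted at 4%,
QALYs (age-invariant utilities) at 1.5%, per 100,000 persons. Strategies are
sorted by cost; strictly dominated entries are removed, then extended
dominance is eliminated until sequential ICERs

    ICER_k = (C_k − C_{k−1}) / (Q_k − Q_{k−1})

strictly increase along the frontier. The PSA samples every probability and
utility from moment-matched beta distributions and every cost from gamma
distributions (ranges read as 95% intervals), evaluates all scenarios under
common random draws, and reports the probability each strategy maximises net
monetary benefit `NMB(λ) = λ·Q − C` (CEAC) and the acceptability frontier
(CEAF).

## Worked example

```r
library(lcscreen)

cfg    <- generator_config(seed = 1)          # synthetic study conditions
params <- generate_parameter_set(cfg)$params  # validated parameter set
fit    <- lc_cea(params)                      # all 6 strategies + no screening
print(summary(fit))
```

```
Cost-effectiveness report (reference: no screening)
       scenario        cost    qalys   icer cost_vs_ref qalys_gained    cer
   no screening  91,703,982 790157.3
  50-60 years * 107,961,843 790482.5         16,257,862        325.2 49,993
    60-70 years 116,972,588 791330.4 21,539  25,268,606       1173.2 21,539
  50-70 years * 133,403,801 791623.5         41,699,819       1466.2 28,440
 70 and older * 140,129,962 792206.2         48,425,980       2049.0 23,634
   60 and older 165,919,592 793305.5 24,783  74,215,610       3148.2 23,574
   50 and older 182,350,805 793598.5 56,071  90,646,823       3441.3 26,341
* extended dominated scenario

Frontier: no screening -> 60-70 years -> 60 and older -> 50 and older
Sequential ICERs at or below EUR 20,000/QALY: none
```

Reading the table: `cost`/`qalys` are discounted totals per 100,000 persons;
`icer` is the sequential ratio versus the next-cheapest frontier strategy
(blank on dominated rows); the last three columns compare each strategy with
no screening. Here, on synthetic inputs, screening 60–70-year-olds is the
cheapest efficient screening strategy at EUR 21,539 per QALY gained, and the
starred strategies are excluded by extended dominance. `plot(fit)` draws the
cost–QALY frontier.

Uncertainty analysis:

```r
spec <- generate_uncertainty_spec(params, cfg$uncertainty_width)  # ±10%
psa  <- run_psa(params, spec, n_draws = 200, seed = 1)
plot(psa)                       # CEAC curves + acceptability frontier
ceaf_switchpoints(ceaf(psa))    # WTP values where the optimal strategy flips
```

A file-based workflow with the same semantics is available through
`cmd_generate()` / `cmd_validate()` / `cmd_run()` / `cmd_psa()` (CSV
parameter directories with provenance headers), or from a shell via the thin
wrapper `inst/cli/lcscreen.R`.

## Package layout

| Area | Entry points |
| --- | --- |
| State space & parameters | `build_state_space()`, `lc_parameters()`, `validate_parameters()`, `validate_transitions()` |
| Cohort engine | `transition_matrix()`, `step_cohort()`, `run_cohort()` |
| Screening | `lc_scenario()`, `scenario_grid()`, `is_eligible()`, `screen_round()`, `apply_stage_shift()` |
| Economics | `discount_factor()`, `accumulate_costs()`, `accumulate_qalys()`, `terminal_palliative_costs()` |
| CEA | `lc_cea()`, `incremental()`, `icer()`, `efficiency_frontier()`, `cer_vs_reference()`, `budget_impact()`, `table1_report()` |
| PSA | `fit_distribution()`, `sample_parameter_set()`, `run_psa()`, `nmb()`, `ceac()`, `ceaf()` |
| Synthetic inputs & I/O | `generator_config()`, `generate_parameter_set()`, `generate_population()`, `generate_uncertainty_spec()`, `write_parameter_dir()`, `read_parameter_dir()` |
| Commands | `cmd_generate()`, `cmd_validate()`, `cmd_run()`, `cmd_psa()` |

The methods vignette (`vignettes/lung-screening-cea.Rmd`) documents the
model assumptions, event ordering, numerical conventions, the synthetic
generator's design and the package's known limitations.
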