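#' Configuration of the synthetic parameter generator
#'
#' Collects every knob of the synthetic input generator with the study's
#' default conditions: 10,000 persons per entry-age group (100,000 total,
#' ages 50+), annual screening with LDCT sensitivity 0.9, a late-stage-heavy
#' clinical stage distribution with a screen-detected distribution shifted
#' toward early stages, cancer mortality rising geometrically with stage,
#' cure probability falling with stage, surgery cheaper than systemic
#' late-stage therapy, palliative costs for the terminal half-year, and
#' ±10% beta/gamma uncertainty ranges. All magnitudes are synthetic package
#' defaults, not registry values.
#'
#' @param seed Integer seed; the generated set is deterministic given it.
#' @param group_size Persons per entry-age group.
#' @param age_groups Entry ages of the closed cohorts.
#' @param histologies,stages State-space labels (defaults: the five
#'   histologies and seven TNM stage groups); smaller spaces are useful for
#'   quick experiments.
#' @param onset_scale,onset_midpoint,onset_slope Logistic-in-age annual onset
#'   probability: `onset_scale * plogis((age - midpoint) / slope)`.
#' @param clinical_tilt Log-linear tilt of the clinical stage distribution
#'   toward late stages (per stage index).
#' @param stage_shift Strength in [0, 1] of the early shift of the
#'   screen-detected stage distribution; 0 reproduces the clinical
#'   distribution.
#' @param death_base,death_ratio Stage-I annual cancer death probability and
#'   geometric ratio per stage, per histology (SCLC first).
#' @param cure_base,cure_ratio Stage-I annual cure probability and geometric
#'   decay per stage.
#' @param progress_rate Annual within-cancer stage-progression probability.
#' @param p_recurrence Annual recurrence probability from post-treatment.
#' @param death_recur Annual cancer death probability in recurrence
#'   (stage-IV-like).
#' @param sens LDCT per-round sensitivity.
#' @param p_present Annual clinical presentation probability of undiagnosed
#'   preclinical disease.
#' @param mix Histology mix (renormalised).
#' @param cost_ldct,cost_workup,cost_surgery,cost_chemo,cost_immuno,cost_palliative
#'   Euro cost scales: LDCT per screen, PET+biopsy confirmation per detected
#'   case, surgery (stages IA-IIB), chemotherapy (IIIA-IIIB), immunotherapy
#'   (IV), palliative terminal half-year.
#' @param u_well Utility of the well state (SF-36-style, age-invariant).
#' @param mort_a,mort_b Gompertz all-cause mortality `qx = a * exp(b * age)`,
#'   closed at 1 from age 99.
#' @param uncertainty_width Half-width of uncertainty ranges relative to the
#'   base value.
#' @param discount_cost,discount_effect Annual discount rates.
#' @param max_age Horizon: cohorts run until this age.
#' @param jitter_sd Log-normal jitter applied to generated magnitudes so
#'   different seeds give different, still-valid parameter sets.
#' @return A validated list of class `lc_genconfig`.
#' @export
generator_config <- function(seed = 1L,
                             group_size = 10000,
                             age_groups = seq(50L, 95L, by = 5L),
                             histologies = lc_histologies,
                             stages = lc_stages,
                             onset_scale = 0.006,
                             onset_midpoint = 72,
                             onset_slope = 9,
                             clinical_tilt = 0.55,
                             stage_shift = 0.8,
                             death_base = c(0.07, 0.028, 0.030, 0.032, 0.030),
                             death_ratio = c(1.45, 1.60, 1.60, 1.60, 1.60),
                             cure_base = c(0.25, 0.50, 0.50, 0.48, 0.48),
                             cure_ratio = 0.55,
                             progress_rate = 0.15,
                             p_recurrence = 0.05,
                             death_recur = 0.45,
                             sens = 0.9,
                             p_present = 0.6,
                             mix = c(0.14, 0.38, 0.25, 0.08, 0.15),
                             cost_ldct = 150,
                             cost_workup = 2500,
                             cost_surgery = 22000,
                             cost_chemo = 35000,
                             cost_immuno = 75000,
                             cost_palliative = 12000,
                             u_well = 0.85,
                             mort_a = 2.8e-5,
                             mort_b = 0.102,
                             uncertainty_width = 0.10,
                             discount_cost = 0.04,
                             discount_effect = 0.015,
                             max_age = 100L,
                             jitter_sd = 0.04) {
  cfg <- as.list(environment())
  scales <- c(cfg$onset_scale, cfg$death_base, cfg$cure_base, cfg$cost_ldct,
              cfg$cost_workup, cfg$cost_surgery, cfg$cost_chemo,
              cfg$cost_immuno, cfg$cost_palliative, cfg$group_size,
              cfg$u_well)
  if (any(scales <= 0)) stop("generator scales must be positive")
  if (cfg$stage_shift < 0 || cfg$stage_shift > 1)
    stop("stage_shift strength must lie in [0, 1]")
  if (cfg$cost_surgery >= cfg$cost_chemo || cfg$cost_chemo >= cfg$cost_immuno)
    stop("treatment cost scales must satisfy surgery < chemo < immunotherapy")
  nS <- length(cfg$stages)
  if (any(cfg$death_base * cfg$death_ratio^(nS - 1) > 0.97))
    stop("death gradient produces probabilities too close to 1; ",
         "reduce death_base or death_ratio")
  structure(cfg, class = "lc_genconfig")
}

#' Generate a complete synthetic parameter set
#'
#' Builds the full model input emulating the structure of registry- and
#' trial-derived parameter tables: stage-specific survival worsening with
#' stage, a screen-detected stage distribution shifted toward early stages
#' relative to the clinical one, treatment costs where systemic late-stage
#' therapy exceeds surgery, terminal palliative costs, SF-36-style
#' age-invariant utilities, a Gompertz all-cause life table, and beta/gamma
#' uncertainty ranges. Deterministic given `config$seed`; seeded log-normal
#' jitter varies magnitudes across seeds while every structural invariant
#' holds by construction.
#'
#' @param config An `lc_genconfig` from [generator_config()].
#' @return List with elements `params` (validated `lc_params`) and `truth`
#'   (named numeric vector of every generated leaf parameter, also attached
#'   as `params$truth`).
#' @export
generate_parameter_set <- function(config = generator_config()) {
  if (!inherits(config, "lc_genconfig")) config <- do.call(generator_config, config)
  set.seed(config$seed)
  jit <- function(n = 1L, sd = config$jitter_sd) exp(stats::rnorm(n, 0, sd))
  sp <- build_state_space(config$histologies, config$stages)
  H <- sp$histologies; S <- sp$stages
  nH <- length(H); nS <- length(S)
  death_base <- rep_len(config$death_base, nH)
  death_ratio <- rep_len(config$death_ratio, nH)
  cure_base <- rep_len(config$cure_base, nH)
  leaves <- c()
  add <- function(ids, vals) leaves[ids] <<- unname(vals)

  mix <- rep_len(config$mix, nH) * jit(nH)
  mix <- mix / sum(mix)
  add(paste("mix", H, sep = "."), mix)

  si <- seq_len(nS)
  lambda <- 1.2  # early-shift strength per unit of stage_shift
  for (hi in seq_len(nH)) {
    w <- exp(config$clinical_tilt * si) * jit(nS, config$jitter_sd)
    cd <- w / sum(w)
    swt <- w * exp(-lambda * config$stage_shift * si)
    sd_ <- swt / sum(swt)
    add(paste("cdist", H[hi], S, sep = "."), cd)
    add(paste("sdist", H[hi], S, sep = "."), sd_)

    base_d <- death_base[hi] * jit()
    ratio_d <- max(1.15, death_ratio[hi] * jit(1, config$jitter_sd / 2))
    d <- base_d * ratio_d^(si - 1)
    if (max(d) > 0.97)
      stop("death gradient produced a probability above 0.97 for ", H[hi])
    add(paste("death", H[hi], S, sep = "."), d)

    ratio_c <- min(0.8, max(0.3, config$cure_ratio * jit()))
    cu <- pmin(0.9, cure_base[hi] * jit() * ratio_c^(si - 1))
    add(paste("cure", H[hi], S, sep = "."), cu)

    g <- min(0.5, config$progress_rate * jit())
    add(paste("prog", H[hi], S, sep = "."), c(rep(g, nS - 1L), 0))
  }

  ages <- 50:(config$max_age - 1L)
  onset <- config$onset_scale * jit() *
    stats::plogis((ages - config$onset_midpoint) / config$onset_slope)
  add(paste("onset", ages, sep = "."), pmin(onset, 0.05))

  add("p_recurrence", min(0.3, config$p_recurrence * jit()))
  add("death_recur", min(0.9, config$death_recur * jit()))
  add("sens", config$sens)
  add("p_present", config$p_present)

  u_well <- min(0.95, config$u_well * jit(1, config$jitter_sd / 2))
  f <- cummin(pmin(0.95, (0.93 - 0.045 * (si - 1)) * jit(nS, 0.02)))
  u_stage <- u_well * (f - 1e-3 * (si - 1))
  add("u.well", u_well)
  add("u.post", 0.95 * u_well)
  add("u.recur", 0.98 * u_stage[nS])
  add(paste("u.stage", S, sep = "."), u_stage)

  surgery <- config$cost_surgery * jit()
  chemo <- surgery * max(1.15, (config$cost_chemo / config$cost_surgery) * jit())
  immuno <- chemo * max(1.2, (config$cost_immuno / config$cost_chemo) * jit())
  add("cost.ldct", config$cost_ldct * jit())
  add("cost.workup", config$cost_workup * jit())
  add("cost.palliative", config$cost_palliative * jit())
  # last stage systemic immunotherapy, the two before it chemotherapy,
  # earlier (operable) stages surgery
  treat_by_stage <- rep(surgery, nS)
  if (nS >= 2L) treat_by_stage[max(1L, nS - 2L):(nS - 1L)] <- chemo
  treat_by_stage[nS] <- immuno
  for (hi in seq_len(nH))
    add(paste("treat", H[hi], S, sep = "."), treat_by_stage)

  mort_age <- 40:config$max_age
  qx <- pmin(0.99, config$mort_a * exp(config$mort_b * mort_age))
  qx[mort_age >= config$max_age - 1L] <- 1
  mortality <- data.frame(age = mort_age, qx = qx)

  params <- lc_parameters(
    leaves, mortality, sp,
    discount = list(cost = config$discount_cost,
                    effect = config$discount_effect),
    config = list(max_age = config$max_age,
                  age_groups = config$age_groups,
                  group_size = config$group_size,
                  stage_shift = config$stage_shift,
                  seed = config$seed))
  list(params = params, truth = params$truth)
}

#' Generate the eligible population structure
#'
#' Per-entry-age counts of eligible heavy (ex-)smokers, plus a sample of
#' individual smoking profiles, each satisfying the programme eligibility
#' criteria (smoked more than 30 years, at least 15 cigarettes per day, quit
#' at most 10 years ago) at its group's entry age.
#'
#' @param config An `lc_genconfig`.
#' @param n_profiles Profiles sampled per age group.
#' @return List with `groups` (data frame `start_age`, `n`) and `profiles`
#'   (data frame of smoking histories with a `group` column).
#' @export
generate_population <- function(config = generator_config(),
                                n_profiles = 50L) {
  if (!inherits(config, "lc_genconfig")) config <- do.call(generator_config, config)
  set.seed(config$seed + 1L)
  groups <- data.frame(start_age = as.integer(config$age_groups),
                       n = rep(config$group_size,
                               length(config$age_groups)))
  profiles <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    a <- groups$start_age[g]
    current <- stats::runif(n_profiles) < 0.6
    data.frame(group = g, age = a,
               years_smoked = 31 + sample(0:min(15, a - 32), n_profiles,
                                          replace = TRUE),
               cigarettes_per_day = sample(15:40, n_profiles, replace = TRUE),
               years_since_cessation = ifelse(current, 0,
                                              sample(1:10, n_profiles,
                                                     replace = TRUE)))
  }))
  list(groups = groups, profiles = profiles)
}

#' Uncertainty specification for every generated parameter
#'
#' Beta entries for every probability and utility leaf, gamma entries for
#' every cost leaf; ranges are `base * (1 +/- width)` clipped to the family
#' support and read as 95% central intervals.
#'
#' @param params An `lc_params` object carrying its `truth` vector.
#' @param width Relative half-width of the range (default 0.10, i.e. ±10%);
#'   0 gives a degenerate spec of point masses reproducing the deterministic
#'   analysis.
#' @return Data frame with columns `parameter_id`, `base`, `family`, `lo`,
#'   `hi`, covering exactly the leaves in `params$truth`.
#' @export
generate_uncertainty_spec <- function(params, width = 0.10) {
  if (width < 0) stop("width must be non-negative")
  ids <- names(params$truth)
  base <- unname(params$truth)
  is_cost <- grepl("^(cost|treat)\\.", ids)
  family <- ifelse(is_cost, "gamma", "beta")
  lo <- base * (1 - width)
  hi <- base * (1 + width)
  lo[!is_cost] <- pmax(lo[!is_cost], 0)
  hi[!is_cost] <- pmin(hi[!is_cost], 1)
  data.frame(parameter_id = ids, base = base, family = family,
             lo = lo, hi = hi)
}

#' @export
print.lc_genconfig <- function(x, ...) {
  cat("Synthetic input generator configuration\n")
  cat(sprintf("  seed %d; %d age groups x %d persons\n", x$seed,
              length(x$age_groups), x$group_size))
  cat(sprintf("  stage-shift strength %.2f, LDCT sensitivity %.2f\n",
              x$stage_shift, x$sens))
  cat(sprintf("  costs (EUR): LDCT %d, surgery %d, chemo %d, immuno %d\n",
              round(x$cost_ldct), round(x$cost_surgery), round(x$cost_chemo),
              round(x$cost_immuno)))
  invisible(x)
}
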