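test_that("eligibility implements the heavy-smoker criteria", {
  prof <- data.frame(
    age = c(55, 55, 49, 55, 55),
    years_smoked = c(31, 31, 40, 30, 31),
    cigarettes_per_day = c(15, 15, 20, 20, 14),
    years_since_cessation = c(0, 11, 0, 0, 0))
  expect_identical(unname(is_eligible(prof, min_age = 50)),
                   c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_error(is_eligible(data.frame(age = 50), 50), "lacks fields")
})

test_that("the scenario grid yields the six strategies plus the reference", {
  g <- scenario_grid()
  expect_length(g, 7L)
  expect_null(g[["no screening"]])
  expect_setequal(setdiff(names(g), "no screening"),
                  c("50-60 years", "50-70 years", "50 and older",
                    "60-70 years", "60 and older", "70 and older"))
  g70 <- scenario_grid(starts = 70)
  expect_identical(setdiff(names(g70), "no screening"), "70 and older")
  g2 <- scenario_grid(starts = 50, stops = c(55, 60),
                      include_reference = FALSE)
  expect_length(g2, 2L)
})

test_that("screen rounds split detected/missed exactly and carry over", {
  occ <- matrix(c(100, 40, 0, 7.5), 2, 2,
                dimnames = list(c("h1", "h2"), c("early", "late")))
  full <- screen_round(occ, list(sens = 1))
  expect_equal(full$detected, occ)
  expect_true(all(full$missed == 0))
  none <- screen_round(occ, list(sens = 0))
  expect_true(all(none$detected == 0))
  expect_equal(none$missed, occ)

  r1 <- screen_round(occ, list(sens = 0.9))
  expect_equal(r1$detected + r1$missed, occ)
  expect_equal(r1$detected["h1", "early"], 90)
  r2 <- screen_round(r1$missed, list(sens = 0.9))
  expect_equal(r2$detected["h1", "early"], 9)
  expect_error(screen_round(occ, list(sens = 0.9, fp_rate = 0.01)),
               "false-positive")
})

test_that("stage-shift rules conserve mass and reject bad weights", {
  cases <- c(IA = 10)
  point <- apply_stage_shift(cases, c(IV = 1))
  expect_equal(unname(point["IV"]), 10)
  expect_equal(sum(point), sum(cases))
  split <- apply_stage_shift(cases, c(IIIB = 0.5, IV = 0.5))
  expect_equal(unname(split[c("IIIB", "IV")]), c(5, 5))
  expect_error(apply_stage_shift(cases, c(IV = 0.8)), "sum to 1")
  expect_error(apply_stage_shift(cases, c(X = 1)), "unknown stages")
})

test_that("counterfactual late-stage presentation yields fewer life-years", {
  p <- small_params(9)
  sp <- p$space
  # place one cohort of detected cases in screen-detected IA versus the
  # counterfactual clinical stage IV, then compare discounted life-years
  life_years <- function(state) {
    init <- stats::setNames(numeric(length(sp$all_states)), sp$all_states)
    init[state] <- 1000
    tr <- run_cohort(p, NULL, start_age = 65L, init = init, validate = FALSE)
    u <- utility_vector(p)
    u[] <- as.numeric(!grepl("^death", names(u)))
    accumulate_qalys(tr, u, list(effect = 0))
  }
  for (h in sp$histologies[c(1, 3)]) {
    ly_screen <- life_years(paste(h, "IA", "scr", sep = "|"))
    shifted <- apply_stage_shift(c(IA = 1000), p$config$shift_rule,
                                 sp$stages)
    target <- names(shifted)[shifted > 0]
    ly_counter <- life_years(paste(h, target, "clin", sep = "|"))
    expect_lt(ly_counter, ly_screen)
  }
})

test_that("no screening occurs outside the window; empty windows match no screening", {
  p <- small_params(10)
  tr_none <- run_cohort(p, NULL, start_age = 65L, validate = FALSE)
  sc_empty <- lc_scenario(70, 70)
  tr_empty <- run_cohort(p, sc_empty, start_age = 65L, validate = FALSE)
  expect_identical(unclass(tr_empty)[, ], unclass(tr_none)[, ])

  sc <- lc_scenario(70, 75)
  tr <- run_cohort(p, sc, start_age = 65L, validate = FALSE)
  ev <- trace_events(tr)
  expect_identical(ev$age[ev$round], 70:74)
})

test_that("zero-sensitivity screening changes only programme costs", {
  p <- small_params(11)
  tr0 <- p$truth
  tr0["sens"] <- 0
  p0 <- lc_parameters(tr0, p$mortality, p$space, p$discount, p$config)
  sc <- lc_scenario(55, 75)
  a <- evaluate_scenario(p0, sc, validate = FALSE)
  b <- evaluate_scenario(p0, NULL, validate = FALSE)
  expect_identical(a$qaly, b$qaly)
  programme <- sum(discount_factor(p$discount$cost, a$stream$cycle) *
                     a$stream$screening) * a$scale
  expect_equal(a$cost - b$cost, programme, tolerance = 1e-9)
  expect_gt(programme, 0)
})

test_that("screening shifts person-years to early stages and averts deaths", {
  p <- small_params(12)
  sc <- lc_scenario(55, Inf)
  tr_s <- run_cohort(p, sc, start_age = 55L, validate = FALSE)
  tr_n <- run_cohort(p, NULL, start_age = 55L, validate = FALSE)
  early <- grep("\\|(IA|IB)\\|", colnames(tr_s))
  expect_gt(sum(tr_s[, early]), sum(tr_n[, early]))
  expect_lt(tr_s[nrow(tr_s), "death_lung_cancer"],
            tr_n[nrow(tr_n), "death_lung_cancer"])
})
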