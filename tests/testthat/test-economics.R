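test_that("discount factors follow 1/(1+r)^t", {
  expect_identical(discount_factor(0, 0:50), rep(1, 51))
  expect_equal(discount_factor(0.04, 1), 1 / 1.04)
  f <- 1
  for (t in 1:10) {
    f <- f / 1.015
    expect_equal(discount_factor(0.015, t), f, tolerance = 1e-12)
  }
  expect_equal(discount_factor(0.04, 3, timing = "begin"),
               discount_factor(0.04, 2))
})

test_that("cost accumulation matches a per-cell brute-force oracle", {
  p <- small_params(13)
  sc <- lc_scenario(55, 70)
  tr <- run_cohort(p, sc, start_age = 55L, validate = FALSE)
  costs <- cost_table(p)
  total <- accumulate_costs(tr, costs, p$discount)

  # brute force: loop over every cycle and category
  ev <- trace_events(tr)
  det <- trace_detections(tr)
  oracle <- 0
  for (t in seq_len(nrow(ev))) {
    df <- 1 / (1 + p$discount$cost)^t
    cyc <- ev$screened[t] * costs$ldct + ev$detected_scr[t] * costs$workup +
      ev$lc_deaths[t] * costs$palliative
    for (s in colnames(det))
      if (det[t, s] > 0) cyc <- cyc + det[t, s] * costs$treatment[[s]]
    oracle <- oracle + df * cyc
  }
  expect_equal(as.numeric(total), oracle, tolerance = 1e-9)

  # linearity: doubling every cost entry doubles the total
  costs2 <- costs
  for (nm in c("ldct", "workup", "palliative")) costs2[[nm]] <- 2 * costs2[[nm]]
  costs2$treatment <- 2 * costs2$treatment
  expect_equal(as.numeric(accumulate_costs(tr, costs2, p$discount)),
               2 * as.numeric(total), tolerance = 1e-9)

  # all-zero costs give zero
  costs0 <- costs
  costs0$ldct <- costs0$workup <- costs0$palliative <- 0
  costs0$treatment <- 0 * costs0$treatment
  expect_equal(as.numeric(accumulate_costs(tr, costs0, p$discount)), 0)
})

test_that("discounting can only shrink non-negative streams", {
  p <- small_params(13)
  tr <- run_cohort(p, lc_scenario(55, Inf), start_age = 55L, validate = FALSE)
  costs <- cost_table(p)
  disc <- as.numeric(accumulate_costs(tr, costs, list(cost = 0.04)))
  undisc <- as.numeric(accumulate_costs(tr, costs, list(cost = 0)))
  expect_lt(disc, undisc)
  expect_equal(undisc, sum(cost_stream(tr, costs)$total), tolerance = 1e-9)
})

test_that("QALY accumulation matches its oracle and is monotone in utilities", {
  p <- small_params(14)
  tr <- run_cohort(p, NULL, start_age = 65L, validate = FALSE)
  u <- utility_vector(p)
  q <- accumulate_qalys(tr, u, p$discount)
  oracle <- 0
  for (t in 2:nrow(tr))
    oracle <- oracle + sum(tr[t, ] * u[colnames(tr)]) /
      (1 + p$discount$effect)^(t - 1)
  expect_equal(q, oracle, tolerance = 1e-9)

  # utilities of 1 at zero discount equal life-years; utilities of 0 give 0
  u1 <- u; u1[] <- as.numeric(!grepl("^death", names(u1)))
  ly <- accumulate_qalys(tr, u1, list(effect = 0))
  expect_equal(ly, sum(tr[-1, !grepl("^death", colnames(tr))]),
               tolerance = 1e-9)
  u0 <- u; u0[] <- 0
  expect_equal(accumulate_qalys(tr, u0, p$discount), 0)

  # raising any single utility weight cannot lower the total
  u2 <- u
  u2["recurrence"] <- min(1, u2["recurrence"] + 0.1)
  expect_gte(accumulate_qalys(tr, u2, p$discount), q)

  expect_error(accumulate_qalys(tr, u + 1.5, p$discount), "\\[-1, 1\\]")
  expect_error(accumulate_qalys(tr, u[-1], p$discount), "missing")
})

test_that("palliative costs charge each lung-cancer death at its cycle", {
  p <- small_params(15)
  tr <- run_cohort(p, NULL, start_age = 60L, validate = FALSE)
  costs <- cost_table(p)
  ev <- trace_events(tr)
  oracle <- sum(ev$lc_deaths * costs$palliative /
                  (1 + p$discount$cost)^ev$cycle)
  expect_equal(terminal_palliative_costs(tr, costs, p$discount), oracle,
               tolerance = 1e-9)
  # no deaths -> no cost: zero out the death flows
  attr(tr, "events")$lc_deaths <- 0
  expect_equal(terminal_palliative_costs(tr, costs, p$discount), 0)
})

test_that("hand-built flows reproduce closed-form discounted amounts", {
  # single person incurring EUR 100 in cycle 1 only, at 4 percent
  expect_equal(100 * discount_factor(0.04, 1), 96.15, tolerance = 1e-3)
  # 10 lung-cancer deaths in cycle 2 with palliative cost C
  C <- 12000
  expect_equal(10 * C * discount_factor(0.04, 2), 10 * C / 1.04^2)
})

test_that("missing treatment costs for occupied states raise errors", {
  p <- small_params(16)
  tr <- run_cohort(p, lc_scenario(55, Inf), start_age = 55L, validate = FALSE)
  costs <- cost_table(p)
  det_states <- colnames(trace_detections(tr))[colSums(trace_detections(tr)) > 0]
  costs$treatment <- costs$treatment[setdiff(names(costs$treatment),
                                             det_states[1L])]
  expect_error(cost_stream(tr, costs), "no treatment cost")
})
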