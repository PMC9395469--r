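test_that("moment matching hits the base mean for beta and gamma", {
  b <- fit_distribution(0.5, 0.4, 0.6, "beta")
  expect_identical(b$family, "beta")
  expect_equal(unname(b$pars["shape1"]), unname(b$pars["shape2"]))
  expect_equal(b$pars[["shape1"]] / sum(b$pars), 0.5, tolerance = 1e-9)

  g <- fit_distribution(1000, 900, 1100, "gamma")
  set.seed(1)
  draws <- stats::rgamma(1e5, g$pars[["shape"]], g$pars[["rate"]])
  expect_equal(mean(draws), 1000, tolerance = 0.01)
  # the range is read as a 95% central interval
  expect_equal(stats::sd(draws), 100 / stats::qnorm(0.975), tolerance = 0.02)

  d <- fit_distribution(0.3, 0.3, 0.3, "auto")
  expect_identical(d$family, "fixed")
  expect_error(fit_distribution(1.5, 1.4, 1.6, "beta"), "\\[0, 1\\]")
  expect_error(fit_distribution(5, 6, 4), "lo <= hi")
})

test_that("parameter sampling is seeded, mean-centred and respects support", {
  p <- tiny_params(1)
  spec <- generate_uncertainty_spec(p, 0.10)

  set.seed(11); a <- sample_parameter_set(p, spec)
  set.seed(11); b <- sample_parameter_set(p, spec)
  expect_identical(a$truth, b$truth)

  expect_identical(sample_parameter_set(p, spec[0, ])$truth, p$truth)

  # CLT check on leaves free of ordering constraints and renormalisation
  ids <- c("cost.ldct", "cost.workup", "cost.palliative", "sens",
           "p_present", "p_recurrence")
  set.seed(202)
  n <- 400L
  draws <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  for (i in seq_len(n)) draws[i, ] <- sample_parameter_set(p, spec)$truth[ids]
  for (id in ids) {
    se <- stats::sd(draws[, id]) / sqrt(n)
    expect_lt(abs(mean(draws[, id]) - p$truth[[id]]), 4 * se + 1e-12)
  }
  # every draw is a valid parameter set
  expect_true(all(apply(draws, 1, function(x) all(x >= 0))))
})

test_that("PSA with a degenerate spec reproduces the deterministic run bitwise", {
  p <- tiny_params(2)
  spec <- generate_uncertainty_spec(p, 0)  # width 0: point masses
  scen <- scenario_grid(starts = 60, stops = c(70, Inf))
  det <- lc_cea(p, scen)
  psa <- run_psa(p, spec, scen, n_draws = 3, seed = 5)
  for (d in unique(psa$draws$draw)) {
    sub <- psa$draws[psa$draws$draw == d, ]
    expect_identical(sub$cost, det$results$cost)
    expect_identical(sub$qaly, det$results$qaly)
  }
})

test_that("PSA draws are reproducible and centred on the base case", {
  p <- tiny_params(3)
  spec <- generate_uncertainty_spec(p, 0.10)
  scen <- scenario_grid(starts = 60, stops = Inf)
  psa1 <- run_psa(p, spec, scen, n_draws = 8, seed = 42)
  psa2 <- run_psa(p, spec, scen, n_draws = 8, seed = 42)
  expect_identical(psa1$draws, psa2$draws)

  psa <- run_psa(p, spec, scen, n_draws = 60, seed = 9)
  for (lab in psa$scenarios) {
    sub <- psa$draws[psa$draws$scenario == lab, ]
    base <- psa$base_results[psa$base_results$scenario == lab, ]
    se_c <- stats::sd(sub$cost) / sqrt(nrow(sub))
    se_q <- stats::sd(sub$qaly) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$cost) - base$cost), 4 * se_c)
    expect_lt(abs(mean(sub$qaly) - base$qaly), 4 * se_q)
  }
})

test_that("net monetary benefit is the linear WTP transform", {
  expect_equal(nmb(0, 1234, 10), -1234)
  # arithmetic on the published no-screening row
  expect_equal(nmb(20000, 18475224, 2520.9), 31942776)
  set.seed(3)
  w <- stats::runif(20, 0, 5e4); c0 <- stats::runif(20, 0, 1e6)
  q <- stats::runif(20, 0, 1e3)
  expect_equal(nmb(2 * w, c0, q) - nmb(w, c0, q), w * q)
})

test_that("CEAC matches exhaustive enumeration on hand-built draws", {
  set.seed(8)
  n_draws <- 50L
  labs <- c("A", "B", "C")
  draws <- expand.grid(draw = seq_len(n_draws), scenario = labs,
                       stringsAsFactors = FALSE)
  draws$cost <- stats::runif(nrow(draws), 0, 100)
  draws$qaly <- stats::runif(nrow(draws), 0, 10)
  grid <- seq(0, 40, by = 5)
  cc <- ceac(draws, grid)
  for (w in grid) {
    expect_equal(sum(cc$probability[cc$wtp == w]), 1, tolerance = 1e-9)
    counts <- stats::setNames(numeric(3), labs)
    for (d in seq_len(n_draws)) {
      sub <- draws[draws$draw == d, ]
      b <- w * sub$qaly - sub$cost
      counts[sub$scenario[which.max(b)]] <-
        counts[sub$scenario[which.max(b)]] + 1
    }
    for (lab in labs)
      expect_equal(cc$probability[cc$wtp == w & cc$scenario == lab],
                   unname(counts[lab]) / n_draws)
  }
  # single scenario: probability one everywhere
  one <- draws[draws$scenario == "A", ]
  cc1 <- ceac(one, grid)
  expect_true(all(cc1$probability == 1))
  # at WTP 0 the cheapest scenario wins most often
  cc0 <- ceac(draws, 0)
  mean_cost <- tapply(draws$cost, draws$scenario, mean)
  expect_identical(cc0$scenario[which.max(cc0$probability)],
                   names(which.min(mean_cost)))
})

test_that("CEAF selects the expected-NMB maximiser and degenerates correctly", {
  set.seed(12)
  labs <- c("cheap", "mid", "dear")
  draws <- expand.grid(draw = 1:40, scenario = labs,
                       stringsAsFactors = FALSE)
  base <- data.frame(scenario = labs, cost = c(10, 50, 120),
                     qaly = c(1, 3, 5))
  m <- match(draws$scenario, base$scenario)
  draws$cost <- base$cost[m] + stats::rnorm(nrow(draws), 0, 2)
  draws$qaly <- base$qaly[m] + stats::rnorm(nrow(draws), 0, 0.05)
  grid <- seq(0, 60, by = 1)
  fr <- ceaf(draws, grid)
  cc <- ceac(draws, grid)
  for (i in seq_len(nrow(fr))) {
    w <- fr$wtp[i]
    agg <- tapply(w * draws$qaly - draws$cost, draws$scenario, mean)
    expect_identical(fr$scenario[i], names(which.max(agg)))
    expect_equal(fr$probability[i],
                 cc$probability[cc$wtp == w & cc$scenario == fr$scenario[i]])
    # the frontier never exceeds the maximum CEAC at that WTP
    expect_lte(fr$probability[i], max(cc$probability[cc$wtp == w]) + 1e-12)
  }

  # zero variance: frontier switch-points sit at the deterministic ICERs
  dd <- expand.grid(draw = 1:5, scenario = labs, stringsAsFactors = FALSE)
  mm <- match(dd$scenario, base$scenario)
  dd$cost <- base$cost[mm]; dd$qaly <- base$qaly[mm]
  # offset grid so no grid point ties exactly at an ICER
  fr0 <- ceaf(dd, seq(0.25, 60.25, by = 0.5))
  expect_true(all(fr0$probability == 1))
  sw <- ceaf_switchpoints(fr0)
  icers <- c((50 - 10) / (3 - 1), (120 - 50) / (5 - 3))  # 20, 35
  expect_equal(sw$wtp, icers + 0.25, tolerance = 1e-9)
})

test_that("PSA results do not depend on scenario evaluation order", {
  p <- tiny_params(4)
  spec <- generate_uncertainty_spec(p, 0.10)
  scen <- scenario_grid(starts = 60, stops = c(70, Inf))
  a <- run_psa(p, spec, scen, n_draws = 4, seed = 77)
  b <- run_psa(p, spec, rev(scen), n_draws = 4, seed = 77)
  key <- function(x) x$draws[order(x$draws$draw, x$draws$scenario), ]
  ka <- key(a); kb <- key(b)
  rownames(ka) <- rownames(kb) <- NULL
  expect_identical(ka, kb)
})
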