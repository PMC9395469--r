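#' Default multi-age population structure
#'
#' The screened population is modelled as closed cohorts entering at each
#' start age. The default takes the age-group structure stored in the
#' parameter set's config (10,000 persons per group).
#'
#' @param params An `lc_params` object.
#' @return Data frame with columns `start_age` and `n`.
#' @export
default_population <- function(params) {
  cfg <- params$config
  ages <- cfg$age_groups
  if (is.null(ages)) ages <- seq(50L, 95L, by = 5L)
  n <- cfg$group_size
  if (is.null(n)) n <- 10000
  data.frame(start_age = as.integer(ages), n = rep(n, length(ages)))
}

#' Evaluate one screening scenario over the multi-age population
#'
#' Runs each start-age cohort separately, accumulates discounted costs and
#' QALYs, pools the cohorts, and normalises to a per-100,000-person scale.
#'
#' @param params An `lc_params` object.
#' @param scenario An `lc_scenario` or `NULL` for no screening.
#' @param population Data frame with columns `start_age`, `n`; default
#'   [default_population()].
#' @param keep_traces Keep the per-cohort traces in the result.
#' @param validate Validate `params` once up front.
#' @param cache Optional environment memoising per-age transition matrices
#'   across cohorts and scenarios of the same parameter set.
#' @return List with elements `label`, `cost`, `qaly` (discounted, per
#'   100,000 persons), `stream` (pooled undiscounted cost stream), `events`
#'   (pooled per-cycle event flows) and optionally `traces`.
#' @export
evaluate_scenario <- function(params, scenario = NULL, population = NULL,
                              keep_traces = FALSE, validate = TRUE,
                              cache = NULL) {
  if (validate) {
    rep <- validate_parameters(params)
    if (nrow(rep))
      stop("invalid parameter set: ", rep$check[1L], " at ", rep$where[1L])
  }
  if (is.null(population)) population <- default_population(params)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  costs <- cost_table(params)
  u <- utility_vector(params)
  half <- isTRUE(params$config$half_cycle)
  scale <- 1e5 / sum(population$n)

  total_cost <- 0; total_qaly <- 0
  Tmax <- max(params$config$max_age - population$start_age)
  stream <- data.frame(cycle = seq_len(Tmax), screening = 0, treatment = 0,
                       palliative = 0, chronic = 0, total = 0)
  ev_pool <- data.frame(cycle = seq_len(Tmax), screened = 0, detected_scr = 0,
                        detected_clin = 0, lc_deaths = 0)
  traces <- if (keep_traces) list() else NULL
  for (g in seq_len(nrow(population))) {
    tr <- run_cohort(params, scenario, start_age = population$start_age[g],
                     size = population$n[g], validate = FALSE, cache = cache)
    dc <- accumulate_costs(tr, costs, params$discount)
    total_cost <- total_cost + as.numeric(dc)
    total_qaly <- total_qaly +
      accumulate_qalys(tr, u, params$discount, half_cycle = half)
    st <- attr(dc, "stream")
    for (col in c("screening", "treatment", "palliative", "chronic", "total"))
      stream[[col]][st$cycle] <- stream[[col]][st$cycle] + st[[col]]
    ev <- trace_events(tr)
    for (col in c("screened", "detected_scr", "detected_clin", "lc_deaths"))
      ev_pool[[col]][ev$cycle] <- ev_pool[[col]][ev$cycle] + ev[[col]]
    if (keep_traces) traces[[g]] <- tr
  }
  list(label = if (is.null(scenario)) "no screening" else scenario$label,
       cost = total_cost * scale, qaly = total_qaly * scale,
       stream = stream, events = ev_pool, scale = scale, traces = traces)
}

#' Cost-effectiveness analysis of a set of screening scenarios
#'
#' The package's central constructor: runs the Markov cohort model for every
#' scenario (including the no-screening reference), accumulates discounted
#' costs and QALYs per 100,000 persons, and derives the efficiency frontier,
#' sequential ICERs, CERs versus no screening and budget-impact streams.
#'
#' @param params An `lc_params` object.
#' @param scenarios Named list of `lc_scenario` objects; a `NULL` entry is
#'   the no-screening reference. Default: [scenario_grid()].
#' @param population Data frame with columns `start_age`, `n`; default
#'   [default_population()].
#' @param reference Label of the reference scenario.
#' @param keep_traces Keep per-cohort traces.
#' @return An object of class `lc_cea` with elements `results` (scenario,
#'   cost, qaly), `table` ([table1_report()] output), `streams`, `events`,
#'   `reference`, `params`.
#' @export
lc_cea <- function(params, scenarios = scenario_grid(), population = NULL,
                   reference = "no screening", keep_traces = FALSE) {
  rep <- validate_parameters(params)
  if (nrow(rep))
    stop("invalid parameter set: ", rep$check[1L], " at ", rep$where[1L])
  if (is.null(population)) population <- default_population(params)
  labels <- names(scenarios)
  if (is.null(labels))
    labels <- vapply(scenarios, function(s)
      if (is.null(s)) "no screening" else s$label, character(1))
  cache <- new.env(parent = emptyenv())
  evals <- lapply(seq_along(scenarios), function(i)
    evaluate_scenario(params, scenarios[[i]], population,
                      keep_traces = keep_traces, validate = FALSE,
                      cache = cache))
  results <- data.frame(
    scenario = labels,
    cost = vapply(evals, `[[`, numeric(1), "cost"),
    qaly = vapply(evals, `[[`, numeric(1), "qaly"))
  streams <- stats::setNames(lapply(evals, `[[`, "stream"), labels)
  events <- stats::setNames(lapply(evals, `[[`, "events"), labels)
  tab <- table1_report(results, reference = reference)
  structure(list(results = results, table = tab, streams = streams,
                 events = events, reference = reference, params = params,
                 population = population,
                 traces = if (keep_traces)
                   stats::setNames(lapply(evals, `[[`, "traces"), labels)
                 else NULL),
            class = "lc_cea")
}

#' @export
print.lc_cea <- function(x, ...) {
  print(x$table)
  invisible(x)
}

#' @export
summary.lc_cea <- function(object, wtp = 20000, ...) {
  tab <- object$table
  on_frontier <- tab$scenario[tab$status == "on_frontier"]
  below <- tab$scenario[!is.na(tab$icer_seq) & tab$icer_seq <= wtp]
  structure(list(table = tab, wtp = wtp, on_frontier = on_frontier,
                 below_threshold = below, reference = object$reference),
            class = "summary.lc_cea")
}

#' @export
print.summary.lc_cea <- function(x, ...) {
  print(x$table)
  cat(sprintf("\nFrontier: %s\n", paste(x$on_frontier, collapse = " -> ")))
  cat(sprintf("Sequential ICERs at or below EUR %s/QALY: %s\n",
              formatC(x$wtp, format = "d", big.mark = ","),
              if (length(x$below_threshold))
                paste(x$below_threshold, collapse = ", ") else "none"))
  invisible(x)
}

#' Plot the efficiency frontier
#'
#' Cost-QALY scatter of all scenarios with the frontier segments drawn
#' through the non-dominated entries; extended-dominated scenarios are
#' marked with open symbols.
#'
#' @param x An `lc_cea` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.lc_cea <- function(x, ...) {
  tab <- x$table
  on <- tab$status == "on_frontier"
  graphics::plot(tab$qaly, tab$cost, pch = ifelse(on, 19, 1),
                 xlab = "Discounted QALYs (per 100,000)",
                 ylab = "Discounted costs (EUR, per 100,000)", ...)
  graphics::lines(tab$qaly[on], tab$cost[on], lty = 2)
  graphics::text(tab$qaly, tab$cost, tab$scenario, pos = 3, cex = 0.7)
  invisible(x)
}
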