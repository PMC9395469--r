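#' Moment-matched uncertainty distribution for one parameter
#'
#' Probabilities and utilities receive a beta distribution, costs a gamma
#' distribution. The stated `(lo, hi)` range is read as a 95% central
#' interval, converted to a standard deviation via the normal approximation
#' `sd = (hi - lo) / (2 * 1.96)`; hyperparameters are then moment-matched so
#' the distribution mean equals the base value. A zero-width range yields a
#' point mass (`family = "fixed"`).
#'
#' @param base Base (mean) value.
#' @param lo,hi Range bounds (95% central interval).
#' @param family `"beta"`, `"gamma"`, `"fixed"` or `"auto"` (beta if the
#'   base and range lie in [0, 1], otherwise gamma).
#' @return List with elements `family`, `pars` (named hyperparameters),
#'   `mean`.
#' @export
fit_distribution <- function(base, lo, hi, family = "auto") {
  if (hi < lo) stop("range must satisfy lo <= hi")
  if (family == "auto")
    family <- if (base >= 0 && base <= 1 && lo >= 0 && hi <= 1) "beta"
              else "gamma"
  sd <- (hi - lo) / (2 * stats::qnorm(0.975))
  if (sd == 0 || family == "fixed")
    return(list(family = "fixed", pars = c(value = base), mean = base))
  if (family == "beta") {
    if (base < 0 || base > 1) stop("beta requires a base value in [0, 1]")
    if (base == 0 || base == 1)
      return(list(family = "fixed", pars = c(value = base), mean = base))
    vmax <- base * (1 - base)
    v <- min(sd^2, 0.95 * vmax)
    k <- vmax / v - 1
    return(list(family = "beta",
                pars = c(shape1 = base * k, shape2 = (1 - base) * k),
                mean = base))
  }
  if (family == "gamma") {
    if (base < 0) stop("gamma requires a non-negative base value")
    if (base == 0)
      return(list(family = "fixed", pars = c(value = 0), mean = 0))
    shape <- (base / sd)^2
    return(list(family = "gamma",
                pars = c(shape = shape, rate = shape / base), mean = base))
  }
  stop("unknown distribution family: ", family)
}

.sample_distribution <- function(dist, n = 1L) {
  switch(dist$family,
         fixed = rep(dist$pars[["value"]], n),
         beta = stats::rbeta(n, dist$pars[["shape1"]], dist$pars[["shape2"]]),
         gamma = stats::rgamma(n, dist$pars[["shape"]], dist$pars[["rate"]]),
         stop("unknown distribution family: ", dist$family))
}

.is_prob_leaf <- function(id) {
  grepl("^(mix|cdist|sdist|death|cure|prog|onset)\\.", id) |
    id %in% c("p_recurrence", "death_recur", "sens", "p_present") |
    grepl("^u\\.", id)
}

#' Draw a parameter set from its uncertainty specification
#'
#' Samples every parameter listed in the spec from its fitted distribution
#' (beta for probabilities and utilities, gamma for costs), rebuilds the
#' parameter set, proportionally renormalises the simplex groups (histology
#' mix, stage distributions), and validates the result; invalid draws (e.g.
#' a non-monotone stage ladder) are redrawn, with the redraw count recorded
#' in attribute `"redraws"`. Uses the current RNG state: seed the caller for
#' reproducibility. An empty spec returns the base set unchanged.
#'
#' @param base An `lc_params` object.
#' @param spec Uncertainty specification data frame with columns
#'   `parameter_id`, `base`, `family`, `lo`, `hi` (see
#'   [generate_uncertainty_spec()]).
#' @param max_redraws Redraw budget before giving up.
#' @return A valid `lc_params` object.
#' @export
sample_parameter_set <- function(base, spec, max_redraws = 100L) {
  if (is.null(spec) || nrow(spec) == 0L) return(base)
  dists <- lapply(seq_len(nrow(spec)), function(i)
    fit_distribution(spec$base[i], spec$lo[i], spec$hi[i], spec$family[i]))
  ids <- spec$parameter_id
  unknown <- setdiff(ids, names(base$truth))
  if (length(unknown))
    stop("uncertainty spec names unknown parameters: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  all_fixed <- all(vapply(dists, `[[`, character(1), "family") == "fixed")
  if (all_fixed && all(spec$base == base$truth[ids])) {
    # fully degenerate spec at the base values: the draw IS the base set,
    # bit for bit (no renormalisation noise)
    attr(base, "redraws") <- 0L
    return(base)
  }

  for (attempt in seq_len(max_redraws + 1L)) {
    truth <- base$truth
    truth[ids] <- vapply(dists, .sample_distribution, numeric(1))
    # clip probability leaves to the unit interval, then renormalise simplexes
    pr <- .is_prob_leaf(names(truth))
    truth[pr] <- pmin(pmax(truth[pr], 0), 1)
    renorm <- function(prefix_ids) {
      s <- sum(truth[prefix_ids])
      if (s > 0) truth[prefix_ids] <<- truth[prefix_ids] / s
    }
    H <- base$space$histologies; S <- base$space$stages
    renorm(paste("mix", H, sep = "."))
    for (h in H) {
      renorm(paste("cdist", h, S, sep = "."))
      renorm(paste("sdist", h, S, sep = "."))
    }
    p <- try(lc_parameters(truth, base$mortality, base$space, base$discount,
                           base$config, validate = FALSE), silent = TRUE)
    if (!inherits(p, "try-error")) {
      # component checks only: induced matrices are row-stochastic by
      # construction once the leaf invariants hold
      rep <- validate_parameters(p, ages = integer(0))
      if (!nrow(rep)) {
        attr(p, "redraws") <- attempt - 1L
        return(p)
      }
    }
    if (all_fixed) stop("degenerate uncertainty spec yields an invalid set")
  }
  stop("failed to draw a valid parameter set within ", max_redraws,
       " redraws")
}

.draw_seed <- function(seed, i) {
  (as.numeric(seed) * 69069 + i * 7919) %% 2147483647
}

#' Probabilistic sensitivity analysis
#'
#' Propagates parameter uncertainty through the full scenario evaluation by
#' Monte Carlo: for each draw one parameter set is sampled and every scenario
#' is evaluated under it (common random parameters across scenarios), giving
#' a per-draw, per-scenario discounted cost and QALY total. Draws are seeded
#' independently by draw index from the top-level seed, so runs are
#' reproducible and resumable by index.
#'
#' @param params Base `lc_params` object.
#' @param spec Uncertainty specification (see [generate_uncertainty_spec()]).
#' @param scenarios Named list of scenarios as in [lc_cea()].
#' @param population Population structure; default [default_population()].
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Top-level seed.
#' @param wtp_grid Willingness-to-pay grid (euros/QALY) stored for CEAC/CEAF.
#' @return An object of class `lc_psa` with elements `draws` (data frame
#'   `draw`, `scenario`, `cost`, `qaly`), `scenarios`, `base_results`,
#'   `wtp_grid`, `seed`, `redraws`.
#' @export
run_psa <- function(params, spec, scenarios = scenario_grid(),
                    population = NULL, n_draws = 200L, seed = 1L,
                    wtp_grid = seq(0, 50000, by = 100)) {
  stopifnot(n_draws >= 1L)
  rep <- validate_parameters(params)
  if (nrow(rep))
    stop("invalid parameter set: ", rep$check[1L], " at ", rep$where[1L])
  if (is.null(population)) population <- default_population(params)
  labels <- names(scenarios)
  base_cache <- new.env(parent = emptyenv())
  base_res <- lapply(scenarios, function(s)
    evaluate_scenario(params, s, population, validate = FALSE,
                      cache = base_cache))
  base_results <- data.frame(
    scenario = labels,
    cost = vapply(base_res, `[[`, numeric(1), "cost"),
    qaly = vapply(base_res, `[[`, numeric(1), "qaly"))

  rows <- vector("list", n_draws)
  redraws <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    set.seed(.draw_seed(seed, i))
    p_i <- sample_parameter_set(params, spec)
    redraws[i] <- attr(p_i, "redraws") %||% 0L
    cache_i <- new.env(parent = emptyenv())
    ev <- lapply(scenarios, function(s)
      evaluate_scenario(p_i, s, population, validate = FALSE,
                        cache = cache_i))
    rows[[i]] <- data.frame(
      draw = i, scenario = labels,
      cost = vapply(ev, `[[`, numeric(1), "cost"),
      qaly = vapply(ev, `[[`, numeric(1), "qaly"))
  }
  structure(list(draws = do.call(rbind, c(rows, make.row.names = FALSE)),
                 scenarios = labels, base_results = base_results,
                 wtp_grid = wtp_grid, seed = seed, redraws = redraws),
            class = "lc_psa")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Net monetary benefit
#'
#' @param wtp Willingness to pay (euros per QALY).
#' @param cost Discounted cost (euros).
#' @param qalys Discounted QALYs.
#' @return `wtp * qalys - cost` (vectorised).
#' @export
nmb <- function(wtp, cost, qalys) wtp * qalys - cost

.draws_matrices <- function(draws, scenarios = NULL) {
  if (inherits(draws, "lc_psa")) {
    scenarios <- scenarios %||% draws$scenarios
    draws <- draws$draws
  }
  scenarios <- scenarios %||% unique(draws$scenario)
  ids <- sort(unique(draws$draw))
  C <- matrix(NA_real_, length(ids), length(scenarios),
              dimnames = list(ids, scenarios))
  Q <- C
  ri <- match(draws$draw, ids)
  ci <- match(draws$scenario, scenarios)
  C[cbind(ri, ci)] <- draws$cost
  Q[cbind(ri, ci)] <- draws$qaly
  if (anyNA(C) || anyNA(Q)) stop("draws are not complete over scenarios")
  list(C = C, Q = Q, scenarios = scenarios)
}

#' Cost-effectiveness acceptability curves
#'
#' For every willingness-to-pay value, the fraction of PSA draws in which
#' each scenario attains the maximum net monetary benefit (ties split
#' equally). Probabilities over scenarios sum to 1 at every WTP.
#'
#' @param draws An `lc_psa` object or its `draws` data frame.
#' @param wtp_grid WTP grid (euros/QALY); defaults to the grid stored in the
#'   `lc_psa` object.
#' @return Data frame of class `lc_ceac` with columns `wtp`, `scenario`,
#'   `probability`.
#' @export
ceac <- function(draws, wtp_grid = NULL) {
  if (inherits(draws, "lc_psa")) wtp_grid <- wtp_grid %||% draws$wtp_grid
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 50000, by = 100)
  m <- .draws_matrices(draws)
  n <- nrow(m$C)
  out <- lapply(wtp_grid, function(w) {
    b <- nmb(w, m$C, m$Q)
    mx <- apply(b, 1L, max)
    win <- b >= mx - abs(mx) * 1e-12 - 1e-9
    p <- colSums(win / rowSums(win)) / n
    data.frame(wtp = w, scenario = m$scenarios, probability = unname(p))
  })
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("lc_ceac", "data.frame"))
}

#' Cost-effectiveness acceptability frontier
#'
#' At each willingness-to-pay value, selects the scenario with the highest
#' expected net monetary benefit over the PSA draws and reports that
#' scenario's CEAC probability. The WTP values at which the selection
#' changes are the frontier's switch points.
#'
#' @inheritParams ceac
#' @return Data frame of class `lc_ceaf` with columns `wtp`, `scenario`,
#'   `probability`.
#' @export
ceaf <- function(draws, wtp_grid = NULL) {
  if (inherits(draws, "lc_psa")) wtp_grid <- wtp_grid %||% draws$wtp_grid
  if (is.null(wtp_grid)) wtp_grid <- seq(0, 50000, by = 100)
  m <- .draws_matrices(draws)
  cc <- ceac(draws, wtp_grid)
  mean_c <- colMeans(m$C)
  mean_q <- colMeans(m$Q)
  out <- lapply(wtp_grid, function(w) {
    eb <- nmb(w, mean_c, mean_q)
    best <- m$scenarios[which.max(eb)]
    p <- cc$probability[cc$wtp == w & cc$scenario == best]
    data.frame(wtp = w, scenario = best, probability = p)
  })
  structure(do.call(rbind, c(out, make.row.names = FALSE)),
            class = c("lc_ceaf", "data.frame"))
}

#' Switch points of an acceptability frontier
#'
#' @param frontier An `lc_ceaf` data frame.
#' @return Data frame with columns `wtp` (first WTP at which the selection
#'   changes), `from`, `to`.
#' @export
ceaf_switchpoints <- function(frontier) {
  ch <- which(frontier$scenario[-1L] != frontier$scenario[-nrow(frontier)])
  data.frame(wtp = frontier$wtp[ch + 1L],
             from = frontier$scenario[ch],
             to = frontier$scenario[ch + 1L])
}

#' @export
print.lc_psa <- function(x, ...) {
  n <- length(unique(x$draws$draw))
  cat(sprintf("Probabilistic sensitivity analysis: %d draws x %d scenarios (seed %s)\n",
              n, length(x$scenarios), format(x$seed)))
  agg <- stats::aggregate(cbind(cost, qaly) ~ scenario, x$draws, mean)
  agg <- agg[match(x$scenarios, agg$scenario), ]
  cat("Mean over draws (per 100,000):\n")
  print(data.frame(scenario = agg$scenario,
                   cost = round(agg$cost), qaly = round(agg$qaly, 1)),
        row.names = FALSE)
  if (sum(x$redraws) > 0)
    cat(sprintf("  %d invalid draws redrawn\n", sum(x$redraws)))
  invisible(x)
}

#' Plot CEAC curves and the acceptability frontier
#'
#' @param x An `lc_psa` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.lc_psa <- function(x, ...) {
  cc <- ceac(x)
  wide <- stats::reshape(cc, idvar = "wtp", timevar = "scenario",
                         direction = "wide")
  graphics::matplot(wide$wtp, as.matrix(wide[-1L]), type = "l", lty = 1,
                    xlab = "Willingness to pay (EUR/QALY)",
                    ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::legend("right", legend = x$scenarios, lty = 1,
                   col = seq_along(x$scenarios), cex = 0.7, bty = "n")
  fr <- ceaf(x)
  graphics::lines(fr$wtp, fr$probability, lwd = 3, col = "grey40")
  invisible(x)
}
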