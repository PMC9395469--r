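#' Per-cycle discount factor
#'
#' End-of-cycle convention by default: cycle 0 is undiscounted and cycle `t`
#' is divided by `(1 + rate)^t`. The begin-of-cycle convention shifts the
#' exponent by one cycle.
#'
#' @param rate Annual discount rate (>= 0).
#' @param cycle Cycle index (vectorised, >= 0).
#' @param timing `"end"` (default) or `"begin"`.
#' @return Numeric discount factor(s).
#' @export
discount_factor <- function(rate, cycle, timing = c("end", "begin")) {
  timing <- match.arg(timing)
  stopifnot(rate >= 0, all(cycle >= 0))
  expo <- if (timing == "end") cycle else pmax(cycle - 1, 0)
  (1 + rate)^(-expo)
}

.utility_vector <- function(params) {
  sp <- params$space
  u <- stats::setNames(numeric(length(sp$all_states)), sp$all_states)
  u["well"] <- params$u_well
  u["post_treatment"] <- params$u_post
  u["recurrence"] <- params$u_recur
  u[sp$undiag] <- params$u_well
  for (hi in seq_along(sp$histologies))
    for (v in sp$variants)
      u[.cancer_block(sp, hi, v)] <- params$u_stage
  u
}

#' State utility weights of a parameter set
#'
#' Expands the parameter set's utilities into a named vector over the full
#' internal state space. Undiagnosed preclinical disease carries the well
#' utility; both death states carry 0.
#'
#' @param params An `lc_params` object.
#' @return Named numeric vector over `params$space$all_states`.
#' @export
utility_vector <- function(params) .utility_vector(params)

#' Accumulate discounted QALYs over a trace
#'
#' Sums, over cycles 1..T, occupancy times state utility times the effect
#' discount factor. State membership is valued at cycle end (no half-cycle
#' correction by default); with `half_cycle = TRUE` each cycle contributes the
#' mean of its start and end occupancy.
#'
#' @param trace An `lc_trace` object.
#' @param utilities Named utility vector covering every state in the trace
#'   (see [utility_vector()]); death-state utilities must be 0.
#' @param discount List with element `effect` (annual rate), or a single
#'   rate.
#' @param timing Discounting convention, see [discount_factor()].
#' @param half_cycle Apply the half-cycle correction.
#' @return Total discounted QALYs (scalar).
#' @export
accumulate_qalys <- function(trace, utilities, discount = list(effect = 0.015),
                             timing = "end", half_cycle = FALSE) {
  rate <- if (is.list(discount)) discount$effect else discount
  states <- colnames(trace)
  miss <- setdiff(states, names(utilities))
  if (length(miss))
    stop("utilities missing for states: ", paste(utils::head(miss, 5),
                                                 collapse = ", "))
  u <- utilities[states]
  if (any(u < -1 | u > 1)) stop("utilities must lie in [-1, 1]")
  dead <- grep("^death", states)
  if (any(abs(u[dead]) > 0)) stop("death-state utilities must be 0")
  T <- nrow(trace) - 1L
  if (T < 1L) return(0)
  occ <- trace[-1L, , drop = FALSE]
  if (half_cycle)
    occ <- (occ + trace[-nrow(trace), , drop = FALSE]) / 2
  sum(discount_factor(rate, seq_len(T), timing) * as.vector(occ %*% u))
}

.cost_vectors <- function(params) {
  sp <- params$space
  treat <- stats::setNames(numeric(length(sp$all_states)), sp$all_states)
  for (hi in seq_along(sp$histologies))
    for (v in sp$variants)
      treat[.cancer_block(sp, hi, v)] <- params$cost_treat[hi, ]
  list(ldct = params$cost_ldct, workup = params$cost_workup,
       palliative = params$cost_palliative, treatment = treat,
       per_state = NULL)
}

#' Cost table of a parameter set
#'
#' Expands the parameter set's costs into the list layout the accumulation
#' functions consume: `ldct` (per person screened per round), `workup`
#' (PET + biopsy per screen-detected case), `palliative` (terminal six-month
#' cost per lung-cancer death), `treatment` (lump sum at detection, named
#' over all states, nonzero for cancer states) and optional `per_state`
#' annual chronic costs (default none).
#'
#' @param params An `lc_params` object.
#' @return Cost list as described.
#' @export
cost_table <- function(params) .cost_vectors(params)

#' Undiscounted per-cycle cost stream of a trace
#'
#' Splits programme and care costs by cycle and category: `screening` (LDCT
#' for every eligible alive undiagnosed participant at each round, plus
#' confirmation workup for screen-detected cases), `treatment` (lump sum per
#' newly detected case by histology/stage), `palliative` (terminal-phase cost
#' per lung-cancer death) and `chronic` (optional per-state annual cost).
#'
#' @param trace An `lc_trace` object.
#' @param costs Cost list, see [cost_table()].
#' @return Data frame with columns `cycle`, `screening`, `treatment`,
#'   `palliative`, `chronic`, `total` (euros, undiscounted).
#' @export
cost_stream <- function(trace, costs) {
  ev <- trace_events(trace)
  det <- trace_detections(trace)
  treat <- costs$treatment
  detected_states <- colnames(det)[colSums(det) > 0]
  miss <- setdiff(detected_states, names(treat)[!is.na(treat)])
  if (length(miss))
    stop("no treatment cost for occupied state(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  screening <- ev$screened * costs$ldct + ev$detected_scr * costs$workup
  treatment <- as.vector(det %*% treat[colnames(det)])
  palliative <- ev$lc_deaths * costs$palliative
  chronic <- if (is.null(costs$per_state)) numeric(nrow(ev)) else {
    ps <- costs$per_state
    missc <- setdiff(colnames(trace), names(ps))
    if (length(missc))
      stop("no chronic cost entry for occupied state(s): ",
           paste(utils::head(missc, 5), collapse = ", "))
    as.vector(trace[-1L, , drop = FALSE] %*% ps[colnames(trace)])
  }
  data.frame(cycle = ev$cycle, screening = screening, treatment = treatment,
             palliative = palliative, chronic = chronic,
             total = screening + treatment + palliative + chronic)
}

#' Total discounted cost of a trace
#'
#' Discounts the per-cycle cost stream of [cost_stream()] at the cost rate.
#' All event costs of cycle `t` (screening round, detections, lung-cancer
#' deaths) are discounted with that cycle's factor.
#'
#' @inheritParams cost_stream
#' @param discount List with element `cost` (annual rate), or a single rate.
#' @param timing Discounting convention, see [discount_factor()].
#' @return Total discounted cost in euros; the undiscounted stream is
#'   attached as attribute `"stream"`.
#' @export
accumulate_costs <- function(trace, costs, discount = list(cost = 0.04),
                             timing = "end") {
  rate <- if (is.list(discount)) discount$cost else discount
  st <- cost_stream(trace, costs)
  total <- sum(discount_factor(rate, st$cycle, timing) * st$total)
  attr(total, "stream") <- st
  total
}

#' Discounted terminal palliative-care costs
#'
#' Charges the six-month terminal palliative cost to each lung-cancer death,
#' discounted at the cycle of death.
#'
#' @inheritParams accumulate_costs
#' @return Discounted palliative cost (scalar, euros).
#' @export
terminal_palliative_costs <- function(trace, costs,
                                      discount = list(cost = 0.04),
                                      timing = "end") {
  rate <- if (is.list(discount)) discount$cost else discount
  ev <- trace_events(trace)
  sum(discount_factor(rate, ev$cycle, timing) * ev$lc_deaths *
        costs$palliative)
}
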