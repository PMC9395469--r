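#' Define a screening scenario
#'
#' A scenario schedules annual LDCT rounds at integer ages in
#' `[start_age, stop_age)`; `stop_age = Inf` (or `"lifetime"`) screens for
#' life. A scenario with `start_age == stop_age` performs zero rounds and is
#' equivalent to no screening.
#'
#' @param start_age First screening age (years).
#' @param stop_age Age at which screening stops (exclusive), or `"lifetime"`.
#' @param interval Years between rounds (the programme uses annual rounds).
#' @param label Scenario label; a default is derived from the ages.
#' @return An object of class `lc_scenario`.
#' @export
lc_scenario <- function(start_age, stop_age = Inf, interval = 1L,
                        label = NULL) {
  if (identical(stop_age, "lifetime")) stop_age <- Inf
  stopifnot(is.numeric(start_age), is.numeric(stop_age), start_age >= 0,
            interval >= 1)
  if (stop_age < start_age) stop("stop_age must be >= start_age")
  if (is.null(label))
    label <- if (is.infinite(stop_age)) sprintf("%d and older", start_age)
             else sprintf("%d-%d years", start_age, stop_age)
  structure(list(start_age = start_age, stop_age = stop_age,
                 interval = interval, label = label),
            class = "lc_scenario")
}

#' @export
print.lc_scenario <- function(x, ...) {
  cat(sprintf("Screening scenario '%s': annual LDCT at ages [%s, %s)\n",
              x$label, x$start_age,
              if (is.infinite(x$stop_age)) "lifetime" else x$stop_age))
  invisible(x)
}

#' The start/stop-age scenario grid
#'
#' All combinations of screening start ages and stop ages with
#' `stop > start`, plus the no-screening reference (`NULL` entry named
#' `"no screening"`). The default grid (starts 50/60/70, stops
#' 60/70/lifetime) yields the six screening strategies evaluated alongside no
#' screening: 50-60, 50-70, 50 and older, 60-70, 60 and older, 70 and older.
#'
#' @param starts Candidate start ages.
#' @param stops Candidate stop ages (`Inf` = lifetime).
#' @param include_reference Prepend the no-screening reference entry.
#' @return Named list of `lc_scenario` objects (the reference entry is
#'   `NULL`).
#' @export
scenario_grid <- function(starts = c(50L, 60L, 70L),
                          stops = c(60L, 70L, Inf),
                          include_reference = TRUE) {
  out <- list()
  if (include_reference) out["no screening"] <- list(NULL)
  for (a in sort(starts)) for (b in sort(stops)) {
    if (b > a) {
      sc <- lc_scenario(a, b)
      out[[sc$label]] <- sc
    }
  }
  out
}

#' NELSON-style eligibility for lung cancer screening
#'
#' Eligible are (ex-)smokers who smoked more than 30 years, at least 15
#' cigarettes per day, quit no more than 10 years ago (0 for current
#' smokers), and have reached the programme's minimum age.
#'
#' @param profile Data frame (or list) with columns `age`, `years_smoked`,
#'   `cigarettes_per_day`, `years_since_cessation`.
#' @param min_age Minimum age of the programme (years).
#' @return Logical vector, one entry per profile row.
#' @export
is_eligible <- function(profile, min_age = 50) {
  profile <- as.data.frame(profile)
  req <- c("age", "years_smoked", "cigarettes_per_day",
           "years_since_cessation")
  miss <- setdiff(req, names(profile))
  if (length(miss)) stop("profile lacks fields: ", paste(miss, collapse = ", "))
  if (any(unlist(profile[req]) < 0)) stop("profile fields must be >= 0")
  profile$years_smoked > 30 &
    profile$cigarettes_per_day >= 15 &
    profile$years_since_cessation <= 10 &
    profile$age >= min_age
}

#' Apply one screening round to undiagnosed prevalent cases
#'
#' Splits an occupancy array of undiagnosed cancer cases into screen-detected
#' and missed parts. A fraction `sens` of every cell is detected (the
#' PET-then-biopsy confirmation chain is assumed to add no false positives);
#' the rest are missed and remain eligible for the next round, so repeated
#' rounds detect missed cases geometrically.
#'
#' @param occupancy Non-negative numeric vector/matrix of undiagnosed cases
#'   (any shape, e.g. histology x stage).
#' @param cascade List with element `sens` (LDCT sensitivity in [0, 1]) and
#'   optionally `fp_rate` which must be 0.
#' @return List with elements `detected` and `missed`, same shape as the
#'   input, summing to it cell by cell.
#' @export
screen_round <- function(occupancy, cascade = list(sens = 0.9)) {
  if (any(occupancy < 0)) stop("occupancy must be non-negative")
  sens <- cascade$sens
  if (is.null(sens) || sens < 0 || sens > 1)
    stop("cascade$sens must be a probability")
  if (!is.null(cascade$fp_rate) && cascade$fp_rate != 0)
    stop("the diagnostic cascade assumes a zero false-positive rate")
  list(detected = occupancy * sens, missed = occupancy * (1 - sens))
}

#' Counterfactual presentation stage of screen-detected cases
#'
#' For screen-detected early-stage cases, returns the stage at which each
#' case would have presented clinically without screening, under a rule
#' assigning weights to the configured late stages (default: stage IV with
#' weight 1).
#'
#' @param cases Named numeric vector of screen-detected case counts by stage.
#' @param rule Named numeric weights over target late stages, summing to 1.
#' @param stages Full ordered stage vector defining the output layout.
#' @return Named numeric vector over `stages`: the counterfactual
#'   clinical-stage assignment (mass conserved).
#' @export
apply_stage_shift <- function(cases, rule = c(IV = 1),
                              stages = lc_stages) {
  if (any(cases < 0)) stop("case counts must be non-negative")
  if (abs(sum(rule) - 1) > 1e-9)
    stop("counterfactual rule weights must sum to 1")
  if (!all(names(rule) %in% stages))
    stop("rule targets unknown stages: ",
         paste(setdiff(names(rule), stages), collapse = ", "))
  out <- stats::setNames(numeric(length(stages)), stages)
  total <- sum(cases)
  out[names(rule)] <- out[names(rule)] + total * rule
  out
}
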