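#' Propagate a cohort one cycle
#'
#' Multiplies an occupancy vector by a one-cycle transition matrix. Total
#' occupancy is conserved because valid transition matrices are
#' row-stochastic.
#'
#' @param occupancy Numeric occupancy vector (persons per state).
#' @param mat Square transition matrix with matching dimension.
#' @return The occupancy vector after one cycle.
#' @export
step_cohort <- function(occupancy, mat) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat))
    stop("transition matrix must be square")
  if (length(occupancy) != nrow(mat))
    stop(sprintf("dimension mismatch: occupancy has length %d, matrix is %dx%d",
                 length(occupancy), nrow(mat), ncol(mat)))
  out <- as.vector(occupancy %*% mat)
  names(out) <- colnames(mat)
  out
}

.screening_round <- function(scenario, age) {
  if (is.null(scenario)) return(FALSE)
  age >= scenario$start_age && age < scenario$stop_age &&
    (age - scenario$start_age) %% scenario$interval == 0
}

#' Run the annual-cycle Markov cohort simulation
#'
#' Simulates a closed cohort entering at `start_age` over a lifetime horizon
#' (default: until age `params$config$max_age`). Within every cycle the event
#' order is fixed: screening detection (when the scenario schedules a round at
#' the cohort's current age), then clinical presentation, disease transitions
#' and death. Cycle 0 is the initial distribution.
#'
#' The returned trace records per-cycle state occupancy over the full internal
#' state vector together with the event flows economics needs: persons
#' screened per round, screen- and clinically-detected cases by cancer state,
#' and lung-cancer death increments.
#'
#' @param params An `lc_params` object (validated before any cycle runs).
#' @param scenario An `lc_scenario` or `NULL` for no screening.
#' @param start_age Entry age of the cohort (years).
#' @param size Cohort size (persons); everyone starts in `well` unless `init`
#'   is given.
#' @param horizon Number of cycles; default runs to `max_age - start_age`.
#' @param init Optional full initial occupancy vector over
#'   `params$space$all_states` (overrides `size`).
#' @param keep_matrices Store the per-cycle transition matrices in the trace
#'   (used by the matrix-product oracle; off by default).
#' @param validate Validate `params` first (default `TRUE`).
#' @param cache Optional environment memoising per-age disease matrices of
#'   this parameter set across cohorts and scenarios.
#' @return An object of class `lc_trace`: occupancy matrix of dimension
#'   `(horizon + 1) x n_states` with attributes `events`, `detections`,
#'   `start_age`, `size`, `scenario` and optionally `matrices`.
#' @export
run_cohort <- function(params, scenario = NULL, start_age = 50L,
                       size = 10000, horizon = NULL, init = NULL,
                       keep_matrices = FALSE, validate = TRUE,
                       cache = NULL) {
  if (validate) {
    rep <- validate_parameters(params, ages = start_age + c(0L, 10L, 30L))
    if (nrow(rep))
      stop("invalid parameter set: ", rep$check[1L], " at ", rep$where[1L])
  }
  sp <- params$space
  n <- length(sp$all_states)
  if (is.null(horizon))
    horizon <- max(1L, as.integer(params$config$max_age) - as.integer(start_age))
  if (horizon < 1L) stop("horizon must be at least one cycle")
  if (is.null(init)) {
    v <- numeric(n); names(v) <- sp$all_states
    v["well"] <- size
  } else {
    stopifnot(length(init) == n)
    v <- stats::setNames(as.numeric(init), sp$all_states)
    size <- sum(v)
  }

  trace <- matrix(0, horizon + 1L, n, dimnames = list(0:horizon, sp$all_states))
  detections <- matrix(0, horizon, n,
                       dimnames = list(1:horizon, sp$all_states))
  ev <- data.frame(cycle = 1:horizon, age = start_age + 0:(horizon - 1L),
                   round = FALSE, screened = 0, detected_scr = 0,
                   detected_clin = 0, lc_deaths = 0)
  trace[1L, ] <- v
  Sm <- NULL
  mats <- if (keep_matrices) vector("list", horizon) else NULL
  i_dlc <- 4L
  scr_cols <- unlist(lapply(seq_along(sp$histologies), .cancer_block,
                            space = sp, variant = "scr"))
  u_idx <- .undiag_index(sp)

  for (t in seq_len(horizon)) {
    age <- start_age + t - 1L
    active <- .screening_round(scenario, age)
    D <- if (is.null(cache)) transition_matrix(params, age, screening = FALSE)
         else {
           key <- paste0("D", age)
           if (is.null(cache[[key]]))
             cache[[key]] <- transition_matrix(params, age, screening = FALSE)
           cache[[key]]
         }
    if (active) {
      if (is.null(Sm)) Sm <- screening_matrix(params)
      ev$round[t] <- TRUE
      ev$screened[t] <- v["well"] + sum(v[u_idx])
      v_mid <- step_cohort(v, Sm)
      det_scr <- v_mid[scr_cols] - v[scr_cols]
      detections[t, scr_cols] <- det_scr
      ev$detected_scr[t] <- sum(det_scr)
    } else {
      v_mid <- v
    }
    qx <- .qx_at(params, age)
    for (hi in seq_along(sp$histologies)) {
      det_clin <- v_mid[u_idx[hi]] * (1 - qx) * params$p_present *
        params$cdist[hi, ]
      detections[t, .cancer_block(sp, hi, "clin")] <-
        detections[t, .cancer_block(sp, hi, "clin")] + det_clin
    }
    ev$detected_clin[t] <- sum(detections[t, ]) - ev$detected_scr[t]
    v_new <- step_cohort(v_mid, D)
    ev$lc_deaths[t] <- v_new[i_dlc] - v[i_dlc]
    if (keep_matrices) mats[[t]] <- if (active) Sm %*% D else D
    v <- v_new
    trace[t + 1L, ] <- v
  }

  structure(trace, class = "lc_trace", events = ev, detections = detections,
            start_age = start_age, size = size,
            scenario = if (is.null(scenario)) "no screening" else scenario$label,
            matrices = mats)
}

#' Per-cycle event flows of a cohort trace
#'
#' @param trace An `lc_trace` object.
#' @return Data frame with columns `cycle`, `age`, `round`, `screened`,
#'   `detected_scr`, `detected_clin`, `lc_deaths`.
#' @export
trace_events <- function(trace) attr(trace, "events")

#' Per-cycle detection inflows by cancer state
#'
#' @param trace An `lc_trace` object.
#' @return Matrix `cycles x states` of newly detected cases.
#' @export
trace_detections <- function(trace) attr(trace, "detections")

#' @export
print.lc_trace <- function(x, ...) {
  ev <- trace_events(x)
  alive_end <- sum(x[nrow(x), !colnames(x) %in%
                       c("death_lung_cancer", "death_other")])
  cat(sprintf("Cohort trace: %s, entry age %d, %d persons, %d cycles\n",
              attr(x, "scenario"), attr(x, "start_age"),
              round(attr(x, "size")), nrow(x) - 1L))
  cat(sprintf("  screening rounds: %d; screen-detected %.1f, clinically detected %.1f\n",
              sum(ev$round), sum(ev$detected_scr), sum(ev$detected_clin)))
  cat(sprintf("  lung-cancer deaths %.1f; alive at horizon end %.1f\n",
              sum(ev$lc_deaths), alive_end))
  invisible(x)
}
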