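#' Incremental cost and QALYs between two scenario results
#'
#' @param a,ref Scenario results: lists or one-row data frames with elements
#'   `cost` and `qaly` on the same normalisation (e.g. per 100,000 persons).
#' @return Named numeric vector `c(delta_cost, delta_qaly)`; signs are
#'   preserved.
#' @export
incremental <- function(a, ref) {
  c(delta_cost = as.numeric(a$cost) - as.numeric(ref$cost),
    delta_qaly = as.numeric(a$qaly) - as.numeric(ref$qaly))
}

#' Incremental cost-effectiveness ratio with dominance flags
#'
#' Returns the ratio `delta_cost / delta_qaly` when QALYs differ, together
#' with a flag classifying the quadrant: `"ratio"` for the usual north-east
#' (and south-west) cases, `"dominant"` when QALYs are gained at
#' non-positive extra cost, `"dominated"` when QALYs are lost at
#' non-negative extra cost, and `"equivalent"` when both differences are
#' zero. At `delta_qaly == 0` no ratio is formed.
#'
#' @param delta_cost Incremental cost (euros).
#' @param delta_qaly Incremental QALYs.
#' @return List with elements `value` (euros per QALY, `NA` when undefined)
#'   and `flag`.
#' @export
icer <- function(delta_cost, delta_qaly) {
  if (delta_qaly == 0) {
    flag <- if (delta_cost > 0) "dominated"
            else if (delta_cost < 0) "dominant" else "equivalent"
    return(list(value = NA_real_, flag = flag))
  }
  value <- delta_cost / delta_qaly
  flag <- if (delta_qaly > 0 && delta_cost <= 0) "dominant"
          else if (delta_qaly < 0 && delta_cost >= 0) "dominated"
          else "ratio"
  list(value = value, flag = flag)
}

.as_results <- function(results) {
  df <- as.data.frame(results)
  req <- c("scenario", "cost", "qaly")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("results lack columns: ", paste(miss, collapse = ", "))
  df$scenario <- as.character(df$scenario)
  df
}

#' Efficiency frontier with strict and extended dominance
#'
#' Sorts scenarios by increasing total discounted cost, removes strictly
#' dominated entries (at least as expensive, no more effective than some
#' other entry), then iteratively removes extended-dominated entries (those
#' whose sequential ICER exceeds that of the next more effective option)
#' until sequential ICERs along the frontier are strictly increasing.
#'
#' Ties: equal costs keep the higher-QALY entry; entries equal in both cost
#' and QALYs keep the first by label order (with a warning).
#'
#' @param results Data frame with columns `scenario`, `cost`, `qaly`.
#' @return Data frame sorted by cost with added columns `status`
#'   (`"on_frontier"`, `"dominated"` or `"extended_dominated"`) and
#'   `icer_seq` (sequential ICER in euros/QALY; `NA` off-frontier and for the
#'   cheapest frontier entry).
#' @export
efficiency_frontier <- function(results) {
  df <- .as_results(results)
  if (nrow(df) < 1L) stop("need at least one scenario result")
  ord <- order(df$cost, -df$qaly, df$scenario)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$status <- "on_frontier"
  df$icer_seq <- NA_real_

  if (anyDuplicated(df[c("cost", "qaly")]))
    warning("scenarios tied on both cost and QALYs; keeping first by label")

  # strict dominance: running QALY maximum over weakly cheaper entries
  best_q <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$qaly[i] <= best_q && i > 1L) {
      # equal cost & qaly ties: the first occurrence stays on the frontier
      tie <- df$qaly[i] == best_q &&
        any(df$cost[seq_len(i - 1L)] == df$cost[i] &
              df$qaly[seq_len(i - 1L)] == df$qaly[i] &
              df$status[seq_len(i - 1L)] == "on_frontier")
      df$status[i] <- "dominated"
      if (tie) df$status[i] <- "dominated"
    } else {
      best_q <- max(best_q, df$qaly[i])
    }
  }

  # extended dominance: enforce strictly increasing sequential ICERs
  repeat {
    cand <- which(df$status == "on_frontier")
    if (length(cand) <= 2L) break
    icers <- diff(df$cost[cand]) / diff(df$qaly[cand])
    viol <- which(diff(icers) <= 0)
    if (!length(viol)) break
    df$status[cand[viol[1L] + 1L]] <- "extended_dominated"
  }

  cand <- which(df$status == "on_frontier")
  if (length(cand) > 1L)
    df$icer_seq[cand[-1L]] <- diff(df$cost[cand]) / diff(df$qaly[cand])
  df
}

#' Cost-effectiveness ratios versus a common reference
#'
#' CER of each scenario against the reference (typically no screening):
#' `(cost - cost_ref) / (qaly - qaly_ref)`. The reference itself is excluded
#' from the output; zero QALY differences are flagged instead of divided.
#'
#' @param results Data frame with columns `scenario`, `cost`, `qaly`.
#' @param reference Label of the reference scenario (must be present).
#' @return Data frame with columns `scenario`, `delta_cost`, `delta_qaly`,
#'   `cer`, `flag`.
#' @export
cer_vs_reference <- function(results, reference = "no screening") {
  df <- .as_results(results)
  i <- match(reference, df$scenario)
  if (is.na(i)) stop("reference scenario not found: ", reference)
  ref <- df[i, ]
  out <- df[-i, c("scenario", "cost", "qaly")]
  out$delta_cost <- out$cost - ref$cost
  out$delta_qaly <- out$qaly - ref$qaly
  rr <- lapply(seq_len(nrow(out)),
               function(k) icer(out$delta_cost[k], out$delta_qaly[k]))
  out$cer <- vapply(rr, function(r)
    if (r$flag %in% c("ratio", "dominant") && !is.na(r$value)) r$value
    else NA_real_, numeric(1))
  out$flag <- vapply(rr, `[[`, character(1), "flag")
  rownames(out) <- NULL
  out[c("scenario", "delta_cost", "delta_qaly", "cer", "flag")]
}

#' Annual undiscounted budget impact of a scenario
#'
#' Per-cycle undiscounted cost difference between a scenario and the
#' reference. Streams of unequal length are zero-padded; the stream sums to
#' the undiscounted total incremental cost.
#'
#' @param stream,reference_stream Data frames from [cost_stream()] (or with
#'   columns `cycle` and `total`), pooled over cohorts.
#' @return Data frame with columns `cycle` and `incremental_cost` (euros per
#'   year, undiscounted).
#' @export
budget_impact <- function(stream, reference_stream) {
  pad <- function(x, T) { y <- numeric(T); y[x$cycle] <- x$total; y }
  T <- max(stream$cycle, reference_stream$cycle)
  data.frame(cycle = seq_len(T),
             incremental_cost = pad(stream, T) - pad(reference_stream, T))
}

#' Tabular cost-effectiveness report
#'
#' One row per scenario sorted by increasing total discounted cost, with the
#' dominance status, sequential ICERs for on-frontier rows, and incremental
#' cost, QALYs gained and CER versus the common reference for every
#' non-reference row. Extended-dominated rows are marked with an asterisk by
#' the print method.
#'
#' @param results Data frame with columns `scenario`, `cost`, `qaly`.
#' @param reference Label of the reference scenario.
#' @return Data frame of class `lc_cea_table`.
#' @export
table1_report <- function(results, reference = "no screening") {
  fr <- efficiency_frontier(results)
  if (reference %in% fr$scenario) {
    cer <- cer_vs_reference(results, reference)
    m <- match(fr$scenario, cer$scenario)
    fr$cost_vs_ref <- cer$delta_cost[m]
    fr$qaly_vs_ref <- cer$delta_qaly[m]
    fr$cer <- cer$cer[m]
  } else {
    fr$cost_vs_ref <- fr$qaly_vs_ref <- fr$cer <- NA_real_
  }
  structure(fr, class = c("lc_cea_table", "data.frame"),
            reference = reference)
}

#' @export
print.lc_cea_table <- function(x, ...) {
  eur <- function(v) ifelse(is.na(v), "",
                            formatC(round(v), format = "d", big.mark = ","))
  df <- data.frame(
    scenario = paste0(x$scenario,
                      ifelse(x$status == "extended_dominated", " *", "")),
    cost = eur(x$cost), qalys = formatC(x$qaly, format = "f", digits = 1),
    icer = eur(x$icer_seq), cost_vs_ref = eur(x$cost_vs_ref),
    qalys_gained = ifelse(is.na(x$qaly_vs_ref), "",
                          formatC(x$qaly_vs_ref, format = "f", digits = 1)),
    cer = eur(x$cer), check.names = FALSE)
  cat(sprintf("Cost-effectiveness report (reference: %s)\n",
              attr(x, "reference")))
  print(df, row.names = FALSE)
  if (any(x$status == "extended_dominated"))
    cat("* extended dominated scenario\n")
  if (any(x$status == "dominated"))
    cat("strictly dominated:",
        paste(x$scenario[x$status == "dominated"], collapse = ", "), "\n")
  invisible(x)
}
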