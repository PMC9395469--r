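#' Default histology labels
#'
#' Small-cell lung cancer plus the four histological types of non-small-cell
#' lung cancer distinguished by the model.
#' @export
lc_histologies <- c("SCLC", "adenocarcinoma", "squamous", "large_cell",
                    "other_NSCLC")

#' Default TNM stage groups
#'
#' The seven stage groups IA through IV, ordered by increasing severity.
#' @export
lc_stages <- c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IV")

.non_cancer_states <- c("well", "post_treatment", "recurrence",
                        "death_lung_cancer", "death_other")
.death_states <- c("death_lung_cancer", "death_other")
.variants <- c("clin", "scr")

#' Build the Markov health-state space
#'
#' Constructs the labelled state space of the natural-history model: five
#' non-cancer states (well, post-treatment, recurrence and the two absorbing
#' death states) plus one cancer state per (histology, stage) pair, each split
#' into a clinically detected (`clin`) and a screen-detected (`scr`) variant.
#' The ordering is stable and documented: non-cancer states first, then cancer
#' states histology-major, stage-minor, with the detection variant varying
#' fastest (`clin` before `scr`).
#'
#' In addition to the `states` vector the object carries `all_states`, which
#' appends one auxiliary undiagnosed-preclinical compartment per histology
#' (`undiag|<histology>`). The cohort engine propagates occupancy over
#' `all_states` so that detection dynamics remain part of a single
#' row-stochastic transition matrix.
#'
#' @param histologies Character vector of histology labels, or a single
#'   integer n taking the first n default labels (extended as `H6`, `H7`, ...
#'   beyond five).
#' @param stages Character vector of ordered stage labels.
#' @return An object of class `lc_states`.
#' @examples
#' sp <- build_state_space()
#' sp$n_states  # 5 + 2 * 5 * 7 = 75
#' @export
build_state_space <- function(histologies = lc_histologies,
                              stages = lc_stages) {
  if (is.numeric(histologies)) {
    n <- as.integer(histologies)
    if (length(n) != 1L || is.na(n) || n < 1L)
      stop("number of histologies must be a single integer >= 1")
    histologies <- if (n <= length(lc_histologies)) lc_histologies[seq_len(n)]
                   else c(lc_histologies, paste0("H", seq(6L, n)))
  }
  histologies <- as.character(histologies)
  stages <- as.character(stages)
  if (length(histologies) < 1L || length(stages) < 1L)
    stop("histologies and stages must be non-empty")
  if (anyDuplicated(histologies))
    stop("duplicate histology labels: ",
         paste(unique(histologies[duplicated(histologies)]), collapse = ", "))
  if (anyDuplicated(stages))
    stop("duplicate stage labels: ",
         paste(unique(stages[duplicated(stages)]), collapse = ", "))
  if (any(histologies %in% .non_cancer_states) ||
      any(stages %in% .non_cancer_states))
    stop("histology/stage labels clash with reserved state names")

  cancer <- as.vector(vapply(histologies, function(h)
    as.vector(vapply(stages, function(s)
      paste(h, s, .variants, sep = "|"), character(2L))),
    character(2L * length(stages))))
  undiag <- paste0("undiag|", histologies)
  states <- c(.non_cancer_states, cancer)
  structure(list(
    histologies = histologies,
    stages = stages,
    variants = .variants,
    non_cancer = .non_cancer_states,
    death_states = .death_states,
    cancer = cancer,
    states = states,
    undiag = undiag,
    all_states = c(states, undiag),
    n_states = length(states)
  ), class = "lc_states")
}

#' Index of a cancer state within the full state vector
#'
#' @param space An `lc_states` object.
#' @param histology,stage,variant State coordinates; `variant` is `"clin"` or
#'   `"scr"`.
#' @return Integer position in `space$all_states`.
#' @export
cancer_state <- function(space, histology, stage, variant = "clin") {
  hi <- match(histology, space$histologies)
  si <- match(stage, space$stages)
  vi <- match(variant, space$variants)
  if (anyNA(hi) || anyNA(si) || anyNA(vi))
    stop("unknown histology, stage or detection variant")
  length(space$non_cancer) +
    ((hi - 1L) * length(space$stages) + (si - 1L)) * 2L + vi
}

# positions of all cancer states of one histology and variant, stage-ordered
.cancer_block <- function(space, hi, variant) {
  vi <- match(variant, space$variants)
  length(space$non_cancer) +
    ((hi - 1L) * length(space$stages) + (seq_along(space$stages) - 1L)) * 2L + vi
}

.undiag_index <- function(space, hi = seq_along(space$histologies)) {
  space$n_states + hi
}

#' @export
print.lc_states <- function(x, ...) {
  cat("Lung cancer Markov state space\n")
  cat("  histologies:", paste(x$histologies, collapse = ", "), "\n")
  cat("  stages:     ", paste(x$stages, collapse = ", "), "\n")
  cat(sprintf("  %d model states (%d non-cancer + %d cancer), %d auxiliary undiagnosed\n",
              x$n_states, length(x$non_cancer), length(x$cancer),
              length(x$undiag)))
  invisible(x)
}
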