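#' Assemble a model parameter set
#'
#' Combines the flat named vector of disease, utility and cost parameters
#' (the "leaves", as produced by [generate_parameter_set()] or read back from
#' disk) with the all-cause mortality table and discounting specification into
#' a validated `lc_params` object used by the cohort engine.
#'
#' Leaf naming scheme (histology `h`, stage `s`, age `a`):
#' `mix.<h>` histology mix; `cdist.<h>.<s>` / `sdist.<h>.<s>` clinical and
#' screen-detected stage distributions; `death.<h>.<s>`, `cure.<h>.<s>`,
#' `prog.<h>.<s>` annual cancer-death, cure and stage-progression
#' probabilities; `onset.<a>` annual onset probability at age `a`;
#' `p_recurrence`, `death_recur`, `sens`, `p_present` scalars; `u.well`,
#' `u.post`, `u.recur`, `u.stage.<s>` utilities; `cost.ldct`, `cost.workup`,
#' `cost.palliative`, `treat.<h>.<s>` euro amounts.
#'
#' @param truth Named numeric vector of leaf parameters.
#' @param mortality Data frame with columns `age` and `qx` (annual all-cause
#'   death probability, WHO-life-table style).
#' @param space An `lc_states` object.
#' @param discount List with elements `cost` and `effect` (annual rates).
#' @param config Optional list of extra settings (e.g. `max_age`,
#'   `half_cycle`, `shift_rule`); defaults are filled in.
#' @param validate Run [validate_parameters()] (default `TRUE`).
#' @return An object of class `lc_params`.
#' @export
lc_parameters <- function(truth, mortality, space = build_state_space(),
                          discount = list(cost = 0.04, effect = 0.015),
                          config = list(), validate = TRUE) {
  truth <- unlist(truth)
  if (is.null(names(truth)) || anyNA(names(truth)))
    stop("parameter leaves must be named")
  stopifnot(is.data.frame(mortality), all(c("age", "qx") %in% names(mortality)))
  H <- space$histologies; S <- space$stages

  leaf_mat <- function(prefix) {
    m <- matrix(NA_real_, length(H), length(S), dimnames = list(H, S))
    for (h in H) for (s in S) {
      id <- paste(prefix, h, s, sep = ".")
      if (!id %in% names(truth)) stop("missing parameter leaf: ", id)
      m[h, s] <- truth[[id]]
    }
    m
  }
  leaf_vec <- function(prefix, labels) {
    ids <- paste(prefix, labels, sep = ".")
    miss <- setdiff(ids, names(truth))
    if (length(miss)) stop("missing parameter leaf: ", miss[1L])
    stats::setNames(truth[ids], labels)
  }
  scalar <- function(id) {
    if (!id %in% names(truth)) stop("missing parameter leaf: ", id)
    truth[[id]]
  }

  onset_ids <- grep("^onset\\.", names(truth), value = TRUE)
  if (!length(onset_ids)) stop("missing onset.<age> leaves")
  onset_age <- as.integer(sub("^onset\\.", "", onset_ids))
  onset <- stats::setNames(truth[onset_ids][order(onset_age)],
                           sort(onset_age))

  defaults <- list(max_age = 100L, half_cycle = FALSE,
                   shift_rule = stats::setNames(1, S[length(S)]),
                   currency_year = 2020L)
  config <- utils::modifyList(defaults, config)

  p <- structure(list(
    space = space,
    truth = truth,
    mix = leaf_vec("mix", H),
    cdist = leaf_mat("cdist"),
    sdist = leaf_mat("sdist"),
    p_death = leaf_mat("death"),
    p_cure = leaf_mat("cure"),
    p_prog = leaf_mat("prog"),
    onset = onset,
    p_recurrence = scalar("p_recurrence"),
    death_recur = scalar("death_recur"),
    sens = scalar("sens"),
    p_present = scalar("p_present"),
    u_well = scalar("u.well"),
    u_post = scalar("u.post"),
    u_recur = scalar("u.recur"),
    u_stage = leaf_vec("u.stage", S),
    cost_ldct = scalar("cost.ldct"),
    cost_workup = scalar("cost.workup"),
    cost_palliative = scalar("cost.palliative"),
    cost_treat = leaf_mat("treat"),
    mortality = mortality[order(mortality$age), c("age", "qx")],
    discount = discount,
    config = config
  ), class = "lc_params")

  if (validate) {
    rep <- validate_parameters(p)
    if (nrow(rep))
      stop("invalid parameter set:\n",
           paste(utils::head(paste(rep$check, rep$where, rep$detail, sep = " | "),
                             10L), collapse = "\n"))
  }
  p
}

#' Validate a parameter set
#'
#' Checks probability ranges, distribution normalisation, monotonicity of the
#' annual lung-cancer death probability in stage (a consistency requirement on
#' inputs), utility ordering and cost signs, and validates the per-age
#' transition matrices the set induces.
#'
#' @param params An `lc_params` object.
#' @param ages Ages at which induced transition matrices are checked
#'   (default: a spread over the mortality table range).
#' @return A data frame report with columns `check`, `where`, `detail`;
#'   zero rows iff valid.
#' @export
validate_parameters <- function(params, ages = NULL) {
  out <- list()
  bad <- function(check, where, detail)
    out[[length(out) + 1L]] <<- data.frame(check = check, where = where,
                                           detail = detail)
  S <- params$space$stages; H <- params$space$histologies

  probs <- list(mix = params$mix, cdist = params$cdist, sdist = params$sdist,
                p_death = params$p_death, p_cure = params$p_cure,
                p_prog = params$p_prog, onset = params$onset,
                scalars = c(p_recurrence = params$p_recurrence,
                            death_recur = params$death_recur,
                            sens = params$sens, p_present = params$p_present),
                qx = params$mortality$qx)
  for (nm in names(probs)) {
    v <- probs[[nm]]
    if (any(v < 0 | v > 1))
      bad("probability_range", nm, "entries outside [0, 1]")
  }
  if (abs(sum(params$mix) - 1) > 1e-9)
    bad("simplex", "mix", sprintf("sums to %.12f", sum(params$mix)))
  for (h in H) {
    for (d in c("cdist", "sdist")) {
      s <- sum(params[[d]][h, ])
      if (abs(s - 1) > 1e-9)
        bad("simplex", paste(d, h), sprintf("sums to %.12f", s))
    }
    dh <- params$p_death[h, ]
    if (any(diff(dh) <= 0))
      bad("stage_monotonicity", paste("p_death", h),
          "annual cancer death probability must strictly increase with stage")
  }
  u <- c(params$u_well, params$u_post, params$u_recur, params$u_stage)
  if (any(u < -1 | u > 1)) bad("utility_range", "utilities", "outside [-1, 1]")
  if (any(params$u_stage > params$u_well + 1e-12))
    bad("utility_order", "u.stage", "cancer utility exceeds well utility")
  costs <- c(params$cost_ldct, params$cost_workup, params$cost_palliative,
             params$cost_treat)
  if (any(costs < 0)) bad("cost_sign", "costs", "negative cost")

  if (is.null(ages)) {
    rng <- range(params$mortality$age)
    ages <- unique(round(seq(max(rng[1], 50), rng[2], length.out = 4)))
  }
  for (a in ages) {
    for (scr in c(FALSE, TRUE)) {
      M <- transition_matrix(params, a, screening = scr)
      rep <- validate_transitions(M)
      if (nrow(rep))
        for (i in seq_len(nrow(rep)))
          bad(rep$check[i], sprintf("age %d%s: %s", a,
                                    if (scr) " (screening)" else "",
                                    rep$where[i]), rep$detail[i])
    }
  }
  if (!length(out))
    return(data.frame(check = character(), where = character(),
                      detail = character()))
  do.call(rbind, out)
}

.qx_at <- function(params, age) {
  tab <- params$mortality
  i <- findInterval(age, tab$age)
  if (i < 1L) i <- 1L
  if (i > nrow(tab)) i <- nrow(tab)
  tab$qx[i]
}

.onset_at <- function(params, age) {
  ages <- as.integer(names(params$onset))
  i <- findInterval(age, ages)
  if (i < 1L) return(0)
  params$onset[[i]]
}

#' One-cycle transition matrix at a given age
#'
#' Builds the row-stochastic annual transition matrix over the full internal
#' state vector (`space$all_states`). Event order within a cycle is fixed:
#' screening detection (if `screening = TRUE`) acts first, then clinical
#' presentation of undiagnosed disease, disease transitions and death. With
#' `screening = TRUE` the returned matrix is the product S %*% D of the
#' detection and disease matrices; `parts = TRUE` returns both factors.
#'
#' @param params An `lc_params` object.
#' @param age Current age of the cohort (years).
#' @param screening Is a screening round performed this cycle?
#' @param parts Return `list(S = , D = )` instead of the product.
#' @return A square matrix over `params$space$all_states`.
#' @export
transition_matrix <- function(params, age, screening = FALSE, parts = FALSE) {
  sp <- params$space
  n <- length(sp$all_states)
  D <- matrix(0, n, n, dimnames = list(sp$all_states, sp$all_states))
  qx <- .qx_at(params, age)
  i_well <- 1L; i_post <- 2L; i_rec <- 3L; i_dlc <- 4L; i_doc <- 5L

  # well: other-cause death, onset into undiagnosed preclinical disease
  p_on <- .onset_at(params, age)
  D[i_well, i_doc] <- qx
  D[i_well, .undiag_index(sp)] <- (1 - qx) * p_on * params$mix
  D[i_well, i_well] <- 1 - qx - sum(D[i_well, .undiag_index(sp)])

  # undiagnosed: other-cause death, clinical presentation at the clinical
  # (registry-like) stage distribution; no cancer death while preclinical
  for (hi in seq_along(sp$histologies)) {
    u <- .undiag_index(sp, hi)
    pres <- (1 - qx) * params$p_present
    D[u, i_doc] <- qx
    D[u, .cancer_block(sp, hi, "clin")] <-
      pres * params$cdist[hi, ]
    D[u, u] <- 1 - qx - pres
  }

  # detected cancer states: competing cancer death, cure, stage progression
  nS <- length(sp$stages)
  for (hi in seq_along(sp$histologies)) {
    for (v in sp$variants) {
      idx <- .cancer_block(sp, hi, v)
      for (si in seq_len(nS)) {
        i <- idx[si]
        d <- params$p_death[hi, si]
        cu <- params$p_cure[hi, si]
        g <- if (si < nS) params$p_prog[hi, si] else 0
        D[i, i_doc] <- qx
        D[i, i_dlc] <- (1 - qx) * d
        D[i, i_post] <- (1 - qx) * (1 - d) * cu
        if (si < nS) D[i, idx[si + 1L]] <- (1 - qx) * (1 - d) * (1 - cu) * g
        D[i, i] <- (1 - qx) * (1 - d) * (1 - cu) * (1 - g)
      }
    }
  }

  # post-treatment and recurrence
  D[i_post, i_doc] <- qx
  D[i_post, i_rec] <- (1 - qx) * params$p_recurrence
  D[i_post, i_post] <- 1 - qx - D[i_post, i_rec]
  D[i_rec, i_doc] <- qx
  D[i_rec, i_dlc] <- (1 - qx) * params$death_recur
  D[i_rec, i_rec] <- 1 - qx - D[i_rec, i_dlc]

  # absorbing death states
  D[i_dlc, i_dlc] <- 1
  D[i_doc, i_doc] <- 1

  if (!screening && !parts) return(D)
  Sm <- screening_matrix(params)
  if (parts) return(list(S = Sm, D = D))
  Sm %*% D
}

#' Screening detection matrix
#'
#' Identity everywhere except the undiagnosed compartments, from which a
#' fraction `sens` (LDCT sensitivity; the PET/biopsy confirmation chain adds
#' no false positives) moves to the screen-detected cancer states with the
#' screen-detected (trial-like, early-shifted) stage distribution. The
#' remaining `1 - sens` stay undiagnosed and are screened again next round.
#'
#' @param params An `lc_params` object.
#' @return A square row-stochastic matrix over `params$space$all_states`.
#' @export
screening_matrix <- function(params) {
  sp <- params$space
  n <- length(sp$all_states)
  Sm <- diag(n)
  dimnames(Sm) <- list(sp$all_states, sp$all_states)
  for (hi in seq_along(sp$histologies)) {
    u <- .undiag_index(sp, hi)
    Sm[u, .cancer_block(sp, hi, "scr")] <- params$sens * params$sdist[hi, ]
    Sm[u, u] <- 1 - params$sens
  }
  Sm
}

#' Validate a transition matrix
#'
#' Reports every violated invariant of a one-cycle transition matrix: entries
#' outside [0, 1], rows not summing to 1 (tolerance 1e-9), and death-state
#' rows that are not unit vectors. States are identified by row/column names;
#' death states are recognised by a `death` name prefix.
#'
#' @param mat Square numeric matrix, ideally with state dimnames.
#' @return Data frame with columns `check`, `where`, `detail`; zero rows iff
#'   the matrix is valid.
#' @export
validate_transitions <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  labels <- rownames(mat)
  if (is.null(labels)) labels <- paste0("state", seq_len(nrow(mat)))
  out <- list()
  bad <- function(check, where, detail)
    out[[length(out) + 1L]] <<- data.frame(check = check, where = where,
                                           detail = detail)
  out_of_range <- mat < -1e-12 | mat > 1 + 1e-12
  if (any(out_of_range)) {
    idx <- which(out_of_range, arr.ind = TRUE)
    for (i in seq_len(nrow(idx)))
      bad("entry_range", sprintf("%s -> %s", labels[idx[i, 1]],
                                 labels[idx[i, 2]]),
          sprintf("probability %.6g outside [0, 1]", mat[idx[i, 1], idx[i, 2]]))
  }
  rs <- rowSums(mat)
  off <- which(abs(rs - 1) > 1e-9)
  for (i in off)
    bad("row_sum", labels[i], sprintf("row sums to %.12f", rs[i]))
  for (i in grep("^death", labels))
    if (!isTRUE(all.equal(unname(mat[i, ]),
                          as.numeric(seq_len(ncol(mat)) == i),
                          tolerance = 1e-12)))
      bad("absorbing", labels[i], "death-state row is not a unit vector")
  if (!length(out))
    return(data.frame(check = character(), where = character(),
                      detail = character()))
  do.call(rbind, out)
}

#' @export
print.lc_params <- function(x, ...) {
  sp <- x$space
  cat("Lung cancer screening model parameters\n")
  cat(sprintf("  %d histologies x %d stages; %d model states\n",
              length(sp$histologies), length(sp$stages), sp$n_states))
  cat(sprintf("  LDCT sensitivity %.2f, annual clinical presentation %.2f\n",
              x$sens, x$p_present))
  cat(sprintf("  discounting: costs %.1f%%, effects %.2f%% per year\n",
              100 * x$discount$cost, 100 * x$discount$effect))
  cat(sprintf("  mortality table ages %d-%d; horizon to age %d\n",
              min(x$mortality$age), max(x$mortality$age), x$config$max_age))
  invisible(x)
}
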