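# polynomial rolling hash over a deparsed object; cheap provenance
# fingerprint (not cryptographic)
.hash_obj <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483629
  sprintf("%08x", h)
}

.prov_header <- function(seed, hash) {
  c(sprintf("# lcscreen %s", as.character(utils::packageVersion("lcscreen"))),
    sprintf("# seed: %s", format(seed)),
    sprintf("# config_hash: %s", hash))
}

.write_csv_prov <- function(df, path, seed, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.prov_header(seed, hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.read_csv_prov <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a parameter set (and companions) to a directory of CSV files
#'
#' Emits the full config tree of delimited files the readers consume:
#' histology mix, paired clinical/screen-detected stage distributions,
#' per-histology/stage cancer transition rates, onset probabilities,
#' scalar probabilities, WHO-style mortality, cost and utility tables, the
#' uncertainty specification, scenario manifest and population structure,
#' indexed by a `manifest.yml`. Every file carries a provenance comment
#' header (package version, seed, config hash), so identical seeds produce
#' byte-identical files.
#'
#' @param params An `lc_params` object.
#' @param dir Output directory (created if missing).
#' @param scenarios Named list of scenarios (default [scenario_grid()]).
#' @param population Data frame `start_age`, `n`
#'   (default [default_population()]).
#' @param uncertainty Uncertainty spec data frame
#'   (default [generate_uncertainty_spec()] at ±10%).
#' @param seed Seed recorded in the provenance headers.
#' @return The directory path, invisibly.
#' @export
write_parameter_dir <- function(params, dir, scenarios = scenario_grid(),
                                population = NULL, uncertainty = NULL,
                                seed = params$config$seed %||% NA) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(population)) population <- default_population(params)
  if (is.null(uncertainty)) uncertainty <- generate_uncertainty_spec(params)
  sp <- params$space
  hash <- .hash_obj(params$truth)
  w <- function(df, name) .write_csv_prov(df, file.path(dir, name), seed, hash)

  w(data.frame(histology = sp$histologies, probability = unname(params$mix)),
    "histology_mix.csv")
  sd_long <- expand.grid(stage = sp$stages, histology = sp$histologies,
                         stringsAsFactors = FALSE)[, 2:1]
  sd_long$p_clinical <- as.vector(t(params$cdist))
  sd_long$p_screened <- as.vector(t(params$sdist))
  w(sd_long, "stage_distributions.csv")
  tr <- sd_long[, c("histology", "stage")]
  tr$p_death <- as.vector(t(params$p_death))
  tr$p_cure <- as.vector(t(params$p_cure))
  tr$p_progress <- as.vector(t(params$p_prog))
  w(tr, "cancer_transitions.csv")
  w(data.frame(age = as.integer(names(params$onset)),
               p_onset = unname(params$onset)), "onset.csv")
  w(data.frame(name = c("p_recurrence", "death_recur", "sens", "p_present"),
               value = c(params$p_recurrence, params$death_recur,
                         params$sens, params$p_present)), "scalars.csv")
  w(params$mortality, "mortality.csv")

  costs <- rbind(
    data.frame(category = "screening", item = c("ldct", "workup"),
               histology = NA, stage = NA,
               amount_eur = c(params$cost_ldct, params$cost_workup)),
    data.frame(category = "treatment", item = "treatment",
               histology = sd_long$histology, stage = sd_long$stage,
               amount_eur = as.vector(t(params$cost_treat))),
    data.frame(category = "palliative", item = "terminal_6_months",
               histology = NA, stage = NA,
               amount_eur = params$cost_palliative))
  w(costs, "costs.csv")
  w(data.frame(state = c("well", "post_treatment", "recurrence",
                         paste("stage", sp$stages, sep = ".")),
               utility = c(params$u_well, params$u_post, params$u_recur,
                           unname(params$u_stage))), "utilities.csv")
  w(uncertainty, "uncertainty.csv")
  scen_df <- do.call(rbind, lapply(names(scenarios), function(lab) {
    s <- scenarios[[lab]]
    if (is.null(s))
      data.frame(label = lab, start_age = NA, stop_age = NA, interval = NA)
    else
      data.frame(label = lab, start_age = s$start_age,
                 stop_age = if (is.infinite(s$stop_age)) "lifetime"
                            else s$stop_age,
                 interval = s$interval)
  }))
  w(scen_df, "scenarios.csv")
  w(population, "population.csv")

  settings <- list(seed = seed, config_hash = hash,
                   discount = params$discount,
                   model = params$config[c("max_age", "age_groups",
                                           "group_size", "stage_shift")],
                   histologies = sp$histologies, stages = sp$stages)
  yaml::write_yaml(settings, file.path(dir, "settings.yml"))
  manifest <- list(
    format = "lcscreen-parameter-directory",
    seed = seed, config_hash = hash,
    files = c("histology_mix.csv", "stage_distributions.csv",
              "cancer_transitions.csv", "onset.csv", "scalars.csv",
              "mortality.csv", "costs.csv", "utilities.csv",
              "uncertainty.csv", "scenarios.csv", "population.csv",
              "settings.yml"))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Read a parameter directory back into model objects
#'
#' Inverse of [write_parameter_dir()]: reconstructs the validated parameter
#' set, the scenario list, the population structure and the uncertainty
#' specification from the CSV tree indexed by `manifest.yml`.
#'
#' @param dir Directory written by [write_parameter_dir()] (or
#'   [cmd_generate()]).
#' @return List with elements `params`, `scenarios`, `population`,
#'   `uncertainty`, `seed`.
#' @export
read_parameter_dir <- function(dir) {
  man_path <- file.path(dir, "manifest.yml")
  if (!file.exists(man_path)) stop("no manifest.yml in ", dir)
  manifest <- yaml::read_yaml(man_path)
  missing_files <- setdiff(manifest$files, list.files(dir))
  if (length(missing_files))
    stop("manifest lists missing files: ",
         paste(missing_files, collapse = ", "))
  settings <- yaml::read_yaml(file.path(dir, "settings.yml"))
  r <- function(name) .read_csv_prov(file.path(dir, name))

  sp <- build_state_space(settings$histologies, settings$stages)
  mix <- r("histology_mix.csv")
  sdist <- r("stage_distributions.csv")
  tr <- r("cancer_transitions.csv")
  onset <- r("onset.csv")
  scalars <- r("scalars.csv")
  mortality <- r("mortality.csv")
  costs <- r("costs.csv")
  util <- r("utilities.csv")

  leaves <- c()
  leaves[paste("mix", mix$histology, sep = ".")] <- mix$probability
  leaves[paste("cdist", sdist$histology, sdist$stage, sep = ".")] <-
    sdist$p_clinical
  leaves[paste("sdist", sdist$histology, sdist$stage, sep = ".")] <-
    sdist$p_screened
  leaves[paste("death", tr$histology, tr$stage, sep = ".")] <- tr$p_death
  leaves[paste("cure", tr$histology, tr$stage, sep = ".")] <- tr$p_cure
  leaves[paste("prog", tr$histology, tr$stage, sep = ".")] <- tr$p_progress
  leaves[paste("onset", onset$age, sep = ".")] <- onset$p_onset
  leaves[scalars$name] <- scalars$value
  uval <- stats::setNames(util$utility, util$state)
  leaves["u.well"] <- uval[["well"]]
  leaves["u.post"] <- uval[["post_treatment"]]
  leaves["u.recur"] <- uval[["recurrence"]]
  st <- grep("^stage\\.", util$state)
  leaves[paste("u", util$state[st], sep = ".")] <- util$utility[st]
  scr <- costs[costs$category == "screening", ]
  leaves["cost.ldct"] <- scr$amount_eur[scr$item == "ldct"]
  leaves["cost.workup"] <- scr$amount_eur[scr$item == "workup"]
  leaves["cost.palliative"] <-
    costs$amount_eur[costs$category == "palliative"][1L]
  trt <- costs[costs$category == "treatment", ]
  leaves[paste("treat", trt$histology, trt$stage, sep = ".")] <- trt$amount_eur

  # construct without validating: callers (cmd_validate, cmd_run, lc_cea)
  # validate and report, so a broken directory yields a report, not a crash
  params <- lc_parameters(leaves, mortality, sp,
                          discount = settings$discount,
                          config = c(settings$model,
                                     list(seed = settings$seed)),
                          validate = FALSE)
  scen_df <- r("scenarios.csv")
  scenarios <- list()
  for (i in seq_len(nrow(scen_df))) {
    if (is.na(scen_df$start_age[i])) {
      scenarios[scen_df$label[i]] <- list(NULL)
    } else {
      stop_age <- scen_df$stop_age[i]
      stop_age <- if (identical(stop_age, "lifetime")) Inf
                  else as.numeric(stop_age)
      scenarios[[scen_df$label[i]]] <-
        lc_scenario(scen_df$start_age[i], stop_age,
                    scen_df$interval[i], label = scen_df$label[i])
    }
  }
  list(params = params, scenarios = scenarios,
       population = r("population.csv"),
       uncertainty = r("uncertainty.csv"),
       seed = settings$seed)
}

#' Export per-age transition matrices in long format
#'
#' Writes the one-cycle disease transition matrices as a delimited
#' long-format table with columns `from_state`, `to_state`, `age_band`,
#' `probability`. Only off-diagonal non-zero entries are listed; the
#' diagonal remainder making each row sum to 1 is implied (and recomputed by
#' the reader).
#'
#' @param params An `lc_params` object.
#' @param file Output CSV path.
#' @param ages Integer ages to export.
#' @param screening Export the matrix with the screening detection step
#'   composed in.
#' @return The file path, invisibly.
#' @export
export_transitions <- function(params, file, ages = c(55L, 65L, 75L, 85L),
                               screening = FALSE) {
  rows <- lapply(ages, function(a) {
    M <- transition_matrix(params, a, screening = screening)
    idx <- which(M != 0 & row(M) != col(M), arr.ind = TRUE)
    data.frame(from_state = rownames(M)[idx[, 1]],
               to_state = colnames(M)[idx[, 2]],
               age_band = as.character(a),
               probability = M[idx])
  })
  df <- do.call(rbind, rows)
  .write_csv_prov(df, file, params$config$seed %||% NA,
                  .hash_obj(params$truth))
  invisible(file)
}

#' Read long-format transition tables
#'
#' Reads a `from_state`, `to_state`, `age_band`, `probability` CSV into one
#' square matrix per age band. Unlisted pairs default to 0; each diagonal
#' entry is computed as the remainder making its row sum to 1 (the
#' documented convention), unless the file explicitly lists it.
#'
#' @param file CSV path as written by [export_transitions()].
#' @param states Optional state ordering; defaults to the sorted union of
#'   labels in the file.
#' @return Named list of transition matrices, one per age band.
#' @export
read_transition_table <- function(file, states = NULL) {
  df <- .read_csv_prov(file)
  req <- c("from_state", "to_state", "age_band", "probability")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("transition table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(states))
    states <- sort(unique(c(df$from_state, df$to_state)))
  out <- list()
  for (band in unique(df$age_band)) {
    d <- df[df$age_band == band, ]
    M <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    M[cbind(match(d$from_state, states), match(d$to_state, states))] <-
      d$probability
    explicit_diag <- d$from_state == d$to_state
    rem <- 1 - rowSums(M) + diag(M)
    fill <- !(states %in% d$from_state[explicit_diag])
    dg <- diag(M)
    dg[fill] <- rem[fill]
    dg[abs(dg) < 1e-12] <- 0  # guard against float-remainder noise
    diag(M) <- dg
    out[[as.character(band)]] <- M
  }
  out
}
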