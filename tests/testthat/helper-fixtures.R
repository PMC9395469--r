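# Shared fixtures: all inputs are generated in code, nothing is read from
# disk except the published per-100,000 results table used as input data.

# full-size generator configuration (the study conditions)
study_cfg <- function(seed = 1L) generator_config(seed = seed)

# reduced problem size for fast unit tests: 3 entry-age cohorts of 1,000
small_cfg <- function(seed = 1L, ...) {
  generator_config(seed = seed, group_size = 1000,
                   age_groups = c(55L, 65L, 75L), ...)
}

small_params <- function(seed = 1L, ...) {
  generate_parameter_set(small_cfg(seed, ...))$params
}

# tiny state space (2 histologies x 3 stages) for sampling-heavy tests
tiny_cfg <- function(seed = 1L, ...) {
  generator_config(seed = seed, group_size = 1000, age_groups = c(60L, 70L),
                   histologies = c("SCLC", "adenocarcinoma"),
                   stages = c("IA", "II", "IV"), ...)
}

tiny_params <- function(seed = 1L, ...) {
  generate_parameter_set(tiny_cfg(seed, ...))$params
}

# published Table-style results used as inputs for arithmetic checks
published_results <- function() {
  path <- system.file("extdata", "table1_results.csv", package = "lcscreen")
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

# random valid row-stochastic matrix without absorbing structure
random_stochastic <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(stats::runif(n * n), n, n)
  m / rowSums(m)
}

# brute-force dominance oracle: tests every point against every point and
# every connecting segment (upper-left convex hull definition)
oracle_frontier_status <- function(df) {
  n <- nrow(df)
  status <- rep("on_frontier", n)
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (q != p && df$cost[q] <= df$cost[p] && df$qaly[q] >= df$qaly[p] &&
          (df$cost[q] < df$cost[p] || df$qaly[q] > df$qaly[p])) {
        status[p] <- "dominated"
        break
      }
    }
  }
  for (p in which(status == "on_frontier")) {
    for (i in seq_len(n)) {
      if (status[p] != "on_frontier") break
      for (j in seq_len(n)) {
        if (i == p || j == p || df$cost[i] >= df$cost[j]) next
        if (df$cost[p] <= df$cost[i] || df$cost[p] >= df$cost[j]) next
        lam <- (df$cost[j] - df$cost[p]) / (df$cost[j] - df$cost[i])
        mix_q <- lam * df$qaly[i] + (1 - lam) * df$qaly[j]
        if (mix_q > df$qaly[p]) {
          status[p] <- "extended_dominated"
          break
        }
      }
    }
  }
  status
}
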