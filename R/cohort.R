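# internal: simulate one individual with its own seeds for the initial
# abundances and for the dynamics/read draws; gLV parameters are shared
simulate_individual <- function(nodes, interactions, interventions, config,
                                p_zero, init_seed, sim_seed) {
  set.seed(init_seed)
  nodes <- lapply(nodes, function(nd) {
    nd$initial_abundances <- sample_initial_abundances(nd$dim, p_zero = p_zero)
    nd
  })
  cfg <- config
  cfg$seed <- sim_seed
  simulate_timecourse(nodes, interactions, interventions, cfg)
}

#' Simulate a cohort of individuals sharing gLV parameters
#'
#' Generates `n_individuals` timecourses from identical growth rates and
#' interaction matrices; only the initial abundances are resampled per
#' individual (zero with probability `p_zero`, otherwise log-normal(0, 1)),
#' and each individual's biological noise and read sampling use an
#' independent substream derived from the cohort master seed — so adding an
#' individual never perturbs the others' draws.
#'
#' Growth rates left `NULL` in `nodes` are sampled once, from the cohort
#' seed, and shared by all individuals.
#'
#' @param nodes List of [node_spec()].
#' @param interactions An [interaction_map()] or `NULL`.
#' @param interventions List of [intervention_spec()] applied to every
#'   individual.
#' @param sim_config A [sim_config()]; its own `seed` is ignored in favor
#'   of the cohort seed hierarchy.
#' @param cohort_config A [cohort_config()].
#' @return List of `n_individuals` timecourses.
#' @export
generate_cohort <- function(nodes, interactions = NULL, interventions = list(),
                            sim_config = glvsim::sim_config(),
                            cohort_config) {
  if (!inherits(cohort_config, "cohort_config"))
    glv_config_error("`cohort_config` must be a cohort_config")
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  n <- cohort_config$n_individuals
  all_seeds <- derive_seeds(cohort_config$seed, 2L * n + 1L)
  # shared parameters: any missing growth rates are sampled once, up
  # front, from their own substream, and reused by every individual
  set.seed(all_seeds[1L])
  nodes <- lapply(nodes, function(nd) {
    if (is.null(nd$growth_rates)) nd$growth_rates <- sample_growth_rates(nd$dim)
    nd
  })
  seeds <- matrix(all_seeds[-1L], ncol = 2L, byrow = TRUE)
  lapply(seq_len(n), function(k) {
    tryCatch(
      simulate_individual(nodes, interactions, interventions, sim_config,
                          cohort_config$p_zero, seeds[k, 1L], seeds[k, 2L]),
      glvsim_divergence_error = function(e)
        glv_error(sprintf("individual %d: %s", k, conditionMessage(e)),
                  "glvsim_divergence_error"))
  })
}

#' Simulate a case-control cohort
#'
#' Splits the cohort into cases and controls. Cases receive an always-on
#' intervention (magnitude 1 at every time point, including burn-in) on
#' `intervention_node`, with a single response vector drawn once per cohort
#' with coordinates uniform on (-s/2, s/2) where s is the effect size.
#' Controls receive no intervention. All individuals share growth rates and
#' interactions; initial abundances are resampled per individual.
#'
#' The number of cases is `round(n_individuals * case_ratio)` (half away
#' from zero); the remainder are controls. With `match_seeds = TRUE` in the
#' cohort config, case k and control k share their individual seeds, so at
#' effect size 0 the two arms are identical draw for draw.
#'
#' @inheritParams generate_cohort
#' @return A list with elements `cases` and `controls` (lists of
#'   timecourses), `response` (the drawn response vector, for downstream
#'   power analysis) and `manifest` (data frame: id, arm, init/sim seeds).
#' @export
generate_case_control <- function(nodes, interactions = NULL,
                                  sim_config = glvsim::sim_config(),
                                  cohort_config) {
  if (!inherits(cohort_config, "cohort_config"))
    glv_config_error("`cohort_config` must be a cohort_config")
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  dims <- node_dims(nodes)
  target <- cohort_config$intervention_node
  if (is.null(target) || !target %in% names(dims))
    glv_config_error(sprintf(
      "`intervention_node` ('%s') must name one of: %s",
      target %||% "NULL", paste(names(dims), collapse = ", ")))

  n <- cohort_config$n_individuals
  n_cases <- as.integer(floor(n * cohort_config$case_ratio + 0.5))
  n_controls <- n - n_cases

  if (!is.null(cohort_config$seed)) set.seed(cohort_config$seed)
  s <- cohort_config$effect_size
  b_c <- runif(dims[[target]], min = -s / 2, max = s / 2)
  nodes <- lapply(nodes, function(nd) {
    if (is.null(nd$growth_rates)) nd$growth_rates <- sample_growth_rates(nd$dim)
    nd
  })
  if (cohort_config$match_seeds) {
    seeds <- matrix(derive_seeds(NULL, 2L * max(n_cases, n_controls)), ncol = 2L, byrow = TRUE)
    case_seeds <- seeds[seq_len(n_cases), , drop = FALSE]
    control_seeds <- seeds[seq_len(n_controls), , drop = FALSE]
  } else {
    seeds <- matrix(derive_seeds(NULL, 2L * n), ncol = 2L, byrow = TRUE)
    case_seeds <- seeds[seq_len(n_cases), , drop = FALSE]
    control_seeds <- seeds[n_cases + seq_len(n_controls), , drop = FALSE]
  }

  # always-on: u = 1 at every recorded point; burn-in steps reuse u[1], so
  # the drive is active from the very first integration step
  case_iv <- list(intervention_spec(
    target, magnitudes = rep(1, sim_config$n_timepoints), responses = b_c))

  run_arm <- function(arm_seeds, interventions, arm) {
    lapply(seq_len(nrow(arm_seeds)), function(k) {
      tryCatch(
        simulate_individual(nodes, interactions, interventions, sim_config,
                            cohort_config$p_zero,
                            arm_seeds[k, 1L], arm_seeds[k, 2L]),
        glvsim_divergence_error = function(e)
          glv_error(sprintf("%s %d: %s", arm, k, conditionMessage(e)),
                    "glvsim_divergence_error"))
    })
  }
  cases <- run_arm(case_seeds, case_iv, "case")
  controls <- run_arm(control_seeds, list(), "control")

  manifest <- data.frame(
    id = c(sprintf("case_%d", seq_len(n_cases)),
           sprintf("control_%d", seq_len(n_controls))),
    arm = rep(c("case", "control"), c(n_cases, n_controls)),
    init_seed = c(case_seeds[, 1L], control_seeds[, 1L]),
    sim_seed = c(case_seeds[, 2L], control_seeds[, 2L]))
  list(cases = cases, controls = controls, response = b_c, manifest = manifest)
}
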