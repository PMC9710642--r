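#' Describe one node of a simulated ecosystem
#'
#' A node is one data layer of the simulated system — for example a
#' metagenomics node and a metabolomics node measuring the same community,
#' or two interacting ecosystems. Each node carries its dimensionality
#' (number of taxa/features), per-dimension intrinsic growth rates and an
#' initial abundance vector.
#'
#' @param name Character scalar identifying the node.
#' @param dim Positive integer, number of dimensions (taxa/features).
#' @param growth_rates Numeric vector of length `dim`: intrinsic per-unit-time
#'   growth rates. `NULL` means "sample defaults at run time" (uniform on
#'   (-1, 1), see [sample_growth_rates()]).
#' @param initial_abundances Nonnegative numeric vector of length `dim`.
#'   `NULL` means "sample defaults at run time" (log-normal(0, 1), see
#'   [sample_initial_abundances()]).
#'
#' @return An object of class `node_spec`.
#' @examples
#' node_spec("microbes", 3, growth_rates = c(0.5, -0.2, 1),
#'           initial_abundances = c(1, 2, 0))
#' @export
node_spec <- function(name, dim, growth_rates = NULL, initial_abundances = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    glv_config_error("`name` must be a non-empty string")
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L)
    glv_config_error(sprintf("node '%s': `dim` must be a positive integer", name))
  if (!is.null(growth_rates) && length(growth_rates) != dim)
    glv_config_error(sprintf(
      "node '%s': growth_rates has length %d, expected %d",
      name, length(growth_rates), dim))
  if (!is.null(initial_abundances)) {
    if (length(initial_abundances) != dim)
      glv_config_error(sprintf(
        "node '%s': initial_abundances has length %d, expected %d",
        name, length(initial_abundances), dim))
    if (any(!is.finite(initial_abundances)) || any(initial_abundances < 0))
      glv_config_error(sprintf(
        "node '%s': initial abundances must be finite and >= 0", name))
  }
  structure(
    list(name = name, dim = dim,
         growth_rates = if (is.null(growth_rates)) NULL else as.numeric(growth_rates),
         initial_abundances = if (is.null(initial_abundances)) NULL else as.numeric(initial_abundances)),
    class = "node_spec")
}

#' @export
print.node_spec <- function(x, ...) {
  cat(sprintf("<node_spec> '%s' (%d dims)%s%s\n", x$name, x$dim,
              if (is.null(x$growth_rates)) ", growth: default" else "",
              if (is.null(x$initial_abundances)) ", z0: default" else ""))
  invisible(x)
}

node_dims <- function(nodes) {
  stats::setNames(vapply(nodes, function(n) n$dim, integer(1)),
                  vapply(nodes, function(n) n$name, character(1)))
}

# fill in default-sampled growth rates / initial abundances where NULL,
# drawing from the session RNG stream
complete_nodes <- function(nodes, p_zero = 0) {
  lapply(nodes, function(nd) {
    if (is.null(nd$growth_rates))
      nd$growth_rates <- sample_growth_rates(nd$dim)
    if (is.null(nd$initial_abundances))
      nd$initial_abundances <- sample_initial_abundances(nd$dim, p_zero = p_zero)
    nd
  })
}

#' Describe a time-varying intervention on one node
#'
#' An intervention perturbs the per-capita growth of its target node: at
#' recorded time point t it adds `magnitudes[t] * responses` to the gLV
#' growth term of that node's coordinates (and only that node's).
#'
#' @param node Name of the target node.
#' @param magnitudes Numeric vector of per-time-point intervention
#'   magnitudes (dimensionless); length must equal the configured number of
#'   time points.
#' @param responses Numeric vector of per-dimension responses
#'   (per-unit-time per unit magnitude); length must equal the target
#'   node's dimensionality.
#'
#' @return An object of class `intervention_spec`.
#' @export
intervention_spec <- function(node, magnitudes, responses) {
  if (!is.character(node) || length(node) != 1L)
    glv_config_error("`node` must be a single node name")
  structure(
    list(node = node, magnitudes = as.numeric(magnitudes),
         responses = as.numeric(responses)),
    class = "intervention_spec")
}

#' Simulation configuration
#'
#' Collects the integration and read-sampling knobs of the generator.
#'
#' @param n_timepoints Number of recorded time points `|T|`.
#' @param dt Integration time step (forward Euler).
#' @param noise_var Variance of the per-coordinate biological noise term,
#'   redrawn at every integration step.
#' @param n_reads Sequencing depth `R`: total multinomial count drawn per
#'   recorded time point.
#' @param downsample Integer stride: record every `downsample`-th
#'   integration step.
#' @param burn_in Integration steps before the first recorded sample
#'   ("time to first sample"); their output is discarded.
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#'
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_timepoints = 100L, dt = 0.01, noise_var = 0.01,
                       n_reads = 10000L, downsample = 1L, burn_in = 0L,
                       seed = NULL) {
  n_timepoints <- as.integer(n_timepoints)
  downsample <- as.integer(downsample)
  burn_in <- as.integer(burn_in)
  if (is.na(n_timepoints) || n_timepoints < 1L)
    glv_config_error("`n_timepoints` must be a positive integer")
  if (!is.finite(dt) || dt <= 0) glv_config_error("`dt` must be > 0")
  if (!is.finite(noise_var) || noise_var < 0)
    glv_config_error("`noise_var` must be >= 0")
  if (is.na(n_reads) || n_reads < 1) glv_config_error("`n_reads` must be >= 1")
  if (is.na(downsample) || downsample < 1L)
    glv_config_error("`downsample` must be >= 1")
  if (is.na(burn_in) || burn_in < 0L) glv_config_error("`burn_in` must be >= 0")
  structure(
    list(n_timepoints = n_timepoints, dt = dt, noise_var = noise_var,
         n_reads = as.integer(n_reads), downsample = downsample,
         burn_in = burn_in, seed = seed),
    class = "sim_config")
}

#' Random interaction-matrix configuration
#'
#' Parameters of the random community-matrix ensemble: symmetric-position
#' off-diagonal pairs are drawn from a bivariate normal with per-coordinate
#' variance `pair_var` and correlation `pair_corr`, each off-diagonal entry
#' is kept with probability `connectivity`, and every diagonal entry is set
#' to `-self_penalty`.
#'
#' @param connectivity Probability C in \[0, 1\] that an off-diagonal entry
#'   is retained (nonzero).
#' @param self_penalty Nonnegative magnitude d of the negative
#'   self-interaction placed on the diagonal (the diagonal becomes `-d`).
#' @param pair_var Positive per-coordinate variance of the bivariate normal.
#' @param pair_corr Correlation rho in \[-1, 1\] of the (upper, lower) pair.
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#'
#' @return An object of class `matrix_gen_config`.
#' @export
matrix_gen_config <- function(connectivity = 0.5, self_penalty = 1.0,
                              pair_var = 1.0, pair_corr = 0.0, seed = NULL) {
  if (!is.finite(connectivity) || connectivity < 0 || connectivity > 1)
    glv_config_error("`connectivity` must be in [0, 1]")
  if (!is.finite(self_penalty) || self_penalty < 0)
    glv_config_error("`self_penalty` must be >= 0")
  if (!is.finite(pair_var) || pair_var <= 0)
    glv_config_error("`pair_var` must be > 0")
  if (!is.finite(pair_corr) || abs(pair_corr) > 1)
    glv_config_error("`pair_corr` must be in [-1, 1]")
  structure(
    list(connectivity = connectivity, self_penalty = self_penalty,
         pair_var = pair_var, pair_corr = pair_corr, seed = seed),
    class = "matrix_gen_config")
}

#' Cohort and case-control configuration
#'
#' @param n_individuals Number of individuals to simulate.
#' @param p_zero Probability in \[0, 1\] that an initial abundance
#'   coordinate is zero (zero coordinates stay extinct for the whole
#'   timecourse).
#' @param case_ratio Fraction of individuals assigned to the case arm
#'   (cases = `round(n_individuals * case_ratio)`, half away from zero).
#' @param intervention_node Name of the node the case intervention targets.
#' @param effect_size Nonnegative effect size s: the case response vector
#'   is drawn once per cohort, uniform on (-s/2, s/2) per coordinate.
#' @param seed Integer master seed; per-individual substream seeds are
#'   derived from it so each individual's draws are independent.
#' @param match_seeds If `TRUE`, case k and control k share an individual
#'   seed (matched-pairs design: identical initial abundances, noise and
#'   read draws at effect size 0). Default unmatched.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_individuals, p_zero = 0, case_ratio = 0.5,
                          intervention_node = NULL, effect_size = 1.0,
                          seed = NULL, match_seeds = FALSE) {
  n_individuals <- as.integer(n_individuals)
  if (is.na(n_individuals) || n_individuals < 1L)
    glv_config_error("`n_individuals` must be a positive integer")
  if (!is.finite(p_zero) || p_zero < 0 || p_zero > 1)
    glv_config_error("`p_zero` must be in [0, 1]")
  if (!is.finite(case_ratio) || case_ratio < 0 || case_ratio > 1)
    glv_config_error("`case_ratio` must be in [0, 1]")
  if (!is.finite(effect_size) || effect_size < 0)
    glv_config_error("`effect_size` must be >= 0")
  structure(
    list(n_individuals = n_individuals, p_zero = p_zero,
         case_ratio = case_ratio, intervention_node = intervention_node,
         effect_size = effect_size, seed = seed,
         match_seeds = isTRUE(match_seeds)),
    class = "cohort_config")
}
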