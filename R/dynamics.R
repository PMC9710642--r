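#' One forward-Euler step of the noisy gLV system
#'
#' Advances the abundance vector by
#' `z + dt * z * (growth + M %*% z + intervention_drive + noise_draw)`,
#' the discrete form of generalized Lotka-Volterra dynamics in which each
#' dimension's *per-capita* growth is linear in all abundances. Any
#' negative result is clamped to 0 (abundances are physical and 0 is the
#' absorbing state of the multiplicative form), and a coordinate that is 0
#' stays exactly 0 whatever the other terms.
#'
#' @param z_prev Nonnegative abundance vector of length D.
#' @param growth Growth-rate vector of length D.
#' @param M D x D interaction matrix (target x source orientation).
#' @param intervention_drive Per-coordinate additive drive (already summed
#'   over interventions); scalar 0 recycles.
#' @param noise_draw Per-coordinate noise realization; scalar 0 recycles.
#' @param dt Positive step size.
#' @param step Optional integration-step index, used only to annotate a
#'   divergence error.
#' @return Nonnegative vector of length D.
#' @examples
#' # logistic growth towards the fixed point -g/M = 2
#' z <- 0.1
#' for (i in 1:5000) z <- glv_step(z, 1, matrix(-0.5), 0, 0, dt = 0.01)
#' z
#' @export
glv_step <- function(z_prev, growth, M, intervention_drive = 0,
                     noise_draw = 0, dt, step = NA_integer_) {
  z_new <- z_prev + dt * z_prev *
    (growth + as.vector(M %*% z_prev) + intervention_drive + noise_draw)
  bad <- !is.finite(z_new)
  if (any(bad))
    glv_error(sprintf(
      "gLV integration diverged at step %s, coordinate(s) %s; reduce dt or interaction scale",
      ifelse(is.na(step), "?", step), paste(which(bad), collapse = ", ")),
      "glvsim_divergence_error")
  z_new[z_new < 0] <- 0
  z_new
}

#' Simulate one abundance timecourse
#'
#' Integrates the noisy gLV system by forward Euler and derives the three
#' standard matrices of a synthetic sequencing experiment: `Z` (latent
#' absolute abundances), `X = Z` normalized per row (latent relative
#' abundances) and `Y` (observed read counts, one multinomial draw of size
#' `n_reads` per time point with probability vector the matching row of
#' `X`).
#'
#' Per integration step, a fresh noise vector is drawn from a normal with
#' mean 0 and variance `noise_var` per coordinate and enters the per-capita
#' growth term (so it is scaled by the abundance, like every other term).
#' The first recorded row is the state after `burn_in` integration steps
#' ("time to first sample"; with `burn_in = 0` the initial state at time 0
#' is recorded), and subsequent rows are taken every `downsample`-th step.
#' Intervention magnitudes are indexed by recorded time point: the steps
#' leading to recorded row t use `magnitudes[t]` (burn-in steps use
#' `magnitudes[1]`), and each intervention contributes
#' `magnitudes[t] * responses` to its target node's coordinates only;
#' multiple interventions on one node sum.
#'
#' @param nodes List of [node_spec()]; nodes with `NULL` growth rates or
#'   initial abundances get defaults sampled via [sample_growth_rates()] /
#'   [sample_initial_abundances()].
#' @param interactions An [interaction_map()], or `NULL` for no
#'   interactions.
#' @param interventions List of [intervention_spec()].
#' @param config A [sim_config()]. The run is fully reproducible from
#'   `config$seed`.
#' @return A `timecourse` object: list with `node_names`, `node_dims`, `Z`,
#'   `X`, `Y` (each `n_timepoints` x D) and `times`.
#' @examples
#' tc <- simulate_timecourse(
#'   list(node_spec("a", 2, c(1, 0.5), c(0.1, 0.2))),
#'   config = sim_config(n_timepoints = 10, noise_var = 0, seed = 1))
#' rowSums(tc$Y)
#' @export
simulate_timecourse <- function(nodes, interactions = NULL,
                                interventions = list(), config = sim_config()) {
  if (inherits(nodes, "node_spec")) nodes <- list(nodes)
  if (!length(nodes) || !all(vapply(nodes, inherits, logical(1), "node_spec")))
    glv_config_error("`nodes` must be a list of node_spec objects")
  if (!inherits(config, "sim_config"))
    glv_config_error("`config` must be a sim_config")
  if (!is.null(config$seed)) set.seed(config$seed)

  nodes <- complete_nodes(nodes)
  dims <- node_dims(nodes)
  if (anyDuplicated(names(dims))) glv_config_error("node names must be unique")
  D <- sum(dims)
  TT <- config$n_timepoints

  if (is.null(interactions)) {
    M <- matrix(0, D, D)
  } else {
    if (!inherits(interactions, "interaction_map"))
      glv_config_error("`interactions` must be an interaction_map or NULL")
    if (!identical(unname(interactions$node_dims[names(dims)]), unname(dims)) ||
        !setequal(names(interactions$node_dims), names(dims)))
      glv_config_error("interaction map node dimensions do not match `nodes`")
    M <- as.matrix(interaction_map(interactions$blocks, dims[names(dims)]))
  }

  offsets <- c(0L, cumsum(dims))
  # D x |T| additive drive, one column per recorded time point
  drive <- matrix(0, D, TT)
  for (iv in interventions) {
    if (!inherits(iv, "intervention_spec"))
      glv_config_error("`interventions` must contain intervention_spec objects")
    k <- match(iv$node, names(dims))
    if (is.na(k))
      glv_config_error(sprintf("intervention targets unknown node '%s'", iv$node))
    if (length(iv$magnitudes) != TT)
      glv_config_error(sprintf(
        "intervention on '%s': magnitudes has length %d, expected n_timepoints = %d",
        iv$node, length(iv$magnitudes), TT))
    if (length(iv$responses) != dims[[k]])
      glv_config_error(sprintf(
        "intervention on '%s': responses has length %d, expected dim = %d",
        iv$node, length(iv$responses), dims[[k]]))
    idx <- (offsets[k] + 1):offsets[k + 1]
    drive[idx, ] <- drive[idx, ] + outer(iv$responses, iv$magnitudes)
  }

  growth <- unlist(lapply(nodes, `[[`, "growth_rates"), use.names = FALSE)
  z <- unlist(lapply(nodes, `[[`, "initial_abundances"), use.names = FALSE)
  sd_noise <- sqrt(config$noise_var)
  step_idx <- 0L
  advance <- function(z, t_record) {
    step_idx <<- step_idx + 1L
    noise <- if (sd_noise > 0) rnorm(D, 0, sd_noise) else 0
    glv_step(z, growth, M, drive[, t_record], noise, config$dt, step = step_idx)
  }

  for (s in seq_len(config$burn_in)) z <- advance(z, 1L)
  Z <- matrix(NA_real_, TT, D)
  Z[1L, ] <- z
  for (t in seq_len(TT - 1L) + 1L) {
    for (s in seq_len(config$downsample)) z <- advance(z, t)
    Z[t, ] <- z
  }

  cn <- unlist(lapply(nodes, function(nd) paste(nd$name, seq_len(nd$dim) - 1L, sep = "_")),
               use.names = FALSE)
  colnames(Z) <- cn
  X <- to_relative(Z)
  Y <- sample_reads(X, config$n_reads)
  times <- (config$burn_in + (seq_len(TT) - 1L) * config$downsample) * config$dt
  new_timecourse(names(dims), dims, Z, X, Y, times)
}

new_timecourse <- function(node_names, dims, Z, X, Y, times) {
  structure(
    list(node_names = node_names, node_dims = dims, Z = Z, X = X, Y = Y,
         times = times),
    class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d time points x %d dims (%s), reads/sample = %s\n",
              nrow(x$Z), ncol(x$Z), paste(x$node_names, collapse = " + "),
              format(max(rowSums(x$Y)))))
  invisible(x)
}

#' Convert absolute abundances to relative abundances
#'
#' Divides every row by its sum, the compositional observable of
#' sequencing. An all-zero row (a fully extinct community at that time
#' point) maps to an all-zero row with a warning rather than an error, so
#' parameter sweeps over harsh regimes do not abort.
#'
#' @param Z Nonnegative numeric matrix (rows = time points or samples).
#' @return Matrix of the same shape whose nonzero rows sum to 1.
#' @export
to_relative <- function(Z) {
  Z <- as.matrix(Z)
  if (any(!is.finite(Z)) || any(Z < 0))
    glv_domain_error("`Z` must be finite and nonnegative")
  rs <- rowSums(Z)
  zero <- rs == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero abundance row(s) mapped to all-zero relative rows",
                    sum(zero)), call. = FALSE)
    rs[zero] <- 1
  }
  Z / rs
}

#' Draw multinomial read counts from relative abundances
#'
#' Emulates sequencing at fixed depth: each nonzero row of `X` yields one
#' independent multinomial draw of `n_reads` total counts with that row as
#' the probability vector. All-zero rows yield all-zero count rows.
#'
#' @param X Relative-abundance matrix; every row must sum to 1 within 1e-9
#'   or be all zero.
#' @param n_reads Read depth R (total counts per row).
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#' @return Integer matrix of the same shape; nonzero rows sum to exactly
#'   `n_reads`.
#' @examples
#' sample_reads(matrix(c(0.5, 0.5), 1), n_reads = 10, seed = 1)
#' @export
sample_reads <- function(X, n_reads, seed = NULL) {
  X <- as.matrix(X)
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1L) glv_config_error("`n_reads` must be >= 1")
  rs <- rowSums(X)
  zero <- rs == 0
  if (any(abs(rs[!zero] - 1) > 1e-9) || any(X < 0))
    glv_domain_error("rows of `X` must be nonnegative and sum to 1 (or be all zero)")
  if (!is.null(seed)) set.seed(seed)
  Y <- matrix(0L, nrow(X), ncol(X), dimnames = dimnames(X))
  for (t in which(!zero))
    Y[t, ] <- as.integer(rmultinom(1L, n_reads, X[t, ]))
  Y
}
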