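#' Sample default intrinsic growth rates
#'
#' Draws per-dimension growth rates from the default ensemble, the uniform
#' distribution on (-1, 1) per unit time.
#'
#' @param dim Number of dimensions.
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#' @return Numeric vector of length `dim` with entries in (-1, 1).
#' @examples
#' sample_growth_rates(5, seed = 1)
#' @export
sample_growth_rates <- function(dim, seed = NULL) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) glv_config_error("`dim` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  runif(dim, min = -1, max = 1)
}

#' Sample default initial abundances
#'
#' Each coordinate is zero with probability `p_zero` and otherwise drawn
#' from a log-normal(0, 1). Zero coordinates are absorbing under the gLV
#' dynamics: a dimension that starts extinct stays extinct, which is how
#' structurally absent taxa are modeled across a cohort.
#'
#' @param dim Number of dimensions.
#' @param p_zero Probability in \[0, 1\] of a zero-valued coordinate.
#' @param seed Integer seed; `NULL` continues the session RNG stream.
#' @return Nonnegative numeric vector of length `dim`.
#' @examples
#' sample_initial_abundances(5, p_zero = 0.2, seed = 1)
#' @export
sample_initial_abundances <- function(dim, p_zero = 0, seed = NULL) {
  dim <- as.integer(dim)
  if (is.na(dim) || dim < 1L) glv_config_error("`dim` must be a positive integer")
  if (!is.finite(p_zero) || p_zero < 0 || p_zero > 1)
    glv_config_error("`p_zero` must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  z0 <- rlnorm(dim, meanlog = 0, sdlog = 1)
  if (p_zero > 0) z0[runif(dim) < p_zero] <- 0
  z0
}

#' Sample a random block interaction matrix
#'
#' Builds the full D x D community matrix (D = sum of node dimensions) of
#' the random ensemble: for every off-diagonal symmetric position pair
#' (i, j), (j, i) with i < j, the two entries are drawn jointly from a
#' bivariate normal with per-coordinate variance `pair_var` and correlation
#' `pair_corr`; every off-diagonal entry is then independently zeroed with
#' probability `1 - connectivity`; every diagonal entry is set to
#' `-self_penalty` (diagonal entries are never sparsified, so every
#' dimension is self-limiting). The matrix is finally partitioned into
#' node-pair blocks along the node-dimension boundaries.
#'
#' @param node_dims Named integer vector mapping node name to
#'   dimensionality, in node order.
#' @param config A [matrix_gen_config()].
#' @return An [interaction_map()] whose blocks tile the D x D matrix.
#' @examples
#' m <- sample_interaction_matrix(c(microbes = 3, metabolites = 2),
#'                                matrix_gen_config(connectivity = 0.4, seed = 1))
#' as.matrix(m)
#' @export
sample_interaction_matrix <- function(node_dims, config = matrix_gen_config()) {
  if (!inherits(config, "matrix_gen_config"))
    glv_config_error("`config` must be a matrix_gen_config")
  nms <- names(node_dims) %||% paste0("node", seq_along(node_dims))
  node_dims <- stats::setNames(as.integer(node_dims), nms)
  if (any(is.na(node_dims)) || any(node_dims < 1L))
    glv_config_error("all node dimensions must be >= 1")
  if (!is.null(config$seed)) set.seed(config$seed)

  D <- sum(node_dims)
  M <- matrix(0, D, D)
  if (D > 1L) {
    upper <- which(upper.tri(M))
    n_pairs <- length(upper)
    # bivariate normal via conditional draw: scale both coordinates by
    # sqrt(pair_var) so pair_var = 1 gives the unit-variance ensemble
    a <- rnorm(n_pairs)
    b <- config$pair_corr * a + sqrt(1 - config$pair_corr^2) * rnorm(n_pairs)
    s <- sqrt(config$pair_var)
    M[upper] <- s * a
    M[cbind(col(M)[upper], row(M)[upper])] <- s * b
    # independent Bernoulli(C) retention per off-diagonal entry: a
    # correlated pair can lose one member
    off <- row(M) != col(M)
    M[off] <- M[off] * rbinom(sum(off), 1L, config$connectivity)
  }
  diag(M) <- -config$self_penalty
  partition_matrix(M, node_dims)
}
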