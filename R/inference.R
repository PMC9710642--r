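#' Build the regression design for gLV parameter inference
#'
#' Dividing the gLV equation by the abundance gives
#' `d(log z)/dt = g + M z + u b`, which is linear in the parameters. The
#' design therefore pairs `F`, the matrix of time-scaled changes between
#' successive time points (by default log-increments divided by the time
#' step), with `Ydes`, the row-wise stack of the abundances at time points
#' 1..T-1, a row of ones (carrying the growth-rate intercept) and one row
#' per intervention magnitude series.
#'
#' A pseudocount is added inside the logarithms because observed
#' trajectories may contain exact zeros; the method presumes absolute
#' abundances are observed.
#'
#' @param Z Abundance matrix, T rows (time points) x D columns.
#' @param times Strictly increasing time coordinates, length T. Defaults
#'   to `0:(T-1)`.
#' @param interventions_u Optional T x J matrix of intervention magnitude
#'   series (one column per intervention), or `NULL`.
#' @param pseudocount Positive value added before taking logs; default
#'   `1e-6 *` mean positive abundance.
#' @param mode `"log"` (default): `F[t, ] = diff(log(Z + pc))[t, ] / dt_t`.
#'   `"linear"`: `F[t, ] = (Z[t+1, ] - Z[t, ]) / dt_t / (Z[t, ] + pc)`,
#'   which matches forward-Euler-generated data exactly.
#' @return An object of class `glv_design`: list with `F`
#'   ((T-1) x D) and `Ydes` ((D + 1 + J) x (T-1)).
#' @export
build_design <- function(Z, times = NULL, interventions_u = NULL,
                         pseudocount = NULL, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  Z <- as.matrix(Z)
  TT <- nrow(Z)
  if (TT < 2L) glv_domain_error("`Z` needs at least 2 time points")
  times <- times %||% (seq_len(TT) - 1)
  if (length(times) != TT) glv_domain_error("`times` length must match nrow(Z)")
  dts <- diff(times)
  if (any(dts <= 0)) glv_domain_error("`times` must be strictly increasing")
  if (!is.null(interventions_u)) {
    interventions_u <- as.matrix(interventions_u)
    if (nrow(interventions_u) != TT)
      glv_domain_error("`interventions_u` must have one row per time point")
  }
  if (is.null(pseudocount)) {
    pos <- Z[Z > 0]
    pseudocount <- if (length(pos)) 1e-6 * mean(pos) else 1e-6
  }
  if (!is.finite(pseudocount) || pseudocount <= 0)
    glv_domain_error("`pseudocount` must be > 0")

  Fm <- switch(mode,
    log = diff(log(Z + pseudocount)) / dts,
    linear = (diff(Z) / dts) / (Z[-TT, , drop = FALSE] + pseudocount))
  Ydes <- rbind(t(Z[-TT, , drop = FALSE]), rep(1, TT - 1L))
  if (!is.null(interventions_u))
    Ydes <- rbind(Ydes, t(interventions_u[-TT, , drop = FALSE]))
  structure(list(F = Fm, Ydes = Ydes, n_interventions = ncol(interventions_u) %||% 0L),
            class = "glv_design")
}

#' Infer gLV parameters by ridge regression
#'
#' Solves the regularized least-squares problem whose coefficient matrix
#' stacks the interaction matrix, the growth rates and the intervention
#' responses: `theta = F' Ydes' (Ydes Ydes' + lambda I)^{-1}`, computed via
#' a symmetric linear solve (never an explicit inverse). The first D
#' columns of `theta` are the inferred interaction matrix `M_hat`, the next
#' column the growth rates `g_hat`, and the remaining columns the
#' intervention responses `b_hat`.
#'
#' Designs from several individuals may be passed as a list; their columns
#' are concatenated before solving, pooling evidence across timecourses
#' that share parameters.
#'
#' @param design A `glv_design` from [build_design()], or a list of them.
#' @param lambda Nonnegative ridge penalty. At `lambda = 0` the normal
#'   matrix may be singular, in which case an error advises a positive
#'   penalty.
#' @return An object of class `glv_fit`: list with `M_hat` (D x D),
#'   `g_hat` (length D), `b_hat` (D x J) and `lambda`.
#' @examples
#' z <- 0.1
#' traj <- numeric(200)
#' for (t in 1:200) { traj[t] <- z; z <- glv_step(z, 1, matrix(-0.5), dt = 0.05) }
#' fit <- infer_glv_ridge(build_design(matrix(traj), times = 0.05 * (0:199)),
#'                        lambda = 1e-8)
#' c(fit$g_hat, fit$M_hat)  # close to (1, -0.5)
#' @export
infer_glv_ridge <- function(design, lambda) {
  if (inherits(design, "glv_design")) design <- list(design)
  if (!length(design) || !all(vapply(design, inherits, logical(1), "glv_design")))
    glv_config_error("`design` must be a glv_design or a list of them")
  if (!is.finite(lambda) || lambda < 0) glv_config_error("`lambda` must be >= 0")
  K <- nrow(design[[1L]]$Ydes)
  D <- ncol(design[[1L]]$F)
  n_iv <- K - D - 1L
  if (!all(vapply(design, function(d) nrow(d$Ydes) == K && ncol(d$F) == D,
                  logical(1))))
    glv_config_error("all designs must share dimension and intervention count")
  Fm <- do.call(rbind, lapply(design, `[[`, "F"))
  Ydes <- do.call(cbind, lapply(design, `[[`, "Ydes"))

  A <- Ydes %*% t(Ydes) + lambda * diag(K)
  B <- Ydes %*% Fm                      # K x D
  theta <- tryCatch(t(solve(A, B)),     # D x K
    error = function(e) glv_error(
      paste0("normal matrix is singular; use lambda > 0 (", conditionMessage(e), ")"),
      "glvsim_numerical_error"))
  structure(
    list(M_hat = theta[, seq_len(D), drop = FALSE],
         g_hat = theta[, D + 1L],
         b_hat = if (n_iv > 0L) theta[, D + 1L + seq_len(n_iv), drop = FALSE]
                 else matrix(0, D, 0L),
         lambda = lambda),
    class = "glv_fit")
}

#' @export
print.glv_fit <- function(x, ...) {
  cat(sprintf("<glv_fit> D = %d, interventions = %d, lambda = %g\n",
              length(x$g_hat), ncol(x$b_hat), x$lambda))
  invisible(x)
}

#' Fit gLV parameters from one or more timecourses
#'
#' Convenience wrapper: builds a design from the latent absolute
#' abundances of each timecourse (optionally with shared intervention
#' magnitude series) and pools them into one ridge solve.
#'
#' @param timecourses A `timecourse` or list of them.
#' @param lambda Ridge penalty.
#' @param interventions_u Optional T x J magnitude matrix shared by all
#'   individuals.
#' @param ... Passed to [build_design()] (`pseudocount`, `mode`).
#' @return A `glv_fit`.
#' @export
fit_glv <- function(timecourses, lambda = 1e-6, interventions_u = NULL, ...) {
  if (inherits(timecourses, "timecourse")) timecourses <- list(timecourses)
  designs <- lapply(timecourses, function(tc)
    build_design(tc$Z, tc$times, interventions_u = interventions_u, ...))
  infer_glv_ridge(designs, lambda)
}
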