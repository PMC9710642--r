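test_that("build_design produces the documented F and Ydes shapes and values", {
  # stationary trajectory: F identically zero
  Z <- matrix(1, 5, 2)
  d <- build_design(Z, times = 0:4)
  expect_equal(d$F, matrix(0, 4, 2), ignore_attr = TRUE)
  expect_equal(dim(d$Ydes), c(3, 4))
  expect_true(all(d$Ydes[3, ] == 1))
  # unit log-increment: Z = (1, e), dt = 1 -> F = 1
  d <- build_design(matrix(c(1, exp(1))), times = 0:1, pseudocount = 1e-14)
  expect_equal(d$F[1, 1], 1, tolerance = 1e-10)
  # intervention series are truncated to T-1 columns
  d <- build_design(Z, times = 0:4, interventions_u = matrix(seq_len(5)))
  expect_equal(dim(d$Ydes), c(4, 4))
  expect_equal(d$Ydes[4, ], 1:4)
  expect_error(build_design(Z[1, , drop = FALSE]), class = "glvsim_domain_error")
  expect_error(build_design(Z, times = c(0, 1, 1, 2, 3)), class = "glvsim_domain_error")
})

test_that("log-increment F tracks the instantaneous growth rate of a logistic trajectory", {
  tc <- simulate_timecourse(
    list(logistic_node()), logistic_map(),
    config = sim_config(n_timepoints = 400, noise_var = 0, dt = 0.01,
                        n_reads = 10, seed = 1))
  d <- build_design(tc$Z, tc$times)
  zmid <- (tc$Z[-1, 1] + tc$Z[-nrow(tc$Z), 1]) / 2
  analytic <- 1 - 0.5 * zmid
  expect_lt(max(abs(d$F[, 1] - analytic)), 0.01)
})

test_that("ridge output matches an independent penalized least-squares oracle on tiny systems", {
  set.seed(31)
  for (rep in 1:5) {
    D <- sample(1:3, 1)
    TT <- sample(4:10, 1)
    Z <- matrix(rexp(TT * D, rate = 1), TT, D)
    U <- if (rep %% 2) matrix(rbinom(TT, 1, 0.5)) else NULL
    d <- build_design(Z, times = seq_len(TT), interventions_u = U)
    for (lambda in c(1e-6, 0.1, 10)) {
      fit <- infer_glv_ridge(d, lambda)
      theta <- cbind(fit$M_hat, fit$g_hat, fit$b_hat)
      expect_equal(theta, ridge_oracle(d, lambda), tolerance = 1e-8,
                   ignore_attr = TRUE)
    }
  }
})

test_that("extreme ridge penalties shrink all coefficients towards zero, monotonically", {
  sys <- three_taxon_system()
  tc <- simulate_timecourse(list(sys$node), sys$map,
    config = sim_config(n_timepoints = 50, noise_var = 0, dt = 0.01,
                        n_reads = 10, seed = 2))
  d <- build_design(tc$Z, tc$times)
  fit_huge <- infer_glv_ridge(d, 1e8)
  expect_lt(max(abs(cbind(fit_huge$M_hat, fit_huge$g_hat))), 1e-4)
  norms <- vapply(c(0.001, 0.1, 10, 1000), function(l) {
    f <- infer_glv_ridge(d, l)
    sqrt(sum(cbind(f$M_hat, f$g_hat)^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 0))
})

test_that("noiseless logistic parameters are recovered within 1%", {
  tc <- simulate_timecourse(
    list(logistic_node()), logistic_map(),
    config = sim_config(n_timepoints = 2000, noise_var = 0, dt = 0.01,
                        n_reads = 10, seed = 1))
  fit <- fit_glv(tc, lambda = 1e-8)
  expect_equal(unname(fit$g_hat), 1, tolerance = 0.01)
  expect_equal(unname(fit$M_hat[1, 1]), -0.5, tolerance = 0.01)
})

test_that("a known 3-taxon community matrix is recovered from a noiseless trajectory", {
  sys <- three_taxon_system()
  tc <- simulate_timecourse(list(sys$node), sys$map,
    config = sim_config(n_timepoints = 500, noise_var = 0, dt = 0.01,
                        n_reads = 10, seed = 3))
  fit <- fit_glv(tc, lambda = 1e-8, mode = "linear")
  expect_lt(norm(fit$M_hat - sys$M, "F") / norm(sys$M, "F"), 0.05)
  expect_lt(max(abs(fit$g_hat - sys$g)), 0.05 * max(abs(sys$g)))
})

test_that("recovery error shrinks as the trajectory grows and degrades with noise", {
  sys <- three_taxon_system()
  err_at <- function(TT, noise) {
    tc <- simulate_timecourse(list(sys$node), sys$map,
      config = sim_config(n_timepoints = TT, noise_var = noise, dt = 0.01,
                          n_reads = 10, seed = 4))
    fit <- fit_glv(tc, lambda = 1e-8, mode = "linear")
    norm(fit$M_hat - sys$M, "F") / norm(sys$M, "F")
  }
  errs <- vapply(c(50, 150, 500), err_at, numeric(1), noise = 0)
  expect_true(all(diff(errs) < 0))
  expect_gt(err_at(500, 0.05), errs[3])  # noise hurts
})

test_that("designs from several individuals pool into one consistent fit", {
  sys <- three_taxon_system()
  cc <- generate_cohort(list(sys$node), sys$map, list(),
    sim_config(n_timepoints = 200, noise_var = 0, dt = 0.01, n_reads = 10),
    cohort_config(3, seed = 5))
  fit <- fit_glv(cc, lambda = 1e-8, mode = "linear")
  expect_lt(norm(fit$M_hat - sys$M, "F") / norm(sys$M, "F"), 0.05)
  # mismatched dimensions refuse to pool
  d1 <- build_design(matrix(rexp(10), 5, 2), times = 1:5)
  d2 <- build_design(matrix(rexp(15), 5, 3), times = 1:5)
  expect_error(infer_glv_ridge(list(d1, d2), 0.1), class = "glvsim_config_error")
})

test_that("a singular normal matrix at lambda = 0 advises a positive penalty", {
  Z <- matrix(1, 6, 2)  # constant columns + ones row: rank deficient
  d <- build_design(Z, times = 1:6)
  expect_error(infer_glv_ridge(d, 0), class = "glvsim_numerical_error")
  expect_error(infer_glv_ridge(d, 0), "lambda > 0")
})
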