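test_that("glv_step: zero abundance is absorbing and zero derivative is a fixed point", {
  # all-zero state stays all-zero whatever the drive
  z0 <- rep(0, 4)
  out <- glv_step(z0, growth = runif(4), M = matrix(rnorm(16), 4),
                  intervention_drive = 5, noise_draw = 1, dt = 0.1)
  expect_identical(out, z0)
  # zero derivative: output equals input exactly
  z <- c(0.5, 1.2, 3)
  expect_identical(glv_step(z, rep(0, 3), matrix(0, 3, 3), 0, 0, dt = 0.1), z)
  # a zero coordinate stays exactly zero even among growing neighbors
  z <- c(0, 1)
  out <- glv_step(z, c(2, 2), matrix(0.1, 2, 2), 0, 0, dt = 0.1)
  expect_identical(out[1], 0)
  expect_gt(out[2], 1)
})

test_that("glv_step clamps negative excursions to zero and flags divergence", {
  out <- glv_step(0.5, growth = -100, M = matrix(0), 0, 0, dt = 1)
  expect_identical(out, 0)
  expect_error(
    glv_step(1e308, growth = 1e308, M = matrix(0), 0, 0, dt = 1, step = 7L),
    class = "glvsim_divergence_error")
  expect_error(
    glv_step(1e308, growth = 1e308, M = matrix(0), 0, 0, dt = 1, step = 7L),
    "step 7")
})

test_that("iterated logistic steps reach the fixed point -g/M, matching a fine-grid ODE oracle", {
  z <- 0.1
  for (i in 1:5000) z <- glv_step(z, 1, matrix(-0.5), 0, 0, dt = 0.01)
  expect_equal(z, 2.0, tolerance = 1e-3)
  skip_if_not_installed("deSolve")
  sol <- deSolve::ode(
    y = c(z = 0.1), times = seq(0, 50, by = 1e-3),
    func = function(t, y, p) list(y * (1 - 0.5 * y)))
  expect_equal(z, unname(sol[nrow(sol), "z"]), tolerance = 1e-3)
})

test_that("stationary multi-node systems record constant trajectories", {
  nodes <- list(node_spec("a", 2, growth_rates = c(0, 0),
                          initial_abundances = c(1, 2)),
                node_spec("b", 1, growth_rates = 0, initial_abundances = 3))
  tc <- simulate_timecourse(nodes, interactions = NULL,
                            config = sim_config(n_timepoints = 10, noise_var = 0,
                                                n_reads = 100, seed = 1))
  expect_true(all(apply(tc$Z, 1, identical, c(a_0 = 1, a_1 = 2, b_0 = 3))))
  expect_equal(dim(tc$Z), c(10, 3))
  expect_equal(tc$times, 0.01 * (0:9))
})

test_that("a simulated 1-dim logistic node converges to g/a", {
  tc <- simulate_timecourse(
    list(logistic_node()), logistic_map(),
    config = sim_config(n_timepoints = 5001, noise_var = 0, dt = 0.01,
                        n_reads = 10, seed = 1))
  expect_equal(unname(tc$Z[nrow(tc$Z), 1]), 2.0, tolerance = 1e-3)
  # monotone approach after at most one overshoot at this dt
  traj <- tc$Z[, 1]
  expect_true(all(diff(traj[traj < 2 - 1e-9]) > 0))
})

test_that("simulation is bitwise reproducible from its seed", {
  nodes <- list(node_spec("a", 3), node_spec("b", 2))
  im <- sample_interaction_matrix(c(a = 3, b = 2), matrix_gen_config(seed = 5))
  cfg <- sim_config(n_timepoints = 25, noise_var = 0.05, n_reads = 500, seed = 99)
  tc1 <- simulate_timecourse(nodes, im, config = cfg)
  tc2 <- simulate_timecourse(nodes, im, config = cfg)
  expect_identical_timecourse(tc1, tc2)
})

test_that("burn-in and downsampling set the recorded time grid", {
  nd <- node_spec("x", 1, growth_rates = 0.3, initial_abundances = 1)
  cfg <- sim_config(n_timepoints = 5, dt = 0.1, noise_var = 0, n_reads = 10,
                    downsample = 3, burn_in = 4, seed = 1)
  tc <- simulate_timecourse(list(nd), config = cfg)
  expect_equal(tc$times, (4 + 3 * (0:4)) * 0.1)
  # first recorded value is the state after exactly burn_in Euler steps
  z <- 1
  for (i in 1:4) z <- z * (1 + 0.1 * 0.3)
  expect_equal(unname(tc$Z[1, 1]), z)
})

test_that("interventions drive only their target node and sum per node", {
  nodes <- list(node_spec("a", 1, growth_rates = 0, initial_abundances = 1),
                node_spec("b", 1, growth_rates = 0, initial_abundances = 1))
  iv <- list(intervention_spec("a", magnitudes = rep(1, 3), responses = 0.5),
             intervention_spec("a", magnitudes = rep(1, 3), responses = 0.25))
  cfg <- sim_config(n_timepoints = 3, dt = 0.1, noise_var = 0, n_reads = 10, seed = 1)
  tc <- simulate_timecourse(nodes, interventions = iv, config = cfg)
  # node a grows at summed drive 0.75; node b untouched
  expect_equal(unname(tc$Z[2, 1]), 1 * (1 + 0.1 * 0.75))
  expect_equal(unname(tc$Z[, 2]), rep(1, 3))
})

test_that("shape mismatches raise configuration errors", {
  nd <- node_spec("a", 2, growth_rates = c(0, 0), initial_abundances = c(1, 1))
  expect_error(node_spec("a", 2, growth_rates = 1), class = "glvsim_config_error")
  expect_error(
    simulate_timecourse(list(nd), interventions = list(
      intervention_spec("a", magnitudes = rep(1, 99), responses = c(0, 0))),
      config = sim_config(n_timepoints = 5, seed = 1)),
    class = "glvsim_config_error")
  expect_error(
    simulate_timecourse(list(nd), interventions = list(
      intervention_spec("zzz", magnitudes = rep(1, 5), responses = c(0, 0))),
      config = sim_config(n_timepoints = 5, seed = 1)),
    class = "glvsim_config_error")
})

test_that("to_relative normalizes rows, preserves zero rows with a warning, rejects negatives", {
  expect_equal(to_relative(matrix(c(2, 2, 4), 1)), matrix(c(0.25, 0.25, 0.5), 1))
  expect_warning(out <- to_relative(matrix(c(0, 0, 0, 1, 1, 2), 2, byrow = TRUE)),
                 "all-zero")
  expect_equal(out[1, ], c(0, 0, 0))
  expect_equal(sum(out[2, ]), 1, tolerance = 1e-12)
  expect_error(to_relative(matrix(c(-1, 2), 1)), class = "glvsim_domain_error")
  # random valid rows always renormalize to 1
  set.seed(3)
  for (i in 1:20) {
    Z <- matrix(rexp(12), 3)
    expect_equal(rowSums(to_relative(Z)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("sample_reads conserves depth and honors degenerate rows", {
  Y <- sample_reads(matrix(c(1, 0, 0), 1), n_reads = 100, seed = 1)
  expect_identical(Y, matrix(c(100L, 0L, 0L), 1))
  X <- rbind(c(0.3, 0.7), c(0, 0))
  Y <- sample_reads(X, n_reads = 50, seed = 2)
  expect_equal(rowSums(Y), c(50, 0))
  expect_error(sample_reads(matrix(c(0.5, 0.2), 1), 10),
               class = "glvsim_domain_error")
})

test_that("multinomial sampling matches binomial moments (Monte Carlo)", {
  X <- matrix(c(0.5, 0.5), 1)
  set.seed(11)
  draws <- replicate(1000, sample_reads(X, n_reads = 10000)[1, 1])
  # sd per draw = sqrt(R * 0.25) = 50; 3 standard errors of the mean
  expect_lt(abs(mean(draws) - 5000), 3 * 50 / sqrt(1000))
})

test_that("mean of Y/R over many resamplings approaches X (law of large numbers)", {
  x <- c(0.1, 0.2, 0.3, 0.4)
  set.seed(21)
  acc <- matrix(0, 1000, 4)
  for (i in 1:1000) acc[i, ] <- sample_reads(matrix(x, 1), n_reads = 200) / 200
  se <- sqrt(x * (1 - x) / 200) / sqrt(1000)
  expect_true(all(abs(colMeans(acc) - x) < 3 * se))
})

test_that("coordinates with zero initial abundance stay zero under noise and interventions", {
  nd <- node_spec("a", 4, growth_rates = c(1, 1, -0.5, 0.8),
                  initial_abundances = c(1, 0, 2, 0))
  im <- sample_interaction_matrix(c(a = 4), matrix_gen_config(seed = 4))
  iv <- list(intervention_spec("a", magnitudes = rep(2, 8), responses = runif(4)))
  for (s in 1:25) {
    tc <- simulate_timecourse(list(nd), im, iv,
      config = sim_config(n_timepoints = 8, noise_var = 0.5, n_reads = 100, seed = s))
    expect_true(all(tc$Z[, c(2, 4)] == 0))
    expect_true(all(tc$Y[, c(2, 4)] == 0L))
  }
})
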