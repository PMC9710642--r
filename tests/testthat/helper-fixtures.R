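# Shared fixtures: tiny systems with known parameters, built in code.

# 1-dim logistic node: dz/dt = z (g - a z), fixed point g/a = 2
logistic_node <- function() node_spec("x", 1, growth_rates = 1,
                                      initial_abundances = 0.1)
logistic_map <- function() interaction_map(
  list(x__x = matrix(-0.5, 1, 1)), node_dims = c(x = 1))

# 3-taxon community with a fully connected random matrix and positive
# growth, the standard small recovery benchmark
three_taxon_system <- function(seed = 101) {
  im <- sample_interaction_matrix(
    c(taxa = 3), matrix_gen_config(connectivity = 1, self_penalty = 1,
                                   pair_var = 1, pair_corr = 0, seed = seed))
  set.seed(seed + 1)
  nd <- node_spec("taxa", 3, growth_rates = runif(3, 0.3, 1),
                  initial_abundances = runif(3, 0.5, 1.5))
  list(node = nd, map = im, M = as.matrix(im), g = nd$growth_rates)
}

# independent ridge oracle: per-row penalized least squares solved through
# the QR of the augmented system [t(Ydes); sqrt(lambda) I], never through
# the normal equations the implementation uses
ridge_oracle <- function(design, lambda) {
  K <- nrow(design$Ydes)
  D <- ncol(design$F)
  A <- rbind(t(design$Ydes), sqrt(lambda) * diag(K))
  theta <- vapply(seq_len(D), function(d)
    qr.solve(A, c(design$F[, d], rep(0, K))), numeric(K))
  t(theta)  # D x K
}

# Euclidean distance between the two arms' endpoint centroids in the
# common principal-component plane (the trajectories' destinations, where
# convergence to distinct attractors shows up)
arm_centroid_distance <- function(cc) {
  pt <- project_trajectories(c(cc$cases, cc$controls),
                             labels = rep(c("case", "control"),
                                          c(length(cc$cases), length(cc$controls))))
  endp <- t(vapply(pt$coords, function(m) m[nrow(m), ], numeric(2)))
  cen <- function(arm) colMeans(endp[pt$labels == arm, , drop = FALSE])
  sqrt(sum((cen("case") - cen("control"))^2))
}

expect_identical_timecourse <- function(a, b) {
  expect_identical(a$Z, b$Z)
  expect_identical(a$X, b$X)
  expect_identical(a$Y, b$Y)
  expect_identical(a$times, b$times)
}
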