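toy_instance <- function() {
  # M = 3 (N = 3 nodes), tau = 2, G = 1, p = 1
  X <- developmental_networks(matrix(c(1, 0, 0, 0, 1, 0), 3, 2),
                              node_names = c("a", "b", "c"))
  part <- stage_partition(c(1, 1))
  list(X = X, part = part, graphs = build_smoothness_graphs(part, 2))
}

test_that("smoothness graphs are chains with the right degrees", {
  g1 <- build_smoothness_graphs(stage_partition(c(1, 1, 1)), tau = 3)
  expect_equal(g1$W_U, matrix(0, 1, 1))
  expect_equal(g1$W_V[1, 2], 1)
  expect_equal(g1$W_V[2, 3], 1)
  expect_equal(g1$W_V[1, 3], 0)
  expect_equal(unname(diag(g1$D_V)), c(1, 2, 1))
  g3 <- build_smoothness_graphs(stage_partition(c(1, 2, 3)), tau = 3)
  expect_equal(g3$W_U[1, 2], 1)
  expect_equal(g3$W_U[2, 3], 1)
  expect_equal(g3$W_U[1, 3], 0)
})

test_that("objective matches hand evaluation of every term", {
  t <- toy_instance()
  U <- list(matrix(c(1, 0, 0), 3, 1))
  V <- matrix(c(1, 1), 2, 1)
  cfg <- dmd_config(p = 1, lambda = 1, alpha = 0, beta = 0)
  # 1/2(0 + 1 + 1) + 1/2 * 1 * 2 = 2
  expect_equal(dmd_objective(t$X, t$part, U, V, t$graphs, cfg), 2)
  # perfect reconstruction with no regularization: J = 0
  cfg0 <- dmd_config(p = 1, lambda = 0, alpha = 0, beta = 0)
  V2 <- matrix(c(2, 3), 2, 1)
  X2 <- developmental_networks(matrix(c(2, 0, 0, 3, 0, 0), 3, 2),
                               node_names = c("a", "b", "c"))
  expect_equal(dmd_objective(X2, t$part, U, V2, t$graphs, cfg0), 0)
  # equal stage states and equal trajectory rows: smoothness terms vanish
  part3 <- stage_partition(c(1, 1, 2, 2))
  g3 <- build_smoothness_graphs(part3, 4)
  set.seed(1)
  Uc <- matrix(runif(6), 3, 2)
  Vc <- matrix(rep(runif(2), each = 4), 4, 2)
  X3 <- developmental_networks(matrix(runif(12), 3, 4),
                               node_names = c("a", "b", "c"))
  cfgR <- dmd_config(p = 2, lambda = 0, alpha = 5, beta = 5)
  cfg0R <- dmd_config(p = 2, lambda = 0, alpha = 0, beta = 0)
  expect_equal(dmd_objective(X3, part3, list(Uc, Uc), Vc, g3, cfgR),
               dmd_objective(X3, part3, list(Uc, Uc), Vc, g3, cfg0R))
})

test_that("one update step equals a straight-line evaluation of the formulas", {
  # single-stage toy: X = [[2,0],[0,1],[0,0]], p = 1, U0 = 1/sqrt(3), V0 = 1
  X <- developmental_networks(matrix(c(2, 0, 0, 0, 1, 0), 3, 2),
                              node_names = c("a", "b", "c"))
  part <- stage_partition(c(1, 1))
  graphs <- build_smoothness_graphs(part, 2)
  cfg <- dmd_config(p = 1, lambda = 0.3, alpha = 0, beta = 0, epsilon = 0)
  U0 <- matrix(rep(1 / sqrt(3), 3), 3, 1)
  V0 <- matrix(c(1, 1), 2, 1)
  # straight-line U update: U * (X V) / (U (V^T X^T U))
  Xm <- X$X
  num_u <- Xm %*% V0
  den_u <- U0 %*% (t(V0) %*% t(Xm) %*% U0)
  expected_U <- U0 * num_u / den_u
  got_U <- update_U(X, part, list(U0), V0, graphs, cfg)
  expect_equal(got_U[[1]], expected_U, tolerance = 1e-12, ignore_attr = TRUE)
  # straight-line V update: V * (X^T U) / (V U^T U + lambda V)
  num_v <- t(Xm) %*% U0
  den_v <- V0 %*% (t(U0) %*% U0) + 0.3 * V0
  expected_V <- V0 * num_v / den_v
  got_V <- update_V(X, part, list(U0), V0, graphs, cfg)
  expect_equal(got_V, expected_V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("multi-stage updates match straight-line evaluation with smoothing", {
  set.seed(12)
  part <- stage_partition(c(1, 1, 2, 2, 3))
  X <- developmental_networks(matrix(runif(6 * 5), 6, 5),
                              node_names = paste0("n", 1:4))
  graphs <- build_smoothness_graphs(part, 5)
  cfg <- dmd_config(p = 2, lambda = 0.2, alpha = 0.4, beta = 0.3,
                    epsilon = 0)
  U <- lapply(1:3, function(t) matrix(runif(12), 6, 2))
  V <- matrix(runif(10), 5, 2)
  gotU <- update_U(X, part, U, V, graphs, cfg)
  gotV <- update_V(X, part, U, V, graphs, cfg)
  Xm <- X$X
  for (t in 1:3) {
    idx <- part$blocks[[t]]
    Xt <- Xm[, idx, drop = FALSE]
    Vt <- V[idx, , drop = FALSE]
    num <- Xt %*% Vt
    den <- U[[t]] %*% (t(Vt) %*% t(Xt) %*% U[[t]])
    d_t <- 0
    for (k in 1:3) {
      w <- graphs$W_U[t, k]
      num <- num + 0.4 * w * U[[k]]
      d_t <- d_t + w
    }
    den <- den + 0.4 * d_t * U[[t]]
    expect_equal(gotU[[t]], U[[t]] * num / den, tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # V update via explicit mask matrices H^t
  num <- 0.3 * graphs$W_V %*% V
  den <- 0.2 * V + 0.3 * graphs$D_V %*% V
  for (t in 1:3) {
    H <- matrix(0, 5, length(part$blocks[[t]]))
    H[cbind(part$blocks[[t]], seq_along(part$blocks[[t]]))] <- 1
    Xt <- Xm[, part$blocks[[t]], drop = FALSE]
    num <- num + H %*% t(Xt) %*% U[[t]]
    den <- den + H %*% t(H) %*% V %*% (t(U[[t]]) %*% U[[t]])
  }
  expect_equal(gotV, V * num / den, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("updates preserve zeros and non-negativity", {
  set.seed(7)
  part <- stage_partition(c(1, 1, 2, 2))
  X <- developmental_networks(matrix(runif(24), 6, 4),
                              node_names = paste0("n", 1:4))
  graphs <- build_smoothness_graphs(part, 4)
  cfg <- dmd_config(p = 2)
  U <- lapply(1:2, function(t) matrix(runif(12), 6, 2))
  U[[1]][2, 1] <- 0
  V <- matrix(runif(8), 4, 2)
  V[3, 2] <- 0
  for (i in 1:5) {
    U <- update_U(X, part, U, V, graphs, cfg)
    V <- update_V(X, part, U, V, graphs, cfg)
    expect_equal(unname(U[[1]][2, 1]), 0)
    expect_equal(unname(V[3, 2]), 0)
    expect_true(all(vapply(U, function(u) all(u >= 0), TRUE)))
    expect_true(all(V >= 0))
  }
  expect_error(update_U(X, part, U, -V, graphs, cfg),
               class = "devmeta_validation_error")
})

test_that("an exact orthonormal factorization is a fixed point", {
  # X^t = U^t V^tT with orthonormal non-negative U^t, alpha = 0:
  # both multipliers are exactly 1
  U0 <- matrix(0, 6, 2)
  U0[1:3, 1] <- 1 / sqrt(3)
  U0[4:6, 2] <- 1 / sqrt(3)
  V0 <- matrix(c(1, 2, 3, 4, 2, 1), 3, 2)
  X <- developmental_networks(U0 %*% t(V0), node_names = paste0("n", 1:4))
  part <- stage_partition(c(1, 1, 1))
  graphs <- build_smoothness_graphs(part, 3)
  cfg <- dmd_config(p = 2, lambda = 0, alpha = 0, beta = 0, epsilon = 0)
  expect_equal(update_U(X, part, list(U0), V0, graphs, cfg)[[1]], U0,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(update_V(X, part, list(U0), V0, graphs, cfg), V0,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("objective traces are non-increasing on random instances", {
  worst <- 0
  for (s in 1:15) {
    inst <- random_instance(s)
    fit <- dmd_fit(inst$X, inst$partition,
                   dmd_config(p = inst$p, n_init = 1, max_iter = 200,
                              seed = s))
    rel <- max(diff(fit$objective_trace)) / fit$objective_trace[1]
    worst <- max(worst, rel)
    expect_true(all(vapply(fit$U, function(u) all(u >= 0), TRUE)))
    expect_true(all(fit$V >= 0))
  }
  expect_lte(worst, 1e-9)
})

test_that("with one stage and no smoothing the fit equals a single-block run", {
  set.seed(21)
  X <- developmental_networks(matrix(runif(10 * 6), 10, 6),
                              node_names = paste0("n", 1:5))
  part <- stage_partition(rep(1, 6))
  cfg <- dmd_config(p = 2, lambda = 0.2, alpha = 0, beta = 0, n_init = 1,
                    max_iter = 60, tol = 1e-12, seed = 3)
  fit <- dmd_fit(X, part, cfg)
  # direct single-block implementation of the same damped scheme
  set.seed(3)
  Xm <- X$X
  U <- matrix(runif(20, min = .Machine$double.eps, max = 1), 10, 2)
  U <- sweep(U, 2, sqrt(colSums(U^2)), "/")
  V <- matrix(runif(12, min = .Machine$double.eps, max = 1), 6, 2)
  recon <- U %*% t(V)
  V <- V * sum(Xm * recon) / sum(recon^2)
  J <- function(U, V) 0.5 * sum((Xm - U %*% t(V))^2) + 0.1 * sum(V^2)
  trace <- J(U, V)
  for (it in 1:60) {
    R <- (Xm %*% V) / (U %*% (t(V) %*% t(Xm) %*% U) + 1e-12)
    f0 <- 0.5 * sum((Xm - U %*% t(V))^2)
    eta <- 0.5
    for (h in 1:7) {
      cand <- U * R^eta
      if (0.5 * sum((Xm - cand %*% t(V))^2) <= f0) { U <- cand; break }
      eta <- eta / 2
    }
    V <- V * (t(Xm) %*% U) / (V %*% crossprod(U) + 0.2 * V + 1e-12)
    trace <- c(trace, J(U, V))
    if (abs(trace[length(trace) - 1] - trace[length(trace)]) /
          trace[length(trace) - 1] < 1e-12) break
  }
  expect_equal(fit$objective_trace, trace, tolerance = 1e-12)
  expect_equal(fit$V, V, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("noiseless planted factorizations are recovered near-orthonormally", {
  sim <- generate_planted_networks(noise_sd = 0, seed = 3)
  fit <- dmd_fit(sim$networks, sim$model$partition,
                 dmd_config(p = 3, n_init = 5, max_iter = 2000, tol = 1e-9,
                            seed = 4))
  m <- match_to_planted(fit, sim$model)
  expect_gte(mean(m$cos_U), 0.95)
  expect_gte(mean(m$cos_V), 0.99)
  # stage states have essentially non-overlapping supports (off-diagonal
  # Gram entries near zero); column scales equilibrate near but not at 1
  # under the ridge, so the full gap is a looser diagnostic
  for (t in 1:3) {
    Gm <- crossprod(fit$U[[t]])
    off <- Gm - diag(diag(Gm))
    expect_lte(max(abs(off)), 0.1)
  }
  expect_lte(max(fit$orthogonality_gap), 0.3)
})

test_that("minimal trajectory distance follows its closed forms", {
  expect_equal(compute_mtd(cbind(c(1, 2, 3), c(1, 2, 3))), 0)
  expect_equal(compute_mtd(cbind(c(1, 0), c(0, 1))), sqrt(2))
  # V = [[1,0],[0,1],[1,1]]: normalized columns (1,0,1)/sqrt(2), (0,1,1)/sqrt(2)
  V <- matrix(c(1, 0, 1, 0, 1, 1), 3, 2)
  expect_equal(compute_mtd(V), 1)
  expect_error(compute_mtd(matrix(1, 3, 1)),
               class = "devmeta_parameter_error")
})

test_that("meta-network count selection maximizes MTD with parsimony ties", {
  sim <- generate_planted_networks(N = 12, tau = 6, G = 2, p = 2, seed = 2)
  cfg <- dmd_config(p = 2, n_init = 2, max_iter = 150, seed = 5)
  sel <- select_num_dms(sim$networks, sim$model$partition, p_range = 3, cfg)
  expect_equal(sel$p, 3)
  expect_named(sel$mtd, "3")
  expect_error(select_num_dms(sim$networks, sim$model$partition, 1:3, cfg),
               class = "devmeta_parameter_error")
})

test_that("fit validates the component count", {
  sim <- generate_planted_networks(N = 8, tau = 4, G = 2, p = 2, seed = 1)
  expect_error(dmd_fit(sim$networks, sim$model$partition,
                       dmd_config(p = 5, n_init = 1, max_iter = 5)),
               class = "devmeta_parameter_error")
  expect_warning(dmd_fit(sim$networks, sim$model$partition,
                         dmd_config(p = 3, n_init = 1, max_iter = 5,
                                    seed = 1)),
                 "stage size")
})

test_that("configuration rejects invalid hyperparameters", {
  expect_error(dmd_config(p = 0), class = "devmeta_parameter_error")
  expect_error(dmd_config(p = 2, lambda = -1),
               class = "devmeta_parameter_error")
  expect_error(dmd_config(p = 2, tol = 0), class = "devmeta_parameter_error")
  expect_equal(dmd_config(p = 2)$n_init, 100L)
})
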