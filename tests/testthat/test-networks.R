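test_that("confound regression reduces to centering for a constant covariate", {
  tb <- measurement_table(matrix(c(2, 4, 6), 3, 1), timepoint_label = 5,
                          covariates = data.frame(const = c(1, 1, 1)))
  res <- regress_confounds(tb, "const")
  expect_equal(unname(res$values[, 1]), c(-2, 0, 2))
})

test_that("OLS residuals match the closed-form oracle on the 4-point design", {
  tb <- measurement_table(matrix(c(1, 2, 3, 4), 4, 1), timepoint_label = 1,
                          covariates = data.frame(b = c(0, 0, 1, 1)))
  res <- regress_confounds(tb, "b")
  expect_equal(unname(res$values[, 1]), c(-0.5, 0.5, -0.5, 0.5))
})

test_that("residuals are zero-mean and uncorrelated with numeric confounds", {
  set.seed(31)
  n <- 40
  cov <- data.frame(gender = factor(sample(c("F", "M"), n, replace = TRUE)),
                    mean_thickness = rnorm(n, 2.5, 0.2))
  vals <- matrix(rnorm(n * 6, 2.5, 0.3), n, 6) + 0.5 * cov$mean_thickness
  tb <- measurement_table(vals, timepoint_label = 7, covariates = cov)
  res <- regress_confounds(tb, c("gender", "mean_thickness"))
  expect_true(all(abs(colMeans(res$values)) < 1e-10))
  r <- apply(res$values, 2, function(v) cor(v, cov$mean_thickness))
  expect_true(all(abs(r) < 1e-10))
})

test_that("residuals are invariant to affine rescaling of a numeric confound", {
  set.seed(32)
  n <- 20
  cov1 <- data.frame(x = rnorm(n))
  cov2 <- data.frame(x = 3.7 * cov1$x - 11)
  vals <- matrix(rnorm(n * 4), n, 4)
  r1 <- regress_confounds(measurement_table(vals, 1, cov1), "x")
  r2 <- regress_confounds(measurement_table(vals, 1, cov2), "x")
  expect_equal(r1$values, r2$values, tolerance = 1e-10)
})

test_that("confound regression validates its inputs", {
  tb <- measurement_table(matrix(rnorm(12), 4, 3), timepoint_label = 1,
                          covariates = data.frame(a = rnorm(4)))
  expect_error(regress_confounds(tb, "missing"),
               class = "devmeta_config_error")
  tb2 <- measurement_table(matrix(rnorm(20), 5, 4), timepoint_label = 1,
                           covariates = data.frame(a = rnorm(5),
                                                   b = 1:5, c = 2 * (1:5)))
  err <- tryCatch(regress_confounds(tb2, c("a", "b", "c")),
                  error = function(e) e)
  expect_s3_class(err, "devmeta_degenerate_design_error")
  expect_match(conditionMessage(err), "c")
})

test_that("correlation networks take absolute Pearson r with zero diagonal", {
  vals <- cbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  tb <- measurement_table(vals, timepoint_label = 1)
  net <- build_correlation_network(tb)
  expect_equal(net$weights["a", "b"], 1)   # identical vectors
  expect_equal(net$weights["a", "c"], 1)   # perfect anticorrelation, |r|
  expect_equal(unname(diag(net$weights)), rep(0, 3))
  vals2 <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4))
  net2 <- build_correlation_network(measurement_table(vals2, 1))
  expect_equal(net2$weights["a", "b"], 0.8)  # hand-computed Pearson
})

test_that("correlation network preconditions are enforced", {
  tb <- measurement_table(matrix(rnorm(4), 2, 2), timepoint_label = 1)
  expect_error(build_correlation_network(tb),
               class = "devmeta_insufficient_sample_error")
  vals <- cbind(flat = c(1, 1, 1, 1), x = rnorm(4))
  err <- tryCatch(build_correlation_network(measurement_table(vals, 1)),
                  error = function(e) e)
  expect_s3_class(err, "devmeta_validation_error")
  expect_match(conditionMessage(err), "flat")
})

test_that("vectorization is the strict upper triangle and round-trips", {
  # N = 2: single off-diagonal weight
  net2 <- network(matrix(c(0, 0.4, 0.4, 0), 2, 2),
                  node_names = c("a", "b"), timepoint_label = 1)
  expect_equal(unname(vectorize_network(net2)), 0.4)
  # row-major (i < j) ordering on a labelled 3-node network
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.12
  w[1, 3] <- w[3, 1] <- 0.13
  w[2, 3] <- w[3, 2] <- 0.23
  v <- vectorize_network(network(w, node_names = c("a", "b", "c")))
  expect_equal(unname(v), c(0.12, 0.13, 0.23))
  expect_equal(names(v), c("a--b", "a--c", "b--c"))
  # round-trip identity on a random valid 5-node network
  net5 <- random_network(5, seed = 1)
  back <- devectorize_network(vectorize_network(net5), net5$node_names)
  expect_equal(back$weights, net5$weights)
})

test_that("a 78-node network vectorizes to 3003 connections", {
  net <- random_network(78, seed = 2)
  expect_length(vectorize_network(net), 3003)
})

test_that("asymmetric matrices beyond tolerance are rejected", {
  w <- matrix(c(0, 0.5, 0.1, 0), 2, 2)
  expect_error(network(w), class = "devmeta_validation_error")
})

test_that("assembling networks builds the M x tau stack in time order", {
  nets <- lapply(1:4, function(i) random_network(5, timepoint_label = i,
                                                 seed = i))
  X <- assemble_developmental_networks(nets)
  expect_equal(dim(X$X), c(10, 4))
  expect_equal(X$M, 10)
  expect_equal(X$tau, 4)
  expect_equal(X$X[, 3], unname(vectorize_network(nets[[3]])),
               ignore_attr = TRUE)
  # single network: tau = 1 stack
  X1 <- assemble_developmental_networks(nets[1])
  expect_equal(X1$tau, 1)
  # shuffled labels violate the ordering precondition
  expect_error(assemble_developmental_networks(nets[c(2, 1, 3)]),
               class = "devmeta_validation_error")
  # mismatched node sets are reported with the symmetric difference
  odd <- random_network(5, timepoint_label = 9, seed = 5)
  odd$node_names[5] <- "EXTRA"
  dimnames(odd$weights) <- list(odd$node_names, odd$node_names)
  err <- tryCatch(assemble_developmental_networks(c(nets, list(odd))),
                  error = function(e) e)
  expect_match(conditionMessage(err), "EXTRA")
})
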