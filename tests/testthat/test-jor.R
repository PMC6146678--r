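test_that("a single regressor equals the global ridge closed form", {
  fx <- fixture_linear_pool(N = 50L, noise = 0.02)
  m <- jor_fit(list(X_l = fx$X_l, X_h = fx$X_h), O = 1L, n_iters = 3L,
               lambda = 0.1, seed = 1L)
  P_oracle <- oracle_global_ridge(fx$X_h, fx$X_l, 0.1)
  expect_equal(m$projections[[1L]], P_oracle, tolerance = 1e-8)
  expect_equal(tail(m$objective, 1),
               sum((P_oracle %*% fx$X_l - fx$X_h)^2), tolerance = 1e-8)
})

test_that("EM recovers a planted two-map partition with near-zero objective", {
  fx <- fixture_two_maps(N = 400L)
  m <- jor_fit(list(X_l = fx$X_l, X_h = fx$X_h), O = 2L, n_iters = 20L,
               lambda = 1e-8, seed = 3L, n_restarts = 8L)
  agree <- mean(m$assignments == fx$labels)
  expect_true(agree %in% c(0, 1))            # exact up to label swap
  expect_lt(tail(m$objective, 1), 1e-10)
})

test_that("the joint objective is non-increasing across EM iterations", {
  ps <- fixture_patches(48)
  # with a vanishing ridge weight the E-step minimizes the pure
  # reconstruction objective, so the recorded sequence cannot increase
  m0 <- jor_fit(ps, O = 4L, n_iters = 10L, lambda = 1e-10, seed = 2L)
  expect_true(all(diff(m0$objective) <= 1e-9 * (1 + m0$objective[1])))
  # at the reference ridge weight the E-step trades a little reconstruction
  # error for shrinkage; the sequence still decreases up to that slack
  m <- jor_fit(ps, O = 4L, n_iters = 10L, lambda = 0.1, seed = 2L)
  expect_true(all(diff(m$objective) <= 1e-3 * (1 + m$objective[1])))
  # determinism
  m2 <- jor_fit(ps, O = 4L, n_iters = 10L, lambda = 0.1, seed = 2L)
  expect_identical(m$assignments, m2$assignments)
  expect_identical(m$projections, m2$projections)
})

test_that("regressor selection follows the kNN majority with stated tie-breaks", {
  fx <- fixture_two_maps(N = 100L)
  m <- jor_fit(list(X_l = fx$X_l, X_h = fx$X_h), O = 2L, n_iters = 10L,
               lambda = 1e-8, K_select = 1L, seed = 1L)
  # query equal to a training patch with K_select = 1 -> that sample's label
  expect_equal(jor_select_regressor(fx$X_l[, 17L], m), m$assignments[17L])

  # hand-built 3-cluster model: 5 neighbors with labels (2,2,1,1,1) -> 1
  pool <- cbind(c(0, 0), c(0.1, 0), c(1, 0), c(1.1, 0), c(1.2, 0), c(9, 9))
  hand <- structure(list(
    projections = replicate(3, matrix(0, 2, 2), simplify = FALSE),
    assignments = c(2L, 2L, 1L, 1L, 1L, 3L), pool_lr = pool,
    O = 3L, K_select = 5L, lambda = 0.1), class = c("jor_model", "sr_model"))
  expect_equal(jor_select_regressor(c(0.5, 0), hand), 1L)
  # all neighbors share one label -> that label
  hand$assignments <- rep(2L, 6L)
  expect_equal(jor_select_regressor(c(0.5, 0), hand), 2L)
})

test_that("reconstruction applies the selected stored projection to the raw patch", {
  fx <- fixture_two_maps(N = 200L)
  m <- jor_fit(list(X_l = fx$X_l, X_h = fx$X_h), O = 2L, n_iters = 15L,
               lambda = 1e-8, K_select = 5L, seed = 2L, n_restarts = 8L)
  expect_equal(jor_reconstruct_patch(numeric(9), m), numeric(36))
  q <- fx$X_l[, 30L] + withr::with_seed(4, rnorm(9, sd = 0.05))
  o <- jor_select_regressor(q, m)
  expect_equal(jor_reconstruct_patch(q, m), drop(m$projections[[o]] %*% q))
  # a query from cluster 1's region reconstructs through (almost exactly) A1
  expect_lt(sum((jor_reconstruct_patch(q, m) - fx$A1 %*% q)^2), 1e-8)
})
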