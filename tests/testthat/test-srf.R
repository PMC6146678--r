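test_that("split_quality evaluates the regularized measure term by term", {
  lr <- cbind(c(0, 0), c(2, 2))
  hr <- cbind(c(1, 1, 1), c(3, 3, 3))
  pred <- hr                                  # perfect predictions
  expect_equal(split_quality(lr, hr, pred, kappa = 0), 0)

  # single sample: compactness term vanishes
  expect_equal(split_quality(lr[, 1, drop = FALSE], hr[, 1, drop = FALSE],
                             hr[, 1, drop = FALSE] + 1, kappa = 5), 3)

  # two samples, identity-like prediction error + kappa compactness, by hand:
  # errors: ||(1,1,1)-(0,0,0)||^2 = 3, ||(3,3,3)-(4,4,4)||^2 = 3
  # lr mean (1,1): each sample contributes 2 -> E = (3+3 + 1*(2+2))/2 = 5
  pred2 <- cbind(c(0, 0, 0), c(4, 4, 4))
  expect_equal(split_quality(lr, hr, pred2, kappa = 1), 5)
  expect_error(split_quality(lr[, 0, drop = FALSE], hr[, 0, drop = FALSE],
                             pred2[, 0, drop = FALSE], 1), "empty")
})

test_that("a depth-0 single-tree forest is the global ridge regressor", {
  fx <- fixture_linear_pool(N = 60L, noise = 0.02)
  f <- train_srf(list(X_l = fx$X_l, X_h = fx$X_h), n_trees = 1L,
                 max_depth = 0L, lambda = 0.1, seed = 1L)
  P_oracle <- oracle_global_ridge(fx$X_h, fx$X_l, 0.1)
  q <- withr::with_seed(5, rnorm(9))
  expect_equal(srf_reconstruct_patch(q, f), drop(P_oracle %*% q),
               tolerance = 1e-8)
})

test_that("deeper trees never increase leaf-wise training error", {
  ps <- fixture_patches(48)
  sse_of <- function(depth) {
    f <- train_srf(ps, n_trees = 1L, max_depth = depth, lambda = 0.1,
                   seed = 4L)
    sum((predict_patches(f, ps$X_l) - ps$X_h)^2)
  }
  expect_lte(sse_of(15L), sse_of(0L) + 1e-9)
})

test_that("forests are deterministic for a fixed seed", {
  ps <- fixture_patches(32)
  f1 <- train_srf(ps, n_trees = 2L, max_depth = 4L, seed = 9L)
  f2 <- train_srf(ps, n_trees = 2L, max_depth = 4L, seed = 9L)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  expect_false(identical(serialize(f1, NULL),
                         serialize(train_srf(ps, n_trees = 2L, max_depth = 4L,
                                             seed = 10L), NULL)))
})

test_that("prediction averages the routed leaf models over the trees", {
  W_a <- matrix(1, 4, 2); W_b <- matrix(3, 4, 2)
  leaf <- function(W) list(leaf = TRUE, leaf_map = W, n_samples = 10L)
  forest2 <- structure(list(trees = list(leaf(W_a), leaf(W_b)), n_trees = 2L,
                            max_depth = 0L, lambda = 0.1, kappa = 1,
                            min_leaf = 3L, n_candidates = 1L, seed = 1L),
                       class = c("sr_forest", "sr_model"))
  q <- c(1, 2)
  expect_equal(srf_reconstruct_patch(q, forest2),
               drop((W_a %*% q + W_b %*% q)) / 2)
  # T identical trees collapse to a single tree's prediction
  forest_same <- forest2
  forest_same$trees <- list(leaf(W_a), leaf(W_a))
  expect_equal(srf_reconstruct_patch(q, forest_same), drop(W_a %*% q))
})

test_that("routing is total and a planted linear map is recovered at depth 0", {
  fx <- fixture_linear_pool(N = 300L, noise = 0)
  tr <- 1:250; te <- 251:300
  f <- train_srf(list(X_l = fx$X_l[, tr], X_h = fx$X_h[, tr]), n_trees = 1L,
                 max_depth = 0L, lambda = 1e-8, seed = 1L)
  pred <- predict_patches(f, fx$X_l[, te])
  expect_lt(max(colSums((pred - fx$X_h[, te])^2)), 1e-6)

  # every random query routes to exactly one leaf per tree: predictions finite
  deep <- train_srf(fixture_patches(48), n_trees = 3L, max_depth = 8L,
                    seed = 2L)
  Q <- withr::with_seed(6, matrix(rnorm(9 * 200, sd = 10), 9, 200))
  expect_true(all(is.finite(predict_patches(deep, Q))))
})
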