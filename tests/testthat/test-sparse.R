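test_that("OMP selects exact atoms, honors L, and is near the exhaustive bound", {
  D <- fixture_dictionary(S = 5L, B = 8L)
  sig <- D[, 3L]
  code <- omp_encode(sig, D, L = 3L)
  expect_equal(which(code != 0), 3L)
  expect_equal(code[3L], 1)

  withr::with_seed(4, s <- rnorm(5))
  c1 <- omp_encode(s, D, L = 1L)
  expect_equal(which(c1 != 0), which.max(abs(crossprod(D, s))))

  # greedy residual can never beat the best support of the same size, and
  # must equal its own support's exhaustive least-squares re-fit
  for (i in 1:10) {
    withr::with_seed(300 + i, sg <- rnorm(5))
    code2 <- omp_encode(sg, D, L = 2L)
    act <- which(code2 != 0)
    r_greedy <- sqrt(sum((sg - D %*% code2)^2))
    r_best <- oracle_best_support_residual(sg, D, 2L)
    expect_gte(r_greedy, r_best - 1e-12)
    refit <- solve(crossprod(D[, act]), crossprod(D[, act], sg))
    expect_equal(sqrt(sum((sg - D[, act] %*% refit)^2)), r_greedy,
                 tolerance = 1e-10)
  }

  expect_error(omp_encode(s, D, L = 9L), "L must be")
  expect_error(omp_encode(s, 2 * D, L = 1L), "unit-normalized")
})

test_that("OMP residual norm is non-increasing in L", {
  D <- fixture_dictionary(S = 9L, B = 20L, seed = 33L)
  withr::with_seed(12, s <- rnorm(9))
  res <- vapply(1:6, function(L)
    sqrt(sum((s - D %*% omp_encode(s, D, L))^2)), numeric(1))
  expect_true(all(diff(res) <= 1e-12))
})

test_that("K-SVD recovers planted atoms and keeps unit norms and falling MSE", {
  fx <- fixture_planted_atoms(B0 = 8L, reps = 20L)
  dict <- train_zeyde_dictionary(
    list(X_l = fx$X_l, X_h = fx$X_l), B = 8L, L = 1L, n_iters = 20L, seed = 2L)

  expect_equal(sqrt(colSums(dict$D_l^2)), rep(1, 8), tolerance = 1e-10)
  # greedy-match recovered atoms to planted atoms by absolute correlation
  corr <- abs(crossprod(fx$atoms, dict$D_l))
  matched <- numeric(8)
  for (k in 1:8) {
    w <- which(corr == max(corr), arr.ind = TRUE)[1, ]
    matched[k] <- corr[w[1], w[2]]
    corr[w[1], ] <- -1; corr[, w[2]] <- -1
  }
  expect_true(all(matched >= 0.99))

  # coding MSE non-increasing over full sweeps
  expect_true(all(diff(dict$objective) <= 1e-6 * (1 + dict$objective[-1])))
})

test_that("the pseudo-inverse HR dictionary beats random candidates", {
  fx <- fixture_linear_pool(N = 80L)
  dict <- train_zeyde_dictionary(list(X_l = fx$X_l, X_h = fx$X_h),
                                 B = 16L, L = 3L, n_iters = 5L, seed = 3L)
  codes <- ffasr:::.omp_batch(dict$D_l, fx$X_l, 3L)
  Z <- ffasr:::.omp_codes_dense(codes, 16L)
  err_closed <- sum((fx$X_h - dict$D_h %*% Z)^2)
  errs <- withr::with_seed(44, vapply(1:100, function(i) {
    cand <- matrix(rnorm(length(dict$D_h), sd = stats::sd(dict$D_h)),
                   nrow(dict$D_h))
    sum((fx$X_h - cand %*% Z)^2)
  }, numeric(1)))
  expect_true(all(err_closed <= errs))
})

test_that("joint coupled training decreases its objective and beats the data-copy bound", {
  ps <- fixture_patches(64)
  sub <- list(X_l = ps$X_l[, 1:200], X_h = ps$X_h[, 1:200])
  dict <- train_joint_dictionary(sub, B = 48L, lambda = 0.1, n_iters = 10L,
                                 seed = 1L)
  expect_equal(dim(dict$D_l), c(9L, 48L))
  expect_equal(dim(dict$D_h), c(36L, 48L))
  expect_equal(sqrt(colSums(dict$D_l^2)), rep(1, 48L), tolerance = 1e-10)
  obj <- dict$objective
  expect_true(all(diff(obj) <= 1e-6 * (1 + abs(obj[-length(obj)]))))

  # feasible-point bound: with B = N, lambda ~ 0 and the data as the initial
  # dictionary, Z = I is feasible with objective ~ the L1 term only
  tiny <- list(X_l = ps$X_l[, 1:40], X_h = ps$X_h[, 1:40])
  lam <- 1e-3
  d2 <- train_joint_dictionary(tiny, B = 40L, lambda = lam, n_iters = 3L,
                               seed = 1L, max_pass = 1000L, tol = 1e-10,
                               init = list(D_l = tiny$X_l, D_h = tiny$X_h))
  S_h <- 36L; S_l <- 9L
  init_obj <- lam * (1 / S_h + 1 / S_l) * 40  # ||Z||_1 = N at Z = I
  expect_lte(tail(d2$objective, 1), init_obj + 1e-10)
})

test_that("coupled reconstruction: atom transfer, zero patches, and DC invariance", {
  fx <- fixture_linear_pool(N = 100L)
  dict <- train_zeyde_dictionary(list(X_l = fx$X_l, X_h = fx$X_h),
                                 B = 24L, L = 4L, n_iters = 5L, seed = 5L)
  j <- 7L
  expect_equal(sparse_reconstruct_patch(dict$D_l[, j], dict), dict$D_h[, j],
               tolerance = 1e-8)
  expect_equal(sparse_reconstruct_patch(numeric(9), dict), numeric(36))

  ps <- fixture_patches(64)
  ydict <- train_joint_dictionary(list(X_l = ps$X_l[, 1:150],
                                       X_h = ps$X_h[, 1:150]),
                                  B = 32L, n_iters = 5L, seed = 2L)
  expect_equal(sparse_reconstruct_patch(numeric(9), ydict), numeric(36))
})

test_that("held-out sparse reconstruction beats bicubic patch upscaling on linear-map data", {
  # HR patches are a fixed linear map of the LR patches; a trained coupled
  # dictionary should predict held-out HR patches far better than bicubic
  # upscaling of the LR patch can
  fx <- fixture_linear_pool(N = 260L, noise = 0.001, seed = 15L)
  scale <- 6                       # keep intensities patch-like
  X_l <- fx$X_l / scale; X_h <- fx$X_h / scale
  tr <- 1:200; te <- 201:260
  dict <- train_zeyde_dictionary(list(X_l = X_l[, tr], X_h = X_h[, tr]),
                                 B = 64L, L = 3L, n_iters = 8L, seed = 1L)
  err_dict <- mean(colSums((predict_patches(dict, X_l[, te]) - X_h[, te])^2))
  err_bic <- mean(vapply(te, function(i) {
    lrp <- matrix(X_l[, i] + 0.5, 3, 3)       # shift into [0,1] for resizing
    up <- bicubic_resize(pmin(pmax(lrp, 0), 1), 6, 6) - 0.5
    sum((up - X_h[, i])^2)
  }, numeric(1)))
  expect_lt(err_dict, err_bic)
})
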