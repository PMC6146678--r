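test_that("knn_search matches an exhaustive distance sort and breaks ties low", {
  pool <- fixture_linear_pool(N = 20L)$X_l
  q <- pool[, 7L]
  nn <- knn_search(q, pool, 1L)
  expect_equal(nn$indices, 7L)
  expect_equal(nn$distances, 0)

  withr::with_seed(3, {
    pool5 <- matrix(rnorm(45), 9, 5)
    q2 <- rnorm(9)
  })
  d <- sqrt(colSums((pool5 - q2)^2))
  expect_equal(knn_search(q2, pool5, 3L)$indices, order(d)[1:3])
  expect_equal(knn_search(q2, pool5, 5L)$indices, order(d))

  # duplicated columns: the lower index wins
  dup <- cbind(pool5[, 2], pool5)
  expect_equal(knn_search(pool5[, 2], dup, 2L)$indices, c(1L, 3L))
  expect_error(knn_search(q2, pool5, 6L), "exceeds")
})

test_that("batch kNN agrees with the single-query search", {
  pool <- fixture_linear_pool(N = 60L)$X_l
  Q <- pool[, 1:10] + 0.01
  nb <- ffasr:::.knn_batch(Q, pool, 4L, chunk = 3L)
  for (i in 1:10)
    expect_equal(nb$indices[, i], knn_search(Q[, i], pool, 4L)$indices)
})

test_that("sum-to-one LS weights match the equality-constrained oracle", {
  expect_equal(solve_ls_weights(rnorm(9), matrix(rnorm(9), 9, 1)), 1)

  withr::with_seed(5, {
    N <- matrix(rnorm(18), 9, 2)
    q <- 0.5 * N[, 1] + 0.5 * N[, 2]
  })
  expect_equal(solve_ls_weights(q, N), c(0.5, 0.5), tolerance = 1e-6)

  # general position, K < S: jittered Gram vs direct KKT solve
  withr::with_seed(6, {
    N4 <- matrix(rnorm(36), 9, 4)
    q4 <- rnorm(9)
  })
  expect_equal(solve_ls_weights(q4, N4), oracle_ls_sum1(q4, N4),
               tolerance = 1e-5)

  # identical neighbors collapse to uniform weights (up to the Gram jitter)
  withr::with_seed(31, {
    same <- matrix(rep(rnorm(9), 4), 9, 4)
    q_same <- rnorm(9)
  })
  expect_equal(solve_ls_weights(q_same, same), rep(0.25, 4),
               tolerance = 1e-6)

  # weights always sum to one
  for (i in 1:20) {
    withr::with_seed(100 + i, {
      Nr <- matrix(rnorm(9 * 24), 9, 24)
      qr_ <- rnorm(9)
    })
    expect_equal(sum(solve_ls_weights(qr_, Nr)), 1, tolerance = 1e-8)
  }
})

test_that("NNLS weights match the exhaustive-active-set oracle and stay non-negative", {
  n1 <- c(1, 2, 0.5, 1)
  expect_equal(solve_nnls_weights(2 * n1, matrix(n1, 4, 1)), 2,
               tolerance = 1e-10)
  expect_equal(solve_nnls_weights(-n1, matrix(n1, 4, 1)), 0)

  for (i in 1:10) {
    withr::with_seed(200 + i, {
      A <- matrix(abs(rnorm(20)), 5, 4)
      b <- A %*% c(0.3, 0, 0.7, 0) + rnorm(5, sd = 0.05)
    })
    w <- solve_nnls_weights(drop(b), A)
    expect_true(all(w >= -1e-12))
    expect_equal(w, oracle_nnls(A, drop(b)), tolerance = 1e-8)
  }
})

test_that("NE reconstruction transfers, interpolates and commutes with pool permutation", {
  fx <- fixture_linear_pool(N = 50L)
  m1 <- ne_model(fx$X_l, fx$X_h, K = 1L, variant = "ls")
  # K = 1 is exact nearest-neighbor patch transfer
  expect_equal(ne_reconstruct_patch(fx$X_l[, 12L], m1), fx$X_h[, 12L])

  # query midway between two neighbors with a two-column pool -> HR mean
  m2 <- ne_model(fx$X_l[, 1:2], fx$X_h[, 1:2], K = 2L, variant = "ls")
  q <- 0.5 * fx$X_l[, 1] + 0.5 * fx$X_l[, 2]
  expect_equal(ne_reconstruct_patch(q, m2),
               0.5 * (fx$X_h[, 1] + fx$X_h[, 2]), tolerance = 1e-6)

  # HR = A LR pool: reconstruction equals A applied to the LR combination
  m <- ne_model(fx$X_l, fx$X_h, K = 5L, variant = "ls")
  qq <- withr::with_seed(8, rnorm(9, sd = 0.3))
  nn <- knn_search(qq, fx$X_l, 5L)
  w <- solve_ls_weights(qq, fx$X_l[, nn$indices])
  comb <- drop(fx$X_l[, nn$indices] %*% w)
  expect_equal(ne_reconstruct_patch(qq, m), drop(fx$A %*% comb),
               tolerance = 1e-8)

  # joint column permutation leaves reconstructions unchanged
  perm <- withr::with_seed(9, sample(50L))
  mp <- ne_model(fx$X_l[, perm], fx$X_h[, perm], K = 5L, variant = "nnls")
  mo <- ne_model(fx$X_l, fx$X_h, K = 5L, variant = "nnls")
  expect_equal(ne_reconstruct_patch(qq, mp), ne_reconstruct_patch(qq, mo),
               tolerance = 1e-8)
})
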