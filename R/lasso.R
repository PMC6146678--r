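# Batch L1-regularized least squares (lasso) by cyclic coordinate descent,
# vectorized across signals: for objective ||x - D a||_2^2 + lambda ||a||_1
# the atom-j update is a soft threshold at lambda / 2.

# D: S x B, X: S x N, Z0 optional warm start (B x N).  Returns B x N codes.
.lasso_cd <- function(D, X, lambda, max_pass = 50L, tol = 1e-6, Z0 = NULL) {
  B <- ncol(D)
  n <- ncol(X)
  dn2 <- colSums(D^2)
  Z <- Z0 %||% matrix(0, B, n)
  R <- X - D %*% Z
  thr <- lambda / 2
  for (pass in seq_len(max_pass)) {
    delta_max <- 0
    for (j in seq_len(B)) {
      if (dn2[j] <= 1e-20) next
      zj <- Z[j, ]
      cj <- drop(crossprod(D[, j], R)) + dn2[j] * zj
      znew <- sign(cj) * pmax(abs(cj) - thr, 0) / dn2[j]
      d <- znew - zj
      if (any(d != 0)) {
        R <- R - tcrossprod(D[, j], d)
        Z[j, ] <- znew
        delta_max <- max(delta_max, max(abs(d)))
      }
    }
    if (delta_max < tol * max(1, max(abs(Z)))) break
  }
  Z
}
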