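# Independent oracles.  Each is coded from the definition, without reusing
# the implementation paths it checks.

# Naive bicubic resampler: per output sample, evaluate the cubic kernel
# (a = -0.5) against every input sample, clamp coordinates, renormalize.
# Same conventions (center alignment, edge replication, kernel dilation on
# downscale) as the production resampler, but direct O(n^2) evaluation.
oracle_bicubic <- function(img, out_h, out_w) {
  cub <- function(t) {
    t <- abs(t)
    ifelse(t <= 1, 1.5 * t^3 - 2.5 * t^2 + 1,
           ifelse(t < 2, -0.5 * t^3 + 2.5 * t^2 - 4 * t + 2, 0))
  }
  axis_weights <- function(n_in, n_out) {
    scale <- n_out / n_in
    W <- matrix(0, n_out, n_in)
    for (i in seq_len(n_out)) {
      u <- (i - 0.5) / scale + 0.5
      for (j in seq_len(n_in)) {
        # accumulate the kernel mass of every tap whose clamped index is j
        w <- 0
        for (jj in seq.int(floor(u) - 12, floor(u) + 12)) {
          if (min(max(jj, 1), n_in) == j) {
            w <- w + if (scale < 1) scale * cub(scale * (u - jj)) else cub(u - jj)
          }
        }
        W[i, j] <- w
      }
      W[i, ] <- W[i, ] / sum(W[i, ])
    }
    W
  }
  out <- axis_weights(nrow(img), out_h) %*% img %*% t(axis_weights(ncol(img), out_w))
  pmin(pmax(out, 0), 1)
}

# Exhaustive-active-set NNLS: enumerate every support, keep supports whose
# unconstrained LS solution is non-negative, return the best objective.
oracle_nnls <- function(A, b) {
  K <- ncol(A)
  best <- list(w = numeric(K), obj = sum(b^2))
  for (sz in seq_len(K)) {
    for (S in utils::combn(K, sz, simplify = FALSE)) {
      As <- A[, S, drop = FALSE]
      ws <- tryCatch(solve(crossprod(As), crossprod(As, b)),
                     error = function(e) NULL)
      if (is.null(ws) || any(ws < 0)) next
      w <- numeric(K)
      w[S] <- ws
      obj <- sum((b - A %*% w)^2)
      if (obj < best$obj - 1e-12) best <- list(w = w, obj = obj)
    }
  }
  best$w
}

# Equality-constrained least squares (sum of weights = 1) via the KKT system.
oracle_ls_sum1 <- function(y, N) {
  K <- ncol(N)
  KKT <- rbind(cbind(2 * crossprod(N), rep(1, K)), c(rep(1, K), 0))
  sol <- solve(KKT, c(2 * crossprod(N, y), 1))
  sol[seq_len(K)]
}

# Best residual over every support of size <= L (exhaustive OMP bound).
oracle_best_support_residual <- function(signal, D, L) {
  best <- sqrt(sum(signal^2))
  for (sz in seq_len(L)) {
    for (S in utils::combn(ncol(D), sz, simplify = FALSE)) {
      Ds <- D[, S, drop = FALSE]
      cf <- tryCatch(solve(crossprod(Ds), crossprod(Ds, signal)),
                     error = function(e) NULL)
      if (is.null(cf)) next
      best <- min(best, sqrt(sum((signal - Ds %*% cf)^2)))
    }
  }
  best
}

# Global multivariate ridge map in the printed K x K Gram form.
oracle_global_ridge <- function(X_h, X_l, lambda) {
  N <- ncol(X_l)
  X_h %*% solve(crossprod(X_l) + diag(lambda, N)) %*% t(X_l)
}

# Direct per-query anchored ridge (coefficients first, then HR synthesis).
oracle_anchored_ridge <- function(y, N_l, N_h, lambda) {
  beta <- solve(crossprod(N_l) + diag(lambda, ncol(N_l)), crossprod(N_l, y))
  drop(N_h %*% beta)
}
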