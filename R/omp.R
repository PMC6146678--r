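# Orthogonal matching pursuit.

#' Greedy OMP sparse coding
#'
#' Selects, at each step, the atom with maximal absolute correlation with
#' the current residual, re-fits the coefficients of the active set by least
#' squares, and stops after `L` atoms or when the residual norm drops below
#' `tol`.  Ties are broken by lower atom index.
#'
#' @param signal Length-`S` vector.
#' @param dictionary `S x B` matrix with unit-norm columns.
#' @param L Maximum number of atoms (`1 <= L <= B`).
#' @param tol Residual-norm stopping tolerance (default `1e-10`).
#' @return Length-`B` coefficient vector (dense, zero off the active set).
#' @export
omp_encode <- function(signal, dictionary, L, tol = 1e-10) {
  B <- ncol(dictionary)
  if (L < 1 || L > B) .stopf("omp_encode: L must be in [1, %d]", B)
  nrm <- sqrt(colSums(dictionary^2))
  if (any(abs(nrm - 1) > 1e-6))
    .stopf("omp_encode: dictionary columns must be unit-normalized")
  active <- integer(0)
  coef <- numeric(0)
  r <- signal
  for (step in seq_len(L)) {
    if (sqrt(sum(r^2)) < tol) break
    corr <- abs(drop(crossprod(dictionary, r)))
    if (length(active)) corr[active] <- -Inf
    j <- which.max(corr)
    active <- c(active, j)
    Da <- dictionary[, active, drop = FALSE]
    G <- crossprod(Da)
    coef <- solve(G + diag(1e-12 * (1 + sum(diag(G))), length(active)),
                  crossprod(Da, signal))
    r <- signal - drop(Da %*% coef)
  }
  out <- numeric(B)
  out[active] <- coef
  out
}

# Batch OMP in the correlation domain (precomputed D'D and D'X); returns a
# list of (active, coef) pairs, avoiding a dense B x N code matrix.
.omp_batch <- function(D, X, L, tol = 1e-10) {
  B <- ncol(D)
  DtD <- crossprod(D)
  C0 <- crossprod(D, X)                       # B x N
  n <- ncol(X)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    x <- X[, i]
    active <- integer(0)
    coef <- numeric(0)
    c_res <- C0[, i]
    r2 <- sum(x^2)
    for (step in seq_len(L)) {
      if (r2 < tol^2) break
      ac <- abs(c_res)
      if (length(active)) ac[active] <- -Inf
      j <- which.max(ac)
      active <- c(active, j)
      G <- DtD[active, active, drop = FALSE]
      coef <- solve(G + diag(1e-12 * (1 + sum(diag(G))), length(active)),
                    C0[active, i])
      c_res <- C0[, i] - drop(DtD[, active, drop = FALSE] %*% coef)
      # residual tracked in signal space for an accurate stopping test
      r2 <- sum((x - drop(D[, active, drop = FALSE] %*% coef))^2)
    }
    out[[i]] <- list(active = active, coef = as.numeric(coef))
  }
  out
}

# Expand batch-OMP output into a dense B x N code matrix.
.omp_codes_dense <- function(codes, B) {
  Z <- matrix(0, B, length(codes))
  for (i in seq_along(codes))
    if (length(codes[[i]]$active))
      Z[codes[[i]]$active, i] <- codes[[i]]$coef
  Z
}
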