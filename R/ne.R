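# Neighborhood-embedding SR.  An LR query patch is approximated by a weighted
# combination of its K nearest training LR patches; the same weights applied
# to the paired HR patches give the HR reconstruction.  Weights are fit in LR
# space (the printed objective's y_h is a typo for y_l: the neighbor matrix
# has LR dimensionality and the HR side is only used for synthesis).

#' Neighborhood-embedding SR model
#'
#' Stores the column-aligned LR/HR training pools, the neighborhood size and
#' the weight solver variant (`"ls"`: equality-constrained least squares with
#' weights summing to 1; `"nnls"`: non-negative least squares).
#'
#' @param X_l,X_h Column-aligned `S_l x N` / `S_h x N` patch pools, or a
#'   `patch_pair_set` passed as `X_l` (then `X_h` is taken from it).
#' @param K Neighborhood size (default 24).
#' @param variant `"ls"` or `"nnls"`.
#' @param factor Upscaling factor carried for pipeline dispatch (optional).
#' @return An object of class `ne_model`.
#' @export
ne_model <- function(X_l, X_h = NULL, K = 24L, variant = c("ls", "nnls"),
                     factor = NULL) {
  if (inherits(X_l, "patch_pair_set")) {
    factor <- factor %||% X_l$factor
    X_h <- X_l$X_h
    X_l <- X_l$X_l
  }
  variant <- match.arg(variant)
  if (ncol(X_l) != ncol(X_h)) .stopf("ne_model: pools are not column-aligned")
  if (K > ncol(X_l)) .stopf("ne_model: K exceeds pool size")
  structure(list(pool_lr = X_l, pool_hr = X_h, K = as.integer(K),
                 variant = variant, factor = factor),
            class = c("ne_model", "sr_model"))
}

#' Sum-to-one least-squares neighborhood weights
#'
#' Minimizes `||query - neighbors %*% w||^2` subject to `sum(w) = 1` via the
#' Gram-matrix closed form on the centered neighbor differences, with a small
#' ridge jitter (`1e-8 * trace/K`, plus an absolute floor) so degenerate
#' neighborhoods remain solvable; identical neighbors yield uniform weights.
#'
#' @param query Length-`S` vector.
#' @param neighbors `S x K` matrix of neighbor columns.
#' @param jitter Relative jitter scale for the Gram diagonal.
#' @return Length-`K` weight vector summing to 1.
#' @export
solve_ls_weights <- function(query, neighbors, jitter = 1e-8) {
  K <- ncol(neighbors)
  if (K == 1L) return(1)
  C <- neighbors - query
  G <- crossprod(C)
  G <- G + diag(jitter * sum(diag(G)) / K + 1e-12, K)
  w <- solve(G, rep(1, K))
  w / sum(w)
}

#' Non-negative least-squares neighborhood weights
#'
#' Lawson-Hanson active-set NNLS for
#' `min ||query - neighbors %*% w||^2  s.t.  w >= 0` (no sum constraint).
#'
#' @inheritParams solve_ls_weights
#' @param tol Dual-feasibility tolerance.
#' @return Length-`K` non-negative weight vector.
#' @export
solve_nnls_weights <- function(query, neighbors, tol = 1e-10) {
  A <- neighbors
  K <- ncol(A)
  x <- numeric(K)
  P <- logical(K)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, query))
  for (outer_it in seq_len(30L * K + 10L)) {
    grad <- Atb - drop(AtA %*% x)
    cand <- which(!P & grad > tol)
    if (length(cand) == 0L) break
    j <- cand[which.max(grad[cand])]
    P[j] <- TRUE
    repeat {
      p <- which(P)
      s <- numeric(K)
      G <- AtA[p, p, drop = FALSE]
      s[p] <- solve(G + diag(1e-12 * (1 + sum(diag(G))), length(p)), Atb[p])
      if (all(s[p] > 0)) { x <- s; break }
      neg <- p[s[p] <= 0]
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      P[x <= tol & P] <- FALSE
      x[!P] <- 0
      if (!any(P)) { x[] <- 0; break }
    }
  }
  pmax(x, 0)
}

# Weights for one query given its neighbor matrix, per model variant.
.ne_weights <- function(model, query, neighbors) {
  switch(model$variant,
         ls = solve_ls_weights(query, neighbors),
         nnls = solve_nnls_weights(query, neighbors))
}

#' Reconstruct one HR patch by neighborhood embedding
#'
#' Finds the `K` nearest LR pool patches, solves the variant's weights in LR
#' space and applies them to the paired HR patches.
#'
#' @param query Length-`S_l` (mean-removed) LR patch vector.
#' @param model An [ne_model()].
#' @return Length-`S_h` HR patch vector.
#' @export
ne_reconstruct_patch <- function(query, model) {
  stopifnot(inherits(model, "ne_model"))
  nn <- knn_search(query, model$pool_lr, model$K)
  w <- .ne_weights(model, query, model$pool_lr[, nn$indices, drop = FALSE])
  drop(model$pool_hr[, nn$indices, drop = FALSE] %*% w)
}

#' @export
predict_patches.ne_model <- function(model, X, ...) {
  nn <- .knn_batch(X, model$pool_lr, model$K)
  Y <- matrix(0, nrow(model$pool_hr), ncol(X))
  for (i in seq_len(ncol(X))) {
    nb <- model$pool_lr[, nn$indices[, i], drop = FALSE]
    w <- .ne_weights(model, X[, i], nb)
    Y[, i] <- model$pool_hr[, nn$indices[, i], drop = FALSE] %*% w
  }
  Y
}

#' @export
print.ne_model <- function(x, ...) {
  cat(sprintf("<ne_model> variant %s, K=%d, pool N=%d\n",
              toupper(x$variant), x$K, ncol(x$pool_lr)))
  invisible(x)
}
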