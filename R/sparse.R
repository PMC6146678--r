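# Sparsity-based SR: coupled LR/HR dictionaries sharing one sparse code.
# Two trainers are provided: joint alternating minimization of the coupled
# L1 objective ("yang") and K-SVD on the LR side followed by a closed-form
# pseudo-inverse HR dictionary ("zeyde").

.as_patch_matrices <- function(patches) {
  if (inherits(patches, "patch_pair_set"))
    list(X_l = patches$X_l, X_h = patches$X_h, factor = patches$factor)
  else if (is.list(patches) && !is.null(patches$X_l) && !is.null(patches$X_h))
    list(X_l = patches$X_l, X_h = patches$X_h, factor = patches$factor %||% NULL)
  else .stopf("expected a patch_pair_set or a list with X_l and X_h")
}

.new_coupled_dictionary <- function(D_l, D_h, lambda, L, trained_by, seed,
                                    n_iters, objective = NULL, factor = NULL) {
  structure(list(D_l = D_l, D_h = D_h, B = ncol(D_l), lambda = lambda,
                 L = as.integer(L), trained_by = trained_by,
                 seed = as.integer(seed), n_iters = as.integer(n_iters),
                 objective = objective, factor = factor),
            class = c("coupled_dictionary", "sr_model"))
}

#' @export
print.coupled_dictionary <- function(x, ...) {
  cat(sprintf("<coupled_dictionary> %s, B=%d atoms (S_l=%d, S_h=%d)\n",
              x$trained_by, x$B, nrow(x$D_l), nrow(x$D_h)))
  invisible(x)
}

# Stacked coupled objective used by the joint trainer (per-space 1/S
# weighting folded into the 1/sqrt(S)-scaled blocks).
.joint_objective <- function(Dst, Z, Sst, lam_eff) {
  sum((Sst - Dst %*% Z)^2) + lam_eff * sum(abs(Z))
}

#' Jointly train coupled LR/HR dictionaries
#'
#' Alternating minimization of the coupled sparse objective
#' `1/S_h ||X_h - D_h Z||^2 + 1/S_l ||X_l - D_l Z||^2 +
#'  lambda (1/S_h + 1/S_l) ||Z||_1`:
#' the per-space `1/S` weights are folded in by stacking the HR and LR blocks
#' scaled by `1/sqrt(S)`, the sparse-code step is batch coordinate-descent
#' lasso (warm-started), and the dictionary step is block-coordinate descent
#' with unit-ball projection of the stacked atoms (so the recorded objective
#' is non-increasing).  Unused atoms are replaced by the worst-represented
#' signal.  After the final iteration `D_l` is renormalized to unit columns
#' with `D_h` scaled by the same factor (the coupled map is preserved).
#'
#' @param patches A `patch_pair_set` (or list with `X_l`, `X_h`).
#' @param B Number of dictionary atoms (default 2048).
#' @param lambda Sparsity weight (default 0.1).
#' @param n_iters Alternating iterations (default 10).
#' @param seed Seed for the initialization sample.
#' @param init Optional list `list(D_l =, D_h =)` overriding the seeded
#'   data-sample initialization (atoms are projected to the unit ball in the
#'   stacked space).
#' @param max_pass,tol Coordinate-descent passes / convergence tolerance for
#'   the coding step.
#' @return A `coupled_dictionary` with `trained_by = "yang"`; the per-
#'   iteration objective values are stored in `$objective`.
#' @export
train_joint_dictionary <- function(patches, B = 2048L, lambda = 0.1,
                                   n_iters = 10L, seed = 1L, init = NULL,
                                   max_pass = 30L, tol = 1e-6) {
  pm <- .as_patch_matrices(patches)
  N <- ncol(pm$X_l)
  if (B < 1L || N < 1L) .stopf("train_joint_dictionary: empty patches or B < 1")
  if (n_iters < 1L) .stopf("train_joint_dictionary: n_iters must be >= 1")
  S_h <- nrow(pm$X_h); S_l <- nrow(pm$X_l)
  Sst <- rbind(pm$X_h / sqrt(S_h), pm$X_l / sqrt(S_l))
  lam_eff <- lambda * (1 / S_h + 1 / S_l)

  if (is.null(init)) {
    if (N < B) .stopf("train_joint_dictionary: need N >= B training patches")
    sel <- withr::with_seed(.derive_seed(seed, 3L), sample.int(N, B))
    Dst <- Sst[, sel, drop = FALSE]
  } else {
    if (ncol(init$D_l) != B || ncol(init$D_h) != B)
      .stopf("train_joint_dictionary: init dictionaries must have B = %d atoms", B)
    Dst <- rbind(init$D_h / sqrt(S_h), init$D_l / sqrt(S_l))
  }
  nrm <- sqrt(colSums(Dst^2))
  scl <- pmax(nrm, 1)
  Dst <- sweep(Dst, 2L, scl, `/`)            # project atoms into unit ball
  dead <- nrm < 1e-12
  if (any(dead)) Dst[, dead] <- Sst[, seq_len(sum(dead)), drop = FALSE]

  Z <- NULL
  obj <- numeric(n_iters)
  for (it in seq_len(n_iters)) {
    Z <- .lasso_cd(Dst, Sst, lam_eff, max_pass = max_pass, tol = tol, Z0 = Z)
    # dictionary block-coordinate update with unit-ball projection
    ZZt <- tcrossprod(Z)
    XZt <- tcrossprod(Sst, Z)
    Rres <- NULL
    for (j in seq_len(ncol(Dst))) {
      denom <- ZZt[j, j]
      if (denom <= 1e-12) {
        if (is.null(Rres)) Rres <- colSums((Sst - Dst %*% Z)^2)
        Dst[, j] <- Sst[, which.max(Rres)]
        n2 <- sqrt(sum(Dst[, j]^2))
        if (n2 > 1) Dst[, j] <- Dst[, j] / n2
        next
      }
      u <- Dst[, j] + (XZt[, j] - drop(Dst %*% ZZt[, j])) / denom
      Dst[, j] <- u / max(1, sqrt(sum(u^2)))
    }
    obj[it] <- .joint_objective(Dst, Z, Sst, lam_eff)
  }

  D_h <- Dst[seq_len(S_h), , drop = FALSE] * sqrt(S_h)
  D_l <- Dst[S_h + seq_len(S_l), , drop = FALSE] * sqrt(S_l)
  nl <- sqrt(colSums(D_l^2))
  nl[nl < 1e-12] <- 1
  D_l <- sweep(D_l, 2L, nl, `/`)
  D_h <- sweep(D_h, 2L, nl, `/`)
  .new_coupled_dictionary(D_l, D_h, lambda, L = NA_integer_,
                          trained_by = "yang", seed = seed,
                          n_iters = n_iters, objective = obj,
                          factor = pm$factor)
}

#' Train coupled dictionaries by K-SVD and pseudo-inverse
#'
#' The LR dictionary is learned by K-SVD on `X_l` under the L0 constraint
#' `||z||_0 <= L` (sparse coding by OMP, atom updates by the rank-1 SVD of
#' the restricted residual; unused atoms are replaced by the currently
#' worst-represented signal).  The HR dictionary is then the closed-form
#' least-squares/pseudo-inverse solution
#' `D_h = X_h Z' (Z Z' + eps I)^-1` with jitter `eps = 1e-8`.
#'
#' @inheritParams train_joint_dictionary
#' @param L Maximum atoms per representation vector (default 24).
#' @param n_iters K-SVD sweeps (default 20).
#' @param lambda Sparsity weight stored for downstream anchored models.
#' @return A `coupled_dictionary` with `trained_by = "zeyde"`, unit-norm
#'   `D_l` columns and the per-sweep LR coding MSE in `$objective`.
#' @export
train_zeyde_dictionary <- function(patches, B = 2048L, L = 24L, n_iters = 20L,
                                   seed = 1L, lambda = 0.1) {
  pm <- .as_patch_matrices(patches)
  X_l <- pm$X_l; X_h <- pm$X_h
  N <- ncol(X_l)
  if (B < 1L || N < 1L) .stopf("train_zeyde_dictionary: empty patches or B < 1")
  if (N < B) .stopf("train_zeyde_dictionary: need N >= B training patches")

  nrm <- colSums(X_l^2)
  cand <- which(nrm > 1e-12)
  if (length(cand) < B) cand <- seq_len(N)
  sel <- withr::with_seed(.derive_seed(seed, 4L),
                          sample(cand, B))
  D <- X_l[, sel, drop = FALSE]
  D <- sweep(D, 2L, pmax(sqrt(colSums(D^2)), 1e-12), `/`)

  mse <- numeric(n_iters)
  Z <- NULL
  for (it in seq_len(n_iters)) {
    codes <- .omp_batch(D, X_l, L)
    Z <- .omp_codes_dense(codes, B)
    Rfull <- X_l - D %*% Z
    res2 <- colSums(Rfull^2)
    for (j in seq_len(B)) {
      users <- which(Z[j, ] != 0)
      if (length(users) == 0L) {
        w <- which.max(res2)
        D[, j] <- X_l[, w] / max(sqrt(sum(X_l[, w]^2)), 1e-12)
        res2[w] <- 0  # avoid reseeding several dead atoms identically
        next
      }
      E <- Rfull[, users, drop = FALSE] +
        tcrossprod(D[, j], Z[j, users])
      sv <- svd(E, nu = 1L, nv = 1L)
      d_new <- sv$u[, 1L]
      z_new <- sv$d[1L] * sv$v[, 1L]
      Rfull[, users] <- E - tcrossprod(d_new, z_new)
      D[, j] <- d_new
      Z[j, users] <- z_new
    }
    mse[it] <- mean(colSums((X_l - D %*% Z)^2))
  }
  # final coding against the final dictionary, then the HR closed form
  codes <- .omp_batch(D, X_l, L)
  Z <- .omp_codes_dense(codes, B)
  ZZt <- tcrossprod(Z) + diag(1e-8, B)
  D_h <- t(solve(ZZt, tcrossprod(Z, X_h)))
  .new_coupled_dictionary(D, D_h, lambda, L = L, trained_by = "zeyde",
                          seed = seed, n_iters = n_iters, objective = mse,
                          factor = pm$factor)
}

#' Reconstruct one HR patch from a coupled dictionary
#'
#' For a Zeyde-trained dictionary the sparse code comes from OMP with the
#' dictionary's `L`; for a jointly-trained dictionary it comes from
#' L1-regularized least squares with the dictionary's `lambda`, applied to
#' the unit-normalized query with the output rescaled by the query norm (the
#' method family's standard convention, which makes `lambda` scale-free).
#' The HR patch is `D_h %*% alpha`.
#'
#' @param lr_patch Length-`S_l` mean-removed LR patch vector.
#' @param dict A trained `coupled_dictionary`.
#' @return Length-`S_h` HR patch vector.
#' @export
sparse_reconstruct_patch <- function(lr_patch, dict) {
  stopifnot(inherits(dict, "coupled_dictionary"))
  drop(predict_patches(dict, matrix(lr_patch, ncol = 1L)))
}

#' @export
predict_patches.coupled_dictionary <- function(model, X, ...) {
  if (model$trained_by == "zeyde") {
    codes <- .omp_batch(model$D_l, X, model$L)
    Y <- matrix(0, nrow(model$D_h), ncol(X))
    for (i in seq_len(ncol(X))) {
      a <- codes[[i]]
      if (length(a$active))
        Y[, i] <- model$D_h[, a$active, drop = FALSE] %*% a$coef
    }
    Y
  } else {
    qn <- sqrt(colSums(X^2))
    live <- qn > 1e-12
    Y <- matrix(0, nrow(model$D_h), ncol(X))
    if (any(live)) {
      Xn <- sweep(X[, live, drop = FALSE], 2L, qn[live], `/`)
      Z <- .lasso_cd(model$D_l, Xn, model$lambda, max_pass = 30L, tol = 1e-6)
      Y[, live] <- sweep(model$D_h %*% Z, 2L, qn[live], `*`)
    }
    Y
  }
}
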