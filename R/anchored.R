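# Anchored neighborhood regression (ANR and A+).  Each LR dictionary atom
# anchors a local neighborhood -- its K nearest atoms (ANR) or its K nearest
# training patches (A+) -- and a precomputed ridge projection matrix maps an
# LR patch assigned to that anchor straight to its HR reconstruction.

# One anchored projection P = N_h (N_l' N_l + lambda I)^-1 N_l'.
.anchored_projection <- function(N_l, N_h, lambda) {
  .ridge_map(N_h, N_l, lambda)
}

#' Build anchored projection matrices (ANR / A+)
#'
#' Starting from a Zeyde-trained coupled dictionary, builds one ridge
#' projection matrix per LR atom.  For `variant = "anr"` the neighborhood of
#' atom `j` is its `K` nearest dictionary atoms; for `variant = "aplus"` it
#' is its `K` nearest training LR patches (with the paired HR patches on the
#' HR side).  Nearness is absolute correlation on unit-normalized vectors
#' (Euclidean on normalized vectors available via `metric`).
#'
#' @param dict A `coupled_dictionary` (Zeyde-trained by convention).
#' @param patches Training `patch_pair_set`; required for `"aplus"`.
#' @param K Neighborhood size (40 for ANR, 2048 for A+ in the reference
#'   parameterization).
#' @param lambda Ridge weight (default 0.1).
#' @param variant `"anr"` or `"aplus"`.
#' @param metric Anchor-neighbor distance: `"correlation"` (default) or
#'   `"euclidean"` on unit-normalized vectors.
#' @param pool_cap Maximum training-pool size searched by A+ (sampled with
#'   `seed` when exceeded; default 100000).
#' @param seed Seed for the pool subsample.
#' @return An `anchored_model` with `anchors` (`S_l x B`) and one
#'   `S_h x S_l` projection per anchor.
#' @export
build_anchor_projections <- function(dict, patches = NULL, K,
                                     lambda = 0.1,
                                     variant = c("anr", "aplus"),
                                     metric = c("correlation", "euclidean"),
                                     pool_cap = 1e5, seed = 1L) {
  stopifnot(inherits(dict, "coupled_dictionary"))
  variant <- match.arg(variant)
  metric <- match.arg(metric)
  B <- dict$B
  D_l <- dict$D_l

  if (variant == "anr") {
    if (K > B) .stopf("build_anchor_projections: K = %d exceeds B = %d", K, B)
    sim <- crossprod(D_l)                       # atoms are unit-norm
    nb_of <- function(j) {
      s <- if (metric == "correlation") -abs(sim[, j]) else 2 - 2 * sim[, j]
      order(s, seq_len(B))[seq_len(K)]
    }
    N_l_of <- function(nb) D_l[, nb, drop = FALSE]
    N_h_of <- function(nb) dict$D_h[, nb, drop = FALSE]
  } else {
    pm <- .as_patch_matrices(patches)
    keep <- .cap_columns(ncol(pm$X_l), pool_cap, seed)
    X_l <- pm$X_l[, keep, drop = FALSE]
    X_h <- pm$X_h[, keep, drop = FALSE]
    if (K > ncol(X_l))
      .stopf("build_anchor_projections: K = %d exceeds pool size %d", K, ncol(X_l))
    nrm <- pmax(sqrt(colSums(X_l^2)), 1e-12)
    Xn <- sweep(X_l, 2L, nrm, `/`)
    sim <- crossprod(Xn, D_l)                   # pool x B correlations
    nb_of <- function(j) {
      s <- if (metric == "correlation") -abs(sim[, j]) else 2 - 2 * sim[, j]
      order(s, seq_along(s))[seq_len(K)]
    }
    N_l_of <- function(nb) X_l[, nb, drop = FALSE]
    N_h_of <- function(nb) X_h[, nb, drop = FALSE]
  }

  projections <- vector("list", B)
  for (j in seq_len(B)) {
    nb <- nb_of(j)
    projections[[j]] <- .anchored_projection(N_l_of(nb), N_h_of(nb), lambda)
  }
  structure(list(anchors = D_l, projections = projections, K = as.integer(K),
                 lambda = lambda, variant = variant, metric = metric,
                 factor = dict$factor),
            class = c("anchored_model", "sr_model"))
}

#' Reconstruct one HR patch with an anchored model
#'
#' Finds the anchor nearest to the unit-normalized query (absolute
#' correlation) and applies its stored projection matrix to the raw
#' (unnormalized, mean-removed) patch.  A zero patch returns a zero HR patch.
#'
#' @param lr_patch Length-`S_l` mean-removed LR patch vector.
#' @param model An `anchored_model`.
#' @return Length-`S_h` HR patch vector.
#' @export
anchored_reconstruct_patch <- function(lr_patch, model) {
  stopifnot(inherits(model, "anchored_model"))
  drop(predict_patches(model, matrix(lr_patch, ncol = 1L)))
}

#' @export
predict_patches.anchored_model <- function(model, X, ...) {
  S_h <- nrow(model$projections[[1L]])
  Y <- matrix(0, S_h, ncol(X))
  qn <- sqrt(colSums(X^2))
  live <- which(qn > 1e-12)
  if (length(live) == 0L) return(Y)
  Xn <- sweep(X[, live, drop = FALSE], 2L, qn[live], `/`)
  sim <- abs(crossprod(model$anchors, Xn))       # B x n
  assign <- max.col(t(sim), ties.method = "first")
  for (j in unique(assign)) {
    cols <- live[assign == j]
    Y[, cols] <- model$projections[[j]] %*% X[, cols, drop = FALSE]
  }
  Y
}

#' @export
print.anchored_model <- function(x, ...) {
  cat(sprintf("<anchored_model> %s, %d anchors, K=%d, lambda=%g\n",
              toupper(x$variant), length(x$projections), x$K, x$lambda))
  invisible(x)
}
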