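# Jointly optimized regressors: EM-style alternation between per-cluster
# ridge maps (E-step) and minimum-reconstruction-error reassignment (M-step),
# with kNN majority voting to pick the regressor at test time.

#' Fit jointly optimized regressors
#'
#' Seeded random initial assignment (every cluster non-empty), then
#' alternation of (a) per-cluster ridge fits
#' `P_o = X_h^o ((X_l^o)' X_l^o + lambda I)^-1 (X_l^o)'` and (b)
#' reassignment of every sample to the regressor with minimum reconstruction
#' error, until assignments are stable or `n_iters` is reached.  The joint
#' objective (sum of assigned squared errors) is recorded per iteration and
#' is non-increasing.  A cluster left empty by reassignment is repaired with
#' the sample of largest current error.
#'
#' @param patches A `patch_pair_set` (or list with `X_l`, `X_h`).
#' @param O Number of regressors (default 32).
#' @param n_iters Maximum EM iterations (default 20).
#' @param lambda Ridge weight (default 0.1).
#' @param K_select Test-time neighborhood size for regressor selection
#'   (default 32).
#' @param seed Integer seed for the initial assignment.
#' @param n_restarts Number of independently seeded EM runs; the run with
#'   the lowest final objective is kept (default 1, a single seeded run).
#' @return A `jor_model`: projections (list of `S_h x S_l`), `assignments`,
#'   the LR training pool, parameters and the per-iteration `objective`.
#' @export
jor_fit <- function(patches, O = 32L, n_iters = 20L, lambda = 0.1,
                    K_select = 32L, seed = 1L, n_restarts = 1L) {
  pm <- .as_patch_matrices(patches)
  X_l <- pm$X_l; X_h <- pm$X_h
  N <- ncol(X_l)
  if (N < O) .stopf("jor_fit: need at least O = %d samples", O)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    run <- .jor_em(X_l, X_h, O, n_iters, lambda,
                   .derive_seed(seed, 7L + 131L * (r - 1L)))
    if (is.null(best) || tail(run$objective, 1) < tail(best$objective, 1))
      best <- run
  }
  structure(list(projections = best$projections,
                 assignments = best$assignments, pool_lr = X_l,
                 O = as.integer(O), n_iters = as.integer(n_iters),
                 K_select = as.integer(K_select), lambda = lambda,
                 seed = as.integer(seed), objective = best$objective,
                 factor = pm$factor),
            class = c("jor_model", "sr_model"))
}

# One seeded EM run (random balanced init, E/M alternation, empty repair).
.jor_em <- function(X_l, X_h, O, n_iters, lambda, init_seed) {
  N <- ncol(X_l)
  assign <- withr::with_seed(init_seed, sample(rep_len(seq_len(O), N)))
  fit_all <- function(assign) {
    lapply(seq_len(O), function(o) {
      idx <- which(assign == o)
      .ridge_map(X_h[, idx, drop = FALSE], X_l[, idx, drop = FALSE], lambda)
    })
  }
  errors_all <- function(P) {
    E <- matrix(0, O, N)
    for (o in seq_len(O))
      E[o, ] <- colSums((P[[o]] %*% X_l - X_h)^2)
    E
  }
  obj <- numeric(0)
  P <- NULL
  for (it in seq_len(n_iters)) {
    P <- fit_all(assign)                       # E-step
    E <- errors_all(P)
    new_assign <- max.col(t(-E), ties.method = "first")  # M-step
    obj <- c(obj, sum(E[cbind(new_assign, seq_len(N))]))
    stable <- identical(new_assign, assign)
    assign <- new_assign
    # empty-cluster repair: hand the worst-reconstructed sample over
    emin <- E[cbind(assign, seq_len(N))]
    for (o in which(tabulate(assign, O) == 0L)) {
      w <- which.max(emin)
      assign[w] <- o
      emin[w] <- -Inf
    }
    if (stable) break
  }
  P <- fit_all(assign)                         # final maps match assignments
  list(projections = P, assignments = assign, objective = obj)
}

# Majority label among K nearest pool neighbors; ties go to the label with
# the larger summed inverse neighbor distance, then to the lower index.
.jor_vote <- function(labels, distances) {
  counts <- table(labels)
  top <- names(counts)[counts == max(counts)]
  if (length(top) > 1L) {
    invd <- vapply(top, function(l)
      sum(1 / (distances[labels == as.integer(l)] + 1e-12)), numeric(1))
    top <- top[invd == max(invd)]
  }
  min(as.integer(top))
}

#' Select the most suitable regressor for an LR patch
#'
#' Majority cluster label among the `K_select` nearest training LR patches.
#'
#' @param lr_patch Length-`S_l` mean-removed LR patch vector.
#' @param model A `jor_model`.
#' @return Cluster index in `1..O`.
#' @export
jor_select_regressor <- function(lr_patch, model) {
  stopifnot(inherits(model, "jor_model"))
  nn <- knn_search(lr_patch, model$pool_lr, model$K_select)
  .jor_vote(model$assignments[nn$indices], nn$distances)
}

#' Reconstruct one HR patch with the selected regressor
#'
#' @inheritParams jor_select_regressor
#' @return Length-`S_h` HR patch vector `P_o %*% lr_patch`.
#' @export
jor_reconstruct_patch <- function(lr_patch, model) {
  o <- jor_select_regressor(lr_patch, model)
  drop(model$projections[[o]] %*% lr_patch)
}

#' @export
predict_patches.jor_model <- function(model, X, ...) {
  nn <- .knn_batch(X, model$pool_lr, model$K_select)
  sel <- vapply(seq_len(ncol(X)), function(i)
    .jor_vote(model$assignments[nn$indices[, i]], nn$distances[, i]),
    integer(1))
  Y <- matrix(0, nrow(model$projections[[1L]]), ncol(X))
  for (o in unique(sel)) {
    cols <- which(sel == o)
    Y[, cols] <- model$projections[[o]] %*% X[, cols, drop = FALSE]
  }
  Y
}

#' @export
print.jor_model <- function(x, ...) {
  cat(sprintf("<jor_model> O=%d regressors, pool N=%d, K_select=%d\n",
              x$O, ncol(x$pool_lr), x$K_select))
  invisible(x)
}
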