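# Super-resolution forests: regression trees whose internal nodes hold
# axis-aligned threshold tests on the LR patch vector and whose leaves hold
# ridge linear maps; predictions average over the trees.  Splits are scored
# by a regularized quality measure combining the HR prediction error with
# kappa-weighted LR compactness.

#' Regularized split quality
#'
#' `E = 1/|X| * sum_n ( ||x_h^n - m(x_l^n)||^2 + kappa ||x_l^n - mean(x_l)||^2 )`
#' where `m(.)` supplies the HR predictions and the LR mean is taken over
#' the node's samples.
#'
#' @param samples_lr `S_l x n` LR sample matrix.
#' @param samples_hr `S_h x n` column-aligned HR sample matrix.
#' @param predictions `S_h x n` HR predictions `m(x_l^n)`.
#' @param kappa Compactness weight.
#' @return Scalar quality `E` (lower is better).
#' @export
split_quality <- function(samples_lr, samples_hr, predictions, kappa) {
  n <- ncol(samples_lr)
  if (n < 1L) .stopf("split_quality: empty node")
  if (ncol(samples_hr) != n || ncol(predictions) != n)
    .stopf("split_quality: matrices are not column-aligned")
  mu <- rowMeans(samples_lr)
  (sum((samples_hr - predictions)^2) + kappa * sum((samples_lr - mu)^2)) / n
}

# Node sum of squares around the mean (HR prediction surrogate during the
# split search is the child's HR mean), computed from sums/sums of squares.
.sse_about_mean <- function(sum_v, sq_sum, n) sq_sum - sum(sum_v^2) / n

# Recursively grow one tree.  Candidate splits are axis-aligned: R random
# (feature, threshold) pairs, threshold uniform within the node's range of
# that feature; the best candidate minimizes the sample-weighted mean of the
# children's quality measure with the constant (child-mean) surrogate.
.grow_node <- function(X_l, X_h, idx, depth, params) {
  n <- length(idx)
  make_leaf <- function() {
    list(leaf = TRUE,
         leaf_map = .ridge_map(X_h[, idx, drop = FALSE],
                               X_l[, idx, drop = FALSE], params$lambda),
         n_samples = n)
  }
  if (depth >= params$max_depth || n < 2L * params$min_leaf) return(make_leaf())
  Xl_n <- X_l[, idx, drop = FALSE]
  Xh_n <- X_h[, idx, drop = FALSE]
  ln2 <- colSums(Xl_n^2)
  hn2 <- colSums(Xh_n^2)
  Ht <- rowSums(Xh_n); Lt <- rowSums(Xl_n)
  parent <- (.sse_about_mean(Ht, sum(hn2), n) +
             params$kappa * .sse_about_mean(Lt, sum(ln2), n)) / n

  feats <- sample.int(nrow(X_l), params$n_candidates, replace = TRUE)
  thr <- numeric(params$n_candidates)
  M <- matrix(0, n, params$n_candidates)
  for (r in seq_len(params$n_candidates)) {
    v <- Xl_n[feats[r], ]
    thr[r] <- runif(1, min(v), max(v))
    M[, r] <- as.numeric(v <= thr[r])
  }
  nL <- colSums(M)
  valid <- nL >= params$min_leaf & (n - nL) >= params$min_leaf
  if (!any(valid)) return(make_leaf())

  Hs <- Xh_n %*% M; Ls <- Xl_n %*% M            # child sums, all candidates
  hq <- drop(hn2 %*% M); lq <- drop(ln2 %*% M)
  sseL <- (hq - colSums(Hs^2) / nL) +
    params$kappa * (lq - colSums(Ls^2) / nL)
  sseR <- ((sum(hn2) - hq) - colSums((Ht - Hs)^2) / (n - nL)) +
    params$kappa * ((sum(ln2) - lq) - colSums((Lt - Ls)^2) / (n - nL))
  score <- (sseL + sseR) / n
  score[!valid] <- Inf
  best <- which.min(score)
  if (score[best] >= parent - 1e-12) return(make_leaf())

  go_left <- Xl_n[feats[best], ] <= thr[best]
  left <- idx[go_left]
  right <- idx[!go_left]
  list(leaf = FALSE, split_feature = feats[best], split_threshold = thr[best],
       n_samples = n,
       left = .grow_node(X_l, X_h, left, depth + 1L, params),
       right = .grow_node(X_l, X_h, right, depth + 1L, params))
}

#' Train a super-resolution forest
#'
#' Grows `n_trees` regression trees independently (each with its own derived
#' seed) on the training patch pairs.  Node splitting draws `n_candidates`
#' random axis-aligned (feature, threshold) candidates and keeps the one
#' minimizing the children's sample-weighted regularized quality (HR
#' prediction surrogate: the child's HR mean); growth stops at `max_depth`,
#' at `min_leaf` samples, or at zero gain.  Once the structure is fixed, each
#' leaf gets a ridge linear map
#' `w = X_h ((X_l)' X_l + lambda I)^-1 (X_l)'` over its routed samples.
#'
#' @param patches A `patch_pair_set` (or list with `X_l`, `X_h`).
#' @param n_trees Number of trees `T` (default 6).
#' @param max_depth Maximum depth (default 15; 0 gives a single global leaf).
#' @param lambda Leaf ridge weight (default 0.1).
#' @param kappa LR-compactness weight in the split quality (default 1).
#' @param min_leaf Minimum samples per leaf (default `S_l + 1`, so leaf ridge
#'   systems are overdetermined).
#' @param n_candidates Random split candidates per node (default 32).
#' @param seed Integer seed.
#' @return An `sr_forest` (list of tree roots plus parameters).
#' @export
train_srf <- function(patches, n_trees = 6L, max_depth = 15L, lambda = 0.1,
                      kappa = 1, min_leaf = NULL, n_candidates = 32L,
                      seed = 1L) {
  pm <- .as_patch_matrices(patches)
  X_l <- pm$X_l; X_h <- pm$X_h
  min_leaf <- as.integer(min_leaf %||% (nrow(X_l) + 1L))
  if (ncol(X_l) < min_leaf) .stopf("train_srf: fewer samples than min_leaf")
  params <- list(max_depth = as.integer(max_depth), lambda = lambda,
                 kappa = kappa, min_leaf = min_leaf,
                 n_candidates = as.integer(n_candidates))
  trees <- lapply(seq_len(n_trees), function(t)
    withr::with_seed(.derive_seed(seed, 20L + t),
                     .grow_node(X_l, X_h, seq_len(ncol(X_l)), 0L, params)))
  structure(c(list(trees = trees, n_trees = as.integer(n_trees),
                   seed = as.integer(seed), factor = pm$factor), params),
            class = c("sr_forest", "sr_model"))
}

# Route a block of query columns through one tree, accumulating leaf
# predictions into Y (in place via returned matrix).
.route_tree <- function(node, X, cols, Y) {
  if (node$leaf) {
    Y[, cols] <- Y[, cols] + node$leaf_map %*% X[, cols, drop = FALSE]
    return(Y)
  }
  go_left <- X[node$split_feature, cols] <= node$split_threshold
  if (any(go_left)) Y <- .route_tree(node$left, X, cols[go_left], Y)
  if (any(!go_left)) Y <- .route_tree(node$right, X, cols[!go_left], Y)
  Y
}

#' Reconstruct one HR patch with a super-resolution forest
#'
#' Routes the patch down every tree by its split tests and averages the `T`
#' leaf-model predictions.
#'
#' @param lr_patch Length-`S_l` mean-removed LR patch vector.
#' @param forest An `sr_forest`.
#' @return Length-`S_h` HR patch vector.
#' @export
srf_reconstruct_patch <- function(lr_patch, forest) {
  stopifnot(inherits(forest, "sr_forest"))
  drop(predict_patches(forest, matrix(lr_patch, ncol = 1L)))
}

#' @export
predict_patches.sr_forest <- function(model, X, ...) {
  S_h <- nrow(.first_leaf(model$trees[[1L]])$leaf_map)
  Y <- matrix(0, S_h, ncol(X))
  for (tr in model$trees) Y <- .route_tree(tr, X, seq_len(ncol(X)), Y)
  Y / model$n_trees
}

.first_leaf <- function(node) if (node$leaf) node else .first_leaf(node$left)

#' @export
print.sr_forest <- function(x, ...) {
  cat(sprintf("<sr_forest> T=%d trees, max depth %d, lambda=%g, kappa=%g\n",
              x$n_trees, x$max_depth, x$lambda, x$kappa))
  invisible(x)
}
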