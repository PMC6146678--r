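# Exact exhaustive k-nearest-neighbor search (pools are desk-scale).

#' K nearest neighbors of a query vector in a patch pool
#'
#' Exhaustive Euclidean search.  Ties are broken by lower column index and
#' indices are returned in ascending distance order.
#'
#' @param query Numeric vector of length `S`.
#' @param pool `S x N` matrix whose columns are candidate vectors.
#' @param K Number of neighbors, `K <= N`.
#' @return List with `indices` (length `K`) and `distances` (ascending).
#' @export
knn_search <- function(query, pool, K) {
  if (K > ncol(pool)) .stopf("knn_search: K = %d exceeds pool size %d", K, ncol(pool))
  d2 <- colSums((pool - query)^2)
  ord <- order(d2, seq_along(d2))[seq_len(K)]
  list(indices = ord, distances = sqrt(pmax(d2[ord], 0)))
}

# Batch kNN: queries Q (S x m), returns K x m index matrix and K x m distance
# matrix.  Chunked so the full m x N distance matrix is never materialized.
.knn_batch <- function(Q, pool, K, chunk = 512L) {
  m <- ncol(Q)
  pool_sq <- colSums(pool^2)
  idx <- matrix(0L, K, m)
  dst <- matrix(0, K, m)
  for (s in seq.int(1L, m, by = chunk)) {
    e <- min(s + chunk - 1L, m)
    Qc <- Q[, s:e, drop = FALSE]
    d2 <- pool_sq - 2 * crossprod(pool, Qc)            # N x (e-s+1)
    d2 <- sweep(d2, 2L, colSums(Qc^2), `+`)
    for (j in seq_len(ncol(d2))) {
      o <- order(d2[, j], seq_len(nrow(d2)))[seq_len(K)]
      idx[, s + j - 1L] <- o
      dst[, s + j - 1L] <- sqrt(pmax(d2[o, j], 0))
    }
  }
  list(indices = idx, distances = dst)
}
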