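# Dense overlapping patch extraction and overlap-averaged reassembly.
# Grid anchors are 0-based so the HR anchor of a pair is exactly M times the
# LR anchor, including the extra flush-to-border patch appended when the
# stride does not tile the image exactly.

# 0-based anchors covering a length-`len` axis with `patch`-wide windows at
# `stride`; one extra flush patch is appended if the last window falls short.
.patch_anchors <- function(len, patch, stride) {
  if (len < patch) .stopf("image extent %d smaller than patch size %d", len, patch)
  a <- seq.int(0L, len - patch, by = stride)
  if (a[length(a)] + patch < len) a <- c(a, len - patch)
  as.integer(a)
}

# Extract all patches of `patch` x `patch` at the given 0-based anchor grid.
# Returns S x N matrix (columns are vectorized patches, column-major within
# the window) and the N x 2 (row, col) anchor table.
.extract_grid <- function(img, patch, stride) {
  ra <- .patch_anchors(nrow(img), patch, stride)
  ca <- .patch_anchors(ncol(img), patch, stride)
  pos <- cbind(row = rep(ra, times = length(ca)),
               col = rep(ca, each = length(ra)))
  off <- as.vector(outer(seq_len(patch), (seq_len(patch) - 1L) * nrow(img), `+`))
  base <- pos[, 1L] + pos[, 2L] * nrow(img)        # 0-based linear anchor
  idx <- outer(off, base, `+`)                     # S x N linear indices
  X <- matrix(img[idx], nrow = patch * patch)
  list(X = X, positions = pos)
}

#' Extract co-registered LR/HR training patch pairs
#'
#' Densely extracts 3x3 LR patches at stride 2 over the LR image and the
#' corresponding 3Mx3M HR patches at stride 2M, each HR patch anchored at
#' `M` times its LR anchor.  The per-patch DC level (the LR patch mean) is
#' removed from the LR vector and stored in `lr_means`, so linear patch
#' models operate on zero-mean signals; with `target = "raw"` it is removed
#' from the HR vector too and re-added at reconstruction.  Border
#' rows/columns not reached by the stride grid are covered by one extra
#' patch flush with the border.
#'
#' @param pair An `image_pair` from [degrade()].
#' @param lr_patch_size LR patch side (default 3).
#' @param lr_stride LR sampling stride (default 2).
#' @param target HR training target.  `"raw"`: the HR patch itself, with the
#'   LR patch mean removed (re-added at assembly).  `"residual"`: the HR
#'   patch minus the corresponding patch of the bicubic interpolation of the
#'   LR image, so a zero prediction reproduces the bicubic baseline and the
#'   model only learns the detail bicubic misses.
#' @return A `patch_pair_set`: list with `X_l` (`S_l x N`), `X_h` (`S_h x N`),
#'   `positions` (`N x 2`, 0-based LR anchors), `lr_means` (length `N`),
#'   patch geometry fields, `factor` and `hr_target`.
#' @export
extract_training_patches <- function(pair, lr_patch_size = 3L, lr_stride = 2L,
                                     target = c("raw", "residual")) {
  if (!inherits(pair, "image_pair")) .stopf("`pair` must be an image_pair")
  target <- match.arg(target)
  M <- pair$factor
  lr <- .extract_grid(pair$lr, lr_patch_size, lr_stride)
  hp <- lr_patch_size * M
  hr_pos <- lr$positions * M
  off <- as.vector(outer(seq_len(hp), (seq_len(hp) - 1L) * nrow(pair$hr), `+`))
  base <- hr_pos[, 1L] + hr_pos[, 2L] * nrow(pair$hr)
  idx <- outer(off, base, `+`)
  X_h <- matrix(pair$hr[idx], nrow = hp * hp)
  mu <- colMeans(lr$X)
  X_h <- if (target == "residual") {
    mid <- bicubic_resize(pair$lr, nrow(pair$hr), ncol(pair$hr))
    X_h - matrix(mid[idx], nrow = hp * hp)
  } else {
    sweep(X_h, 2L, mu)
  }
  structure(list(
    X_l = sweep(lr$X, 2L, mu),
    X_h = X_h,
    positions = lr$positions,
    lr_means = mu,
    hr_target = target,
    lr_patch_size = as.integer(lr_patch_size),
    hr_patch_size = as.integer(hp),
    lr_stride = as.integer(lr_stride),
    hr_stride = as.integer(lr_stride * M),
    factor = as.integer(M)
  ), class = "patch_pair_set")
}

#' @export
print.patch_pair_set <- function(x, ...) {
  cat(sprintf(
    "<patch_pair_set> N=%d pairs, LR %dx%d / HR %dx%d, factor %d, %s target\n",
    ncol(x$X_l), x$lr_patch_size, x$lr_patch_size,
    x$hr_patch_size, x$hr_patch_size, x$factor, x$hr_target %||% "raw"))
  invisible(x)
}

# Concatenate patch sets extracted from several image pairs.
.bind_patch_sets <- function(sets) {
  stopifnot(length(sets) >= 1L)
  out <- sets[[1L]]
  if (length(sets) > 1L) {
    out$X_l <- do.call(cbind, lapply(sets, `[[`, "X_l"))
    out$X_h <- do.call(cbind, lapply(sets, `[[`, "X_h"))
    out$positions <- do.call(rbind, lapply(sets, `[[`, "positions"))
    out$lr_means <- unlist(lapply(sets, `[[`, "lr_means"), use.names = FALSE)
  }
  out
}

#' Reassemble an image from overlapping HR patches
#'
#' Each patch has its stored DC mean re-added and is placed at `factor` times
#' its 0-based LR anchor; pixels covered by several overlapping patches are
#' averaged with equal weights and the result is clipped to `[0, 1]`.
#'
#' @param patches `S_h x N` matrix of (mean-removed) HR patch vectors.
#' @param positions `N x 2` matrix of 0-based LR `(row, col)` anchors.
#' @param lr_means Length-`N` vector of DC levels to re-add.
#' @param out_shape Integer vector `c(height, width)` of the output image.
#' @param factor Upscaling factor `M`.
#' @return Numeric matrix `out_shape[1] x out_shape[2]` in `[0, 1]`.
#' @export
assemble_image <- function(patches, positions, lr_means, out_shape, factor) {
  if (length(lr_means) != ncol(patches))
    .stopf("assemble_image: positions/lr_means length mismatch")
  ov <- .overlap_average(patches + rep(lr_means, each = nrow(patches)),
                         positions, out_shape, factor)
  .clip01(ov)
}

# Equal-weight overlap averaging of patch columns placed at factor * anchor;
# errors on any uncovered pixel.  No clipping, no DC handling.
.overlap_average <- function(patches, positions, out_shape, factor) {
  p <- as.integer(round(sqrt(nrow(patches))))
  if (p * p != nrow(patches)) .stopf("assemble_image: patches are not square")
  n <- ncol(patches)
  if (nrow(positions) != n)
    .stopf("assemble_image: positions/patches length mismatch")
  acc <- matrix(0, out_shape[1], out_shape[2])
  cnt <- matrix(0, out_shape[1], out_shape[2])
  for (i in seq_len(n)) {
    r <- factor * positions[i, 1L] + seq_len(p)
    cc <- factor * positions[i, 2L] + seq_len(p)
    acc[r, cc] <- acc[r, cc] + patches[, i]
    cnt[r, cc] <- cnt[r, cc] + 1
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)[1L, ]
    .stopf("assemble_image: pixel (%d, %d) covered by no patch (0-based: %d, %d)",
           bad[1], bad[2], bad[1] - 1L, bad[2] - 1L)
  }
  acc / cnt
}

#' Serialize / restore a patch-pair set
#'
#' Writes the named arrays `X_l`, `X_h`, `positions`, `lr_means` and the
#' scalar geometry metadata as a single RDS container.
#'
#' @param patches A `patch_pair_set`.
#' @param path File path.
#' @return `path` (write) or the restored `patch_pair_set` (read).
#' @export
save_patch_set <- function(patches, path) {
  stopifnot(inherits(patches, "patch_pair_set"))
  saveRDS(patches, path)
  invisible(path)
}

#' @rdname save_patch_set
#' @export
load_patch_set <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "patch_pair_set")) .stopf("'%s' is not a patch_pair_set", path)
  x
}
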