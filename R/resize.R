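# Bicubic resampling.  One kernel (Catmull-Rom family cubic, a = -0.5) is
# shared by the degradation operator and the interpolation baseline so the
# two are mutually consistent; when downsampling the kernel is dilated by
# the scale factor (antialiasing), as in the standard imresize convention.

# Cubic convolution kernel with a = -0.5 (support [-2, 2], h(0)=1, h(+-1)=0).
.cubic_kernel <- function(x) {
  ax <- abs(x)
  w <- x * 0  # keeps dim attributes
  i1 <- ax <= 1
  i2 <- ax > 1 & ax < 2
  w[i1] <- (1.5 * ax[i1] - 2.5) * ax[i1]^2 + 1
  w[i2] <- ((-0.5 * ax[i2] + 2.5) * ax[i2] - 4) * ax[i2] + 2
  w
}

# Contribution table for resampling one axis from in_len to out_len samples:
# output i = sum_p w[i, p] * input[ind[i, p]].  Center-aligned coordinate
# mapping, boundary handled by index clamping (edge replication), weights
# renormalized to sum 1.
.resize_contributions <- function(in_len, out_len) {
  scale <- out_len / in_len
  if (scale < 1) {            # antialiasing: dilate kernel by the scale
    kern <- function(x) scale * .cubic_kernel(scale * x)
    kwidth <- 4 / scale
  } else {
    kern <- .cubic_kernel
    kwidth <- 4
  }
  u <- (seq_len(out_len) - 0.5) / scale + 0.5   # output center in input coords
  left <- floor(u - kwidth / 2)
  P <- ceiling(kwidth) + 2L
  ind <- outer(left, seq_len(P) - 1, `+`)
  w <- kern(u - ind)
  w <- w / rowSums(w)
  ind <- pmin(pmax(ind, 1), in_len)
  list(ind = ind, w = w, P = P)
}

.resize_axis <- function(mat, contrib) {
  # resample along rows of `mat` (dim 1)
  out <- matrix(0, nrow(contrib$ind), ncol(mat))
  for (p in seq_len(contrib$P))
    out <- out + contrib$w[, p] * mat[contrib$ind[, p], , drop = FALSE]
  out
}

#' Bicubic resampling
#'
#' Resizes an image with the cubic convolution kernel (`a = -0.5`).  The same
#' operator implements the degradation model's downsampling matrix `G` and
#' the bicubic interpolation baseline; antialiasing (kernel dilation) is
#' applied automatically when a dimension shrinks.  Output intensities are
#' clipped to `[0, 1]`.
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param out_height,out_width Target dimensions (positive integers).
#' @return Resampled matrix of size `out_height` x `out_width`.
#' @export
bicubic_resize <- function(img, out_height, out_width) {
  .check_image(img)
  if (out_height < 1 || out_width < 1)
    .stopf("bicubic_resize: target dimensions must be positive")
  out <- img
  if (out_height != nrow(img))
    out <- .resize_axis(out, .resize_contributions(nrow(img), out_height))
  if (out_width != ncol(img))
    out <- t(.resize_axis(t(out), .resize_contributions(ncol(img), out_width)))
  .clip01(out)
}

#' Degrade an HR image into an HR/LR training pair
#'
#' Implements the simplified degradation model `x_l = G x_h`: the HR image is
#' cropped (top-left) to dimensions divisible by the upscaling factor and the
#' LR image is its bicubic downsampling by that factor.
#'
#' @param hr Numeric HR matrix in `[0, 1]`.
#' @param factor Upscaling factor `M`, 2 or 4.
#' @return An `image_pair`: list with elements `hr`, `lr`, `factor`.
#' @export
degrade <- function(hr, factor) {
  .check_image(hr, "hr")
  if (!factor %in% c(2L, 4L)) .stopf("degrade: factor must be 2 or 4")
  factor <- as.integer(factor)
  if (nrow(hr) < factor || ncol(hr) < factor)
    .stopf("degrade: image smaller than the factor")
  h <- (nrow(hr) %/% factor) * factor
  w <- (ncol(hr) %/% factor) * factor
  hr <- hr[seq_len(h), seq_len(w), drop = FALSE]
  lr <- bicubic_resize(hr, h %/% factor, w %/% factor)
  structure(list(hr = hr, lr = lr, factor = factor), class = "image_pair")
}

#' @export
print.image_pair <- function(x, ...) {
  cat(sprintf("<image_pair> HR %dx%d, LR %dx%d, factor %d\n",
              nrow(x$hr), ncol(x$hr), nrow(x$lr), ncol(x$lr), x$factor))
  invisible(x)
}
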