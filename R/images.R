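#' Read a grayscale image
#'
#' Loads a PNG or TIFF raster and returns it as a numeric matrix with
#' intensities in `[0, 1]` (8- and 16-bit integer rasters are normalized by
#' the reader).  Multi-channel images are converted to luminance
#' (ITU-R BT.601 weights 0.299/0.587/0.114, which sum to 1) before
#' normalization; an alpha channel, if present, is ignored.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix in `[0, 1]`, rows = image rows (origin top-left).
#' @seealso [save_image()]
#' @export
load_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    .stopf("cannot read image: '%s' does not exist", as.character(path)[1])
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    .stopf("unsupported raster format '.%s' (PNG or TIFF expected)", ext)
  )
  if (is.list(arr)) arr <- arr[[1]]  # multi-page TIFF: first page
  if (length(arr) == 0L) .stopf("zero-sized raster in '%s'", path)
  img <- if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3]
    if (nc >= 3L) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  } else {
    as.matrix(arr)
  }
  .check_image(.clip01(img), "image")
}

#' Write a grayscale image
#'
#' @param img Numeric matrix in `[0, 1]`.
#' @param path Output path; format chosen by extension (`.png`, `.tif`/`.tiff`).
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  .check_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    .stopf("unsupported raster format '.%s' (PNG or TIFF expected)", ext)
  )
  invisible(path)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(peak^2 / MSE)` with peak 1.0 on the normalized intensity scale
#' (equivalent to 255 on an 8-bit scale).  Identical images have zero MSE and
#' return the `Inf` sentinel.
#'
#' @param ref,test Numeric matrices of identical dimensions, intensities in
#'   `[0, 1]`.
#' @return PSNR in dB (`Inf` for identical images).
#' @export
psnr <- function(ref, test) {
  if (!identical(dim(ref), dim(test)))
    .stopf("psnr: dimension mismatch (%s vs %s)",
           paste(dim(ref), collapse = "x"), paste(dim(test), collapse = "x"))
  mse <- mean((ref - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

# 1-D Gaussian taps, normalized to sum 1.
.gauss_taps <- function(size, sigma) {
  x <- seq_len(size) - (size + 1) / 2
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

# "Valid" separable filtering: band matrix multiplication on both sides.
.filter_valid <- function(img, taps) {
  k <- length(taps)
  band <- function(n) {
    m <- n - k + 1L
    W <- matrix(0, m, n)
    for (j in seq_len(k)) W[cbind(seq_len(m), seq_len(m) + j - 1L)] <- taps[j]
    W
  }
  Wr <- band(nrow(img))
  Wc <- band(ncol(img))
  Wr %*% img %*% t(Wc)
}

#' Structural similarity index (SSIM)
#'
#' Mean local SSIM with the standard reference parameterization: 11x11
#' Gaussian window with sigma 1.5, stability constants `K1 = 0.01`,
#' `K2 = 0.03`, dynamic range 1.0.  Local statistics are computed over the
#' valid (fully-overlapping) window positions.  The measure is symmetric in
#' its arguments and equals 1 for identical images.
#'
#' @inheritParams psnr
#' @param window Window side length (default 11).
#' @param sigma Gaussian window standard deviation (default 1.5).
#' @param K1,K2 Stability constants.
#' @return Scalar SSIM in `[-1, 1]`.
#' @export
ssim <- function(ref, test, window = 11L, sigma = 1.5, K1 = 0.01, K2 = 0.03) {
  if (!identical(dim(ref), dim(test)))
    .stopf("ssim: dimension mismatch")
  if (nrow(ref) < window || ncol(ref) < window)
    .stopf("ssim: image smaller than the %dx%d window", window, window)
  taps <- .gauss_taps(window, sigma)
  C1 <- (K1 * 1.0)^2
  C2 <- (K2 * 1.0)^2
  mu1 <- .filter_valid(ref, taps)
  mu2 <- .filter_valid(test, taps)
  s11 <- .filter_valid(ref * ref, taps) - mu1^2
  s22 <- .filter_valid(test * test, taps) - mu2^2
  s12 <- .filter_valid(ref * test, taps) - mu1 * mu2
  num <- (2 * mu1 * mu2 + C1) * (2 * s12 + C2)
  den <- (mu1^2 + mu2^2 + C1) * (s11 + s22 + C2)
  mean(num / den)
}
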