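# Synthetic fundus phantoms.  The generator emulates the gross anatomy an
# angiogram shows -- a bright optic disc, a darker macular region and a
# branching vessel tree over a smoothly illuminated background -- so the SR
# pipeline can be exercised end to end without clinical data.

#' Phantom generation parameters
#'
#' @param image_size Square image side in pixels (>= 64).
#' @param n_vessels Number of primary vessel branches leaving the disc.
#' @param vessel_width_range `c(min, max)` vessel width in pixels (>= 1).
#' @param disc_radius Optic disc radius in pixels (default `image_size / 9`).
#' @param background_gradient Amplitude of the smooth illumination gradient.
#' @param noise_sigma Standard deviation of additive Gaussian noise.
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(image_size = 128L, n_vessels = 7L,
                           vessel_width_range = c(1.5, 3.5),
                           disc_radius = NULL, background_gradient = 0.08,
                           noise_sigma = 0.01, seed = 1L) {
  if (image_size < 64L) .stopf("image_size must be >= 64")
  if (noise_sigma < 0) .stopf("noise_sigma must be >= 0")
  if (any(vessel_width_range < 1)) .stopf("vessel widths must be >= 1 pixel")
  if (n_vessels < 0) .stopf("n_vessels must be >= 0")
  structure(list(
    image_size = as.integer(image_size),
    n_vessels = as.integer(n_vessels),
    vessel_width_range = as.numeric(vessel_width_range),
    disc_radius = disc_radius %||% (image_size / 9),
    background_gradient = as.numeric(background_gradient),
    noise_sigma = as.numeric(noise_sigma),
    seed = as.integer(seed)
  ), class = "phantom_params")
}

# Rasterize one quadratic Bezier curve of half-width w/2 by stamping discs
# along the curve into `canvas` (value `level`), returning the canvas.
.stamp_bezier <- function(canvas, p0, p1, p2, w, level) {
  n <- nrow(canvas)
  npts <- max(64L, 4L * as.integer(round(sqrt(sum((p2 - p0)^2)))))
  t <- seq(0, 1, length.out = npts)
  bx <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  by <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  r <- w / 2
  ir <- as.integer(ceiling(r))
  win <- seq.int(-ir, ir)
  for (k in seq_len(npts)) {
    cx <- bx[k]; cy <- by[k]
    rows <- as.integer(round(cx)) + win
    cols <- as.integer(round(cy)) + win
    ok_r <- rows >= 1L & rows <= n
    ok_c <- cols >= 1L & cols <= n
    if (!any(ok_r) || !any(ok_c)) next
    rr <- rows[ok_r]; cc <- cols[ok_c]
    d2 <- outer((rr - cx)^2, (cc - cy)^2, `+`)
    hit <- d2 <= r^2
    if (any(hit)) {
      sub <- canvas[rr, cc, drop = FALSE]
      sub[hit] <- level
      canvas[rr, cc] <- sub
    }
  }
  canvas
}

# One vessel tree branch (recursive), deterministic for the supplied seed.
.draw_vessel <- function(canvas, origin, params, seed) {
  withr::with_seed(seed, {
    n <- params$image_size
    wr <- params$vessel_width_range
    ang <- runif(1, 0, 2 * pi)
    len <- runif(1, 0.45, 0.85) * n
    segs <- list(list(p0 = origin, ang = ang, len = len,
                      w = runif(1, wr[1], wr[2]), depth = 0L))
    while (length(segs) > 0L) {
      s <- segs[[1L]]; segs <- segs[-1L]
      p2 <- s$p0 + s$len * c(cos(s$ang), sin(s$ang))
      bend <- runif(1, -0.25, 0.25)
      mid <- (s$p0 + p2) / 2 +
        s$len * bend * c(cos(s$ang + pi / 2), sin(s$ang + pi / 2))
      canvas <- .stamp_bezier(canvas, s$p0, mid, p2, s$w, 1)
      if (s$depth < 2L && s$w > 1.2) {
        for (sgn in c(-1, 1)) {
          if (runif(1) < 0.75) {
            segs[[length(segs) + 1L]] <- list(
              p0 = p2, ang = s$ang + sgn * runif(1, 0.25, 0.7),
              len = s$len * runif(1, 0.45, 0.7),
              w = s$w * runif(1, 0.6, 0.8), depth = s$depth + 1L)
          }
        }
      }
    }
    canvas
  })
}

# Structural layers of a phantom: background+gradient, disc/macula fields and
# the binary vessel mask.  Exposed (internal) for tests that count vessel
# pixels or inspect the noise-free construction.
.phantom_layers <- function(params) {
  n <- params$image_size
  xs <- matrix(seq_len(n), n, n)
  ys <- matrix(seq_len(n), n, n, byrow = TRUE)

  withr::with_seed(.derive_seed(params$seed, 1L), {
    # smooth illumination gradient along a random direction
    theta <- runif(1, 0, 2 * pi)
    grad <- if (params$background_gradient > 0) {
      u <- (cos(theta) * (xs - n / 2) + sin(theta) * (ys - n / 2)) / n
      params$background_gradient * u
    } else matrix(0, n, n)
    # optic disc center in a lateral band, macula offset toward center
    disc_c <- c(runif(1, 0.35, 0.65) * n, runif(1, 0.18, 0.32) * n)
    mac_c <- disc_c + c(runif(1, -0.08, 0.08) * n, runif(1, 0.35, 0.5) * n)
  })

  background <- 0.25
  disc_level <- 0.85
  macula_drop <- 0.12

  d_disc <- sqrt((xs - disc_c[1])^2 + (ys - disc_c[2])^2)
  disc <- (disc_level - background) * (d_disc <= params$disc_radius)
  d_mac <- sqrt((xs - mac_c[1])^2 + (ys - mac_c[2])^2)
  macula <- -macula_drop * (d_mac <= 1.6 * params$disc_radius)

  vessel_mask <- matrix(0, n, n)
  if (params$n_vessels > 0L) {
    for (k in seq_len(params$n_vessels)) {
      vessel_mask <- .draw_vessel(vessel_mask, disc_c, params,
                                  .derive_seed(params$seed, 100L + k))
    }
  }
  list(background = background, gradient = grad, disc = disc,
       macula = macula, vessel_mask = vessel_mask,
       vessel_level = 0.62, disc_level = disc_level)
}

#' Generate a fundus phantom image
#'
#' Renders a synthetic angiogram-like image: a bright optic disc, a darker
#' macular region, a recursively branching vessel tree of quadratic Bezier
#' segments (bright vessels, mimicking the fluorescing phase), a smooth
#' illumination gradient, and additive Gaussian noise, clipped to `[0, 1]`.
#' Bitwise deterministic for a fixed seed.  Vessels are seeded individually,
#' so increasing `n_vessels` adds vessels without changing the existing ones.
#'
#' @param params A [phantom_params()] list.
#' @return Numeric `image_size` x `image_size` matrix in `[0, 1]`.
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    .stopf("`params` must come from phantom_params()")
  lay <- .phantom_layers(params)
  img <- lay$background + lay$gradient + lay$disc + lay$macula
  img[lay$vessel_mask > 0] <- lay$vessel_level
  if (params$noise_sigma > 0) {
    img <- img + withr::with_seed(
      .derive_seed(params$seed, 2L),
      matrix(rnorm(length(img), 0, params$noise_sigma), nrow(img)))
  }
  .clip01(img)
}
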