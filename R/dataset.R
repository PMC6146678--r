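# Grouped phantom datasets.  Each group plays the role of one eye: its
# members share one base phantom and differ by small translation, rotation
# and illumination changes ("homologous images"); different groups have
# different anatomy ("non-homologous images").

# Rigid warp (rotation about the image center + translation) with bilinear
# interpolation and edge replication.
.warp_image <- function(img, tx, ty, angle_deg) {
  n <- nrow(img); m <- ncol(img)
  th <- angle_deg * pi / 180
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  X <- matrix(seq_len(n), n, m) - cx
  Y <- matrix(seq_len(m), n, m, byrow = TRUE) - cy
  # inverse map: rotate by -theta, untranslate
  xs <- cos(th) * X + sin(th) * Y + cx - tx
  ys <- -sin(th) * X + cos(th) * Y + cy - ty
  xs <- pmin(pmax(xs, 1), n)
  ys <- pmin(pmax(ys, 1), m)
  x0 <- pmin(floor(xs), n - 1); y0 <- pmin(floor(ys), m - 1)
  fx <- xs - x0; fy <- ys - y0
  idx <- function(i, j) img[cbind(as.vector(i), as.vector(j))]
  v <- (1 - fx) * (1 - fy) * idx(x0, y0) +
       fx * (1 - fy) * idx(x0 + 1, y0) +
       (1 - fx) * fy * idx(x0, y0 + 1) +
       fx * fy * idx(x0 + 1, y0 + 1)
  matrix(v, n, m)
}

#' Generate a grouped phantom dataset of HR/LR image pairs
#'
#' Builds `n_groups` base phantoms (one simulated eye each) and renders
#' `per_group` homologous members per group by perturbing the base with a
#' random translation, rotation and multiplicative illumination change plus
#' a small amount of fresh acquisition noise.  Every member is degraded to an
#' HR/LR pair at the given factor and each group is split into training and
#' test members following `split_ratio` (at least one member on each side).
#' Groups listed in `exclude_groups_from_train` contribute no training pairs;
#' their test members are unchanged, so ablation runs ("homologous exclusion")
#' can be compared on an identical test set.
#'
#' Deterministic for a fixed seed: images, split membership and pair order
#' are identical across calls, and independent of the exclusion list.
#'
#' @param n_groups Number of simulated eyes (>= 1).
#' @param per_group Images per group (>= 2).
#' @param factor Upscaling factor M (2 or 4).
#' @param image_size Square phantom side (pixels).
#' @param variation List with `translation` (max |shift| px), `rotation`
#'   (max |angle| deg) and `illumination` (`c(lo, hi)` multiplicative range).
#' @param split_ratio Length-2 vector of train:test proportions per group
#'   (default `c(23, 14)`).
#' @param seed Integer seed.
#' @param exclude_groups_from_train Integer group ids excluded from training.
#' @param phantom_args Extra arguments forwarded to [phantom_params()].
#' @return A `grouped_dataset`: lists `train_pairs`/`test_pairs` of
#'   `image_pair` objects (names `gXX_mYY`), a `manifest` data frame
#'   (group, member, split), `groups` (member images), `bases`, `factor`,
#'   `split_ratio`, `excluded`, `seed`.
#' @export
generate_grouped_dataset <- function(n_groups = 10L, per_group = 4L,
                                     factor = 2L, image_size = 128L,
                                     variation = list(translation = 5,
                                                      rotation = 3,
                                                      illumination = c(0.9, 1.1)),
                                     split_ratio = c(23, 14), seed = 1L,
                                     exclude_groups_from_train = integer(),
                                     phantom_args = list()) {
  if (n_groups < 1L) .stopf("n_groups must be >= 1")
  if (per_group < 2L) .stopf("per_group must be >= 2")
  excl <- as.integer(exclude_groups_from_train)
  if (length(setdiff(seq_len(n_groups), excl)) == 0L)
    .stopf("excluding every group leaves an empty training set")

  frac <- split_ratio[1] / sum(split_ratio)
  n_train <- max(1L, min(per_group - 1L, as.integer(round(per_group * frac))))

  groups <- vector("list", n_groups)
  bases <- vector("list", n_groups)
  train_pairs <- list(); test_pairs <- list()
  manifest <- NULL
  for (g in seq_len(n_groups)) {
    pp <- do.call(phantom_params,
                  c(list(image_size = image_size,
                         seed = .derive_seed(seed, 10L * g)),
                    phantom_args))
    base <- generate_phantom(pp)
    bases[[g]] <- base
    members <- vector("list", per_group)
    for (m in seq_len(per_group)) {
      members[[m]] <- withr::with_seed(.derive_seed(seed, 1000L * g + m), {
        tx <- runif(1, -variation$translation, variation$translation)
        ty <- runif(1, -variation$translation, variation$translation)
        ang <- runif(1, -variation$rotation, variation$rotation)
        illum <- runif(1, variation$illumination[1], variation$illumination[2])
        img <- .clip01(.warp_image(base, tx, ty, ang) * illum)
        .clip01(img + matrix(rnorm(length(img), 0, 0.004), nrow(img)))
      })
    }
    groups[[g]] <- members
    train_m <- withr::with_seed(.derive_seed(seed, 5000L + g),
                                sort(sample.int(per_group, n_train)))
    for (m in seq_len(per_group)) {
      pr <- degrade(members[[m]], factor)
      nm <- sprintf("g%02d_m%02d", g, m)
      is_train <- m %in% train_m && !(g %in% excl)
      split <- if (m %in% train_m) "train" else "test"
      if (is_train) train_pairs[[nm]] <- pr
      if (split == "test") test_pairs[[nm]] <- pr
      manifest <- rbind(manifest, data.frame(
        image = nm, group = g, member = m,
        split = if (is_train) "train" else if (split == "test") "test" else "dropped",
        stringsAsFactors = FALSE))
    }
  }
  if (length(train_pairs) == 0L) .stopf("empty training set")
  structure(list(groups = groups, bases = bases,
                 train_pairs = train_pairs, test_pairs = test_pairs,
                 manifest = manifest, factor = as.integer(factor),
                 split_ratio = split_ratio, excluded = excl,
                 image_size = as.integer(image_size), seed = as.integer(seed)),
            class = "grouped_dataset")
}

#' @export
print.grouped_dataset <- function(x, ...) {
  cat(sprintf(paste0("<grouped_dataset> %d groups, %d train / %d test pairs, ",
                     "%dpx, factor %d%s\n"),
              length(x$groups), length(x$train_pairs), length(x$test_pairs),
              x$image_size, x$factor,
              if (length(x$excluded)) paste0(", excluded from train: ",
                                             paste(x$excluded, collapse = ","))
              else ""))
  invisible(x)
}

#' Write a grouped dataset to disk
#'
#' Writes the HR member images as a PNG tree (`group_XX/img_YY.png`) plus a
#' JSON manifest recording splits, factor, seed and exclusions.
#'
#' @param dataset A `grouped_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "grouped_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (g in seq_along(dataset$groups)) {
    gd <- file.path(dir, sprintf("group_%02d", g))
    dir.create(gd, showWarnings = FALSE)
    for (m in seq_along(dataset$groups[[g]]))
      save_image(dataset$groups[[g]][[m]],
                 file.path(gd, sprintf("img_%02d.png", m)))
  }
  jsonlite::write_json(
    list(manifest = dataset$manifest, factor = dataset$factor,
         seed = dataset$seed, split_ratio = dataset$split_ratio,
         excluded_from_train = dataset$excluded,
         image_size = dataset$image_size),
    file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
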