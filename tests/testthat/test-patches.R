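test_that("patch grid counts, flush border patches and anchor alignment", {
  img <- matrix(runif(81), 9, 9)
  pr <- structure(list(hr = bicubic_resize(img, 18, 18) * 0 + 0.5,
                       lr = img, factor = 2L), class = "image_pair")
  pr$hr <- matrix(runif(324), 18, 18)
  ps <- extract_training_patches(pr)
  expect_equal(ncol(ps$X_l), 16L)           # 4 anchors per axis on a 9px side
  expect_equal(nrow(ps$X_l), 9L)
  expect_equal(nrow(ps$X_h), 36L)           # HR patches are 3M x 3M = 6x6
  expect_equal(ps$hr_patch_size, 6L)
  expect_equal(ps$hr_stride, 4L)

  # flush border: a 10px side needs a fifth anchor at 7
  expect_equal(ffasr:::.patch_anchors(10L, 3L, 2L), c(0L, 2L, 4L, 6L, 7L))

  # HR anchors are exactly factor * LR anchors by construction: verify the
  # extracted HR content matches a direct window read at 2x the LR anchor
  i <- 7L
  r <- 2L * ps$positions[i, 1L] + 1:6
  cc <- 2L * ps$positions[i, 2L] + 1:6
  expect_equal(ps$X_h[, i] + ps$lr_means[i], as.vector(pr$hr[r, cc]))
})

test_that("mean removal stores the DC level and zeroes constant patches", {
  const <- matrix(0.42, 24, 24)
  ps <- extract_training_patches(degrade(const, 2L))
  expect_true(all(abs(ps$X_l) < 1e-12))
  expect_true(all(abs(ps$X_h) < 1e-12))
  expect_equal(ps$lr_means, rep(0.42, ncol(ps$X_l)), tolerance = 1e-12)
})

test_that("extract / assemble round trip reproduces the HR image", {
  pr <- fixture_pair(48)
  ps <- extract_training_patches(pr)
  rec <- assemble_image(ps$X_h, ps$positions, ps$lr_means, dim(pr$hr), 2L)
  expect_lt(max(abs(rec - pr$hr)), 1e-10)

  pr4 <- fixture_pair(64, factor = 4L, seed = 8L)
  ps4 <- extract_training_patches(pr4)
  rec4 <- assemble_image(ps4$X_h, ps4$positions, ps4$lr_means, dim(pr4$hr), 4L)
  expect_lt(max(abs(rec4 - pr4$hr)), 1e-10)
})

test_that("residual targets are HR minus the bicubic mid-image and rebuild exactly", {
  pr <- fixture_pair(48)
  ps <- extract_training_patches(pr, target = "residual")
  mid <- bicubic_resize(pr$lr, nrow(pr$hr), ncol(pr$hr))
  # adding the averaged residual patches back onto the mid image is exact
  rec <- mid + ffasr:::.overlap_average(ps$X_h, ps$positions, dim(pr$hr), 2L)
  expect_lt(max(abs(rec - pr$hr)), 1e-10)
  # LR side is unchanged between the two target modes
  raw <- extract_training_patches(pr, target = "raw")
  expect_identical(ps$X_l, raw$X_l)
  expect_identical(ps$lr_means, raw$lr_means)
  # a zero residual prediction reproduces bicubic: targets are small
  expect_lt(mean(abs(ps$X_h)), mean(abs(raw$X_h)))
})

test_that("overlap averaging and coverage validation behave as specified", {
  # two 3x3 patches (factor 1 grid) overlapping on a strip, values 0 and 1
  patches <- cbind(rep(0, 9), rep(1, 9))
  pos <- rbind(c(0L, 0L), c(0L, 2L))
  out <- assemble_image(patches, pos, c(0.0, 0.0), c(3L, 5L), 1L)
  expect_equal(out[, 3], rep(0.5, 3))
  expect_equal(out[, 1:2], matrix(0, 3, 2))
  expect_equal(out[, 4:5], matrix(1, 3, 2))

  # constant patches (after mean re-add) give the constant image
  cp <- matrix(0, 9, 2)
  outc <- assemble_image(cp, rbind(c(0L, 0L), c(0L, 1L)), c(0.6, 0.6),
                         c(3L, 4L), 1L)
  expect_equal(outc, matrix(0.6, 3, 4))

  expect_error(assemble_image(cp, rbind(c(0L, 0L), c(0L, 1L)), c(0.6, 0.6),
                              c(3L, 6L), 1L), "covered by no patch")
})

test_that("patch-pair sets serialize and restore losslessly", {
  ps <- fixture_patches(32)
  f <- withr::local_tempfile(fileext = ".rds")
  save_patch_set(ps, f)
  expect_identical(load_patch_set(f), ps)
})
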