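# End-to-end orchestration: method configs with the reference defaults,
# training dispatch, whole-image reconstruction, evaluation and the
# all-methods benchmark.

#' Batch patch prediction generic
#'
#' Maps an `S_l x N` matrix of mean-removed LR patch vectors to the
#' `S_h x N` matrix of HR reconstructions under a trained SR model.  Every
#' model class implements a method; this is the hot path used by
#' [super_resolve_image()].
#'
#' @param model A trained SR model.
#' @param X `S_l x N` matrix of LR patch vectors.
#' @param ... Unused.
#' @return `S_h x N` matrix.
#' @export
predict_patches <- function(model, X, ...) UseMethod("predict_patches")

.sr_methods <- c("bicubic", "ne_ls", "ne_nnls", "sb_yang", "sb_zeyde",
                 "anr", "aplus", "jor", "srf")

# Reference defaults for each method (upscaling-independent).
.method_defaults <- function(method) {
  switch(method,
    bicubic = list(),
    ne_ls = ,
    ne_nnls = list(K = 24L, pool_cap = Inf, hr_target = "residual"),
    sb_yang = list(B = 2048L, lambda = 0.1, n_iters = 10L, train_cap = Inf,
                   hr_target = "residual"),
    sb_zeyde = list(B = 2048L, L = 24L, n_iters = 20L, lambda = 0.1,
                    train_cap = Inf, hr_target = "residual"),
    anr = list(K = 40L, lambda = 0.1, dict = NULL,
               B = 2048L, L = 24L, dict_iters = 20L, train_cap = Inf,
               hr_target = "residual"),
    aplus = list(K = 2048L, lambda = 0.1, dict = NULL, pool_cap = 1e5,
                 B = 2048L, L = 24L, dict_iters = 20L, train_cap = Inf,
                 hr_target = "residual"),
    jor = list(O = 32L, n_iters = 20L, lambda = 0.1, K_select = 32L,
               n_restarts = 1L, pool_cap = Inf, hr_target = "residual"),
    srf = list(n_trees = 6L, max_depth = 15L, lambda = 0.1, kappa = 1,
               min_leaf = NULL, n_candidates = 32L, pool_cap = Inf,
               hr_target = "residual")
  )
}

#' Method configuration
#'
#' Builds a validated configuration for one SR method with the reference
#' parameter defaults baked in (neighborhood size 24 for NE; 2048 atoms,
#' `lambda = 0.1`, `L = 24` for the sparse methods; K = 40 / 2048 and
#' `lambda = 0.1` for ANR / A+; 32 regressors, 20 iterations, K = 32 for
#' JOR; 6 trees, depth 15, `lambda = 0.1`, `kappa = 1` for SRF); any default
#' can be overridden through `...`.
#'
#' @param method One of `"bicubic"`, `"ne_ls"`, `"ne_nnls"`, `"sb_yang"`,
#'   `"sb_zeyde"`, `"anr"`, `"aplus"`, `"jor"`, `"srf"`.
#' @param factor Upscaling factor M, 2 or 4.
#' @param seed Integer seed used for every random choice during training.
#' @param ... Method-specific parameter overrides.
#' @return A `method_config` list.
#' @export
method_config <- function(method, factor = 2L, seed = 1L, ...) {
  if (!method %in% .sr_methods)
    .stopf("unknown method '%s' (expected one of: %s)", method,
           paste(.sr_methods, collapse = ", "))
  if (!factor %in% c(2L, 4L)) .stopf("factor must be 2 or 4")
  params <- .method_defaults(method)
  over <- list(...)
  bad <- setdiff(names(over), names(params))
  if (length(bad))
    .stopf("unknown parameter(s) for %s: %s", method, paste(bad, collapse = ", "))
  params[names(over)] <- over
  structure(list(method = method, factor = as.integer(factor),
                 seed = as.integer(seed), params = params),
            class = "method_config")
}

#' @export
print.method_config <- function(x, ...) {
  cat(sprintf("<method_config> %s, factor %d, seed %d\n",
              x$method, x$factor, x$seed))
  invisible(x)
}

# Extract + concatenate training patches from image pairs, with an optional
# seeded column cap.
.training_patches <- function(train_pairs, factor, cap = Inf, seed = 1L,
                              target = "residual") {
  stopifnot(length(train_pairs) >= 1L)
  for (p in train_pairs)
    if (p$factor != factor) .stopf("training pair factor %d != config factor %d",
                                   p$factor, factor)
  ps <- .bind_patch_sets(lapply(train_pairs, extract_training_patches,
                                target = target))
  keep <- .cap_columns(ncol(ps$X_l), cap, seed)
  if (length(keep) < ncol(ps$X_l)) {
    ps$X_l <- ps$X_l[, keep, drop = FALSE]
    ps$X_h <- ps$X_h[, keep, drop = FALSE]
    ps$positions <- ps$positions[keep, , drop = FALSE]
    ps$lr_means <- ps$lr_means[keep]
  }
  ps
}

#' Train an SR model from HR/LR image pairs
#'
#' Extracts the dense training patch pairs from every image pair and
#' dispatches to the configured method's trainer.  Deterministic for a fixed
#' config and seed.  `bicubic` needs no training and returns a stub model.
#'
#' @param config A [method_config()].
#' @param train_pairs List of `image_pair` objects (ignored for bicubic).
#' @return A trained model (class `sr_model`), carrying `factor` and the
#'   config snapshot.
#' @seealso [save_model()], [super_resolve_image()]
#' @export
train_model <- function(config, train_pairs = NULL) {
  stopifnot(inherits(config, "method_config"))
  if (config$method == "bicubic") {
    return(structure(list(factor = config$factor, config = config),
                     class = c("bicubic_model", "sr_model")))
  }
  if (length(train_pairs) == 0L) .stopf("empty training set")
  p <- config$params
  seed <- config$seed
  target <- p$hr_target %||% "residual"
  ps <- .training_patches(train_pairs, config$factor,
                          cap = p$pool_cap %||% Inf, seed = seed,
                          target = target)
  model <- switch(config$method,
    ne_ls = ne_model(ps, K = p$K, variant = "ls"),
    ne_nnls = ne_model(ps, K = p$K, variant = "nnls"),
    sb_yang = {
      psd <- .training_patches(train_pairs, config$factor,
                               cap = p$train_cap, seed = seed,
                               target = target)
      train_joint_dictionary(psd, B = p$B, lambda = p$lambda,
                             n_iters = p$n_iters, seed = seed)
    },
    sb_zeyde = {
      psd <- .training_patches(train_pairs, config$factor,
                               cap = p$train_cap, seed = seed,
                               target = target)
      train_zeyde_dictionary(psd, B = p$B, L = p$L, n_iters = p$n_iters,
                             seed = seed, lambda = p$lambda)
    },
    anr = ,
    aplus = {
      dict <- p$dict
      if (is.null(dict)) {
        psd <- .training_patches(train_pairs, config$factor,
                                 cap = p$train_cap, seed = seed,
                                 target = target)
        dict <- train_zeyde_dictionary(psd, B = p$B, L = p$L,
                                       n_iters = p$dict_iters, seed = seed,
                                       lambda = p$lambda)
      }
      build_anchor_projections(dict, patches = ps, K = p$K,
                               lambda = p$lambda,
                               variant = if (config$method == "anr") "anr"
                                         else "aplus",
                               pool_cap = p$pool_cap %||% 1e5, seed = seed)
    },
    jor = jor_fit(ps, O = p$O, n_iters = p$n_iters, lambda = p$lambda,
                  K_select = p$K_select, seed = seed,
                  n_restarts = p$n_restarts),
    srf = train_srf(ps, n_trees = p$n_trees, max_depth = p$max_depth,
                    lambda = p$lambda, kappa = p$kappa,
                    min_leaf = p$min_leaf, n_candidates = p$n_candidates,
                    seed = seed)
  )
  model$factor <- config$factor
  model$hr_target <- target
  model$config <- config
  model
}

#' Save / load a trained model
#'
#' Self-describing single-file RDS container carrying the model, its class,
#' the config snapshot and the training seed.
#'
#' @param model A trained `sr_model`.
#' @param path File path.
#' @return `path` (write) or the model (read).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sr_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "sr_model")) .stopf("'%s' is not a saved sr_model", path)
  m
}

#' Super-resolve a whole LR image
#'
#' Densely extracts 3x3 LR patches at stride 2 (with flush border patches),
#' removes each patch's DC mean and reconstructs every HR patch with the
#' model.  For a model trained on residual targets (the default) the
#' overlap-averaged predictions are added onto the bicubic interpolation of
#' the input; for raw targets the DC means are re-added during assembly.
#' The result is clipped to `[0, 1]` and has `factor` times the input
#' dimensions.  The bicubic model bypasses the patch path and calls
#' [bicubic_resize()] directly.
#'
#' @param lr Numeric LR matrix in `[0, 1]`.
#' @param model A trained `sr_model`.
#' @param factor Upscaling factor; must match the model's.
#' @return HR matrix of size `factor * dim(lr)`.
#' @export
super_resolve_image <- function(lr, model, factor = model$factor) {
  .check_image(lr, "lr")
  if (!is.null(model$factor) && factor != model$factor)
    .stopf("factor %s does not match the model's factor %s",
           factor, model$factor)
  if (inherits(model, "bicubic_model"))
    return(bicubic_resize(lr, factor * nrow(lr), factor * ncol(lr)))
  out_shape <- c(factor * nrow(lr), factor * ncol(lr))
  g <- .extract_grid(lr, 3L, 2L)
  mu <- colMeans(g$X)
  Y <- predict_patches(model, sweep(g$X, 2L, mu))
  if ((model$hr_target %||% "residual") == "residual") {
    mid <- bicubic_resize(lr, out_shape[1], out_shape[2])
    .clip01(mid + .overlap_average(Y, g$positions, out_shape, factor))
  } else {
    assemble_image(Y, g$positions, mu, out_shape, factor)
  }
}

#' Evaluate trained models on a test set
#'
#' Super-resolves the LR member of every test pair with every model and
#' scores PSNR and SSIM against the HR member.  A bicubic baseline row is
#' always included.  The report stores the per-image values, their
#' arithmetic means, the config snapshots and a content hash of the test
#' manifest, so reports are reproducible and hash-comparable.
#'
#' @param test_pairs Named list of `image_pair` objects.
#' @param models Named list of trained models (names become report rows).
#' @return A `metrics_report`: list with `per_image` and `summary` data
#'   frames, `factor`, `manifest_hash`, `configs`.
#' @export
evaluate <- function(test_pairs, models) {
  if (length(test_pairs) == 0L) .stopf("empty test set")
  factor <- test_pairs[[1L]]$factor
  if (!"bicubic" %in% names(models))
    models <- c(list(bicubic = train_model(method_config("bicubic", factor))),
                models)
  img_names <- names(test_pairs) %||% sprintf("img_%03d", seq_along(test_pairs))
  per <- NULL
  for (mn in names(models)) {
    model <- models[[mn]]
    for (i in seq_along(test_pairs)) {
      pr <- test_pairs[[i]]
      sr <- super_resolve_image(pr$lr, model, factor)
      per <- rbind(per, data.frame(
        method = mn, image = img_names[i],
        psnr_db = psnr(pr$hr, sr), ssim = ssim(pr$hr, sr),
        stringsAsFactors = FALSE))
    }
  }
  summary <- do.call(rbind, lapply(split(per, per$method), function(d)
    data.frame(method = d$method[1L], mean_psnr_db = mean(d$psnr_db),
               mean_ssim = mean(d$ssim), n_images = nrow(d),
               stringsAsFactors = FALSE)))
  summary <- summary[order(match(summary$method, names(models))), ]
  rownames(summary) <- NULL
  structure(list(per_image = per, summary = summary,
                 factor = as.integer(factor),
                 manifest_hash = .hash_obj(lapply(test_pairs, `[[`, "lr")),
                 configs = lapply(models, function(m) m$config)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> factor %dx, %d test images\n",
              x$factor, x$summary$n_images[1L]))
  print(format(x$summary, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Write a metrics report
#'
#' @param report A `metrics_report`.
#' @param path Output path; `.csv` writes the per-image table, `.json` the
#'   full report.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    utils::write.csv(report$per_image, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(summary = report$summary, per_image = report$per_image,
           factor = report$factor, manifest_hash = report$manifest_hash),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  invisible(path)
}

#' Desk-scale benchmark over all SR methods
#'
#' Trains every (requested) method on a grouped phantom dataset and
#' evaluates all of them, plus the bicubic baseline, on its test pairs.
#' The default configuration is the package's reduced desk-scale benchmark:
#' 512 dictionary atoms, 5 dictionary-learning iterations over a 5000-patch
#' subsample, an A+ pool of 20000 patches, and an SRF of 3 trees at depth
#' 10; all other parameters keep the reference defaults.  The Zeyde
#' dictionary is trained once and shared by `sb_zeyde`, `anr` and `aplus`.
#'
#' @param dataset A `grouped_dataset`, or `NULL` to generate the default one
#'   (10 groups x 4 images at 128 px, factor 2) from `seed`.
#' @param methods Character vector of methods to run (default: all).
#' @param seed Integer seed for dataset generation and training.
#' @param sizes Named list of reduced sizes: `B`, `dict_iters`, `yang_cap`,
#'   `aplus_pool`, `srf_trees`, `srf_depth`.
#' @return List with `report` (a `metrics_report`), `models`, `dataset`.
#' @export
benchmark <- function(dataset = NULL,
                      methods = setdiff(.sr_methods, "bicubic"),
                      seed = 1L,
                      sizes = list(B = 512L, dict_iters = 5L,
                                   yang_cap = 5000L, aplus_pool = 20000L,
                                   srf_trees = 3L, srf_depth = 10L)) {
  if (is.null(dataset))
    dataset <- generate_grouped_dataset(n_groups = 10L, per_group = 4L,
                                        factor = 2L, image_size = 128L,
                                        seed = seed)
  factor <- dataset$factor
  shared_dict <- NULL
  need_dict <- any(c("sb_zeyde", "anr", "aplus") %in% methods)
  if (need_dict) {
    psd <- .training_patches(dataset$train_pairs, factor, seed = seed)
    shared_dict <- train_zeyde_dictionary(psd, B = sizes$B, L = 24L,
                                          n_iters = sizes$dict_iters,
                                          seed = seed)
  }
  cfg_of <- function(m) switch(m,
    sb_yang = method_config(m, factor, seed, B = sizes$B,
                            n_iters = sizes$dict_iters,
                            train_cap = sizes$yang_cap),
    sb_zeyde = method_config(m, factor, seed, B = sizes$B,
                             n_iters = sizes$dict_iters),
    anr = method_config(m, factor, seed, dict = shared_dict),
    aplus = method_config(m, factor, seed, dict = shared_dict,
                          pool_cap = sizes$aplus_pool),
    srf = method_config(m, factor, seed, n_trees = sizes$srf_trees,
                        max_depth = sizes$srf_depth),
    method_config(m, factor, seed)
  )
  models <- lapply(setNames(methods, methods), function(m) {
    message(sprintf("[benchmark] training %s ...", m))
    if (m == "sb_zeyde" && !is.null(shared_dict)) {
      model <- shared_dict          # same params and seed: reuse the fit
      model$factor <- factor
      model$config <- cfg_of(m)
      model
    } else {
      train_model(cfg_of(m), dataset$train_pairs)
    }
  })
  message("[benchmark] evaluating ...")
  report <- evaluate(dataset$test_pairs, models)
  list(report = report, models = models, dataset = dataset)
}
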