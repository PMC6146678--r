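# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img))
    .stopf("`%s` must be a numeric matrix", arg)
  if (nrow(img) < 1L || ncol(img) < 1L)
    .stopf("`%s` has zero extent", arg)
  if (anyNA(img) || any(!is.finite(img)))
    .stopf("`%s` contains non-finite values", arg)
  if (min(img) < -1e-8 || max(img) > 1 + 1e-8)
    .stopf("`%s` has intensities outside [0, 1]", arg)
  invisible(img)
}

.clip01 <- function(x) pmin(pmax(x, 0), 1)

# Deterministic sub-seed derivation that stays inside 32-bit integer range.
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k) * 104729) %% 2147483647)
}

# Sample at most `cap` column indices, deterministically for a given seed.
.cap_columns <- function(n, cap, seed) {
  if (!is.finite(cap) || n <= cap) return(seq_len(n))
  withr::with_seed(.derive_seed(seed, 811L),
                   sort(sample.int(n, as.integer(cap))))
}

# Content hash of an arbitrary R object (used for report provenance).
.hash_obj <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2L, xdr = TRUE)
  close(con)
  unname(tools::md5sum(f))
}
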