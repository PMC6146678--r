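# Shared fixtures, all generated in code under fixed seeds.

# Small phantom HR/LR pair and its training patches.
fixture_pair <- function(size = 48L, factor = 2L, seed = 11L) {
  img <- generate_phantom(phantom_params(image_size = max(size, 64L), seed = seed))
  img <- img[seq_len(size), seq_len(size)]
  degrade(img, factor)
}

fixture_patches <- function(size = 48L, factor = 2L, seed = 11L) {
  extract_training_patches(fixture_pair(size, factor, seed))
}

# Random column-aligned LR/HR patch matrices with HR = A %*% LR (+ noise).
fixture_linear_pool <- function(N = 200L, S_l = 9L, S_h = 36L, noise = 0,
                                seed = 5L) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(S_h * S_l, sd = 0.4), S_h, S_l)
    X_l <- matrix(rnorm(S_l * N, sd = 0.3), S_l, N)
    X_h <- A %*% X_l + matrix(rnorm(S_h * N, sd = noise), S_h, N)
    list(X_l = X_l, X_h = X_h, A = A)
  })
}

# Two well-separated LR clusters, each with its own exact linear HR map.
fixture_two_maps <- function(N = 400L, S_l = 9L, S_h = 36L, seed = 9L) {
  withr::with_seed(seed, {
    A1 <- matrix(rnorm(S_h * S_l, sd = 0.4), S_h, S_l)
    A2 <- matrix(rnorm(S_h * S_l, sd = 0.4), S_h, S_l)
    n1 <- N %/% 2L
    X1 <- matrix(rnorm(S_l * n1, mean = 3, sd = 0.3), S_l, n1)
    X2 <- matrix(rnorm(S_l * (N - n1), mean = -3, sd = 0.3), S_l, N - n1)
    list(X_l = cbind(X1, X2), X_h = cbind(A1 %*% X1, A2 %*% X2),
         labels = rep(1:2, c(n1, N - n1)), A1 = A1, A2 = A2)
  })
}

# B0 distinct planted unit atoms, each repeated with small scaling + noise.
fixture_planted_atoms <- function(B0 = 8L, reps = 20L, S = 9L,
                                  noise = 0.005, seed = 21L) {
  withr::with_seed(seed, {
    atoms <- qr.Q(qr(matrix(rnorm(S * B0), S, B0)))  # orthonormal, distinct
    scale <- runif(B0 * reps, 0.5, 1.5)
    X <- atoms[, rep(seq_len(B0), each = reps)] * rep(scale, each = S) +
      matrix(rnorm(S * B0 * reps, sd = noise), S)
    list(X_l = X, atoms = atoms)
  })
}

# Random unit-column dictionary.
fixture_dictionary <- function(S = 5L, B = 8L, seed = 31L) {
  withr::with_seed(seed, {
    D <- matrix(rnorm(S * B), S, B)
    sweep(D, 2L, sqrt(colSums(D^2)), `/`)
  })
}
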