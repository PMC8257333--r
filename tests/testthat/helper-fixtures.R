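# Fixture builders shared across test files. All fixtures are generated
# in code; nothing is read from disk except files the tests themselves
# write to tempdir().

# Two constant plateaus (0 | 255) split by a vertical border.
two_plateau_image <- function(H = 20, W = 20, left = 0, right = 255) {
  img <- matrix(left, H, W)
  img[, (W %/% 2 + 1):W] <- right
  img
}

# Disc of `inner` intensity on `outer` background plus Gaussian noise.
disc_phantom <- function(H = 50, W = 50, center = c(25, 25), radius = 12,
                         inner = 40, outer = 200, noise_sd = 2, seed = 1) {
  r <- matrix(seq_len(H), H, W)
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  disc <- (r - center[1])^2 + (cc - center[2])^2 <= radius^2
  img <- matrix(outer, H, W)
  img[disc] <- inner
  set.seed(seed)
  img <- pmin(pmax(img + rnorm(H * W, 0, noise_sd), 0), 255)
  list(image = img, mask = disc)
}

# Three constant plateaus stacked vertically (dark / mid / bright).
three_plateau_image <- function(H = 30, W = 30, levels = c(40, 140, 240)) {
  img <- matrix(levels[1], H, W)
  img[(H %/% 3 + 1):(2 * H %/% 3), ] <- levels[2]
  img[(2 * H %/% 3 + 1):H, ] <- levels[3]
  img
}

random_mask <- function(H, W, p = 0.4, seed = 1) {
  set.seed(seed)
  matrix(runif(H * W) < p, H, W)
}

# Small low-noise phantom the GA can solve in a few seconds.
small_phantom <- function(seed = 1, noise_sd = 3) {
  make_phantom(phantom_spec(height = 96, width = 96, noise_sd = noise_sd,
                            n_vessels = 2, rng_seed = seed))
}

fast_ga <- function(seed = 1, generations = 25) {
  ga_config(n_generations = generations, stall_generations = generations,
            rng_seed = seed)
}
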