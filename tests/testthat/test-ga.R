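test_that("build_reference isolates plateaus and validates K", {
  img <- three_plateau_image()
  fit <- run_fcm(img, fcm_params(K = 3))
  ref <- build_reference(img, fit)
  expect_identical(ref$BM == 1, img == 40)
  expect_identical(ref$GM == 1, img == 140)
  expect_identical(ref$WM == 1, img == 240)
  expect_true(ref$breaks[1] > 40 && ref$breaks[1] < 140)
  expect_true(ref$breaks[2] > 140 && ref$breaks[2] < 240)

  fit2 <- run_fcm(img, fcm_params(K = 2))
  expect_error(build_reference(img, fit2), class = "angioseg_validation")

  # degenerate constant image: one tier holds everything
  cimg <- matrix(100, 10, 10)
  cfit <- run_fcm(cimg, fcm_params(K = 6))
  cref <- build_reference(cimg, cfit)
  masses <- c(sum(cref$BM), sum(cref$GM), sum(cref$WM))
  expect_identical(sum(masses == 100), 1L)
  expect_identical(sum(masses == 0), 2L)
})

test_that("tier supports match an independent sort-and-scan oracle", {
  ph <- small_phantom(seed = 2)
  fit <- run_fcm(ph$image, fcm_params(K = 6))
  ref <- build_reference(ph$image, fit)
  centers <- fit$centers
  # oracle: nearest-center labels, centers grouped at the two largest gaps
  gaps <- diff(centers)
  splits <- sort(order(gaps, decreasing = TRUE)[1:2])
  tier_of <- cut(seq_along(centers), c(0, splits, length(centers)),
                 labels = FALSE)
  nearest <- apply(abs(outer(centers, as.numeric(ph$image), "-")), 2,
                   which.min)
  want_bm <- matrix(tier_of[nearest] == 1, nrow(ph$image))
  expect_identical(ref$BM == 1, want_bm)
})

test_that("chromosome cost is zero for a perfect reproduction", {
  img <- three_plateau_image()
  fit <- run_fcm(img, fcm_params(K = 3))
  ref <- build_reference(img, fit)
  cfg <- growth_config(max_region_fraction = 1)
  chrom <- seed_chromosome(rbind(c(2, 2), c(15, 15), c(28, 28)))
  expect_equal(chromosome_cost(chrom, img, ref, cfg), 0)

  # near-null segmentation pays roughly the non-mid reference support
  lone <- seed_chromosome(rbind(c(2, 2)))
  cost <- chromosome_cost(lone, img, ref, cfg)
  expect_gt(cost, 0)
})

test_that("chromosome cost equals an explicit pixel-loop evaluation", {
  ph <- small_phantom(seed = 3)
  fit <- run_fcm(ph$image, fcm_params(K = 6))
  ref <- build_reference(ph$image, fit)
  cfg <- growth_config()
  chrom <- seed_chromosome(rbind(c(48, 48), c(10, 10), c(90, 90)))
  got <- chromosome_cost(chrom, ph$image, ref, cfg)

  grown <- grow_all(ph$image, chrom$seeds, cfg, quiet = TRUE)
  mu <- vapply(grown$stats, function(s) s$mu, numeric(1))
  tier <- ifelse(mu < ref$breaks[1], 1L, ifelse(mu < ref$breaks[2], 2L, 3L))
  total <- 0
  for (r in seq_len(nrow(ph$image))) for (c in seq_len(ncol(ph$image))) {
    lab <- grown$labels[r, c]
    pt <- if (lab > 0) tier[lab] else 0L
    i1 <- as.numeric(pt == 2L); i2 <- as.numeric(pt == 3L)
    i3 <- as.numeric(pt == 1L)
    total <- total + (ref$GM[r, c] - i1)^2 + (ref$WM[r, c] - i2)^2 +
      (ref$BM[r, c] - i3)^2
  }
  expect_equal(got, total / length(ph$image), tolerance = 1e-12)
})

test_that("mutation respects rates, bounds, and seed counts", {
  img <- matrix(0, 100, 100)
  base <- seed_chromosome(cbind(rep(50, 6), rep(50, 6)))

  cfg0 <- ga_config(mutation_rate = 0)
  set.seed(1)
  expect_identical(mutate(base, cfg0, img)$seeds, base$seeds)

  cfg1 <- ga_config(mutation_rate = 1, n_min = 6, n_max = 6)
  set.seed(2)
  mut <- mutate(base, cfg1, img)
  expect_identical(nrow(mut$seeds), 6L)
  expect_true(all(mut$seeds >= 1 & mut$seeds <= 100))
  expect_true(all(abs(mut$seeds - 50) <= 5))

  # per-seed jitter frequency ~ mutation_rate over many trials
  cfg <- ga_config(mutation_rate = 0.2, n_min = 1, n_max = 1)
  one <- seed_chromosome(c(50, 50))
  set.seed(3)
  jittered <- 0L
  n_trials <- 10000L
  for (i in seq_len(n_trials)) {
    m <- mutate(one, cfg, img)
    if (!identical(m$seeds, one$seeds)) jittered <- jittered + 1L
  }
  rate <- jittered / n_trials
  # jitter fires at 0.2 but an offset can be (0,0) with prob 1/121
  expect_lt(abs(rate - 0.2 * (1 - 1 / 121)), 0.01)
})

test_that("crossover recombines heads and tails at a shared cut", {
  cfg <- ga_config()
  a <- seed_chromosome(cbind(1:4, 1:4))
  b <- seed_chromosome(cbind(11:16, 11:16))

  set.seed(4)
  kids <- crossover(a, a, cfg)
  expect_identical(kids[[1]]$seeds, a$seeds)
  expect_identical(kids[[2]]$seeds, a$seeds)

  # oracle splice with the same RNG draw
  set.seed(5)
  cut <- sample(0:4, 1)
  set.seed(5)
  kids <- crossover(a, b, cfg)
  want1 <- rbind(a$seeds[seq_len(4) <= cut, , drop = FALSE],
                 b$seeds[seq_len(6) > cut, , drop = FALSE])
  want2 <- rbind(b$seeds[seq_len(6) <= cut, , drop = FALSE],
                 a$seeds[seq_len(4) > cut, , drop = FALSE])
  expect_identical(kids[[1]]$seeds, want1)
  expect_identical(kids[[2]]$seeds, want2)
  # offspring lengths swap the parents'
  expect_identical(nrow(kids[[1]]$seeds), 6L)
  expect_identical(nrow(kids[[2]]$seeds), 4L)
})

test_that("run_ga history is monotone and reproducible", {
  ph <- small_phantom(seed = 5)
  fit <- run_fcm(ph$image, fcm_params(K = 6))
  ref <- build_reference(ph$image, fit)
  cfg <- fast_ga(seed = 11, generations = 12)
  out1 <- run_ga(ph$image, ref, cfg, growth_config())
  expect_true(all(diff(out1$history$best_cost) <= 0))
  expect_true(all(out1$best$seeds[, 1] >= 1 &
                    out1$best$seeds[, 1] <= nrow(ph$image)))
  expect_true(nrow(out1$best$seeds) >= cfg$n_min &&
                nrow(out1$best$seeds) <= cfg$n_max)

  out2 <- run_ga(ph$image, ref, cfg, growth_config())
  expect_identical(out1$best$seeds, out2$best$seeds)
  expect_identical(out1$history, out2$history)
})

test_that("constant-cost landscape yields a flat history", {
  img <- matrix(77, 12, 12)
  fit <- run_fcm(img, fcm_params(K = 3))
  ref <- build_reference(img, fit)
  cfg <- ga_config(n_generations = 5, rng_seed = 3)
  out <- run_ga(img, ref, cfg, growth_config(max_region_fraction = 1))
  expect_identical(length(unique(out$history$best_cost)), 1L)
})

test_that("single-seed optimum matches exhaustive enumeration on 6x6", {
  set.seed(21)
  img <- pmin(pmax(matrix(c(rep(40, 12), rep(200, 24)), 6, 6) +
                     rnorm(36, 0, 3), 0), 255)
  fit <- run_fcm(img, fcm_params(K = 3))
  ref <- build_reference(img, fit)
  gcfg <- growth_config(max_region_fraction = 1)
  costs <- matrix(NA_real_, 6, 6)
  for (r in 1:6) for (c in 1:6) {
    costs[r, c] <- chromosome_cost(seed_chromosome(c(r, c)), img, ref, gcfg)
  }
  cfg <- ga_config(population_size = 10, n_generations = 30,
                   n_min = 1, n_max = 1, rng_seed = 5,
                   stall_generations = 30)
  out <- run_ga(img, ref, cfg, gcfg)
  expect_equal(out$best$fitness, min(costs), tolerance = 1e-12)
})

test_that("GA beats a random-search baseline on a lesion phantom", {
  ph <- small_phantom(seed = 7)
  fit <- run_fcm(ph$image, fcm_params(K = 6))
  ref <- build_reference(ph$image, fit)
  gcfg <- growth_config()
  out <- run_ga(ph$image, ref, fast_ga(seed = 13, generations = 20), gcfg)
  random_best <- vapply(1:5, function(s) {
    set.seed(1000 + s)
    min(vapply(1:5, function(i) {
      n <- sample(1:10, 1)
      ch <- seed_chromosome(cbind(sample.int(nrow(ph$image), n, TRUE),
                                  sample.int(ncol(ph$image), n, TRUE)))
      chromosome_cost(ch, ph$image, ref, gcfg)
    }, numeric(1)))
  }, numeric(1))
  expect_lte(out$best$fitness, median(random_best))
})
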