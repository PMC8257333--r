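test_that("membership update reproduces hand-evaluated cases", {
  p <- fcm_params(K = 2, fuzzifier = 2)

  # pixel 0 against centers {10, 30}: (1 + (10/30)^2)^-1 = 0.9
  mem <- update_memberships(matrix(c(0, 0, 0, 0), 2, 2), c(10, 30), p)
  expect_equal(mem[1, 1], 0.9, tolerance = 1e-12)
  expect_equal(mem[2, 1], 0.1, tolerance = 1e-12)

  # singularity: pixel coinciding with a center gets crisp membership
  mem <- update_memberships(matrix(10, 2, 2), c(10, 200), p)
  expect_equal(mem[, 1], c(1, 0))

  # equidistant pixel splits evenly
  mem <- update_memberships(matrix(20, 2, 2), c(10, 30), p)
  expect_equal(mem[, 1], c(0.5, 0.5))
})

test_that("membership columns always sum to one", {
  set.seed(1)
  img <- matrix(runif(200, 0, 255), 10, 20)
  for (K in c(2, 4, 6)) {
    p <- fcm_params(K = K)
    mem <- update_memberships(img, init_centers(img, p), p)
    expect_true(all(abs(colSums(mem) - 1) < 1e-9))
    expect_true(all(mem >= 0 & mem <= 1))
  }
})

test_that("center update matches direct weighted means", {
  p <- fcm_params(K = 2, fuzzifier = 2)
  img <- matrix(c(0, 0, 100, 100), 2, 2)

  # crisp memberships -> plain class means
  mem <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(update_centers(img, mem, p), c(0, 100))

  # uniform memberships over {0, 100} -> every center = 50
  memu <- matrix(0.5, 2, 4)
  expect_equal(update_centers(img, memu, p), c(50, 50))

  # random memberships vs brute-force summation
  set.seed(3)
  px <- c(0, 100, 200)
  raw <- matrix(runif(6), 2, 3)
  mem <- sweep(raw, 2, colSums(raw), "/")
  got <- update_centers(matrix(px, 1, 3), mem, p)
  m <- p$fuzzifier
  for (k in 1:2) {
    num <- 0; den <- 0
    for (i in 1:3) {
      num <- num + mem[k, i]^m * px[i]
      den <- den + mem[k, i]^m
    }
    expect_equal(got[k], num / den, tolerance = 1e-12)
  }
})

test_that("objective equals triple-loop summation and is zero when exact", {
  p <- fcm_params(K = 2, fuzzifier = 2)
  px <- c(3, 50, 97, 140, 220)
  img <- matrix(px, 1, 5)
  set.seed(5)
  raw <- matrix(runif(10), 2, 5)
  mem <- sweep(raw, 2, colSums(raw), "/")
  centers <- c(40, 180)
  got <- fcm_objective(img, centers, mem, p)
  want <- 0
  for (k in 1:2) for (i in 1:5) {
    want <- want + mem[k, i]^p$fuzzifier * (centers[k] - px[i])^2
  }
  expect_equal(got, want, tolerance = 1e-12)

  cimg <- matrix(77, 3, 3)
  p1 <- fcm_params(K = 1)
  memc <- matrix(1, 1, 9)
  expect_equal(fcm_objective(cimg, 77, memc, p1), 0)

  # crisp memberships with class-mean centers reduce to k-means WSS
  img2 <- matrix(c(0, 2, 100, 104), 2, 2)
  mem2 <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(fcm_objective(img2, c(1, 102), mem2, p),
               sum((c(0, 2) - 1)^2) + sum((c(100, 104) - 102)^2))
})

test_that("init_centers is deterministic, spread, and distinct", {
  p1 <- fcm_params(K = 1)
  expect_equal(init_centers(matrix(42, 4, 4), p1), 42)

  img <- matrix(c(0, 255), 4, 4)
  p2 <- fcm_params(K = 2, rng_seed = 42)
  cen <- init_centers(img, p2)
  expect_identical(length(unique(cen)), 2L)

  # K above the number of distinct intensities still yields K distinct
  p6 <- fcm_params(K = 6, rng_seed = 42)
  cen6 <- init_centers(img, p6)
  expect_identical(length(unique(cen6)), 6L)
  expect_identical(cen6, init_centers(img, p6)) # rerun oracle

  expect_error(fcm_params(K = 0), class = "angioseg_validation")
})

test_that("run_fcm recovers two well-separated Gaussian components", {
  for (seed in 1:3) {
    set.seed(seed)
    px <- pmin(pmax(c(rnorm(800, 50, 5), rnorm(800, 200, 5)), 0), 255)
    img <- matrix(px, 40, 40)
    fit <- run_fcm(img, fcm_params(K = 2, rng_seed = seed))
    expect_lt(abs(fit$centers[1] - 50), 2)
    expect_lt(abs(fit$centers[2] - 200), 2)
    # monotone objective trace
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    # column stochasticity of the returned memberships
    expect_true(all(abs(colSums(fit$memberships) - 1) < 1e-9))
  }
})

test_that("run_fcm on a constant image converges immediately", {
  fit <- run_fcm(matrix(128, 6, 6), fcm_params(K = 1))
  expect_lte(fit$iterations, 2L)
  expect_equal(fit$centers, 128)
  img <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(run_fcm(img, fcm_params()), class = "angioseg_validation")
})

test_that("permuting pixels permutes memberships and fixes centers", {
  set.seed(8)
  px <- runif(60, 0, 255)
  p <- fcm_params(K = 3)
  centers <- c(30, 120, 230)
  mem <- update_memberships(matrix(px, 1), centers, p)
  perm <- sample(60)
  mem_p <- update_memberships(matrix(px[perm], 1), centers, p)
  expect_equal(mem_p, mem[, perm], tolerance = 1e-12)
  expect_equal(update_centers(matrix(px[perm], 1), mem_p, p),
               update_centers(matrix(px, 1), mem, p), tolerance = 1e-9)
})

test_that("near-crisp FCM agrees with Lloyd k-means labels", {
  set.seed(13)
  px <- pmin(pmax(c(rnorm(300, 40, 4), rnorm(300, 150, 4),
                    rnorm(300, 240, 4)), 0), 255)
  img <- matrix(px, 30, 30)
  p <- fcm_params(K = 3, fuzzifier = 1.05, rng_seed = 2)
  cen0 <- init_centers(img, p)
  fit <- run_fcm(img, p)
  km <- lloyd_kmeans(as.numeric(img), cen0)
  # same cluster geometry -> identical hard labels (both center-sorted)
  km_order <- order(km$centers)
  km_labels <- match(km$labels, km_order)
  expect_identical(defuzzify(fit), km_labels)
})

test_that("defuzzify takes the argmax with low-index ties", {
  mem <- rbind(c(1, 0, 0.5, 0.2), c(0, 1, 0.5, 0.3), c(0, 0, 0, 0.5))
  expect_identical(defuzzify(mem), c(1L, 2L, 1L, 3L))

  set.seed(17)
  raw <- matrix(runif(5 * 40), 5, 40)
  mem <- sweep(raw, 2, colSums(raw), "/")
  got <- defuzzify(mem)
  want <- integer(40)
  for (i in 1:40) want[i] <- which.max(mem[, i])
  expect_identical(got, want)

  lab <- defuzzify(mem, dim = c(8, 5))
  expect_identical(dim(lab), c(8L, 5L))
})
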