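# Seeded region growing with online statistics.
#
# Growth is breadth-first over the 8-connected lattice: the frontier is a
# FIFO queue, neighbors are examined in the fixed order N, NE, E, SE, S,
# SW, W, NW, and each accepted pixel updates the running mean/variance
# immediately, so later candidates are judged against the statistics of
# everything accepted so far. The traversal is single-pass: a pixel
# rejected by a region is not re-examined by that region even after its
# statistics drift (it may still be claimed by a later region).

#' Running region statistics
#'
#' Count, mean, and standard deviation of a growing region, maintained with
#' the numerically stable online (Welford) recurrence. `sigma` is the
#' sample standard deviation (n - 1 denominator), 0 for n <= 1.
#'
#' @param intensities Optional numeric vector to initialize from.
#' @return Object of class `region_stats` with fields `n`, `mu`, `m2`.
#' @export
region_stats <- function(intensities = numeric(0)) {
  s <- structure(list(n = 0L, mu = NA_real_, m2 = 0), class = "region_stats")
  for (x in intensities) s <- update_region_stats(s, x)
  s
}

#' @rdname region_stats
#' @param stats A `region_stats` object.
#' @return `region_sd()`: the running sample standard deviation.
#' @export
region_sd <- function(stats) {
  if (stats$n <= 1L) return(0)
  sqrt(stats$m2 / (stats$n - 1L))
}

#' @export
print.region_stats <- function(x, ...) {
  if (x$n == 0L) {
    cat("region_stats: empty\n")
  } else {
    cat(sprintf("region_stats: n = %d, mu = %.6g, sigma = %.6g\n",
                x$n, x$mu, region_sd(x)))
  }
  invisible(x)
}

#' Extend region statistics by one intensity
#'
#' One step of the online mean/variance recurrence
#' `mu_N = ((N-1) mu_{N-1} + I_N) / N` and the matching standard-deviation
#' update, implemented in the Welford form that avoids catastrophic
#' cancellation: `M2_N = M2_{N-1} + (I_N - mu_{N-1})(I_N - mu_N)` with
#' `sigma_N^2 = M2_N / (N - 1)`.
#'
#' @param stats A `region_stats` object.
#' @param intensity Finite numeric scalar.
#' @return Updated `region_stats`.
#' @export
update_region_stats <- function(stats, intensity) {
  check_scalar_number(intensity, "intensity")
  n <- stats$n + 1L
  if (n == 1L) {
    stats$n <- 1L
    stats$mu <- intensity
    stats$m2 <- 0
    return(stats)
  }
  delta <- intensity - stats$mu
  mu <- stats$mu + delta / n
  stats$m2 <- stats$m2 + delta * (intensity - mu)
  stats$mu <- mu
  stats$n <- n
  stats
}

#' Similarity criteria
#'
#' `sd_criterion()` accepts a candidate intensity iff it falls strictly
#' inside `mu +/- x * sigma_eff`, where `sigma_eff` substitutes
#' `sigma_floor` for the running sigma while the region is still small
#' (`n < floor_until`) and sigma is below the floor. When `sigma_eff` is 0
#' the strict window is empty; the limiting rule "accept iff intensity ==
#' mu" is used instead so constant regions can grow. `mean_criterion()`
#' accepts iff `|intensity - mu| < x` (strict), with `x` in gray levels.
#' Both are vectorized over `intensity`.
#'
#' @param stats Nonempty `region_stats`.
#' @param intensity Numeric vector of candidate intensities.
#' @param x Window half-width: multiples of sigma for `sd_criterion()`,
#'   gray levels for `mean_criterion()`.
#' @param sigma_floor,floor_until Cold-start floor, see [growth_config()].
#' @return Logical vector: accept/reject per candidate.
#' @export
sd_criterion <- function(stats, intensity, x = 3, sigma_floor = 0,
                         floor_until = 8L) {
  if (stats$n == 0L) stop_validation("sd_criterion requires nonempty stats")
  check_scalar_number(x, "x", lower = 0, strict_lower = TRUE)
  sigma <- region_sd(stats)
  sigma_eff <- if (stats$n < floor_until && sigma < sigma_floor) {
    sigma_floor
  } else {
    sigma
  }
  if (sigma_eff == 0) return(intensity == stats$mu)
  (stats$mu - x * sigma_eff < intensity) & (intensity < stats$mu + x * sigma_eff)
}

#' @rdname sd_criterion
#' @export
mean_criterion <- function(stats, intensity, x = 3) {
  if (stats$n == 0L) stop_validation("mean_criterion requires nonempty stats")
  check_scalar_number(x, "x", lower = 0, strict_lower = TRUE)
  (stats$mu - x < intensity) & (intensity < stats$mu + x)
}

#' Region-growing configuration
#'
#' @param x_sd Half-width of the standard-deviation window, in multiples of
#'   the running sigma. Default 3, which accepts about 99.7\% of
#'   Gaussian-distributed in-region intensities once sigma has converged.
#' @param x_mean Half-width of the absolute mean window, in gray levels on
#'   the 0-255 scale. The window must contain the within-region intensity
#'   variation (illumination shading of roughly +/-20 gray levels plus
#'   ~3 noise sigma) while staying below the smallest between-class
#'   contrast (about 50 gray levels between perfused tissue and vessels);
#'   default 30 sits between the two.
#' @param criterion_mode `"sd"`, `"mean"`, or `"both"` (conjunction;
#'   default).
#' @param max_region_fraction Runaway guard: a region stops growing once it
#'   reaches this fraction of the image area. Default 0.9.
#' @param sigma_floor Effective minimum sigma for the sd window while the
#'   region is smaller than `floor_until` pixels; lets regions bootstrap
#'   from a single seed (where sigma = 0) without leaking indefinitely.
#'   Must sit at the imaging-noise scale: early acceptances happen inside
#'   this window, so a floor far below the noise sd truncates the sample,
#'   biases the running sigma low, and collapses growth. Default 5 gray
#'   levels, a typical 8-bit angiography noise level.
#' @param floor_until Region size at which the floor stops applying.
#' @return Object of class `growth_config`. Connectivity is fixed at 8.
#' @export
growth_config <- function(x_sd = 3, x_mean = 30, criterion_mode = "both",
                          max_region_fraction = 0.9, sigma_floor = 5,
                          floor_until = 8L) {
  check_scalar_number(x_sd, "x_sd", lower = 0, strict_lower = TRUE)
  check_scalar_number(x_mean, "x_mean", lower = 0, strict_lower = TRUE)
  criterion_mode <- match.arg(criterion_mode, c("sd", "mean", "both"))
  check_scalar_number(max_region_fraction, "max_region_fraction",
                      lower = 0, upper = 1, strict_lower = TRUE)
  check_scalar_number(sigma_floor, "sigma_floor", lower = 0)
  check_scalar_number(floor_until, "floor_until", lower = 0)
  structure(list(x_sd = x_sd, x_mean = x_mean,
                 criterion_mode = criterion_mode,
                 connectivity = 8L,
                 max_region_fraction = max_region_fraction,
                 sigma_floor = sigma_floor,
                 floor_until = as.integer(floor_until)),
            class = "growth_config")
}

mode_code <- function(criterion_mode) {
  match(criterion_mode, c("sd", "mean", "both")) - 1L
}

#' Grow a single region from a seed
#'
#' @param image Numeric intensity matrix.
#' @param seed Length-2 `(row, col)` vector, 1-based.
#' @param config [growth_config()].
#' @return List with `mask` (logical matrix) and `stats` (`region_stats`
#'   over the accepted pixels, seed included).
#' @export
grow_region <- function(image, seed, config = growth_config()) {
  check_gray_image(image)
  seeds <- as_seed_matrix(seed)
  if (nrow(seeds) != 1L) stop_validation("grow_region takes exactly one seed")
  check_seeds_in_bounds(seeds, image)
  res <- grow_all_cpp(image, seeds, config$x_sd, config$x_mean,
                      mode_code(config$criterion_mode),
                      config$max_region_fraction, config$sigma_floor,
                      config$floor_until)
  stats <- structure(list(n = as.integer(res$n[1L]), mu = res$mu[1L],
                          m2 = res$m2[1L]), class = "region_stats")
  list(mask = res$labels == 1L, stats = stats)
}

#' Grow regions from several seeds
#'
#' Regions are grown sequentially in seed order; pixels claimed by an
#' earlier region are never reassigned. A seed that falls inside an
#' existing region is skipped with a notice.
#'
#' @param image Numeric intensity matrix.
#' @param seeds n x 2 matrix of 1-based `(row, col)` seeds.
#' @param config [growth_config()].
#' @param quiet Suppress the skipped-seed notice.
#' @return List with `labels` (integer matrix, 0 = background, seed index
#'   otherwise), `stats` (list of `region_stats`, one per seed; skipped
#'   seeds get an empty stats object), and `skipped` (logical vector).
#' @export
grow_all <- function(image, seeds, config = growth_config(), quiet = FALSE) {
  check_gray_image(image)
  seeds <- as_seed_matrix(seeds)
  check_seeds_in_bounds(seeds, image)
  res <- grow_all_cpp(image, seeds, config$x_sd, config$x_mean,
                      mode_code(config$criterion_mode),
                      config$max_region_fraction, config$sigma_floor,
                      config$floor_until)
  if (any(res$skipped) && !quiet) {
    message("grow_all: skipped seed(s) ",
            paste(which(res$skipped), collapse = ", "),
            " already inside an existing region")
  }
  stats <- lapply(seq_len(nrow(seeds)), function(s) {
    n <- as.integer(res$n[s])
    structure(list(n = n, mu = if (n > 0L) res$mu[s] else NA_real_,
                   m2 = res$m2[s]),
              class = "region_stats")
  })
  list(labels = res$labels, stats = stats, skipped = res$skipped)
}
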