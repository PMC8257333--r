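# Synthetic angiography phantoms with exact ground truth.
#
# A phantom emulates the gross intensity structure of a fluorescein
# angiogram around the macula: a bright, smoothly shaded background
# (perfused tissue), bright curvilinear vessel tracks, and a dark,
# roughly elliptical avascular target region. Rendering order is
# background -> target ellipse -> vessels -> noise, so vessels may cross
# the target and exercise the region grower's leak resistance. The ground
# truth is the analytic ellipse rasterization, with no annotation noise.

#' Phantom specification
#'
#' Defaults describe a 250 x 250, 8-bit angiography-like scene: background
#' 180 gray levels with a +/-20 horizontal shading ramp, a dark (60)
#' rotated ellipse as the target, five bright (230) vessel tracks of width
#' 2-4 px, and additive Gaussian noise of sd 5 clipped to \[0, 255\].
#'
#' @param height,width Image size in pixels.
#' @param center Ellipse center `(row, col)`, 1-based.
#' @param semiaxes Ellipse semi-axes `(a, b)` in pixels along the rotated
#'   row/col directions.
#' @param rotation Ellipse rotation in radians.
#' @param target_intensity Gray level of the target region.
#' @param n_vessels Number of vessel tracks (0 disables vessels).
#' @param vessel_width_range Min/max vessel width in pixels.
#' @param vessel_intensity Gray level of vessels.
#' @param background Base background gray level.
#' @param gradient Amplitude of the horizontal background ramp; column 1
#'   is `background - gradient`, the last column `background + gradient`.
#' @param noise_sd Gaussian noise standard deviation (gray levels).
#' @param rng_seed Seed making the rendered scene fully deterministic.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 250L, width = 250L,
                         center = c(height / 2 + 0.5, width / 2 + 0.5),
                         semiaxes = c(0.18 * height, 0.11 * width),
                         rotation = 0.4,
                         target_intensity = 60,
                         n_vessels = 5L,
                         vessel_width_range = c(2, 4),
                         vessel_intensity = 230,
                         background = 180,
                         gradient = 20,
                         noise_sd = 5,
                         rng_seed = 1L) {
  check_scalar_number(height, "height", lower = 2)
  check_scalar_number(width, "width", lower = 2)
  check_scalar_number(rotation, "rotation")
  for (v in list(c(target_intensity, "target_intensity"),
                 c(vessel_intensity, "vessel_intensity"),
                 c(background, "background"))) {
    check_scalar_number(as.numeric(v[1L]), v[2L], lower = 0, upper = 255)
  }
  check_scalar_number(noise_sd, "noise_sd", lower = 0)
  check_scalar_number(n_vessels, "n_vessels", lower = 0)
  if (length(semiaxes) != 2L || any(!is.finite(semiaxes)) || any(semiaxes <= 0)) {
    stop_validation("semiaxes must be two positive numbers")
  }
  if (length(center) != 2L || any(!is.finite(center))) {
    stop_validation("center must be two finite numbers")
  }
  # axis-aligned bounding half-extents of the rotated ellipse
  a <- semiaxes[1L]; b <- semiaxes[2L]
  ext_r <- sqrt((a * cos(rotation))^2 + (b * sin(rotation))^2)
  ext_c <- sqrt((a * sin(rotation))^2 + (b * cos(rotation))^2)
  if (center[1L] - ext_r < 1 || center[1L] + ext_r > height ||
      center[2L] - ext_c < 1 || center[2L] + ext_c > width) {
    stop_validation("target ellipse extends outside the image bounds")
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 center = as.numeric(center), semiaxes = as.numeric(semiaxes),
                 rotation = rotation, target_intensity = target_intensity,
                 n_vessels = as.integer(n_vessels),
                 vessel_width_range = as.numeric(vessel_width_range),
                 vessel_intensity = vessel_intensity,
                 background = background, gradient = gradient,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

ellipse_mask <- function(spec) {
  r <- matrix(seq_len(spec$height), spec$height, spec$width)
  c_ <- matrix(seq_len(spec$width), spec$height, spec$width, byrow = TRUE)
  dr <- r - spec$center[1L]
  dc <- c_ - spec$center[2L]
  u <- dr * cos(spec$rotation) + dc * sin(spec$rotation)
  v <- -dr * sin(spec$rotation) + dc * cos(spec$rotation)
  (u / spec$semiaxes[1L])^2 + (v / spec$semiaxes[2L])^2 <= 1
}

# Random-walk vessel tracks: each starts on a random image border heading
# inward, takes unit steps with small angular jitter, and stamps a disc of
# the vessel's half-width at every step. Draws come from the caller's RNG.
vessel_mask <- function(spec) {
  H <- spec$height; W <- spec$width
  mask <- matrix(FALSE, H, W)
  if (spec$n_vessels == 0L) return(mask)
  n_steps <- H + W
  for (v in seq_len(spec$n_vessels)) {
    side <- sample.int(4L, 1L)
    pos <- switch(side,
      c(1, runif(1, 1, W)),          # top
      c(runif(1, 1, H), W),          # right
      c(H, runif(1, 1, W)),          # bottom
      c(runif(1, 1, H), 1)           # left
    )
    heading <- switch(side, pi / 2, pi, -pi / 2, 0) + runif(1, -0.6, 0.6)
    w <- runif(1, spec$vessel_width_range[1L], spec$vessel_width_range[2L])
    rad <- w / 2
    ir <- ceiling(rad)
    offs <- expand.grid(dr = -ir:ir, dc = -ir:ir)
    offs <- offs[offs$dr^2 + offs$dc^2 <= rad^2, , drop = FALSE]
    turns <- rnorm(n_steps, 0, 0.12)
    for (s in seq_len(n_steps)) {
      heading <- heading + turns[s]
      # step direction: heading 0 = +col, pi/2 = +row
      pos <- pos + c(sin(heading), cos(heading))
      pr <- round(pos[1L]); pc <- round(pos[2L])
      if (pr < 1 - ir || pr > H + ir || pc < 1 - ir || pc > W + ir) break
      rr <- pr + offs$dr; cc <- pc + offs$dc
      keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
      mask[cbind(rr[keep], cc[keep])] <- TRUE
    }
  }
  mask
}

#' Render a phantom
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix on \[0, 255\]), `mask`
#'   (logical ground truth: the target ellipse), and `spec`.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  H <- spec$height; W <- spec$width
  ramp <- if (W > 1) (seq_len(W) - 1) / (W - 1) * 2 - 1 else 0
  img <- matrix(spec$background + spec$gradient * ramp, H, W, byrow = TRUE)
  truth <- ellipse_mask(spec)
  img[truth] <- spec$target_intensity
  with_seed(spec$rng_seed, {
    vm <- vessel_mask(spec)
    img[vm] <- spec$vessel_intensity
    if (spec$noise_sd > 0) {
      img <- img + rnorm(H * W, 0, spec$noise_sd)
    }
  })
  img <- pmin(pmax(img, 0), 255)
  list(image = img, mask = truth, spec = spec)
}

#' Independent Gaussian intensity draws
#'
#' `n` unclipped draws from Normal(mu, sd), deterministic per seed.
#' Support utility for calibration checks such as the 3-sigma acceptance
#' law of the standard-deviation growth criterion.
#'
#' @param n Number of draws.
#' @param mu,sd Mean and standard deviation.
#' @param rng_seed Seed.
#' @return Numeric vector of length `n`.
#' @export
make_gaussian_field <- function(n, mu, sd, rng_seed = 1L) {
  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(sd, "sd", lower = 0)
  with_seed(rng_seed, rnorm(n, mu, sd))
}

#' Render a batch of phantoms to disk
#'
#' Writes `image_<id>.png` / `mask_<id>.png` pairs plus a `manifest.csv`
#' with one row per phantom (id, image path, mask path, and the scalar
#' spec fields).
#'
#' @param specs List of [phantom_spec()] objects.
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a `data.frame`, invisibly written to
#'   `out_dir/manifest.csv`.
#' @export
make_batch <- function(specs, out_dir) {
  if (inherits(specs, "phantom_spec")) specs <- list(specs)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(specs), function(i) {
    ph <- make_phantom(specs[[i]])
    image_path <- file.path(out_dir, sprintf("image_%03d.png", i))
    mask_path <- file.path(out_dir, sprintf("mask_%03d.png", i))
    write_gray_image(ph$image, image_path)
    write_mask(ph$mask, mask_path)
    s <- specs[[i]]
    data.frame(id = sprintf("%03d", i), image = image_path, mask = mask_path,
               height = s$height, width = s$width,
               center_row = s$center[1L], center_col = s$center[2L],
               semi_a = s$semiaxes[1L], semi_b = s$semiaxes[2L],
               rotation = s$rotation,
               target_intensity = s$target_intensity,
               n_vessels = s$n_vessels,
               vessel_intensity = s$vessel_intensity,
               background = s$background, gradient = s$gradient,
               noise_sd = s$noise_sd, rng_seed = s$rng_seed)
  })
  manifest <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), image = character(0), mask = character(0))
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
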