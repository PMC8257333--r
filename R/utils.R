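# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("angioseg_validation", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("angioseg_io", "error")))
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (strict_lower) {
    if (x <= lower) stop_validation(name, " must be > ", lower)
  } else if (x < lower) {
    stop_validation(name, " must be >= ", lower)
  }
  if (x > upper) stop_validation(name, " must be <= ", upper)
  invisible(x)
}

check_gray_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_validation(name, " must be a numeric matrix")
  }
  if (nrow(image) < 2L || ncol(image) < 2L) {
    stop_validation(name, " must be at least 2x2 pixels")
  }
  if (anyNA(image) || !all(is.finite(image))) {
    stop_validation(name, " contains non-finite intensities")
  }
  if (min(image) < 0 || max(image) > 255) {
    stop_validation(name, " intensities must lie in [0, 255]")
  }
  invisible(image)
}

check_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_validation(name, " must be a logical matrix")
  }
  if (anyNA(mask)) stop_validation(name, " contains NA")
  invisible(mask)
}

check_same_shape <- function(a, b, name_a = "first", name_b = "second") {
  if (!identical(dim(a), dim(b))) {
    stop_validation(name_a, " and ", name_b, " must have identical shape")
  }
  invisible(NULL)
}

# Seeds are 1-based (row, col) pairs; accept a length-2 vector or an n x 2
# matrix / data.frame and return an integer n x 2 matrix.
as_seed_matrix <- function(seeds) {
  if (is.data.frame(seeds)) seeds <- as.matrix(seeds)
  if (is.numeric(seeds) && is.null(dim(seeds)) && length(seeds) == 2L) {
    seeds <- matrix(seeds, nrow = 1L)
  }
  if (!is.matrix(seeds) || ncol(seeds) != 2L || nrow(seeds) < 1L) {
    stop_validation("seeds must be a length-2 vector or an n x 2 matrix of (row, col)")
  }
  storage.mode(seeds) <- "integer"
  if (anyNA(seeds)) stop_validation("seeds contain NA")
  colnames(seeds) <- c("row", "col")
  seeds
}

check_seeds_in_bounds <- function(seeds, image) {
  bad <- seeds[, 1L] < 1L | seeds[, 1L] > nrow(image) |
    seeds[, 2L] < 1L | seeds[, 2L] > ncol(image)
  if (any(bad)) {
    stop_validation("seed(s) out of image bounds: ",
                    paste(which(bad), collapse = ", "))
  }
  invisible(seeds)
}
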