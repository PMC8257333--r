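# Fuzzy C-means clustering of pixel intensities.
#
# Clustering operates on the scalar intensity of each pixel (no spatial
# features). Memberships are stored as a K x N matrix whose columns sum to
# one; the fuzzifier m > 1 controls membership softness through the
# exponent t = 2 / (m - 1) in the membership update.

#' FCM parameters
#'
#' @param K Number of clusters (>= 1). The pipeline default is 6, the low
#'   end of the 6-10 range that keeps the dark/mid/bright tier grouping
#'   stable (two clusters per tier).
#' @param fuzzifier Membership softness exponent m > 1; 2 is the standard
#'   choice.
#' @param tol Convergence tolerance on the maximum absolute center shift
#'   between iterations, in gray levels.
#' @param max_iter Iteration cap.
#' @param rng_seed Seed for deterministic center initialization.
#' @return An object of class `fcm_params`.
#' @export
fcm_params <- function(K = 6L, fuzzifier = 2, tol = 1e-4, max_iter = 300L,
                       rng_seed = 1L) {
  check_scalar_number(K, "K", lower = 1)
  check_scalar_number(fuzzifier, "fuzzifier", lower = 1, strict_lower = TRUE)
  check_scalar_number(tol, "tol", lower = 0)
  check_scalar_number(max_iter, "max_iter", lower = 1)
  structure(list(K = as.integer(K), fuzzifier = fuzzifier, tol = tol,
                 max_iter = as.integer(max_iter),
                 rng_seed = as.integer(rng_seed)),
            class = "fcm_params")
}

#' Initial cluster centers
#'
#' Centers are drawn deterministically (per `rng_seed`) as mid-quantiles of
#' the intensity distribution, which spreads them over the occupied range.
#' When the image has fewer distinct intensities than `K`, quantiles
#' collide and a small seeded jitter restores distinctness.
#'
#' @param image Numeric intensity matrix.
#' @param params [fcm_params()].
#' @return Sorted numeric vector of `K` distinct centers.
#' @export
init_centers <- function(image, params) {
  check_gray_image(image)
  px <- as.numeric(image)
  K <- params$K
  centers <- quantile(px, probs = (seq_len(K) - 0.5) / K, names = FALSE)
  if (length(unique(centers)) < K) {
    centers <- with_seed(params$rng_seed, {
      jitter_scale <- max(diff(range(px)), 1) / (4 * K)
      out <- centers + runif(K, -jitter_scale, jitter_scale)
      while (length(unique(out)) < K) {
        dup <- duplicated(out)
        out[dup] <- out[dup] + runif(sum(dup), 0, jitter_scale)
      }
      out
    })
  }
  sort(centers)
}

#' Membership update
#'
#' Computes `mem[k, i] = 1 / sum_j (d_ki / d_ji)^t` with
#' `t = 2 / (fuzzifier - 1)` and `d_ki = |pixel_i - center_k|`. A pixel
#' coinciding with one or more centers receives membership 1 for the first
#' (lowest-index) coincident center and 0 elsewhere.
#'
#' @param image Numeric intensity matrix (or vector).
#' @param centers Numeric vector of cluster centers.
#' @param params [fcm_params()].
#' @return K x N membership matrix; every column sums to 1.
#' @export
update_memberships <- function(image, centers, params) {
  px <- as.numeric(image)
  K <- length(centers)
  t_exp <- 2 / (params$fuzzifier - 1)
  d <- abs(outer(centers, px, "-"))          # K x N
  w <- d^(-t_exp)
  mem <- sweep(w, 2L, colSums(w), "/")
  singular <- which(colSums(d == 0) > 0L)
  if (length(singular)) {
    for (i in singular) {
      col <- numeric(K)
      col[which(d[, i] == 0)[1L]] <- 1
      mem[, i] <- col
    }
  }
  mem
}

#' Center update
#'
#' `center_k = sum_i mem[k,i]^m * pixel_i / sum_i mem[k,i]^m`, the
#' stationary point of the fuzzy objective in the centers. A cluster with
#' zero total membership (reachable on degenerate inputs, e.g. a constant
#' image whose centers have collapsed onto the single intensity) keeps
#' its previous center when `fallback_centers` is supplied and is `NaN`
#' otherwise.
#'
#' @inheritParams update_memberships
#' @param memberships K x N membership matrix.
#' @param fallback_centers Optional centers to retain for empty clusters.
#' @return Numeric vector of K centers.
#' @export
update_centers <- function(image, memberships, params,
                           fallback_centers = NULL) {
  px <- as.numeric(image)
  um <- memberships^params$fuzzifier
  denom <- rowSums(um)
  out <- as.numeric(um %*% px) / denom
  empty <- denom == 0
  if (any(empty) && !is.null(fallback_centers)) {
    out[empty] <- fallback_centers[empty]
  }
  out
}

#' Fuzzy objective
#'
#' `E = sum_k sum_i mem[k,i]^m * (center_k - pixel_i)^2`. Zero exactly when
#' every pixel with nonzero membership coincides with its center.
#'
#' @inheritParams update_centers
#' @param centers Numeric vector of centers.
#' @return Nonnegative scalar.
#' @export
fcm_objective <- function(image, centers, memberships, params) {
  px <- as.numeric(image)
  if (length(centers) != nrow(memberships) ||
      length(px) != ncol(memberships)) {
    stop_validation("centers/memberships/image shapes disagree")
  }
  d2 <- outer(centers, px, "-")^2
  sum(memberships^params$fuzzifier * d2)
}

#' Run fuzzy C-means
#'
#' Alternates membership and center updates until the maximum absolute
#' center shift drops below `tol` or `max_iter` is reached. The recorded
#' objective trace is non-increasing (standard alternating-minimization
#' guarantee).
#'
#' @param image Numeric intensity matrix.
#' @param params [fcm_params()].
#' @return An object of class `fcm_fit`: list with `centers` (sorted),
#'   `memberships` (rows in center order), `objective_trace`, `iterations`,
#'   and `params`.
#' @export
run_fcm <- function(image, params = fcm_params()) {
  check_gray_image(image)
  centers <- init_centers(image, params)
  trace <- numeric(0)
  mem <- NULL
  iter <- 0L
  for (iter in seq_len(params$max_iter)) {
    mem <- update_memberships(image, centers, params)
    new_centers <- update_centers(image, mem, params, centers)
    trace <- c(trace, fcm_objective(image, new_centers, mem, params))
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    if (shift < params$tol) break
  }
  ord <- order(centers)
  structure(list(centers = centers[ord],
                 memberships = mem[ord, , drop = FALSE],
                 objective_trace = trace,
                 iterations = iter,
                 params = params),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy C-means fit: K =", length(x$centers),
      "| iterations =", x$iterations,
      "| objective =", format(utils::tail(x$objective_trace, 1L)), "\n")
  cat("centers:", paste(format(x$centers, digits = 5), collapse = ", "), "\n")
  invisible(x)
}

#' Defuzzify memberships to hard labels
#'
#' Each pixel is assigned the cluster of maximal membership; ties break
#' toward the lowest cluster index.
#'
#' @param memberships K x N membership matrix, or an `fcm_fit`.
#' @param dim Optional `c(height, width)` to reshape labels to a matrix.
#' @return Integer vector (or matrix) of cluster indices in `1..K`.
#' @export
defuzzify <- function(memberships, dim = NULL) {
  if (inherits(memberships, "fcm_fit")) memberships <- memberships$memberships
  labels <- max.col(t(memberships), ties.method = "first")
  if (!is.null(dim)) labels <- matrix(labels, nrow = dim[1L], ncol = dim[2L])
  labels
}
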