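# End-to-end GA-FCM segmentation.
#
# segment(): FCM clustering -> tri-class reference -> GA seed search ->
# final region growing from the best chromosome -> target-tier mask.
# segment_manual(): same tail end, but with user-supplied seeds instead
# of the GA (the hand-seeding baseline).

#' Pipeline configuration
#'
#' @param fcm [fcm_params()].
#' @param ga [ga_config()].
#' @param growth [growth_config()].
#' @param target_tier Which intensity tier constitutes the target region:
#'   `"dark"` (default; avascular/hypofluorescent lesions), `"mid"`, or
#'   `"bright"`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(fcm = fcm_params(), ga = ga_config(),
                            growth = growth_config(),
                            target_tier = "dark") {
  stopifnot(inherits(fcm, "fcm_params"), inherits(ga, "ga_config"),
            inherits(growth, "growth_config"))
  target_tier <- match.arg(target_tier, c("dark", "mid", "bright"))
  structure(list(fcm = fcm, ga = ga, growth = growth,
                 target_tier = target_tier),
            class = "pipeline_config")
}

tier_code <- function(target_tier) {
  match(target_tier, c("dark", "mid", "bright"))
}

# FCM on large images: fit centers on a stride-2 subsample to bound cost,
# then one full-resolution membership pass so the reference is exact.
fit_fcm_for_pipeline <- function(image, params) {
  if (length(image) > 1e5) {
    sub <- image[seq(1L, nrow(image), by = 2L), seq(1L, ncol(image), by = 2L)]
    fit <- run_fcm(sub, params)
    mem <- update_memberships(image, fit$centers, params)
    fit$memberships <- mem
    fit
  } else {
    run_fcm(image, params)
  }
}

finish_segmentation <- function(image, seeds, reference, growth,
                                target_tier, fcm_result, cost_history,
                                best_chromosome) {
  grown <- grow_all(image, seeds, growth, quiet = TRUE)
  region_mu <- vapply(grown$stats, function(s) s$mu, numeric(1))
  tier <- rep(NA_integer_, length(region_mu))
  ok <- !is.na(region_mu)
  tier[ok] <- region_tier(region_mu[ok], reference$breaks)
  target <- which(tier == tier_code(target_tier))
  mask <- matrix(grown$labels %in% target, nrow(image), ncol(image))
  structure(list(mask = mask, label_map = grown$labels,
                 region_stats = grown$stats, region_tier = tier,
                 best_chromosome = best_chromosome,
                 fcm_result = fcm_result, reference = reference,
                 cost_history = cost_history,
                 target_tier = target_tier),
            class = "segmentation_result")
}

#' Segment an image with the GA-FCM pipeline
#'
#' Runs fuzzy C-means on the intensities, folds the clusters into the
#' dark/mid/bright tri-class reference, searches seed configurations with
#' the genetic algorithm, grows regions from the best chromosome, and
#' returns the union of grown regions whose mean intensity falls in the
#' target tier. Deterministic given the seeds in `config`.
#'
#' @param image Numeric intensity matrix on \[0, 255\].
#' @param config A [pipeline_config()].
#' @return Object of class `segmentation_result`: `mask` (logical),
#'   `label_map`, `region_stats`, `region_tier`, `best_chromosome`,
#'   `fcm_result`, `reference`, `cost_history`, `target_tier`.
#' @export
segment <- function(image, config = pipeline_config()) {
  check_gray_image(image)
  stopifnot(inherits(config, "pipeline_config"))
  fit <- fit_fcm_for_pipeline(image, config$fcm)
  reference <- build_reference(image, fit)
  ga_out <- run_ga(image, reference, config$ga, config$growth)
  finish_segmentation(image, ga_out$best$seeds, reference, config$growth,
                      config$target_tier, fit, ga_out$history, ga_out$best)
}

#' Segment with manually chosen seeds
#'
#' Bypasses the genetic search: regions are grown from the supplied seeds
#' and classified against the same FCM-derived tier reference. This is
#' the hand-seeding baseline the GA is compared against.
#'
#' @param image Numeric intensity matrix.
#' @param seeds n x 2 matrix (or length-2 vector) of 1-based seeds.
#' @param growth A [growth_config()].
#' @param target_tier `"dark"`, `"mid"`, or `"bright"`.
#' @param fcm A [fcm_params()] used to build the tier reference.
#' @return A `segmentation_result` (with `best_chromosome` holding the
#'   manual seeds and an empty `cost_history`).
#' @export
segment_manual <- function(image, seeds, growth = growth_config(),
                           target_tier = "dark", fcm = fcm_params()) {
  check_gray_image(image)
  if (is.null(seeds) || length(seeds) == 0L) {
    stop_validation("segment_manual requires at least one seed")
  }
  seeds <- as_seed_matrix(seeds)
  check_seeds_in_bounds(seeds, image)
  target_tier <- match.arg(target_tier, c("dark", "mid", "bright"))
  fit <- fit_fcm_for_pipeline(image, fcm)
  reference <- build_reference(image, fit)
  finish_segmentation(image, seeds, reference, growth, target_tier, fit,
                      data.frame(generation = integer(0),
                                 best_cost = numeric(0),
                                 mean_cost = numeric(0)),
                      seed_chromosome(seeds))
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat("GA-FCM segmentation result\n")
  cat("  target tier:", x$target_tier, "| mask pixels:", sum(x$mask),
      "of", length(x$mask), "\n")
  cat("  regions grown:", length(x$region_stats),
      "| seeds:", nrow(x$best_chromosome$seeds), "\n")
  if (nrow(x$cost_history)) {
    cat("  final GA cost:",
        format(utils::tail(x$cost_history$best_cost, 1L)), "after",
        utils::tail(x$cost_history$generation, 1L), "generations\n")
  }
  invisible(x)
}
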