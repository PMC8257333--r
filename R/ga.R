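# Genetic search over seed configurations.
#
# A chromosome is an ordered list of (row, col) seed points (count within
# [n_min, n_max]). Fitness is the tri-class squared-difference cost: the
# chromosome's seeds are grown into regions, each region is assigned to
# the dark/mid/bright tier whose intensity band contains its mean, and
# the binary tier supports are compared pixelwise against the FCM-derived
# reference. Selection is tournament (size 3), recombination is classical
# one-point crossover (shared cut), mutation jitters seed positions and
# inserts/deletes seeds, and elitism carries the best individuals
# unchanged so the best-cost history is non-increasing.

#' GA configuration
#'
#' @param population_size Individuals per generation (default 20).
#' @param mutation_rate Per-seed jitter probability and per-chromosome
#'   insert/delete probability (default 0.2).
#' @param n_generations Generations to run (default 120; discovery of a
#'   small target region relies on delete-then-insert mutation chains
#'   whose waiting time is long once the population has converged on
#'   background coverage).
#' @param elitism Number of best individuals copied unchanged (>= 1).
#' @param n_min,n_max Bounds on the seed count per chromosome.
#' @param rng_seed Seed; fixes the whole run bit-reproducibly.
#' @param tournament_size Tournament selection size.
#' @param stall_generations Early stop after this many generations without
#'   improvement of the best cost.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population_size = 20L, mutation_rate = 0.2,
                      n_generations = 120L, elitism = 1L, n_min = 1L,
                      n_max = 20L, rng_seed = 1L, tournament_size = 3L,
                      stall_generations = 40L) {
  check_scalar_number(population_size, "population_size", lower = 2)
  check_scalar_number(mutation_rate, "mutation_rate", lower = 0, upper = 1)
  check_scalar_number(n_generations, "n_generations", lower = 0)
  check_scalar_number(elitism, "elitism", lower = 1)
  check_scalar_number(n_min, "n_min", lower = 1)
  check_scalar_number(n_max, "n_max", lower = n_min)
  check_scalar_number(tournament_size, "tournament_size", lower = 1)
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 n_generations = as.integer(n_generations),
                 elitism = as.integer(elitism),
                 n_min = as.integer(n_min), n_max = as.integer(n_max),
                 rng_seed = as.integer(rng_seed),
                 tournament_size = as.integer(tournament_size),
                 stall_generations = as.integer(stall_generations)),
            class = "ga_config")
}

#' Seed chromosome
#'
#' @param seeds n x 2 matrix (or length-2 vector) of 1-based `(row, col)`
#'   seed coordinates.
#' @param fitness Optional cached cost.
#' @return Object of class `seed_chromosome`.
#' @export
seed_chromosome <- function(seeds, fitness = NA_real_) {
  seeds <- as_seed_matrix(seeds)
  structure(list(seeds = seeds, fitness = fitness),
            class = "seed_chromosome")
}

#' Tri-class reference from an FCM fit
#'
#' Clusters are sorted by center intensity and split into three
#' consecutive groups at the two largest gaps between adjacent centers:
#' the darkest group (BM), the middle group (GM), and the brightest group
#' (WM). Splitting at the largest intensity gaps follows the natural
#' lesion / tissue / vessel structure of angiography intensities; a fixed
#' equal-count split does not, because FCM allocates clusters in
#' proportion to intensity mass, so the dominant tissue background would
#' bleed into the dark tier. Each reference image is the binary (0/1)
#' support of its tier: 1 where the pixel's defuzzified cluster belongs
#' to the tier, 0 elsewhere. Binary tissue maps keep the three tiers
#' commensurate in the squared-difference cost; carrying raw intensities
#' instead would weight a dark-lesion pixel by its small squared gray
#' level and make the lesion tier a negligible fraction of the total
#' cost mass. `breaks` are the midpoints across the two chosen gaps and
#' delimit the intensity band used to classify grown regions by their
#' mean.
#'
#' @param image Numeric intensity matrix.
#' @param fcm_result An `fcm_fit` from [run_fcm()] on the same image (K >= 3).
#' @return Object of class `triclass_reference`: list with matrices `BM`,
#'   `GM`, `WM`, numeric `breaks` (length 2), `centers`, integer
#'   `tier_of_cluster`, and `tier_labels` (integer matrix, 1 = dark,
#'   2 = mid, 3 = bright).
#' @export
build_reference <- function(image, fcm_result) {
  check_gray_image(image)
  stopifnot(inherits(fcm_result, "fcm_fit"))
  K <- length(fcm_result$centers)
  if (K < 3L) stop_validation("build_reference requires K >= 3 clusters")
  centers <- fcm_result$centers # already sorted
  gaps <- diff(centers)
  splits <- sort(order(gaps, decreasing = TRUE)[1:2]) # after these indices
  tier_of_cluster <- as.integer(cut(seq_len(K),
                                    breaks = c(0, splits, K),
                                    labels = FALSE))
  labels <- defuzzify(fcm_result$memberships)
  tier_labels <- matrix(tier_of_cluster[labels], nrow(image), ncol(image))
  b1 <- mean(c(max(centers[tier_of_cluster == 1L]),
               min(centers[tier_of_cluster == 2L])))
  b2 <- mean(c(max(centers[tier_of_cluster == 2L]),
               min(centers[tier_of_cluster == 3L])))
  tier_image <- function(t) (tier_labels == t) * 1
  structure(list(BM = tier_image(1L), GM = tier_image(2L),
                 WM = tier_image(3L), breaks = c(b1, b2),
                 centers = centers, tier_of_cluster = tier_of_cluster,
                 tier_labels = tier_labels),
            class = "triclass_reference")
}

# Tier (1 dark, 2 mid, 3 bright) of a region mean against the reference
# intensity bands.
region_tier <- function(mu, breaks) {
  ifelse(mu < breaks[1L], 1L, ifelse(mu < breaks[2L], 2L, 3L))
}

#' Chromosome cost
#'
#' Grows regions from the chromosome's seeds, assigns every grown region
#' to the dark/mid/bright tier containing its mean intensity, forms the
#' three binary segmentation supports I1 (mid tier), I2 (bright), I3
#' (dark) -- 1 on the region pixels of that tier, 0 elsewhere -- and
#' returns the per-pixel-normalized sum
#' `mean((GM - I1)^2 + (WM - I2)^2 + (BM - I3)^2)`, i.e. the tri-class
#' disagreement fraction between the clustering reference and the
#' region-growing segmentation (0 = perfect reproduction).
#'
#' @param chrom A [seed_chromosome()].
#' @param image Numeric intensity matrix.
#' @param reference A `triclass_reference` from [build_reference()].
#' @param growth_config A [growth_config()].
#' @return Nonnegative scalar cost (lower is better).
#' @export
chromosome_cost <- function(chrom, image, reference,
                            growth_config = growth_config()) {
  stopifnot(inherits(chrom, "seed_chromosome"),
            inherits(reference, "triclass_reference"))
  grown <- grow_all(image, chrom$seeds, growth_config, quiet = TRUE)
  region_mu <- vapply(grown$stats, function(s) s$mu, numeric(1))
  tier <- rep(NA_integer_, length(region_mu))
  ok <- !is.na(region_mu)
  tier[ok] <- region_tier(region_mu[ok], reference$breaks)
  # per-pixel tier of the grown segmentation; 0 where nothing grew
  lab <- grown$labels
  pixel_tier <- matrix(0L, nrow(lab), ncol(lab))
  claimed <- lab > 0L
  pixel_tier[claimed] <- tier[lab[claimed]]
  seg_image <- function(t) (pixel_tier == t) * 1
  mean((reference$GM - seg_image(2L))^2 +
       (reference$WM - seg_image(3L))^2 +
       (reference$BM - seg_image(1L))^2)
}

# Initial individuals carry the full seed budget (n_max seeds; deletion
# mutations prune redundant ones cheaply) with locations stratified
# across the three FCM tiers: slot i draws a uniform random pixel from
# tier (i mod 3)'s support. Stratification is essential for small
# targets: a dark lesion occupying a few percent of the image is worth
# little under the squared-intensity cost, so purely uniform seeding
# routinely converges on background coverage before any chromosome
# carries a lesion seed, and the lesion tier is then never recovered.
# Without a reference, locations are uniform over the image.
random_chromosome <- function(image, config, reference = NULL) {
  n <- config$n_max
  if (is.null(reference)) {
    return(seed_chromosome(cbind(sample.int(nrow(image), n, replace = TRUE),
                                 sample.int(ncol(image), n, replace = TRUE))))
  }
  tier_cells <- lapply(1:3, function(t) which(reference$tier_labels == t))
  seeds <- t(vapply(seq_len(n), function(i) {
    cells <- tier_cells[[(i - 1L) %% 3L + 1L]]
    idx <- if (length(cells)) cells[sample.int(length(cells), 1L)] else
      sample.int(length(image), 1L)
    c((idx - 1L) %% nrow(image) + 1L, (idx - 1L) %/% nrow(image) + 1L)
  }, integer(2)))
  seed_chromosome(seeds)
}

#' Mutate a chromosome
#'
#' Each seed is jittered with probability `mutation_rate` by independent
#' uniform integer offsets in \[-5, 5\] on each coordinate, clipped to the
#' image bounds. Additionally, with probability `mutation_rate` per
#' chromosome, one seed is inserted (uniform position) or deleted,
#' choosing 50/50 when both respect `[n_min, n_max]` and otherwise taking
#' the legal operation. Draws come from the caller's RNG.
#'
#' @param chrom A [seed_chromosome()].
#' @param config A [ga_config()].
#' @param image Image whose bounds constrain coordinates.
#' @return Mutated `seed_chromosome` (fitness cleared).
#' @export
mutate <- function(chrom, config, image) {
  seeds <- chrom$seeds
  n <- nrow(seeds)
  jitter <- runif(n) < config$mutation_rate
  if (any(jitter)) {
    k <- sum(jitter)
    seeds[jitter, 1L] <- pmin(pmax(seeds[jitter, 1L] +
                                     sample(-5:5, k, replace = TRUE), 1L),
                              nrow(image))
    seeds[jitter, 2L] <- pmin(pmax(seeds[jitter, 2L] +
                                     sample(-5:5, k, replace = TRUE), 1L),
                              ncol(image))
  }
  if (runif(1) < config$mutation_rate) {
    can_insert <- n < config$n_max
    can_delete <- n > config$n_min
    insert <- if (can_insert && can_delete) runif(1) < 0.5 else can_insert
    if (insert && can_insert) {
      seeds <- rbind(seeds, c(sample.int(nrow(image), 1L),
                              sample.int(ncol(image), 1L)))
    } else if (!insert && can_delete) {
      seeds <- seeds[-sample.int(n, 1L), , drop = FALSE]
    }
  }
  seed_chromosome(seeds)
}

#' One-point crossover
#'
#' Classical single-cut recombination: one cut position `c` drawn
#' uniformly from `0..min(len_a, len_b)` is applied to both parents, and
#' each offspring splices the head of one parent onto the tail of the
#' other. Offspring lengths equal the parents' lengths (swapped), so the
#' `[n_min, n_max]` bounds hold automatically; identical parents yield
#' identical offspring, and seed counts change through mutation, not
#' crossover.
#'
#' @param parent_a,parent_b `seed_chromosome` objects.
#' @param config A [ga_config()].
#' @return List of two offspring `seed_chromosome`s.
#' @export
crossover <- function(parent_a, parent_b, config) {
  a <- parent_a$seeds; b <- parent_b$seeds
  na <- nrow(a); nb <- nrow(b)
  cut <- sample(0:min(na, nb), 1L)
  child1 <- rbind(a[seq_len(na) <= cut, , drop = FALSE],
                  b[seq_len(nb) > cut, , drop = FALSE])
  child2 <- rbind(b[seq_len(nb) <= cut, , drop = FALSE],
                  a[seq_len(na) > cut, , drop = FALSE])
  list(seed_chromosome(child1), seed_chromosome(child2))
}

tournament_pick <- function(fitness, k) {
  contenders <- sample.int(length(fitness), k, replace = TRUE)
  contenders[which.min(fitness[contenders])]
}

#' Run the genetic seed search
#'
#' Initializes `population_size` chromosomes with `n_max` seeds each,
#' locations stratified across the tri-class tiers, then iterates
#' tournament selection, one-point crossover, mutation, and elitism. The
#' run is bit-reproducible given `rng_seed`, and with `elitism >= 1` the
#' per-generation best cost never increases. Stops early after
#' `stall_generations` generations without improvement.
#'
#' @param image Numeric intensity matrix.
#' @param reference A `triclass_reference` from [build_reference()].
#' @param ga_config A [ga_config()].
#' @param growth_config A [growth_config()].
#' @return List with `best` (best-ever `seed_chromosome`, fitness filled),
#'   `history` (data.frame: generation, best_cost, mean_cost; generation 0
#'   is the initial population), and `n_evaluations`.
#' @export
run_ga <- function(image, reference, ga_config = ga_config(),
                   growth_config = growth_config()) {
  check_gray_image(image)
  stopifnot(inherits(reference, "triclass_reference"))
  cfg <- ga_config
  with_seed(cfg$rng_seed, {
    pop <- replicate(cfg$population_size,
                     random_chromosome(image, cfg, reference),
                     simplify = FALSE)
    n_eval <- 0L
    eval_pop <- function(pop) {
      for (i in seq_along(pop)) {
        if (is.na(pop[[i]]$fitness)) {
          pop[[i]]$fitness <- chromosome_cost(pop[[i]], image, reference,
                                              growth_config)
          n_eval <<- n_eval + 1L
        }
      }
      pop
    }
    pop <- eval_pop(pop)
    fitness <- vapply(pop, `[[`, numeric(1), "fitness")
    history <- data.frame(generation = 0L, best_cost = min(fitness),
                          mean_cost = mean(fitness))
    best <- pop[[which.min(fitness)]]
    stall <- 0L
    gen <- 0L
    while (gen < cfg$n_generations && stall < cfg$stall_generations) {
      gen <- gen + 1L
      elite_idx <- order(fitness)[seq_len(min(cfg$elitism, length(pop)))]
      offspring <- list()
      while (length(offspring) < cfg$population_size - length(elite_idx)) {
        pa <- pop[[tournament_pick(fitness, cfg$tournament_size)]]
        pb <- pop[[tournament_pick(fitness, cfg$tournament_size)]]
        kids <- crossover(pa, pb, cfg)
        kids <- lapply(kids, mutate, config = cfg, image = image)
        offspring <- c(offspring, kids)
      }
      offspring <- offspring[seq_len(cfg$population_size - length(elite_idx))]
      pop <- c(pop[elite_idx], offspring)
      pop <- eval_pop(pop)
      fitness <- vapply(pop, `[[`, numeric(1), "fitness")
      gen_best <- min(fitness)
      if (gen_best < best$fitness) {
        best <- pop[[which.min(fitness)]]
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      history <- rbind(history,
                       data.frame(generation = gen, best_cost = gen_best,
                                  mean_cost = mean(fitness)))
    }
    list(best = best, history = history, n_evaluations = n_eval)
  })
}
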