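# Independent oracle implementations used to cross-check the package.
# Everything here is deliberately written from first principles (plain
# loops, two-pass formulas) and shares no code path with the package.

# 8-connected component of `mask` containing `seed`, by plain BFS.
flood_fill8 <- function(mask, seed) {
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(FALSE, H, W)
  if (!mask[seed[1], seed[2]]) return(out)
  queue <- list(seed)
  out[seed[1], seed[2]] <- TRUE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- p[1] + dr; c <- p[2] + dc
      if (r >= 1 && r <= H && c >= 1 && c <= W && mask[r, c] && !out[r, c]) {
        out[r, c] <- TRUE
        queue <- c(queue, list(c(r, c)))
      }
    }
  }
  out
}

# Lloyd's k-means on a 1-D sample from fixed initial centers.
lloyd_kmeans <- function(x, centers, iters = 100) {
  for (i in seq_len(iters)) {
    d <- abs(outer(centers, x, "-"))
    assign <- apply(d, 2, which.min)
    new_centers <- vapply(seq_along(centers), function(k) {
      xs <- x[assign == k]
      if (length(xs)) mean(xs) else centers[k]
    }, numeric(1))
    if (max(abs(new_centers - centers)) < 1e-10) break
    centers <- new_centers
  }
  list(centers = centers, labels = apply(abs(outer(centers, x, "-")), 2,
                                         which.min))
}

# Otsu's threshold on a [0, 255] image, 256-bin histogram.
otsu_threshold <- function(img) {
  counts <- tabulate(pmin(pmax(floor(img), 0), 255) + 1, nbins = 256)
  p <- counts / sum(counts)
  levels <- 0:255
  best_t <- 0; best_var <- -1
  for (t in 0:254) {
    w0 <- sum(p[1:(t + 1)]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(levels[1:(t + 1)] * p[1:(t + 1)]) / w0
    mu1 <- sum(levels[(t + 2):256] * p[(t + 2):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best_var) { best_var <- v; best_t <- t }
  }
  best_t + 0.5
}

# Two-pass batch mean / sample sd.
batch_stats <- function(x) {
  m <- sum(x) / length(x)
  list(mu = m, sigma = if (length(x) > 1) sqrt(sum((x - m)^2) / (length(x) - 1)) else 0)
}
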