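# Brute-force oracles, written independently of the package internals:
# plain loops, no shared helpers. Slow by design; use small inputs.

clamp <- function(i, lo, hi) pmin(pmax(i, lo), hi)

# direct separable Gaussian convolution with edge replication
oracle_gaussian_blur <- function(m, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  tmp <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (t in seq_along(k)) s <- s + k[t] * m[clamp(i + t - r - 1L, 1L, nr), j]
    tmp[i, j] <- s
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    s <- 0
    for (t in seq_along(k)) s <- s + k[t] * tmp[i, clamp(j + t - r - 1L, 1L, nc)]
    out[i, j] <- s
  }
  out
}

oracle_histogram <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  w <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / w) + 1L, nbins)
  counts <- integer(nbins)
  for (i in idx) counts[i] <- counts[i] + 1L
  list(counts = counts, centers = lo + (seq_len(nbins) - 0.5) * w,
       lo = lo, hi = hi, width = w)
}

# exhaustive Huang fuzzy-entropy search (Shannon form)
oracle_huang <- function(m) {
  h <- oracle_histogram(as.vector(m))
  counts <- h$counts; g <- h$centers
  C <- g[length(g)] - g[1]
  best_s <- Inf; best_t <- NA
  for (t in 1:(length(g) - 1)) {
    n0 <- sum(counts[1:t]); n1 <- sum(counts) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:t] * g[1:t]) / n0
    mu1 <- sum(counts[(t + 1):length(g)] * g[(t + 1):length(g)]) / n1
    s <- 0
    for (i in seq_along(g)) {
      mu <- if (i <= t) mu0 else mu1
      u <- 1 / (1 + abs(g[i] - mu) / C)
      if (u > 0 && u < 1)
        s <- s + counts[i] * (-u * log(u) - (1 - u) * log(1 - u))
    }
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  (g[best_t] + g[best_t + 1]) / 2
}

# isodata fixed-point iteration from the histogram mean, extreme bins
# zeroed (reference-tool dialect)
oracle_isodata <- function(m, trim = TRUE) {
  h <- oracle_histogram(as.vector(m))
  counts <- h$counts; g <- h$centers
  if (trim) { counts[1] <- 0L; counts[length(counts)] <- 0L }
  if (sum(counts > 0) < 2) return((h$lo + h$hi) / 2)
  t <- sum(counts * g) / sum(counts)
  for (i in 1:1000) {
    lo <- g <= t
    if (sum(counts[lo]) == 0 || sum(counts[!lo]) == 0) break
    t_new <- (sum(counts[lo] * g[lo]) / sum(counts[lo]) +
              sum(counts[!lo] * g[!lo]) / sum(counts[!lo])) / 2
    if (abs(t_new - t) < 1e-9 * max(1, abs(t))) { t <- t_new; break }
    t <- t_new
  }
  t
}

# per-pixel neighbourhood sort median over the disc d^2 <= r^2
oracle_median_binary <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  r <- floor(radius)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- integer(0)
    for (di in -r:r) for (dj in -r:r) {
      if (di^2 + dj^2 <= radius^2)
        vals <- c(vals, m[clamp(i + di, 1L, nr), clamp(j + dj, 1L, nc)])
    }
    out[i, j] <- sort(vals)[(length(vals) + 1L) %/% 2L]  # middle of odd count
  }
  out
}

# flood-fill component count
oracle_component_count <- function(m, connectivity = 8) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8)
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  count <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (m[i, j] != 0 && !seen[i, j]) {
      count <- count + 1L
      stack <- list(c(i, j)); seen[i, j] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (o in seq_len(nrow(offs))) {
          q <- p + offs[o, ]
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              m[q[1], q[2]] != 0 && !seen[q[1], q[2]]) {
            seen[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1]] <- q
          }
        }
      }
    }
  }
  count
}

# direct grayscale ball opening (erosion then dilation), edge replication
oracle_ball_opening <- function(m, radius) {
  nr <- nrow(m); nc <- ncol(m)
  r <- floor(radius)
  offs <- list()
  for (di in -r:r) for (dj in -r:r)
    if (di^2 + dj^2 <= radius^2)
      offs[[length(offs) + 1]] <- c(di, dj, sqrt(radius^2 - di^2 - dj^2))
  er <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- Inf
    for (o in offs)
      v <- min(v, m[clamp(i + o[1], 1, nr), clamp(j + o[2], 1, nc)] - o[3])
    er[i, j] <- v
  }
  di <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    v <- -Inf
    for (o in offs)
      v <- max(v, er[clamp(i - o[1], 1, nr), clamp(j - o[2], 1, nc)] + o[3])
    di[i, j] <- v
  }
  di
}

oracle_roi_mean <- function(m, center, radius) {
  vals <- c()
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m)))
    if ((i - center[1])^2 + (j - center[2])^2 <= radius^2)
      vals <- c(vals, m[i, j])
  mean(vals)
}

# count of distance-transform basins expected from two overlapping discs:
# helper to build disc masks
make_disc_mask <- function(nr, nc, centers, radii) {
  m <- matrix(0L, nr, nc)
  for (k in seq_along(radii)) {
    for (i in seq_len(nr)) for (j in seq_len(nc))
      if ((i - centers[k, 1])^2 + (j - centers[k, 2])^2 <= radii[k]^2)
        m[i, j] <- 1L
  }
  m
}

# noiseless spherical Hertz indentation curve built directly from the
# closed-form law (no reliance on the package generator)
oracle_hertz_curve <- function(E, R, nu, delta_max = 300, n = 200) {
  delta <- seq(0.5, delta_max, length.out = n)
  F <- (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5 * 1e-9
  list(delta = delta, F = F)
}
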