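#' @useDynLib plamech, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd median coef lm residuals fitted rnorm runif rpois
NULL

# 1D convolution as a dense matrix with edge replication: row i holds the
# kernel weights accumulated onto clamped indices, so rows always sum to 1.
conv1_replicate <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (k in seq_along(kernel)) {
    off <- k - r - 1L
    j <- pmin(pmax(seq_len(n) + off, 1L), n)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + kernel[k]
  }
  M
}

gaussian_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  x <- seq(-r, r)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur
#'
#' Linear shift-invariant smoothing with a normalized, separable Gaussian
#' kernel (support truncated at 4 sigma). Image borders are handled by edge
#' replication, so a constant image is reproduced exactly and total intensity
#' of interior-supported content is conserved.
#'
#' @param img An [image2d()] or numeric matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @return An `image2d` with the same geometry.
#' @examples
#' img <- image2d(matrix(7, 16, 16))
#' all.equal(gaussian_blur(img, 2)$pixels, img$pixels)
#' @export
gaussian_blur <- function(img, sigma) {
  img <- as_image2d(img)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  p <- img$pixels
  k <- gaussian_kernel_1d(sigma)
  out <- conv1_replicate(nrow(p), k) %*% p %*% t(conv1_replicate(ncol(p), k))
  # clamp tiny negative round-off so the non-negativity invariant holds
  out[out < 0] <- 0
  image2d(out, pixel_size = img$pixel_size, channel = img$channel)
}

# 256-bin histogram spanning [min, max]; returns counts and bin centers.
intensity_histogram <- function(v, nbins = 256L) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) stop("degenerate input: image is constant", call. = FALSE)
  w <- (hi - lo) / nbins
  idx <- pmin(floor((v - lo) / w) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  centers <- lo + (seq_len(nbins) - 0.5) * w
  list(counts = counts, centers = centers, lo = lo, hi = hi, width = w)
}

#' Huang fuzzy-entropy automatic threshold
#'
#' Returns the gray level minimizing the Huang--Wang measure of fuzziness in
#' its Shannon-entropy form, computed on a 256-bin histogram spanning the
#' image's intensity range. For each candidate split the two class means
#' define fuzzy memberships \eqn{u(g) = 1 / (1 + |g - \mu_{class}| / C)}
#' (with \eqn{C} the gray-level range), and the candidate minimizing
#' \eqn{\sum_g h(g)\,[-u \log u - (1-u)\log(1-u)]} wins; ties go to the
#' lowest gray level. Foreground is the set of pixels strictly above the
#' returned threshold (bright objects, "white" convention).
#'
#' @inheritParams gaussian_blur
#' @return A single threshold intensity, strictly between the image minimum
#'   and maximum.
#' @export
threshold_huang <- function(img) {
  img <- as_image2d(img)
  h <- intensity_histogram(img$pixels)
  counts <- h$counts; g <- h$centers
  C <- g[length(g)] - g[1]
  n <- length(counts)
  csum <- cumsum(counts)
  cwsum <- cumsum(counts * g)
  total <- csum[n]; wtotal <- cwsum[n]
  best_s <- Inf; best_t <- NA_integer_
  for (t in seq_len(n - 1L)) {
    n0 <- csum[t]; n1 <- total - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- cwsum[t] / n0
    mu1 <- (wtotal - cwsum[t]) / n1
    mu <- c(rep(mu0, t), rep(mu1, n - t))
    u <- 1 / (1 + abs(g - mu) / C)
    hf <- ifelse(u >= 1 | u <= 0, 0, -u * log(u) - (1 - u) * log(1 - u))
    s <- sum(counts * hf)
    if (s < best_s - 1e-12) { best_s <- s; best_t <- t }
  }
  if (is.na(best_t)) stop("could not determine a threshold", call. = FALSE)
  # report the split point between bins best_t and best_t + 1
  (g[best_t] + g[best_t + 1L]) / 2
}

#' Isodata (iterative intermeans) automatic threshold, desktop-tool dialect
#'
#' The "default" auto-threshold of the common desktop image-analysis tools:
#' an iterative-intermeans (isodata) threshold computed on a 256-bin
#' histogram spanning the image's intensity range, with the two extreme
#' bins zeroed before iterating — the tool's guard against erased/clipped
#' areas dominating the histogram (essential after background subtraction,
#' which piles clipped pixels at zero). The iteration converges to the
#' fixed point \eqn{t = (\mathrm{mean}(v \le t) + \mathrm{mean}(v > t)) /
#' 2} on the trimmed histogram. When trimming empties the histogram (all
#' mass in the extreme bins, e.g. a two-valued image), the midpoint of the
#' intensity range is returned. Foreground is the set of pixels strictly
#' above the returned threshold.
#'
#' @inheritParams gaussian_blur
#' @param trim_extremes Zero the first and last histogram bins before
#'   iterating (the reference-tool behaviour; set `FALSE` for the plain
#'   isodata fixed point on the full histogram).
#' @param max_iter Iteration cap (convergence is typically < 20 steps).
#' @return A single threshold intensity strictly between the image minimum
#'   and maximum.
#' @export
threshold_isodata_default <- function(img, trim_extremes = TRUE,
                                      max_iter = 1000L) {
  img <- as_image2d(img)
  h <- intensity_histogram(img$pixels)
  counts <- h$counts; g <- h$centers
  if (trim_extremes) {
    counts[1] <- 0L
    counts[length(counts)] <- 0L
  }
  nz <- which(counts > 0)
  if (length(nz) < 2L)
    return((h$lo + h$hi) / 2)  # all mass trimmed or unimodal: mid-range
  t <- sum(counts * g) / sum(counts)
  for (i in seq_len(max_iter)) {
    lo <- g <= t
    n0 <- sum(counts[lo]); n1 <- sum(counts[!lo])
    if (n0 == 0) { t <- min(g[!lo]); next }
    if (n1 == 0) { # all mass at or below t: pull t just under the top bin
      t <- (max(g[counts > 0]) + t) / 2
      if (sum(counts[g > t]) == 0) t <- t - h$width
      next
    }
    t_new <- (sum(counts[lo] * g[lo]) / n0 + sum(counts[!lo] * g[!lo]) / n1) / 2
    if (abs(t_new - t) < 1e-9 * max(1, abs(t))) { t <- t_new; break }
    t <- t_new
  }
  if (t <= h$lo || t >= h$hi)
    t <- min(max(t, h$lo + h$width / 2), h$hi - h$width / 2)
  t
}

# spherical-cap structuring element offsets/heights for a ball of radius r
ball_se <- function(radius) {
  r <- floor(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius^2
  list(dr = as.integer(dr[keep]), dc = as.integer(dc[keep]),
       h = sqrt(radius^2 - dr[keep]^2 - dc[keep]^2))
}

disc_se <- function(radius) {
  r <- floor(radius)
  dr <- rep(-r:r, times = 2 * r + 1)
  dc <- rep(-r:r, each = 2 * r + 1)
  keep <- dr^2 + dc^2 <= radius^2
  list(dr = as.integer(dr[keep]), dc = as.integer(dc[keep]))
}

#' Rolling-ball background subtraction
#'
#' Estimates a smooth background as the grayscale opening of the image with a
#' ball (spherical-cap) structuring element of the given radius and subtracts
#' it, clipping at zero. The opening is computed exactly (erosion then
#' dilation with the non-flat ball, edge replication), without the image
#' shrinking some desktop tools apply for large radii.
#'
#' @inheritParams gaussian_blur
#' @param radius Ball radius in pixels (>= 1).
#' @return An `image2d`; pointwise `0 <= out <= img`.
#' @export
rolling_ball_subtract <- function(img, radius) {
  img <- as_image2d(img)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("radius must be a single number >= 1", call. = FALSE)
  p <- img$pixels
  if (radius > nrow(p) && radius > ncol(p))
    stop("ball radius exceeds both image dimensions", call. = FALSE)
  se <- ball_se(radius)
  er <- cpp_erode_gray(p, se$dr, se$dc, se$h)
  bg <- cpp_dilate_gray(er, se$dr, se$dc, se$h)
  out <- pmax(p - bg, 0)
  image2d(out, pixel_size = img$pixel_size, channel = img$channel)
}

#' Difference-of-Gaussians punctum enhancement
#'
#' High-pass enhancement of diffraction-limited spots: the image minus its
#' Gaussian blur, clipped at zero. Adding a constant offset to the input
#' leaves the output unchanged, since the unit-mass blur reproduces the
#' offset exactly.
#'
#' @inheritParams gaussian_blur
#' @return An `image2d` with the same geometry.
#' @export
dog_enhance <- function(img, sigma) {
  img <- as_image2d(img)
  bl <- gaussian_blur(img, sigma)
  image2d(pmax(img$pixels - bl$pixels, 0),
          pixel_size = img$pixel_size, channel = img$channel)
}

#' Binary median (majority) filter over a disc neighbourhood
#'
#' Each output pixel is the median of the input mask over the disc of the
#' given radius centred on it; for 0/1 data and the odd-sized disc this is a
#' majority vote, which removes isolated pixels and is idempotent on large
#' uniform regions. Edges are handled by replication.
#'
#' @param mask A [binary_mask()] or 0/1 matrix.
#' @param radius Disc radius in pixels (>= 1).
#' @return A `binary_mask`.
#' @export
median_filter_binary <- function(mask, radius) {
  m <- as_mask_matrix(mask)
  if (!is.numeric(radius) || length(radius) != 1L || radius < 1)
    stop("radius must be a single number >= 1", call. = FALSE)
  se <- disc_se(radius)
  binary_mask(cpp_median_binary(m, se$dr, se$dc))
}

#' Binary (distance-transform) watershed object splitting
#'
#' Splits touching objects in a binary mask: the exact Euclidean distance
#' transform is computed inside the foreground, its regional maxima — after
#' suppression of maxima shallower than `h_suppress` via the h-maxima
#' transform (grayscale reconstruction) — seed a Meyer flooding of the
#' inverted distance surface. Every foreground pixel receives exactly one
#' label, so foreground area is conserved; background stays 0.
#'
#' @inheritParams median_filter_binary
#' @param h_suppress Minimum dynamic (in pixels of distance) a distance
#'   maximum must have to seed its own object; shallower maxima are merged
#'   into their neighbours. Default 0.5 px.
#' @param connectivity Pixel connectivity for flooding, 4 or 8.
#' @return A [label_map()].
#' @export
watershed_split <- function(mask, h_suppress = 0.5, connectivity = 8L) {
  m <- as_mask_matrix(mask)
  connectivity <- match.arg(as.character(connectivity), c("8", "4"))
  connectivity <- as.integer(connectivity)
  if (sum(m) == 0L)
    return(label_map(matrix(0L, nrow(m), ncol(m))))
  edt <- sqrt(cpp_edt_sq(m))
  marker <- pmax(edt - h_suppress, 0)
  rec <- cpp_reconstruct_dilate(marker, edt)
  seeds <- cpp_regional_maxima(rec, m)
  lab <- cpp_watershed_seeded(edt, seeds, m, connectivity)
  label_map(lab, relabel = TRUE)
}

#' Connected-particle analysis
#'
#' Labels connected components of a binary mask (or takes an existing label
#' map), measures per-object pixel area and intensity-free centroid, and
#' filters by minimum area and optionally by contact with the image border.
#' Mirrors the "analyze particles" step of desktop image-analysis tools.
#'
#' @param x A `binary_mask`/0-1 matrix or a [label_map()].
#' @param connectivity 4 or 8 (default 8, the usual desktop-tool default).
#' @param min_area_px Objects smaller than this many pixels are dropped.
#' @param max_area_px Optional upper area bound (`Inf` = none).
#' @param exclude_border Drop objects touching the image border.
#' @param pixel_size Physical pixel edge (um) used to add `area_um2`.
#' @return A data.frame with one row per surviving particle, sorted by label:
#'   `label`, `area_px`, `centroid_r`, `centroid_c` (1-based pixel
#'   coordinates), and `area_um2` when `pixel_size` is given.
#' @export
analyze_particles <- function(x, connectivity = 8L, min_area_px = 1L,
                              max_area_px = Inf, exclude_border = FALSE,
                              pixel_size = NULL) {
  connectivity <- as.integer(match.arg(as.character(connectivity), c("8", "4")))
  if (inherits(x, "label_map")) {
    lab <- x$pixels
  } else {
    lab <- cpp_label_components(as_mask_matrix(x), connectivity)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  idx <- which(lab > 0L)
  empty <- data.frame(label = integer(), area_px = integer(),
                      centroid_r = numeric(), centroid_c = numeric())
  if (!is.null(pixel_size)) empty$area_um2 <- numeric()
  if (length(idx) == 0L) return(empty)
  lv <- lab[idx]
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  area <- tabulate(lv)
  labs <- which(area > 0L)
  sum_r <- rowsum(as.numeric(rr), lv)
  sum_c <- rowsum(as.numeric(cc), lv)
  out <- data.frame(label = labs,
                    area_px = area[labs],
                    centroid_r = sum_r[, 1] / area[labs],
                    centroid_c = sum_c[, 1] / area[labs])
  if (exclude_border) {
    border <- (rr == 1L | rr == nr | cc == 1L | cc == nc)
    touching <- unique(lv[border])
    out <- out[!(out$label %in% touching), , drop = FALSE]
  }
  out <- out[out$area_px >= min_area_px & out$area_px <= max_area_px, ,
             drop = FALSE]
  if (!is.null(pixel_size)) out$area_um2 <- out$area_px * pixel_size^2
  rownames(out) <- NULL
  out
}

#' Intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at (approximately) unit-pixel
#' spacing along the segment from `p0` to `p1`, optionally rescaling the
#' profile affinely so its minimum maps to 0 and its maximum to 100.
#'
#' @inheritParams gaussian_blur
#' @param p0,p1 Endpoints as `(row, col)` in 1-based pixel coordinates; both
#'   must lie inside the image.
#' @param normalize Rescale intensities to the 0--100 range.
#' @return A data.frame with columns `position` (distance along the segment,
#'   px) and `intensity`.
#' @export
line_profile <- function(img, p0, p1, normalize = FALSE) {
  img <- as_image2d(img)
  p <- img$pixels
  nr <- nrow(p); nc <- ncol(p)
  chk <- function(pt) {
    length(pt) == 2L && all(is.finite(pt)) &&
      pt[1] >= 1 && pt[1] <= nr && pt[2] >= 1 && pt[2] <= nc
  }
  if (!chk(p0) || !chk(p1))
    stop("profile endpoints must lie inside the image", call. = FALSE)
  d <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, round(d) + 1L)
  tt <- seq(0, 1, length.out = n)
  r <- p0[1] + tt * (p1[1] - p0[1])
  c <- p0[2] + tt * (p1[2] - p0[2])
  r0 <- pmin(pmax(floor(r), 1L), nr - 1L); r1 <- r0 + 1L
  c0 <- pmin(pmax(floor(c), 1L), nc - 1L); c1 <- c0 + 1L
  fr <- r - r0; fc <- c - c0
  if (nr == 1L) { r0 <- r1 <- rep(1L, n); fr <- 0 }
  if (nc == 1L) { c0 <- c1 <- rep(1L, n); fc <- 0 }
  val <- p[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
         p[cbind(r1, c0)] * fr * (1 - fc) +
         p[cbind(r0, c1)] * (1 - fr) * fc +
         p[cbind(r1, c1)] * fr * fc
  if (normalize) {
    rng <- range(val)
    if (diff(rng) <= 1e-12 * max(1, abs(rng[2])))
      stop("degenerate input: constant profile cannot be normalized",
           call. = FALSE)
    val <- (val - rng[1]) / diff(rng) * 100
  }
  data.frame(position = tt * d, intensity = val)
}

#' Mean intensity inside a circular region of interest
#'
#' Arithmetic mean over all pixels whose centers lie within the circle of
#' `radius_px` around `center` (1-based `(row, col)` coordinates).
#'
#' @inheritParams gaussian_blur
#' @param center Circle center `(row, col)`, 1-based pixel coordinates.
#' @param radius_px Circle radius in pixels.
#' @return The mean intensity (a single number).
#' @export
roi_mean_intensity <- function(img, center, radius_px) {
  img <- as_image2d(img)
  p <- img$pixels
  nr <- nrow(p); nc <- ncol(p)
  if (length(center) != 2L || !all(is.finite(center)) || radius_px <= 0)
    stop("center must be (row, col) and radius_px positive", call. = FALSE)
  if (center[1] + radius_px < 1 || center[1] - radius_px > nr ||
      center[2] + radius_px < 1 || center[2] - radius_px > nc)
    stop("circle lies entirely outside the image", call. = FALSE)
  rr <- seq_len(nr); cc <- seq_len(nc)
  inside <- outer((rr - center[1])^2, (cc - center[2])^2, "+") <= radius_px^2
  if (!any(inside))
    stop("circle contains no pixel centers", call. = FALSE)
  mean(p[inside])
}
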