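#' 2D intensity image
#'
#' Lightweight container for a single-channel fluorescence raster: a numeric
#' matrix of non-negative intensities (arbitrary units) plus optional physical
#' pixel size and a free-text channel label.
#'
#' @param pixels Numeric matrix of finite, non-negative intensities.
#' @param pixel_size Physical edge length of one pixel in micrometres, or
#'   `NULL` when unknown.
#' @param channel Free-text channel label (e.g. `"dapi"`, `"pla"`).
#' @return An object of class `image2d` with fields `pixels`, `pixel_size`,
#'   `channel`.
#' @examples
#' img <- image2d(matrix(runif(64), 8, 8), pixel_size = 0.1, channel = "dapi")
#' dim(img$pixels)
#' @export
image2d <- function(pixels, pixel_size = NULL, channel = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L || ncol(pixels) < 1L)
    stop("image must be at least 1x1", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must all be finite", call. = FALSE)
  if (any(pixels < 0))
    stop("image intensities must be non-negative", call. = FALSE)
  if (!is.null(pixel_size)) {
    pixel_size <- as.numeric(pixel_size)
    if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0)
      stop("pixel_size must be a single positive number", call. = FALSE)
  }
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 channel = channel),
            class = "image2d")
}

#' Coerce to an image2d
#'
#' @param x A numeric matrix or an existing `image2d`.
#' @param ... Passed to [image2d()] when constructing from a matrix.
#' @return An `image2d`.
#' @export
as_image2d <- function(x, ...) {
  if (inherits(x, "image2d")) return(x)
  image2d(x, ...)
}

#' @export
print.image2d <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image2d> %d x %d px", d[1], d[2]))
  if (!is.null(x$channel)) cat(sprintf(", channel '%s'", x$channel))
  if (!is.null(x$pixel_size)) cat(sprintf(", %.4g um/px", x$pixel_size))
  cat(sprintf(", intensity range [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask sharing the geometry of a source image
#'
#' @param pixels Matrix of 0/1 (or logical) values.
#' @return Integer matrix of 0/1 with class `binary_mask`.
#' @export
binary_mask <- function(pixels) {
  pixels <- as.matrix(pixels)
  if (is.logical(pixels)) pixels <- pixels * 1L
  storage.mode(pixels) <- "integer"
  if (!all(pixels %in% c(0L, 1L)))
    stop("mask pixels must be 0 or 1", call. = FALSE)
  structure(pixels, class = c("binary_mask", class(matrix())))
}

as_mask_matrix <- function(mask) {
  m <- as.matrix(unclass(mask))
  if (is.logical(m)) m <- m * 1L
  storage.mode(m) <- "integer"
  if (!all(m %in% c(0L, 1L)))
    stop("mask pixels must be 0 or 1", call. = FALSE)
  m
}

#' Integer label map
#'
#' Stores an object segmentation: 0 marks background, k marks object k, with
#' labels forming a contiguous range `1..n_labels`.
#'
#' @param pixels Integer matrix of non-negative labels.
#' @param relabel Renumber positive labels to a contiguous `1..n` range
#'   (preserving their order of first appearance in column-major scan).
#' @return An object of class `label_map` with fields `pixels`, `n_labels`.
#' @export
label_map <- function(pixels, relabel = FALSE) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "integer"
  if (any(pixels < 0L)) stop("labels must be non-negative", call. = FALSE)
  pos <- sort(unique(pixels[pixels > 0L]))
  if (relabel && length(pos) > 0L && !identical(pos, seq_along(pos))) {
    lut <- integer(max(pos))
    lut[pos] <- seq_along(pos)
    pixels[pixels > 0L] <- lut[pixels[pixels > 0L]]
    pos <- seq_along(pos)
  }
  if (length(pos) > 0L && !identical(pos, seq_along(pos)))
    stop("labels must form a contiguous range 1..n_labels", call. = FALSE)
  structure(list(pixels = pixels, n_labels = length(pos)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d object(s)\n",
              nrow(x$pixels), ncol(x$pixels), x$n_labels))
  invisible(x)
}

pixels_of <- function(x) {
  if (inherits(x, "image2d")) x$pixels
  else if (inherits(x, "label_map")) x$pixels
  else as.matrix(x)
}
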