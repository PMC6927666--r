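#' Configuration of the PLA quantification pipeline
#'
#' Bundles the tunable parameters of the punctum-quantification algorithm.
#' The defaults are the published parameter set of the high-content analysis
#' this package implements: Gaussian sigma 2 px for nucleus smoothing and for
#' the punctum difference-of-Gaussians, rolling-ball radius 50 px, median
#' radius 2 px. Size filters and connectivity are exposed because the
#' original description leaves them open.
#'
#' @param nucleus_sigma Gaussian sigma (px) for DAPI smoothing.
#' @param ball_radius Rolling-ball radius (px) for PLA background removal.
#' @param dog_sigma Gaussian sigma (px) of the punctum-enhancement blur.
#' @param median_radius Radius (px) of the binary median filter applied to
#'   the thresholded punctum mask.
#' @param nucleus_min_area_px Minimum nucleus area (px); rejects debris.
#' @param spot_min_area_px,spot_max_area_px Punctum area filters (px); the
#'   2-px floor removes residual single detections the median filter
#'   missed.
#' @param connectivity Pixel connectivity (4 or 8) for nucleus particle
#'   analysis (8 is the usual desktop-tool default for large objects).
#' @param spot_connectivity Pixel connectivity for punctum particle
#'   analysis. Defaults to 4: after the disc-median majority filter, true
#'   diffraction-limited puncta are compact (edge-connected) blobs, whereas
#'   diagonal-only pixel pairs are characteristic of surviving noise
#'   residuals, so 4-connectivity drops the latter without touching real
#'   puncta.
#' @param spot_exclude_border Drop puncta touching the image border
#'   (default TRUE): the filtering chain replicates edge pixels, so the
#'   one-pixel frame can carry subtraction artifacts, and border puncta are
#'   only partially observed.
#' @param nucleus_grow_px Optional isotropic grow (> 0) or shrink (< 0) of
#'   the nucleus mask, in px, applied before punctum classification. Default
#'   0 (no adjustment).
#' @param watershed_h Dynamic (px) below which distance-transform maxima are
#'   merged when splitting touching nuclei.
#' @return A list of class `pla_config`.
#' @export
pla_config <- function(nucleus_sigma = 2, ball_radius = 50, dog_sigma = 2,
                       median_radius = 2, nucleus_min_area_px = 200L,
                       spot_min_area_px = 2L, spot_max_area_px = Inf,
                       connectivity = 8L, spot_connectivity = 4L,
                       spot_exclude_border = TRUE,
                       nucleus_grow_px = 0, watershed_h = 0.5) {
  stopifnot(nucleus_sigma > 0, ball_radius >= 1, dog_sigma > 0,
            median_radius >= 1, nucleus_min_area_px >= 1,
            spot_min_area_px >= 1, spot_max_area_px >= spot_min_area_px,
            connectivity %in% c(4L, 8L), spot_connectivity %in% c(4L, 8L),
            watershed_h >= 0)
  structure(list(nucleus_sigma = nucleus_sigma, ball_radius = ball_radius,
                 dog_sigma = dog_sigma, median_radius = median_radius,
                 nucleus_min_area_px = as.integer(nucleus_min_area_px),
                 spot_min_area_px = as.integer(spot_min_area_px),
                 spot_max_area_px = spot_max_area_px,
                 connectivity = as.integer(connectivity),
                 spot_connectivity = as.integer(spot_connectivity),
                 spot_exclude_border = isTRUE(spot_exclude_border),
                 nucleus_grow_px = nucleus_grow_px,
                 watershed_h = watershed_h),
            class = "pla_config")
}

check_nonconstant <- function(img, what) {
  p <- pixels_of(img)
  if (max(p) <= min(p))
    stop(sprintf("degenerate input: %s channel is constant", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Segment nuclei from a DAPI channel
#'
#' The nucleus branch of the PLA algorithm: Gaussian blur (sigma =
#' `cfg$nucleus_sigma`), Huang auto-threshold, binary watershed to split
#' touching nuclei, then particle analysis with the minimum-area filter so
#' only individual, well-separated nuclei are counted.
#'
#' @param dapi Nuclear-stain channel, [image2d()] or matrix.
#' @param cfg A [pla_config()].
#' @return A list with `nuclei` (a [label_map()] containing only surviving
#'   nuclei, relabelled 1..n), `n_nuclei`, and `particles` (per-nucleus
#'   measurement data.frame).
#' @export
segment_nuclei <- function(dapi, cfg = pla_config()) {
  dapi <- as_image2d(dapi)
  check_nonconstant(dapi, "nuclear-stain")
  sm <- gaussian_blur(dapi, cfg$nucleus_sigma)
  thr <- threshold_huang(sm)
  mask <- binary_mask(sm$pixels > thr)
  lab <- watershed_split(mask, h_suppress = cfg$watershed_h,
                         connectivity = cfg$connectivity)
  parts <- analyze_particles(lab, connectivity = cfg$connectivity,
                             min_area_px = cfg$nucleus_min_area_px,
                             pixel_size = dapi$pixel_size)
  keep <- parts$label
  px <- lab$pixels
  px[!(px %in% keep)] <- 0L
  nuclei <- label_map(px, relabel = TRUE)
  parts$label <- seq_len(nrow(parts))
  list(nuclei = nuclei, n_nuclei = nuclei$n_labels, particles = parts)
}

#' Detect PLA puncta
#'
#' The punctum branch of the PLA algorithm: rolling-ball background
#' subtraction (radius `cfg$ball_radius`), difference-of-Gaussians
#' enhancement (subtracting the sigma = `cfg$dog_sigma` blur), isodata
#' ("default") auto-threshold, binary median filter (radius
#' `cfg$median_radius`) to discriminate individual particles, then particle
#' analysis with the punctum size filters.
#'
#' @param pla PLA-signal channel, [image2d()] or matrix.
#' @inheritParams segment_nuclei
#' @return Particle data.frame as from [analyze_particles()].
#' @export
detect_pla_spots <- function(pla, cfg = pla_config()) {
  pla <- as_image2d(pla)
  check_nonconstant(pla, "PLA")
  bg <- rolling_ball_subtract(pla, cfg$ball_radius)
  hp <- dog_enhance(bg, cfg$dog_sigma)
  # structureless image: the enhanced contrast is a negligible fraction of
  # the channel's dynamic range (numerical residue of background removal,
  # e.g. a pure gradient), so there is nothing punctate to threshold
  rng <- diff(range(pla$pixels))
  if (max(hp$pixels) <= min(hp$pixels) || max(hp$pixels) <= 1e-3 * rng) {
    # no structure left after background removal: no detectable puncta
    return(analyze_particles(matrix(0L, nrow(pla$pixels), ncol(pla$pixels)),
                             connectivity = cfg$spot_connectivity,
                             pixel_size = pla$pixel_size))
  }
  thr <- threshold_isodata_default(hp)
  mask <- binary_mask(hp$pixels > thr)
  mask <- median_filter_binary(mask, cfg$median_radius)
  analyze_particles(mask, connectivity = cfg$spot_connectivity,
                    min_area_px = cfg$spot_min_area_px,
                    max_area_px = cfg$spot_max_area_px,
                    exclude_border = cfg$spot_exclude_border,
                    pixel_size = pla$pixel_size)
}

grow_labels <- function(lab, grow_px) {
  px <- lab$pixels
  if (grow_px > 0) {
    fg <- (px > 0L) * 1L
    storage.mode(fg) <- "integer"
    # assign background pixels within grow_px of an object to that object
    inv <- 1L - fg
    d2 <- cpp_edt_sq(inv)          # distance of bg pixels to nearest fg
    near <- inv == 1L & d2 <= grow_px^2
    lab2 <- cpp_watershed_seeded(-sqrt(d2), px, (fg | near) * 1L, 8L)
    label_map(lab2, relabel = FALSE)
  } else if (grow_px < 0) {
    fg <- (px > 0L) * 1L
    storage.mode(fg) <- "integer"
    d2 <- cpp_edt_sq(fg)
    px[sqrt(d2) <= -grow_px] <- 0L
    label_map(px, relabel = FALSE)
  } else lab
}

#' Partition puncta into nuclear and cytosolic compartments
#'
#' A punctum is nuclear when its centroid pixel (rounded to the nearest
#' integer coordinates) carries a positive nucleus label; every other
#' punctum is cytosolic. This centroid-containment rule makes the counts a
#' clean partition: `n_nuclear + n_cytosolic == n_total` always.
#'
#' @param spots Particle data.frame (from [detect_pla_spots()]).
#' @param nuclei Nucleus [label_map()] (from [segment_nuclei()]).
#' @param image_dim Optional `(rows, cols)` of the spots' source image; when
#'   given it must match the nucleus map geometry.
#' @param n_nuclei Optional nucleus count to carry into the result.
#' @param image_id Optional identifier carried into the result.
#' @return A list of class `pla_result` with fields `spots` (data.frame with
#'   added `compartment` column), `n_nuclei`, `n_nuclear`, `n_cytosolic`,
#'   `n_total`, `ratio_nuc_cyt` (NA with `ratio_defined = FALSE` when no
#'   cytosolic puncta), and `image_id`.
#' @export
classify_spots <- function(spots, nuclei, image_dim = NULL,
                           n_nuclei = NULL, image_id = NULL) {
  stopifnot(inherits(nuclei, "label_map"))
  nd <- dim(nuclei$pixels)
  if (!is.null(image_dim) && !identical(as.integer(image_dim), nd))
    stop("geometry mismatch between spot source image and nucleus map",
         call. = FALSE)
  if (nrow(spots) > 0) {
    r <- pmin(pmax(round(spots$centroid_r), 1L), nd[1])
    c <- pmin(pmax(round(spots$centroid_c), 1L), nd[2])
    if (any(spots$centroid_r < 1 | spots$centroid_r > nd[1] |
            spots$centroid_c < 1 | spots$centroid_c > nd[2]))
      stop("spot centroid outside nucleus-map bounds", call. = FALSE)
    nuclear <- nuclei$pixels[cbind(r, c)] > 0L
    spots$compartment <- ifelse(nuclear, "nuclear", "cytosolic")
  } else {
    spots$compartment <- character(0)
  }
  n_nuc <- sum(spots$compartment == "nuclear")
  n_cyt <- sum(spots$compartment == "cytosolic")
  structure(list(spots = spots,
                 n_nuclei = if (is.null(n_nuclei)) NA_integer_
                            else as.integer(n_nuclei),
                 n_nuclear = n_nuc, n_cytosolic = n_cyt,
                 n_total = n_nuc + n_cyt,
                 ratio_nuc_cyt = if (n_cyt > 0) n_nuc / n_cyt else NA_real_,
                 ratio_defined = n_cyt > 0,
                 image_id = image_id),
            class = "pla_result")
}

#' @export
print.pla_result <- function(x, ...) {
  cat(sprintf("<pla_result>%s %d nuclei; puncta: %d nuclear + %d cytosolic = %d total",
              if (is.null(x$image_id)) "" else sprintf(" [%s]", x$image_id),
              x$n_nuclei, x$n_nuclear, x$n_cytosolic, x$n_total))
  if (x$ratio_defined)
    cat(sprintf("; nuc:cyt ratio %.3f\n", x$ratio_nuc_cyt))
  else cat("; nuc:cyt ratio undefined (no cytosolic puncta)\n")
  invisible(x)
}

#' Quantify one PLA image pair
#'
#' End-to-end quantification of the nuclear vs cytosolic PLA signal of one
#' field of view: nuclei are segmented from the DAPI channel
#' ([segment_nuclei()]), puncta detected in the PLA channel
#' ([detect_pla_spots()]), and each punctum assigned to a compartment
#' ([classify_spots()]).
#'
#' @param dapi Nuclear-stain channel.
#' @param pla PLA-signal channel (same geometry).
#' @inheritParams segment_nuclei
#' @param image_id Optional identifier carried into the result.
#' @return A `pla_result` (see [classify_spots()]); additionally carries
#'   `spots_per_nucleus`, the nuclear count normalized per segmented
#'   nucleus.
#' @export
quantify_pla_image <- function(dapi, pla, cfg = pla_config(),
                               image_id = NULL) {
  dapi <- as_image2d(dapi); pla <- as_image2d(pla)
  if (!identical(dim(dapi$pixels), dim(pla$pixels)))
    stop("DAPI and PLA channels must share geometry", call. = FALSE)
  seg <- segment_nuclei(dapi, cfg)
  nuclei <- grow_labels(seg$nuclei, cfg$nucleus_grow_px)
  spots <- detect_pla_spots(pla, cfg)
  res <- classify_spots(spots, nuclei, image_dim = dim(pla$pixels),
                        n_nuclei = seg$n_nuclei, image_id = image_id)
  res$spots_per_nucleus <-
    if (seg$n_nuclei > 0) res$n_total / seg$n_nuclei else NA_real_
  res
}

#' Summarize a batch of PLA results by condition
#'
#' Aggregates per-image counts into a per-condition table (mean and SD of
#' nuclear, cytosolic and total counts, the per-image nuclear:cytosolic
#' ratio, and per-nucleus normalized counts). Hypothesis testing is left to
#' downstream statistics software.
#'
#' @param results List of `pla_result` objects.
#' @param conditions Character vector, one condition label per result.
#' @return A list with `per_image` (one row per image) and `per_condition`
#'   (mean/SD table) data.frames.
#' @export
summarize_pla_batch <- function(results, conditions) {
  stopifnot(length(results) == length(conditions), length(results) > 0)
  per_image <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(image_id = if (is.null(r$image_id)) sprintf("img%03d", i)
                          else as.character(r$image_id),
               condition = conditions[i],
               n_nuclei = r$n_nuclei, n_nuclear = r$n_nuclear,
               n_cytosolic = r$n_cytosolic, n_total = r$n_total,
               ratio_nuc_cyt = r$ratio_nuc_cyt,
               spots_per_nucleus = if (is.null(r$spots_per_nucleus))
                 NA_real_ else r$spots_per_nucleus)
  }))
  agg <- function(v, f) tapply(v, per_image$condition, f)
  conds <- sort(unique(per_image$condition))
  per_condition <- data.frame(
    condition = conds,
    n_images = as.vector(table(per_image$condition)[conds]),
    mean_nuclear = as.vector(agg(per_image$n_nuclear, mean)[conds]),
    sd_nuclear = as.vector(agg(per_image$n_nuclear, sd)[conds]),
    mean_cytosolic = as.vector(agg(per_image$n_cytosolic, mean)[conds]),
    sd_cytosolic = as.vector(agg(per_image$n_cytosolic, sd)[conds]),
    mean_total = as.vector(agg(per_image$n_total, mean)[conds]),
    sd_total = as.vector(agg(per_image$n_total, sd)[conds]),
    mean_ratio = as.vector(agg(per_image$ratio_nuc_cyt,
                               function(v) mean(v, na.rm = TRUE))[conds]),
    sd_ratio = as.vector(agg(per_image$ratio_nuc_cyt,
                             function(v) sd(v, na.rm = TRUE))[conds]))
  list(per_image = per_image, per_condition = per_condition)
}

#' Fill holes in a binary mask
#'
#' Background regions not connected to the image border are converted to
#' foreground (4-connectivity for the background, the complement of
#' 8-connected objects).
#'
#' @inheritParams median_filter_binary
#' @return A `binary_mask`.
#' @export
fill_holes <- function(mask) {
  m <- as_mask_matrix(mask)
  inv <- 1L - m
  lab <- cpp_label_components(inv, 4L)
  nr <- nrow(lab); nc <- ncol(lab)
  border_labels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  hole <- lab > 0L & !(lab %in% border_labels)
  m[hole] <- 1L
  binary_mask(m)
}

#' Measure per-cell spreading area from a membrane stain
#'
#' Threshold-and-measure estimate of cell spreading: Gaussian blur (sigma
#' 2), isodata (intermeans) auto-threshold, hole filling, then particle
#' analysis excluding border-touching objects and objects below the
#' minimum area. The intermeans threshold converges to the midpoint of the
#' background and cell plateau intensities, which is the area-preserving
#' 50% level of a symmetrically blurred edge — so measured areas track the
#' true footprint instead of the blur skirt (an entropy-based threshold
#' sits near the dominant background mode and systematically dilates small
#' cells).
#'
#' @param membrane Membrane/whole-cell stain channel.
#' @inheritParams segment_nuclei
#' @param min_area_px Minimum cell area in px.
#' @return A list of class `spread_result`: `areas_px`, `areas_um2` (NULL
#'   when pixel size unknown), `mean_area_px`, `n_cells`, `particles`.
#' @export
measure_spread_area <- function(membrane, cfg = pla_config(),
                                min_area_px = 50L) {
  membrane <- as_image2d(membrane)
  check_nonconstant(membrane, "membrane")
  sm <- gaussian_blur(membrane, 2)
  thr <- threshold_isodata_default(sm, trim_extremes = FALSE)
  mask <- fill_holes(binary_mask(sm$pixels > thr))
  parts <- analyze_particles(mask, connectivity = cfg$connectivity,
                             min_area_px = min_area_px,
                             exclude_border = TRUE,
                             pixel_size = membrane$pixel_size)
  structure(list(areas_px = parts$area_px,
                 areas_um2 = if (!is.null(membrane$pixel_size))
                   parts$area_um2 else NULL,
                 mean_area_px = if (nrow(parts) > 0) mean(parts$area_px)
                                else NA_real_,
                 n_cells = nrow(parts), particles = parts),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result> %d cell(s), mean area %.1f px\n",
              x$n_cells, x$mean_area_px))
  invisible(x)
}
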