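#' Reconstruct a quantitative-imaging (QI) stiffness and height map
#'
#' Runs the per-pixel force-curve pipeline (baseline correction, contact
#' detection, force-indentation conversion, conical Sneddon fit by default)
#' over a rectangular grid of force curves and assembles the fitted Young's
#' moduli and contact heights into maps. Pixels whose curve cannot be
#' analyzed (no contact, failed fit) are recorded as missing (`NA`), never
#' as zero, so map statistics are not biased.
#'
#' @param grid A `qi_grid` from [make_qi_grid()], or a list with `curves`
#'   (list of [force_curve()] in column-major order), `nrow`, `ncol`, and
#'   optionally `scan_size_um`.
#' @param probe A [probe_spec()] applied to every pixel (defaults to each
#'   curve's own probe).
#' @param fit_depth Maximum indentation per pixel, nm (default: full
#'   indentation at the applied load).
#' @param ... Passed to [analyze_cfs_curve()].
#' @return A list of class `qi_map`: `E` (Pa matrix, NA = failed pixel),
#'   `contact_z` (nm matrix), `height_nm` (sample height above the lowest
#'   recovered contact point; taller features contact the probe at smaller
#'   piezo extension), `r_squared`, `n_failed`, `scan_size_um`.
#' @export
reconstruct_qi_map <- function(grid, probe = NULL, fit_depth = NULL, ...) {
  if (!is.list(grid) || is.null(grid$curves) || is.null(grid$nrow) ||
      is.null(grid$ncol))
    stop("grid must provide curves, nrow and ncol", call. = FALSE)
  nr <- grid$nrow; nc <- grid$ncol
  if (length(grid$curves) != nr * nc)
    stop("ragged grid: expected ", nr * nc, " curves, got ",
         length(grid$curves), call. = FALSE)
  E <- matrix(NA_real_, nr, nc)
  cz <- matrix(NA_real_, nr, nc)
  r2 <- matrix(NA_real_, nr, nc)
  dots <- list(...)
  ncf <- if (is.null(dots$noncontact_fraction)) 0.3
         else dots$noncontact_fraction
  tsd <- if (is.null(dots$threshold_sds)) 3 else dots$threshold_sds
  per <- if (is.null(dots$persistence)) 10L else dots$persistence
  for (i in seq_len(nr * nc)) {
    cur <- grid$curves[[i]]
    pb <- if (is.null(probe)) cur$probe else probe
    r <- ((i - 1L) %% nr) + 1L
    c <- ((i - 1L) %/% nr) + 1L
    # stage 1: contact height (valid even when the elasticity fit fails,
    # e.g. on a rigid substrate)
    stage1 <- tryCatch({
      bc <- baseline_correct(cur, ncf)
      bc$probe <- pb
      cp <- find_contact_point(bc, threshold_sds = tsd, persistence = per,
                               noncontact_fraction = ncf)
      list(bc = bc, cp = cp)
    }, error = function(e) NULL)
    if (is.null(stage1)) next
    cz[r, c] <- stage1$cp$contact_z
    # stage 2: elasticity fit
    fit <- tryCatch({
      ind <- to_force_indentation(stage1$bc, stage1$cp)
      if (is.null(pb)) stop("no probe specification")
      if (pb$geometry == "sphere")
        fit_hertz_sphere(ind, pb,
                         if (is.null(fit_depth)) 50 else fit_depth)
      else
        fit_sneddon_cone(ind, pb,
                         if (is.null(fit_depth)) Inf else fit_depth)
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      E[r, c] <- fit$E
      r2[r, c] <- fit$r_squared
    }
  }
  height <- if (any(is.finite(cz))) max(cz, na.rm = TRUE) - cz
            else cz
  structure(list(E = E, contact_z = cz, height_nm = height,
                 r_squared = r2, n_failed = sum(is.na(E)),
                 scan_size_um = grid$scan_size_um),
            class = "qi_map")
}

#' @export
print.qi_map <- function(x, ...) {
  cat(sprintf("<qi_map> %d x %d px, E range [%.3g, %.3g] Pa, %d failed pixel(s)\n",
              nrow(x$E), ncol(x$E),
              suppressWarnings(min(x$E, na.rm = TRUE)),
              suppressWarnings(max(x$E, na.rm = TRUE)), x$n_failed))
  invisible(x)
}

as_path_matrix <- function(path) {
  p <- if (is.matrix(path)) path else matrix(path, ncol = 2, byrow = TRUE)
  storage.mode(p) <- "integer"
  p
}

#' Height difference between two pixel paths of a QI map
#'
#' Mean sample height along path A minus mean height along path B (for
#' example a path over the nucleus versus one over a cell-cell junction),
#' returned in micrometres.
#'
#' @param map A `qi_map`.
#' @param path_a,path_b Pixel paths: n x 2 integer matrices of `(row, col)`
#'   (or vectors `c(r1, c1, r2, c2, ...)`).
#' @return Height difference in um (positive when path A is higher).
#' @export
height_profile_difference <- function(map, path_a, path_b) {
  stopifnot(inherits(map, "qi_map"))
  a <- as_path_matrix(path_a); b <- as_path_matrix(path_b)
  nr <- nrow(map$height_nm); nc <- ncol(map$height_nm)
  chk <- function(p) all(p[, 1] >= 1 & p[, 1] <= nr &
                         p[, 2] >= 1 & p[, 2] <= nc)
  if (!chk(a) || !chk(b))
    stop("path lies outside the map grid", call. = FALSE)
  ha <- map$height_nm[a]
  hb <- map$height_nm[b]
  if (all(is.na(ha)) || all(is.na(hb)))
    stop("path covers only failed pixels", call. = FALSE)
  (mean(ha, na.rm = TRUE) - mean(hb, na.rm = TRUE)) / 1000
}
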