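#' Indenter probe specification
#'
#' Geometry and material assumptions of the AFM probe/sample pair used by
#' the elasticity fits: a colloidal sphere (Hertz model) needs a radius; a
#' conical tip (Sneddon model) needs a half-opening angle. The sample
#' Poisson ratio defaults to 0.5 (incompressible, the standard assumption
#' for cell surfaces).
#'
#' @param geometry `"sphere"` or `"cone"`.
#' @param R Sphere radius in nm (sphere only).
#' @param half_angle Cone half-opening angle in degrees (cone only),
#'   strictly between 0 and 90.
#' @param nu Sample Poisson ratio, in `[0, 0.5]`.
#' @return A list of class `probe_spec`.
#' @examples
#' probe_spec("sphere", R = 11500)        # colloidal probe
#' probe_spec("cone", half_angle = 17.5)  # sharp pyramidal/conical tip
#' @export
probe_spec <- function(geometry = c("sphere", "cone"), R = NULL,
                       half_angle = NULL, nu = 0.5) {
  geometry <- match.arg(geometry)
  if (!is.numeric(nu) || length(nu) != 1L || nu < 0 || nu > 0.5 + 1e-9)
    stop("nu must be in [0, 0.5]", call. = FALSE)
  if (geometry == "sphere") {
    if (is.null(R) || !is.numeric(R) || R <= 0)
      stop("a spherical probe needs a positive radius R (nm)", call. = FALSE)
    half_angle <- NULL
  } else {
    if (is.null(half_angle) || !is.numeric(half_angle) ||
        half_angle <= 0 || half_angle >= 90)
      stop("a conical probe needs a half_angle strictly between 0 and 90 degrees",
           call. = FALSE)
    R <- NULL
  }
  structure(list(geometry = geometry, R = R, half_angle = half_angle,
                 nu = nu), class = "probe_spec")
}

#' Raw AFM force-distance curve
#'
#' One approach or retract segment of a force-distance cycle: piezo
#' displacement `z` (nm, increasing toward the sample) versus cantilever
#' deflection (photodiode volts, or nm if already calibrated), with the
#' calibration metadata needed to convert to force.
#'
#' @param z Piezo displacement samples in nm; strictly monotone.
#' @param deflection Cantilever deflection samples, same length as `z`.
#' @param k Cantilever spring constant in N/m.
#' @param sensitivity Deflection sensitivity in nm/V, or NULL until
#'   calibrated (required when `deflection_unit = "V"` for force
#'   conversion).
#' @param segment `"approach"` or `"retract"`.
#' @param probe A [probe_spec()], or NULL.
#' @param deflection_unit `"V"` (raw photodiode) or `"nm"`.
#' @return A list of class `force_curve`.
#' @export
force_curve <- function(z, deflection, k, sensitivity = NULL,
                        segment = c("approach", "retract"), probe = NULL,
                        deflection_unit = c("V", "nm")) {
  segment <- match.arg(segment)
  deflection_unit <- match.arg(deflection_unit)
  z <- as.numeric(z); deflection <- as.numeric(deflection)
  if (length(z) != length(deflection) || length(z) < 10L)
    stop("z and deflection must be equal length >= 10", call. = FALSE)
  dz <- diff(z)
  if (!(all(dz > 0) || all(dz < 0)))
    stop("z must be strictly monotone within a segment", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || k <= 0)
    stop("spring constant k must be positive (N/m)", call. = FALSE)
  if (!is.null(sensitivity) &&
      (!is.numeric(sensitivity) || sensitivity <= 0))
    stop("sensitivity must be positive (nm/V)", call. = FALSE)
  if (!is.null(probe) && !inherits(probe, "probe_spec"))
    stop("probe must be a probe_spec", call. = FALSE)
  structure(list(z = z, deflection = deflection, k = k,
                 sensitivity = sensitivity, segment = segment,
                 probe = probe, deflection_unit = deflection_unit),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("<force_curve> %s, %d samples, z [%.0f, %.0f] nm, k = %g N/m%s\n",
              x$segment, length(x$z), min(x$z), max(x$z), x$k,
              if (is.null(x$sensitivity)) ""
              else sprintf(", sens = %g nm/V", x$sensitivity)))
  invisible(x)
}

# deflection in nm regardless of recorded unit
deflection_nm <- function(curve) {
  if (curve$deflection_unit == "nm") return(curve$deflection)
  if (is.null(curve$sensitivity))
    stop("deflection recorded in V but no sensitivity (nm/V) available",
         call. = FALSE)
  curve$deflection * curve$sensitivity
}

# samples reordered so z increases (probe moving toward the sample)
approach_order <- function(curve) order(curve$z)

#' Calibrate deflection sensitivity on a rigid substrate
#'
#' On a hard surface (mica, glass) all piezo travel past contact goes into
#' cantilever bending, so deflection is linear in z with slope 1/sensitivity
#' (V per nm). The contact region is auto-selected as the samples in the
#' upper half of the deflection range, and the inverse slope of a linear fit
#' there is returned.
#'
#' @param hard_curve A [force_curve()] acquired on a rigid substrate, with
#'   deflection in V (a curve already in nm yields sensitivity 1).
#' @return Deflection sensitivity in nm/V.
#' @export
calibrate_sensitivity <- function(hard_curve) {
  stopifnot(inherits(hard_curve, "force_curve"))
  d <- hard_curve$deflection
  z <- hard_curve$z
  rng <- range(d)
  if (diff(rng) <= 0 || diff(rng) < 1e-12 * max(1, abs(rng[2])))
    stop("calibration error: no contact region detectable (flat deflection)",
         call. = FALSE)
  sel <- d >= rng[1] + 0.5 * diff(rng)
  if (sum(sel) < 3L)
    stop("calibration error: too few contact-region samples", call. = FALSE)
  fit <- lm(d[sel] ~ z[sel])
  slope <- coef(fit)[[2]]
  if (!is.finite(slope) || slope <= 0)
    stop("calibration error: non-positive contact slope", call. = FALSE)
  1 / slope
}

#' Baseline-correct the non-contact region of a force curve
#'
#' Fits a line to the declared fraction of samples farthest from the sample
#' (lowest z) and subtracts it from the whole deflection trace, so the
#' free-of-contact deflection averages zero. The window is checked for
#' residual curvature: if a quadratic term deviates from the linear fit by
#' more than `curvature_tol` times the residual noise, the window is judged
#' not free of contact and an error is raised.
#'
#' @param curve A [force_curve()].
#' @param noncontact_fraction Fraction of samples (from the far end) used
#'   for the baseline fit, in `(0, 0.9]`.
#' @param curvature_tol Curvature-to-noise ratio above which the window is
#'   rejected as containing contact.
#' @return The corrected `force_curve`, with `baseline_params = c(intercept,
#'   slope)` (deflection units vs nm) recording the removed line.
#' @export
baseline_correct <- function(curve, noncontact_fraction = 0.3,
                             curvature_tol = 10) {
  stopifnot(inherits(curve, "force_curve"))
  if (!is.numeric(noncontact_fraction) || noncontact_fraction <= 0 ||
      noncontact_fraction > 0.9)
    stop("noncontact_fraction must be in (0, 0.9]", call. = FALSE)
  ord <- approach_order(curve)
  n <- length(curve$z)
  nw <- max(5L, floor(n * noncontact_fraction))
  idx <- ord[seq_len(nw)]
  zf <- curve$z[idx]; df <- curve$deflection[idx]
  fit1 <- lm(df ~ zf)
  fit2 <- lm(df ~ zf + I(zf^2))
  noise <- sd(residuals(fit2))
  span <- diff(range(zf))
  curv_dev <- abs(coef(fit2)[[3]]) * (span / 2)^2
  if (curv_dev > curvature_tol * (noise + 1e-15))
    stop("baseline window does not look free of contact (systematic curvature)",
         call. = FALSE)
  b <- coef(fit1)
  corrected <- curve$deflection - (b[[1]] + b[[2]] * curve$z)
  out <- curve
  out$deflection <- corrected
  out$baseline_params <- c(intercept = b[[1]], slope = b[[2]])
  out
}

#' Locate the probe-sample contact point
#'
#' Two-stage rule on a baseline-corrected curve: (1) walking toward the
#' sample, contact is provisionally the last sample before the deflection
#' first exceeds `threshold_sds` times the baseline noise SD and stays above
#' it for `persistence` consecutive samples; (2) the estimate is refined by
#' back-extrapolating a linearized contact-region fit to zero force:
#' \eqn{F^{1/\gamma}} is linear in tip-sample separation \eqn{s = z -
#' d_{nm}} for a contact law \eqn{F \propto \delta^\gamma} (\eqn{\gamma} =
#' 3/2 for a sphere, 2 for a cone), and the line's root gives the contact
#' position.
#'
#' @param curve A baseline-corrected [force_curve()].
#' @param threshold_sds Detection threshold as a multiple of baseline noise
#'   SD.
#' @param persistence Number of consecutive above-threshold samples required.
#' @param noncontact_fraction Fraction of far-end samples used to estimate
#'   the baseline noise SD.
#' @param refine_max_fraction Upper end of the contact-region fit window, as
#'   a fraction of the maximum deflection.
#' @return A list with `contact_index` (index into the approach-ordered
#'   samples of the last pre-contact sample), `contact_z` (refined contact
#'   position, nm), and `noise_sd`.
#' @export
find_contact_point <- function(curve, threshold_sds = 3, persistence = 10L,
                               noncontact_fraction = 0.3,
                               refine_max_fraction = 0.8) {
  stopifnot(inherits(curve, "force_curve"))
  ord <- approach_order(curve)
  z <- curve$z[ord]; d <- curve$deflection[ord]
  n <- length(z)
  nw <- max(5L, floor(n * noncontact_fraction))
  noise <- sd(d[seq_len(nw)])
  dmax <- max(d)
  if (dmax <= 0) stop("no contact: deflection never rises", call. = FALSE)
  thr <- max(threshold_sds * noise, 1e-6 * dmax)
  above <- d > thr
  persistence <- max(1L, min(as.integer(persistence), n))
  run <- stats::filter(as.numeric(above), rep(1, persistence),
                       sides = 1)
  hit <- which(run == persistence)
  if (length(hit) == 0)
    stop("no contact: force never exceeds the detection threshold",
         call. = FALSE)
  first_above <- hit[1] - persistence + 1L
  ci <- max(first_above - 1L, 1L)
  # refinement: linearized back-extrapolation to zero force
  gamma <- 1.5
  if (!is.null(curve$probe) && identical(curve$probe$geometry, "cone"))
    gamma <- 2
  d_nm <- if (curve$deflection_unit == "nm") d
          else if (!is.null(curve$sensitivity)) d * curve$sensitivity
          else d * 0 # unknown sensitivity: neglect bending in separation
  s <- z - d_nm
  win <- which(d > thr & d <= refine_max_fraction * dmax & seq_len(n) >= ci)
  contact_z <- z[ci]
  if (length(win) >= 5L) {
    y <- pmax(d[win], 0)^(1 / gamma)
    # weight by the inverse variance of d^(1/gamma) under additive force
    # noise: var(y) ~ d^(2/gamma - 2), so w ~ d^(2 - 2/gamma)
    w <- pmax(d[win], 0)^(2 - 2 / gamma)
    fit <- lm(y ~ s[win], weights = w)
    sl <- coef(fit)[[2]]
    if (is.finite(sl) && sl > 0) {
      z0 <- -coef(fit)[[1]] / sl
      # accept the refinement only if it lands inside the sampled range
      if (z0 > min(z) && z0 < max(z)) {
        contact_z <- z0
        ci <- max(c(1L, which(s <= z0)))
      }
    }
  }
  list(contact_index = ci, contact_z = contact_z, noise_sd = noise)
}

#' Convert a force-distance curve to a force-indentation curve
#'
#' Post-contact samples are converted to force \eqn{F = k \cdot s \cdot
#' V_{defl}} (nN; with deflection already in nm, \eqn{F = k \cdot d}) and
#' indentation \eqn{\delta = (z - z_c) - d_{nm}}: piezo travel past contact
#' minus cantilever bending.
#'
#' @param curve Calibrated, baseline-corrected [force_curve()].
#' @param contact Result of [find_contact_point()], or a single number taken
#'   as the contact position `contact_z` in nm.
#' @return A list of class `indentation_curve`: `delta` (nm), `F` (nN),
#'   `contact_z`, `baseline_params`, `probe`.
#' @export
to_force_indentation <- function(curve, contact) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.list(contact)) contact_z <- contact$contact_z
  else contact_z <- as.numeric(contact)
  if (!is.finite(contact_z))
    stop("invalid contact position", call. = FALSE)
  d_nm_all <- deflection_nm(curve)   # errors if sensitivity missing
  ord <- approach_order(curve)
  z <- curve$z[ord]; d_nm <- d_nm_all[ord]
  keep <- z > contact_z
  if (!any(keep))
    stop("no post-contact samples", call. = FALSE)
  delta <- (z[keep] - contact_z) - d_nm[keep]
  F <- curve$k * d_nm[keep]          # N/m * nm = nN
  structure(list(delta = delta, F = F, contact_z = contact_z,
                 baseline_params = curve$baseline_params,
                 probe = curve$probe, k = curve$k),
            class = "indentation_curve")
}

#' @export
print.indentation_curve <- function(x, ...) {
  cat(sprintf("<indentation_curve> %d samples, delta up to %.1f nm, F up to %.3g nN\n",
              length(x$delta), max(x$delta), max(x$F)))
  invisible(x)
}
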