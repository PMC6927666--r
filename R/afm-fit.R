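# Contact-law coefficients in (nN, nm, Pa) units.
# Sphere (Hertz): F = (4/3) E/(1-nu^2) sqrt(R) delta^{3/2} * 1e-9
# Cone (Sneddon): F = (2/pi) tan(alpha) E/(1-nu^2) delta^2 * 1e-9

#' Force predicted by the spherical-indenter Hertz model
#'
#' \eqn{F = \frac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2}}, with
#' `E` in Pa, `R` and `delta` in nm, and the force returned in nN.
#'
#' @param delta Indentation depth(s) in nm.
#' @param E Young's modulus in Pa.
#' @param R Sphere radius in nm.
#' @param nu Sample Poisson ratio.
#' @return Force in nN.
#' @examples
#' hertz_sphere_force(50, E = 1000, R = 11500, nu = 0.5)  # ~0.067 nN
#' @export
hertz_sphere_force <- function(delta, E, R, nu = 0.5) {
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5 * 1e-9
}

#' Force predicted by the conical-indenter Sneddon model
#'
#' \eqn{F = \frac{2}{\pi}\,\tan\alpha\,\frac{E}{1-\nu^2}\,\delta^2}, with
#' `E` in Pa, `delta` in nm, `half_angle` in degrees, force in nN.
#'
#' @inheritParams hertz_sphere_force
#' @param half_angle Cone half-opening angle in degrees.
#' @return Force in nN.
#' @export
sneddon_cone_force <- function(delta, E, half_angle, nu = 0.5) {
  (2 / pi) * tan(half_angle * pi / 180) * E / (1 - nu^2) * delta^2 * 1e-9
}

contact_law_coef <- function(probe, E = 1) {
  if (probe$geometry == "sphere")
    (4 / 3) * E / (1 - probe$nu^2) * sqrt(probe$R) * 1e-9
  else
    (2 / pi) * tan(probe$half_angle * pi / 180) * E / (1 - probe$nu^2) * 1e-9
}

new_elastic_fit <- function(E, contact_z, model, fit_depth, r_squared,
                            n_points, slope) {
  structure(list(E = E, contact_z = contact_z, model = model,
                 fit_depth = fit_depth, r_squared = r_squared,
                 n_points = n_points, slope = slope),
            class = "elastic_fit")
}

#' @export
print.elastic_fit <- function(x, ...) {
  cat(sprintf("<elastic_fit> %s: E = %.4g Pa (R2 = %.4f, %d points, depth %.0f nm)\n",
              x$model, x$E, x$r_squared, x$n_points, x$fit_depth))
  invisible(x)
}

fit_window <- function(ind, fit_depth, min_indent = 1) {
  sel <- which(ind$delta > 0 & ind$delta <= fit_depth & ind$F >= 0)
  if (length(sel) < 5L)
    stop(sprintf("insufficient data: %d samples with 0 < delta <= %g nm (need >= 5)",
                 length(sel), fit_depth), call. = FALSE)
  if (max(ind$delta[sel]) < min_indent)
    stop(sprintf("non-indentable sample: maximum indentation %.3g nm is below the %g nm resolution floor",
                 max(ind$delta[sel]), min_indent), call. = FALSE)
  sel
}

#' Fit the linearized spherical Hertz model
#'
#' Ordinary least squares of \eqn{F^{2/3}} against indentation \eqn{\delta}
#' through the origin, over \eqn{\delta \in (0, \mathrm{fit\_depth}]}. The
#' slope \eqn{m} gives the Young's modulus \eqn{E = \frac{3}{4}\, m^{3/2}
#' (1-\nu^2)/\sqrt{R}} (unit factors for nN/nm/Pa applied internally). The
#' default 50 nm fit depth keeps the fit within the small-deformation
#' validity range of the Hertz model (well below 10% of the indenter
#' radius). An optional free intercept is available as a robustness
#' diagnostic but is not the default, since the linearized law passes
#' through the origin.
#'
#' @param ind An [to_force_indentation()] result.
#' @param probe A spherical [probe_spec()].
#' @param fit_depth Maximum indentation used, nm.
#' @param intercept Allow a free intercept (diagnostic only).
#' @param min_indent Minimum resolvable indentation (nm): a curve whose
#'   maximum in-window indentation stays below it is rejected as
#'   non-indentable (rigid substrate) rather than fitted to numerical
#'   residuals.
#' @return An `elastic_fit` with `E` (Pa), `r_squared` (on the linearized
#'   scale), `n_points`, `contact_z`.
#' @export
fit_hertz_sphere <- function(ind, probe, fit_depth = 50, intercept = FALSE,
                             min_indent = 1) {
  stopifnot(inherits(ind, "indentation_curve"), inherits(probe, "probe_spec"))
  if (probe$geometry != "sphere")
    stop("fit_hertz_sphere needs a spherical probe", call. = FALSE)
  if (!is.numeric(fit_depth) || fit_depth <= 0)
    stop("fit_depth must be positive", call. = FALSE)
  sel <- fit_window(ind, fit_depth, min_indent)
  x <- ind$delta[sel]
  y <- ind$F[sel]^(2 / 3)
  if (intercept) {
    fit <- lm(y ~ x)
    m <- coef(fit)[[2]]
    yhat <- fitted(fit)
  } else {
    m <- sum(x * y) / sum(x * x)
    yhat <- m * x
  }
  if (!is.finite(m) || m <= 0)
    stop("fit error: non-positive linearized slope", call. = FALSE)
  unit_coef <- (4 / 3) / (1 - probe$nu^2) * sqrt(probe$R) * 1e-9
  E <- m^1.5 / unit_coef
  r2 <- 1 - sum((y - yhat)^2) / sum(y^2)
  new_elastic_fit(E, ind$contact_z, "hertz_sphere", fit_depth, r2,
                  length(sel), m)
}

#' Fit the conical Sneddon model
#'
#' Least squares of force against \eqn{\delta^2} through the origin; the
#' slope gives the Young's modulus via \eqn{F = \frac{2}{\pi} \tan\alpha\,
#' \frac{E}{1-\nu^2}\, \delta^2}.
#'
#' @inheritParams fit_hertz_sphere
#' @param probe A conical [probe_spec()] with `half_angle` set.
#' @param fit_depth Maximum indentation used, nm (default: no bound, i.e.
#'   the full indentation reached at the applied load).
#' @return An `elastic_fit`.
#' @export
fit_sneddon_cone <- function(ind, probe, fit_depth = Inf, min_indent = 1) {
  stopifnot(inherits(ind, "indentation_curve"), inherits(probe, "probe_spec"))
  if (probe$geometry != "cone")
    stop("fit_sneddon_cone needs a conical probe", call. = FALSE)
  sel <- fit_window(ind, fit_depth, min_indent)
  x <- ind$delta[sel]^2
  y <- ind$F[sel]
  m <- sum(x * y) / sum(x * x)
  if (!is.finite(m) || m <= 0)
    stop("fit error: non-positive slope", call. = FALSE)
  unit_coef <- (2 / pi) * tan(probe$half_angle * pi / 180) /
    (1 - probe$nu^2) * 1e-9
  E <- m / unit_coef
  r2 <- 1 - sum((y - m * x)^2) / sum(y^2)
  new_elastic_fit(E, ind$contact_z, "sneddon_cone",
                  if (is.finite(fit_depth)) fit_depth else max(ind$delta),
                  r2, length(sel), m)
}

#' Analyze one force curve end to end
#'
#' Convenience pipeline: baseline correction, contact-point detection,
#' force-indentation conversion, then the elasticity fit matching the probe
#' geometry (spherical Hertz or conical Sneddon).
#'
#' @param curve A calibrated [force_curve()] with a probe attached (or
#'   `probe` supplied).
#' @param probe Optional [probe_spec()] overriding `curve$probe`.
#' @param fit_depth Maximum indentation used in the fit, nm (default 50 for
#'   a sphere, unbounded for a cone).
#' @param noncontact_fraction Baseline window, see [baseline_correct()].
#' @param threshold_sds,persistence Contact detection, see
#'   [find_contact_point()].
#' @return An `elastic_fit`.
#' @export
analyze_cfs_curve <- function(curve, probe = NULL, fit_depth = NULL,
                              noncontact_fraction = 0.3, threshold_sds = 3,
                              persistence = 10L) {
  stopifnot(inherits(curve, "force_curve"))
  if (is.null(probe)) probe <- curve$probe
  if (is.null(probe))
    stop("no probe specification available", call. = FALSE)
  curve$probe <- probe
  bc <- baseline_correct(curve, noncontact_fraction)
  cp <- find_contact_point(bc, threshold_sds = threshold_sds,
                           persistence = persistence,
                           noncontact_fraction = noncontact_fraction)
  ind <- to_force_indentation(bc, cp)
  if (probe$geometry == "sphere") {
    if (is.null(fit_depth)) fit_depth <- 50
    fit_hertz_sphere(ind, probe, fit_depth)
  } else {
    if (is.null(fit_depth)) fit_depth <- Inf
    fit_sneddon_cone(ind, probe, fit_depth)
  }
}

#' Summarize elasticity fits by experimental group
#'
#' Per-group mean, SD, median and n of the fitted Young's moduli, plus the
#' fold ratios of each group's mean and median modulus relative to the
#' first group.
#'
#' @param fits List of `elastic_fit` objects (or numeric E values in Pa).
#' @param group_labels Character vector of group labels, one per fit.
#' @return A list with `summary` (one row per group) and, when more than
#'   one group is present, `ratios` (fold change of mean and median E
#'   relative to the reference, i.e. first, group).
#' @export
summarize_cfs <- function(fits, group_labels) {
  E <- vapply(fits, function(f) if (inherits(f, "elastic_fit")) f$E
              else as.numeric(f), numeric(1))
  stopifnot(length(E) == length(group_labels), length(E) > 0)
  groups <- unique(group_labels)
  for (g in groups)
    if (sum(group_labels == g) < 1)
      stop("empty group: ", g, call. = FALSE)
  summ <- do.call(rbind, lapply(groups, function(g) {
    v <- E[group_labels == g]
    data.frame(group = g, n = length(v), mean_E = mean(v),
               sd_E = sd(v), median_E = median(v))
  }))
  out <- list(summary = summ)
  if (length(groups) > 1) {
    ref <- summ[1, ]
    out$ratios <- data.frame(
      group = summ$group[-1],
      reference = ref$group,
      mean_ratio = summ$mean_E[-1] / ref$mean_E,
      median_ratio = summ$median_E[-1] / ref$median_E)
  }
  out
}
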