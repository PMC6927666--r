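# Run expr with a local, seeded RNG stream, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# splitmix64-style integer mixing, reduced to a non-negative 31-bit value so
# derived seeds stay valid R integers. Keeps grid pixels independent and
# reproducible from (base seed, row, col).
mix_seed <- function(seed, a = 0L, b = 0L) {
  x <- (as.double(seed) * 2654435761 + as.double(a) * 40503 +
        as.double(b) * 10369 + 12345) %% 2147483647
  as.integer(floor(x))
}

#' Specification of a synthetic PLA scene
#'
#' Parameters of the ground-truthed two-channel image generator: blurred
#' elliptical nuclei in the DAPI channel; diffraction-limited Gaussian
#' puncta, a planar background gradient and optional noise in the PLA
#' channel. Defaults describe a typical high-magnification field of a
#' confluent endothelial monolayer at desk scale: 12 nuclei of 12-18 px
#' radius in a 256 x 256 frame, 15 nuclear and 25 cytosolic puncta of
#' sigma 1.5 px with peak amplitude five times the background level.
#'
#' @param image_shape `(rows, cols)` of both channels.
#' @param n_nuclei Number of nuclei.
#' @param nucleus_radii `(min, max)` of the ellipse semi-axes, px.
#' @param nucleus_intensity Nucleus fill intensity (a.u.).
#' @param n_nuclear_spots,n_cytosolic_spots Ground-truth punctum counts per
#'   compartment.
#' @param spot_sigma Punctum Gaussian sigma, px.
#' @param spot_peak Punctum peak amplitude (a.u.).
#' @param background `(base, row slope, col slope)` of the planar PLA
#'   background.
#' @param dapi_background DAPI channel base level (a.u.).
#' @param noise_sd Additive Gaussian noise SD (a.u.); 0 = noise-free.
#' @param noise_model `"gaussian"` (default, analytically tractable SNR) or
#'   `"poisson"` (shot noise; `noise_sd` then scales the variance via
#'   intensity rescaling).
#' @param seed RNG seed; the scene is a pure function of the spec.
#' @return A list of class `pla_scene_spec`.
#' @export
pla_scene_spec <- function(image_shape = c(256L, 256L), n_nuclei = 12L,
                           nucleus_radii = c(12, 18),
                           nucleus_intensity = 150,
                           n_nuclear_spots = 15L, n_cytosolic_spots = 25L,
                           spot_sigma = 1.5, spot_peak = 100,
                           background = c(base = 20, row_slope = 0.02,
                                          col_slope = 0.03),
                           dapi_background = 5, noise_sd = 0,
                           noise_model = c("gaussian", "poisson"),
                           seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(image_shape) == 2L, all(image_shape >= 16L),
            n_nuclei >= 0L, n_nuclear_spots >= 0L, n_cytosolic_spots >= 0L,
            length(nucleus_radii) == 2L, nucleus_radii[1] > 0,
            nucleus_radii[2] >= nucleus_radii[1], spot_sigma > 0,
            spot_peak > 0, noise_sd >= 0)
  structure(list(image_shape = as.integer(image_shape),
                 n_nuclei = as.integer(n_nuclei),
                 nucleus_radii = nucleus_radii,
                 nucleus_intensity = nucleus_intensity,
                 n_nuclear_spots = as.integer(n_nuclear_spots),
                 n_cytosolic_spots = as.integer(n_cytosolic_spots),
                 spot_sigma = spot_sigma, spot_peak = spot_peak,
                 background = background,
                 dapi_background = dapi_background,
                 noise_sd = noise_sd, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "pla_scene_spec")
}

# squared normalized ellipse coordinate of all pixels for one nucleus
ellipse_field <- function(nr, nc, cr, cc, a, b) {
  outer(((seq_len(nr) - cr) / a)^2, ((seq_len(nc) - cc) / b)^2, "+")
}

#' Generate a ground-truthed synthetic PLA scene
#'
#' Builds a DAPI channel (blurred axis-aligned ellipses, optics emulated by
#' a sigma = 3 px Gaussian) and a PLA channel (planar background gradient
#' plus Gaussian puncta), with every nucleus and punctum recorded in a truth
#' table. Nuclear puncta are placed well inside a nucleus ellipse and
#' cytosolic puncta well outside all nuclei, with pairwise separation
#' margins so noise-free detection is exact; placement is rejection-sampled
#' and errors out after 10,000 failed attempts.
#'
#' @param spec A [pla_scene_spec()].
#' @return A list with `dapi` and `pla` ([image2d()]) and `truth` (list with
#'   `nuclei` and `spots` data.frames and the realized counts).
#' @export
make_pla_scene <- function(spec = pla_scene_spec()) {
  stopifnot(inherits(spec, "pla_scene_spec"))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  max_attempts <- 10000L
  with_local_seed(spec$seed, {
    # ---- nuclei: non-overlapping axis-aligned ellipses ----
    nuclei <- data.frame(center_r = numeric(0), center_c = numeric(0),
                         a = numeric(0), b = numeric(0))
    attempts <- 0L
    border <- spec$nucleus_radii[2] + 6
    while (nrow(nuclei) < spec$n_nuclei) {
      attempts <- attempts + 1L
      if (attempts > max_attempts)
        stop("generator error: nucleus placement constraints unsatisfiable",
             call. = FALSE)
      a <- runif(1, spec$nucleus_radii[1], spec$nucleus_radii[2])
      b <- runif(1, spec$nucleus_radii[1], spec$nucleus_radii[2])
      cr <- runif(1, border, nr - border)
      cc <- runif(1, border, nc - border)
      rmax <- max(a, b)
      ok <- TRUE
      if (nrow(nuclei) > 0) {
        d <- sqrt((nuclei$center_r - cr)^2 + (nuclei$center_c - cc)^2)
        ok <- all(d > pmax(nuclei$a, nuclei$b) + rmax + 6)
      }
      if (ok) nuclei <- rbind(nuclei, data.frame(center_r = cr,
                                                 center_c = cc, a = a, b = b))
    }
    dapi <- matrix(spec$dapi_background, nr, nc)
    for (i in seq_len(nrow(nuclei)))
      dapi[ellipse_field(nr, nc, nuclei$center_r[i], nuclei$center_c[i],
                         nuclei$a[i], nuclei$b[i]) <= 1] <-
        spec$dapi_background + spec$nucleus_intensity
    if (nrow(nuclei) > 0 || TRUE)
      dapi <- gaussian_blur(image2d(dapi), 3)$pixels

    # ---- puncta ----
    inside_margin <- 3    # nuclear spots this far inside the ellipse edge
    outside_margin <- 5   # cytosolic spots this far outside every ellipse
    min_sep <- 8          # pairwise punctum separation
    in_nucleus <- function(r, c, shrink = 0, grow = 0) {
      if (nrow(nuclei) == 0) return(FALSE)
      any(((r - nuclei$center_r) / (nuclei$a - shrink + grow))^2 +
          ((c - nuclei$center_c) / (nuclei$b - shrink + grow))^2 <= 1)
    }
    spots <- data.frame(r = numeric(0), c = numeric(0),
                        compartment = character(0))
    place <- function(compartment, n) {
      attempts <- 0L
      while (sum(spots$compartment == compartment) < n) {
        attempts <- attempts + 1L
        if (attempts > max_attempts)
          stop("generator error: punctum placement constraints unsatisfiable",
               call. = FALSE)
        r <- runif(1, 8, nr - 8); c <- runif(1, 8, nc - 8)
        ok <- if (compartment == "nuclear")
          in_nucleus(r, c, shrink = inside_margin)
        else !in_nucleus(r, c, grow = outside_margin)
        if (ok && nrow(spots) > 0)
          ok <- all(sqrt((spots$r - r)^2 + (spots$c - c)^2) >= min_sep)
        if (ok)
          spots <<- rbind(spots, data.frame(r = r, c = c,
                                            compartment = compartment))
      }
    }
    if (spec$n_nuclear_spots > 0 && nrow(nuclei) == 0)
      stop("generator error: nuclear spots requested but no nuclei",
           call. = FALSE)
    place("nuclear", spec$n_nuclear_spots)
    place("cytosolic", spec$n_cytosolic_spots)

    rows <- matrix(seq_len(nr), nr, nc)
    cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
    pla <- spec$background[1] + spec$background[2] * rows +
      spec$background[3] * cols
    for (i in seq_len(nrow(spots))) {
      d2 <- outer((seq_len(nr) - spots$r[i])^2,
                  (seq_len(nc) - spots$c[i])^2, "+")
      pla <- pla + spec$spot_peak * exp(-d2 / (2 * spec$spot_sigma^2))
    }

    if (spec$noise_sd > 0) {
      if (spec$noise_model == "gaussian") {
        dapi <- dapi + rnorm(nr * nc, 0, spec$noise_sd)
        pla <- pla + rnorm(nr * nc, 0, spec$noise_sd)
      } else {
        # Poisson shot noise with variance ~ noise_sd^2 at the background
        # level: scale so the background has mean noise_sd^2 counts
        s <- spec$noise_sd^2 / max(spec$background[1], 1)
        dapi <- rpois(nr * nc, pmax(dapi * s, 0)) / s
        pla <- rpois(nr * nc, pmax(pla * s, 0)) / s
        dim(dapi) <- dim(pla) <- c(nr, nc)
      }
      dapi <- pmax(dapi, 0); pla <- pmax(pla, 0)
      dim(dapi) <- dim(pla) <- c(nr, nc)
    }

    list(dapi = image2d(dapi, channel = "dapi"),
         pla = image2d(pla, channel = "pla"),
         truth = list(nuclei = nuclei, spots = spots,
                      n_nuclei = nrow(nuclei),
                      n_nuclear = sum(spots$compartment == "nuclear"),
                      n_cytosolic = sum(spots$compartment == "cytosolic")))
  })
}

#' Generate a synthetic membrane-stain image of filled discs
#'
#' Places non-overlapping filled discs of the given radii (cells of known
#' spreading area pi r^2) on a flat background, for validating the
#' threshold-and-measure spreading-area pipeline.
#'
#' @param radii Disc radii in px, one per cell.
#' @param image_shape `(rows, cols)`.
#' @param intensity Disc fill intensity above background.
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise SD.
#' @param seed RNG seed.
#' @return A list with `img` ([image2d()]) and `truth` (data.frame of
#'   centers, radii and analytic areas).
#' @export
make_disc_scene <- function(radii, image_shape = c(384L, 384L),
                            intensity = 100, background = 10,
                            noise_sd = 0, seed = 1L) {
  nr <- image_shape[1]; nc <- image_shape[2]
  stopifnot(all(radii > 0))
  with_local_seed(seed, {
    centers <- data.frame(r = numeric(0), c = numeric(0), radius = numeric(0))
    attempts <- 0L
    for (rad in radii) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 10000L)
          stop("generator error: disc placement constraints unsatisfiable",
               call. = FALSE)
        cr <- runif(1, rad + 4, nr - rad - 4)
        cc <- runif(1, rad + 4, nc - rad - 4)
        ok <- nrow(centers) == 0 ||
          all(sqrt((centers$r - cr)^2 + (centers$c - cc)^2) >
              centers$radius + rad + 5)
        if (ok) {
          centers <- rbind(centers, data.frame(r = cr, c = cc, radius = rad))
          break
        }
      }
    }
    img <- matrix(background, nr, nc)
    for (i in seq_len(nrow(centers))) {
      d2 <- outer((seq_len(nr) - centers$r[i])^2,
                  (seq_len(nc) - centers$c[i])^2, "+")
      img[d2 <= centers$radius[i]^2] <- background + intensity
    }
    if (noise_sd > 0)
      img <- pmax(img + rnorm(nr * nc, 0, noise_sd), 0)
    dim(img) <- c(nr, nc)
    centers$area_true_px <- pi * centers$radius^2
    list(img = image2d(img, channel = "membrane"), truth = centers)
  })
}

#' Specification of a synthetic force curve
#'
#' Forward model of one AFM approach (or retract) segment: a linear
#' non-contact baseline, then a Hertz (sphere) or Sneddon (cone) contact
#' law solved self-consistently with cantilever bending, truncated at the
#' maximum load, emitted as photodiode volts via the deflection
#' sensitivity, with optional seeded force noise. Defaults mirror the
#' colloidal-probe acquisition this package analyzes: R = 11,500 nm sphere,
#' nu = 0.5, k = 0.03 N/m, 1 nN maximal load.
#'
#' @param E_true Ground-truth Young's modulus, Pa.
#' @param probe A [probe_spec()].
#' @param contact_z True contact position, nm.
#' @param z_max Piezo range end, nm (default: far enough past contact to
#'   reach `max_load`).
#' @param dz Piezo sampling step, nm.
#' @param k Cantilever spring constant, N/m.
#' @param sensitivity Deflection sensitivity, nm/V.
#' @param baseline `(intercept_V, slope_V_per_nm)` of the non-contact line.
#' @param noise_sd_frac Force-noise scale as a fraction of the maximum
#'   force.
#' @param noise_model `"additive"` (SD = frac x max force everywhere) or
#'   `"multiplicative"` (per-sample SD = frac x |F|).
#' @param max_load Maximum loading force, nN; samples beyond it are
#'   truncated.
#' @param segment `"approach"` or `"retract"`.
#' @param seed RNG seed.
#' @return A list of class `force_scene_spec`.
#' @export
force_scene_spec <- function(E_true = 1000,
                             probe = probe_spec("sphere", R = 11500,
                                                nu = 0.5),
                             contact_z = 2000, z_max = NULL, dz = 2,
                             k = 0.03, sensitivity = 50,
                             baseline = c(0, 0), noise_sd_frac = 0,
                             noise_model = c("additive", "multiplicative"),
                             max_load = 1, segment = "approach",
                             seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(E_true > 0, inherits(probe, "probe_spec"), contact_z > 0,
            dz > 0, k > 0, sensitivity > 0, length(baseline) == 2L,
            noise_sd_frac >= 0, max_load > 0)
  structure(list(E_true = E_true, probe = probe, contact_z = contact_z,
                 z_max = z_max, dz = dz, k = k, sensitivity = sensitivity,
                 baseline = baseline, noise_sd_frac = noise_sd_frac,
                 noise_model = noise_model, max_load = max_load,
                 segment = segment, seed = as.integer(seed)),
            class = "force_scene_spec")
}

# indentation depth solving delta + F(delta)/k = t for each piezo overshoot
# t >= 0; Newton from delta = t (monotone for the convex contact laws),
# converged to 1e-9 nm.
solve_indentation <- function(t, coefC, gamma, k) {
  delta <- t
  for (i in 1:200) {
    g <- delta + coefC * delta^gamma / k - t
    gp <- 1 + coefC * gamma * pmax(delta, 1e-300)^(gamma - 1) / k
    step <- g / gp
    delta <- pmax(delta - step, 0)
    if (max(abs(step)) < 1e-9) break
  }
  delta
}

#' Generate a synthetic force curve with known ground truth
#'
#' @param spec A [force_scene_spec()].
#' @return A [force_curve()] with an extra `truth` element recording the
#'   generating parameters and the noiseless per-sample indentation and
#'   force.
#' @export
make_force_curve <- function(spec = force_scene_spec()) {
  stopifnot(inherits(spec, "force_scene_spec"))
  gamma <- if (spec$probe$geometry == "sphere") 1.5 else 2
  coefC <- contact_law_coef(spec$probe, spec$E_true)  # nN per nm^gamma
  delta_max <- (spec$max_load / coefC)^(1 / gamma)
  z_max <- spec$z_max
  if (is.null(z_max))
    z_max <- spec$contact_z + delta_max + spec$max_load / spec$k
  z <- seq(0, z_max, by = spec$dz)
  t <- pmax(z - spec$contact_z, 0)
  delta <- solve_indentation(t, coefC, gamma, spec$k)
  F_true <- coefC * delta^gamma
  keep <- F_true <= spec$max_load + 1e-12
  if (sum(keep) < 10L)
    stop("generator error: z range leaves fewer than 10 samples below max_load",
         call. = FALSE)
  z <- z[keep]; delta <- delta[keep]; F_true <- F_true[keep]
  F_noisy <- with_local_seed(spec$seed, {
    if (spec$noise_sd_frac > 0) {
      sd_i <- if (spec$noise_model == "additive")
        rep(spec$noise_sd_frac * max(F_true), length(F_true))
      else spec$noise_sd_frac * abs(F_true)
      F_true + rnorm(length(F_true), 0, sd_i)
    } else F_true
  })
  d_nm <- F_noisy / spec$k
  d_V <- d_nm / spec$sensitivity +
    spec$baseline[1] + spec$baseline[2] * z
  curve <- force_curve(z = z, deflection = d_V, k = spec$k,
                       sensitivity = spec$sensitivity,
                       segment = spec$segment, probe = spec$probe,
                       deflection_unit = "V")
  curve$truth <- list(E_true = spec$E_true, contact_z = spec$contact_z,
                      delta = delta, F = F_true, spec = spec)
  curve
}

#' Generate a QI grid of synthetic force curves
#'
#' One curve per pixel of a ground-truth Young's-modulus map, with optional
#' per-pixel topography (sample height in nm; taller pixels contact the
#' probe at smaller piezo extension). Per-pixel RNG seeds are derived from
#' the base seed and the pixel coordinates by integer mixing, so pixels are
#' independent and the grid is reproducible.
#'
#' @param E_map Matrix of ground-truth moduli, Pa.
#' @param template A [force_scene_spec()] providing everything but `E_true`
#'   and `contact_z` (typically a conical probe and the 2 nN QI load).
#' @param height_map_nm Optional matrix (same shape) of sample heights, nm.
#' @param scan_size_um Optional physical scan size `(um, um)` carried into
#'   the map.
#' @param seed Base seed for per-pixel seed derivation.
#' @return A list of class `qi_grid` with `curves` (column-major list, as R
#'   stores matrices), `nrow`, `ncol`, `E_true`, `height_true_nm`,
#'   `scan_size_um`.
#' @export
make_qi_grid <- function(E_map, template = force_scene_spec(
                           probe = probe_spec("cone", half_angle = 17.5),
                           max_load = 2),
                         height_map_nm = NULL, scan_size_um = NULL,
                         seed = 1L) {
  E_map <- as.matrix(E_map)
  nr <- nrow(E_map); nc <- ncol(E_map)
  if (!is.null(height_map_nm) &&
      !identical(dim(as.matrix(height_map_nm)), dim(E_map)))
    stop("height_map_nm must match E_map in shape", call. = FALSE)
  curves <- vector("list", nr * nc)
  for (c in seq_len(nc)) for (r in seq_len(nr)) {
    sp <- template
    sp$E_true <- E_map[r, c]
    if (!is.null(height_map_nm))
      sp$contact_z <- template$contact_z - height_map_nm[r, c]
    sp$seed <- mix_seed(seed, r, c)
    curves[[(c - 1L) * nr + r]] <- make_force_curve(sp)
  }
  structure(list(curves = curves, nrow = nr, ncol = nc, E_true = E_map,
                 height_true_nm = height_map_nm,
                 scan_size_um = scan_size_um),
            class = "qi_grid")
}
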