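sphere_probe <- probe_spec("sphere", R = 11500, nu = 0.5)

test_that("probe_spec and force_curve validate their invariants", {
  expect_error(probe_spec("sphere"), "radius")
  expect_error(probe_spec("cone", half_angle = 95), "half_angle")
  expect_error(probe_spec("sphere", R = 100, nu = 0.7), "nu")
  expect_error(force_curve(1:5, 1:5, k = 0.03), "length")
  expect_error(force_curve(c(1:5, 5, 6:9), rep(0, 10), k = 0.03),
               "monotone")
  expect_error(force_curve(1:10, rep(0, 10), k = -1), "spring")
})

test_that("calibrate_sensitivity recovers the true inverse contact slope", {
  hard <- make_force_curve(force_scene_spec(E_true = 1e12, sensitivity = 50,
                                            k = 0.03))
  expect_equal(calibrate_sensitivity(hard), 50, tolerance = 1e-3)

  # deflection already in nm: identity calibration
  z <- seq(0, 1000, by = 5)
  d <- pmax(z - 600, 0)
  nmcurve <- force_curve(z, d, k = 0.05, deflection_unit = "nm")
  expect_equal(calibrate_sensitivity(nmcurve), 1, tolerance = 1e-9)

  flat <- force_curve(seq(0, 90, by = 1), rep(0.2, 91), k = 0.03)
  expect_error(calibrate_sensitivity(flat), "calibration error")
})

test_that("baseline_correct removes an injected tilt and flags all-contact curves", {
  sp <- force_scene_spec(E_true = 1000, baseline = c(0.05, 1e-4),
                         noise_sd_frac = 0.01, seed = 3)
  cv <- make_force_curve(sp)
  bc <- baseline_correct(cv)
  nw <- floor(length(bc$z) * 0.3)
  noncontact <- bc$deflection[order(bc$z)][seq_len(nw)]
  expect_lt(abs(mean(noncontact)), 3 * sd(noncontact) / sqrt(nw))
  expect_equal(unname(bc$baseline_params["slope"]), 1e-4, tolerance = 0.05)

  # zero-baseline noiseless curve passes through unchanged
  cv0 <- make_force_curve(force_scene_spec(E_true = 1000, seed = 1))
  bc0 <- baseline_correct(cv0)
  expect_equal(bc0$deflection, cv0$deflection, tolerance = 1e-10)

  # all-contact curve: convex contact-law deflection everywhere
  z <- seq(0, 800, by = 2)
  dall <- 1e-4 * (z + 200)^1.5 / 50
  allc <- force_curve(z, dall, k = 0.03, sensitivity = 50)
  expect_error(baseline_correct(allc), "free of contact")

  expect_error(baseline_correct(cv0, noncontact_fraction = 0.95),
               "noncontact_fraction")
})

test_that("find_contact_point recovers contact within one sample noiselessly, five samples at 2% noise", {
  sp <- force_scene_spec(E_true = 1000, contact_z = 2000, dz = 2, seed = 1)
  cv <- baseline_correct(make_force_curve(sp))
  cp <- find_contact_point(cv)
  expect_lt(abs(cp$contact_z - 2000), 2)

  errs <- sapply(1:20, function(s) {
    spn <- force_scene_spec(E_true = 1000, contact_z = 2000, dz = 2,
                            noise_sd_frac = 0.02, seed = 100 + s)
    cvn <- baseline_correct(make_force_curve(spn))
    find_contact_point(cvn)$contact_z - 2000
  })
  # typical recovery at 2% force noise stays within 5 sample spacings
  expect_lt(median(abs(errs)), 5 * 2)

  pure_noise <- force_curve(seq(1, 400, by = 2),
                            rnorm(200, 0, 0.01), k = 0.03, sensitivity = 50)
  expect_error(find_contact_point(pure_noise), "no contact")
})

test_that("to_force_indentation inverts the generator and handles limit cases", {
  sp <- force_scene_spec(E_true = 1000, seed = 1)
  cv <- make_force_curve(sp)
  bc <- baseline_correct(cv)
  ind <- to_force_indentation(bc, list(contact_z = 2000))
  # round trip: recovered (delta, F) match the generating law
  pred <- hertz_sphere_force(pmax(ind$delta, 0), 1000, 11500, 0.5)
  expect_equal(ind$F, pred, tolerance = 1e-6)

  # rigid surface: all travel goes into bending, delta ~ 0
  rigid <- baseline_correct(make_force_curve(
    force_scene_spec(E_true = 1e12, seed = 2)))
  ir <- to_force_indentation(rigid, list(contact_z = 2000))
  expect_lt(max(abs(ir$delta)), 0.01)

  # zero deflection: F = 0 and delta = z - contact
  z <- seq(0, 500, by = 5)
  flat <- force_curve(z, rep(0, length(z)), k = 0.03, sensitivity = 50)
  i0 <- to_force_indentation(flat, 100)
  expect_true(all(i0$F == 0))
  expect_equal(i0$delta, z[z > 100] - 100)

  # missing calibration metadata
  vcurve <- force_curve(z, rep(0, length(z)), k = 0.03)
  expect_error(to_force_indentation(vcurve, 100), "sensitivity")
})

test_that("fit_hertz_sphere is exact on noiseless curves and matches the printed-law force", {
  oc <- oracle_hertz_curve(E = 1000, R = 11500, nu = 0.5, delta_max = 50)
  ind <- structure(list(delta = oc$delta, F = oc$F, contact_z = 0,
                        probe = sphere_probe), class = "indentation_curve")
  fit <- fit_hertz_sphere(ind, sphere_probe, fit_depth = 50)
  expect_equal(fit$E, 1000, tolerance = 1e-3)
  expect_gt(fit$r_squared, 0.999999)

  # force at 50 nm indentation for E = 1000 Pa, R = 11500 nm, nu = 0.5:
  # independent evaluation in SI units, converted to nN
  F_si <- (4 / 3) * 1000 / (1 - 0.5^2) * sqrt(11500e-9) * (50e-9)^1.5 * 1e9
  expect_equal(hertz_sphere_force(50, 1000, 11500, 0.5), F_si,
               tolerance = 1e-12)
  expect_equal(F_si, 0.067, tolerance = 0.01)

  zero <- structure(list(delta = 1:10, F = rep(0, 10), contact_z = 0),
                    class = "indentation_curve")
  expect_error(fit_hertz_sphere(zero, sphere_probe), "slope")
})

test_that("linearized Hertz fit agrees with a nonlinear least-squares oracle", {
  skip_if_not_installed("minpack.lm")
  sp <- force_scene_spec(E_true = 1000, seed = 1)
  fitl <- analyze_cfs_curve(make_force_curve(sp))
  expect_equal(fitl$E, 1000, tolerance = 1e-3)

  cv <- baseline_correct(make_force_curve(sp))
  cp <- find_contact_point(cv)
  ind <- to_force_indentation(cv, cp)
  sel <- ind$delta > 0 & ind$delta <= 50
  df <- data.frame(d = ind$delta[sel], F = ind$F[sel])
  nls_fit <- minpack.lm::nlsLM(F ~ C * d^1.5, data = df,
                               start = list(C = 1e-4))
  E_nls <- coef(nls_fit)[["C"]] / ((4 / 3) / (1 - 0.25) * sqrt(11500) * 1e-9)
  expect_equal(fitl$E, E_nls, tolerance = 0.005)
})

test_that("linearized Hertz estimator is nearly unbiased at 2% force noise", {
  E_hat <- sapply(1:40, function(s) {
    sp <- force_scene_spec(E_true = 1000, noise_sd_frac = 0.02,
                           noise_model = "multiplicative", seed = 5000 + s)
    analyze_cfs_curve(make_force_curve(sp))$E
  })
  expect_lt(abs(median(E_hat) / 1000 - 1), 0.05)
})

test_that("fit_sneddon_cone is exact, proportional to tan(alpha), and guards sample count", {
  cone10 <- probe_spec("cone", half_angle = 10, nu = 0.5)
  sp <- force_scene_spec(E_true = 5000, probe = cone10, max_load = 2,
                         seed = 1)
  fit <- analyze_cfs_curve(make_force_curve(sp))
  expect_equal(fit$E, 5000, tolerance = 5)

  # doubling tan(half_angle) halves the recovered modulus
  cv <- baseline_correct(make_force_curve(sp))
  ind <- to_force_indentation(cv, find_contact_point(cv))
  a2 <- atan(2 * tan(10 * pi / 180)) * 180 / pi
  fit2 <- fit_sneddon_cone(ind, probe_spec("cone", half_angle = a2))
  expect_equal(fit2$E, fit$E / 2, tolerance = fit$E * 1e-6)

  short <- structure(list(delta = c(1, 2, 3), F = c(0.1, 0.4, 0.9),
                          contact_z = 0), class = "indentation_curve")
  expect_error(fit_sneddon_cone(short, cone10), "insufficient")
})

test_that("rigid-limit curves are rejected as non-indentable", {
  rigid <- baseline_correct(make_force_curve(
    force_scene_spec(E_true = 1e12, seed = 2)))
  ir <- to_force_indentation(rigid, list(contact_z = 2000))
  expect_error(fit_hertz_sphere(ir, sphere_probe), "non-indentable")
})

test_that("fitted E scales linearly with force and is unit-coherent", {
  sp <- force_scene_spec(E_true = 1000, seed = 1)
  cv <- baseline_correct(make_force_curve(sp))
  ind <- to_force_indentation(cv, find_contact_point(cv))
  base <- fit_hertz_sphere(ind, sphere_probe)$E
  ind_scaled <- ind
  ind_scaled$F <- ind$F * 3
  expect_equal(fit_hertz_sphere(ind_scaled, sphere_probe)$E, 3 * base,
               tolerance = 1e-9 * base)

  # same physical curve expressed with a different sensitivity gives same E
  sps <- force_scene_spec(E_true = 1000, sensitivity = 120, seed = 1)
  expect_equal(analyze_cfs_curve(make_force_curve(sps))$E, 1000,
               tolerance = 1e-3)
})

test_that("summarize_cfs reports group statistics and fold ratios", {
  fits <- as.list(c(rep(500, 30), rep(2000, 30)))
  out <- summarize_cfs(fits, rep(c("wt", "ko"), each = 30))
  expect_equal(out$summary$mean_E, c(500, 2000))
  expect_equal(out$ratios$mean_ratio, 4)
  expect_equal(out$ratios$median_ratio, 4)

  one <- summarize_cfs(list(100, 200), c("a", "a"))
  expect_null(one$ratios)

  same <- summarize_cfs(as.list(rep(1000, 10)), rep(c("a", "b"), 5))
  expect_equal(same$ratios$mean_ratio, 1)
})
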