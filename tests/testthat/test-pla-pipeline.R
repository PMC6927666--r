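# The default synthetic scene (12 nuclei, 15 nuclear + 25 cytosolic puncta)
# is the reference condition for pipeline recovery; scenes are regenerated
# per test from their seeds.

test_that("segment_nuclei counts well-separated nuclei exactly and rejects blanks", {
  s <- make_pla_scene(pla_scene_spec(noise_sd = 0, seed = 1))
  seg <- segment_nuclei(s$dapi)
  expect_equal(seg$n_nuclei, s$truth$n_nuclei)
  expect_equal(seg$nuclei$n_labels, s$truth$n_nuclei)
  # every true nucleus center carries a distinct label
  labs <- seg$nuclei$pixels[cbind(round(s$truth$nuclei$center_r),
                                  round(s$truth$nuclei$center_c))]
  expect_true(all(labs > 0))
  expect_equal(length(unique(labs)), s$truth$n_nuclei)

  expect_error(segment_nuclei(image2d(matrix(0, 64, 64))), "degenerate")
})

test_that("watershed separates two overlapping elliptical nuclei", {
  # two circular nuclei radius 20 overlapping by 25% of the radius
  m <- matrix(5, 90, 120)
  d1 <- outer((1:90 - 45)^2, (1:120 - 45)^2, "+")
  d2 <- outer((1:90 - 45)^2, (1:120 - 80)^2, "+")
  m[d1 <= 400 | d2 <= 400] <- 155
  dapi <- gaussian_blur(image2d(m), 3)
  seg <- segment_nuclei(dapi)
  expect_equal(seg$n_nuclei, 2L)
})

test_that("detect_pla_spots finds all noise-free puncta and is offset-invariant", {
  s <- make_pla_scene(pla_scene_spec(noise_sd = 0, seed = 2))
  n_true <- s$truth$n_nuclear + s$truth$n_cytosolic
  sp <- detect_pla_spots(s$pla)
  expect_equal(nrow(sp), n_true)

  sp_off <- detect_pla_spots(image2d(s$pla$pixels + 30))
  expect_equal(nrow(sp_off), nrow(sp))
  expect_equal(sp_off$centroid_r, sp$centroid_r, tolerance = 1e-6)
  expect_equal(sp_off$centroid_c, sp$centroid_c, tolerance = 1e-6)

  # background-only image: ramp with no puncta
  bgonly <- outer(1:128, 1:128, function(r, c) 20 + 0.02 * r + 0.03 * c)
  expect_equal(nrow(detect_pla_spots(image2d(bgonly))), 0L)

  expect_error(detect_pla_spots(image2d(matrix(7, 32, 32))), "degenerate")
})

test_that("classify_spots partitions by centroid-in-nucleus membership", {
  lab <- label_map(make_disc_mask(40, 40, rbind(c(20, 12)), 8))
  spots <- data.frame(label = 1:2, area_px = c(4L, 5L),
                      centroid_r = c(20, 20), centroid_c = c(12, 35))
  res <- classify_spots(spots, lab)
  expect_equal(res$n_nuclear, 1L)
  expect_equal(res$n_cytosolic, 1L)
  expect_equal(res$n_total, 2L)

  res0 <- classify_spots(spots[0, ], lab)
  expect_equal(res0$n_total, 0L)
  expect_false(res0$ratio_defined)

  expect_error(classify_spots(spots, lab, image_dim = c(64L, 64L)),
               "geometry")
})

test_that("quantify_pla_image recovers the ground-truth partition exactly without noise", {
  s <- make_pla_scene(pla_scene_spec(noise_sd = 0, seed = 1))
  res <- quantify_pla_image(s$dapi, s$pla, image_id = "scene1")
  expect_equal(res$n_nuclei, s$truth$n_nuclei)
  expect_equal(res$n_nuclear, s$truth$n_nuclear)
  expect_equal(res$n_cytosolic, s$truth$n_cytosolic)
  expect_equal(res$n_total, s$truth$n_nuclear + s$truth$n_cytosolic)
  expect_equal(res$ratio_nuc_cyt, res$n_nuclear / res$n_cytosolic)

  expect_error(quantify_pla_image(s$dapi, image2d(matrix(1:4 / 4, 2, 2))),
               "geometry")
})

test_that("count conservation holds across noisy scenes", {
  for (seed in 1:4) {
    s <- make_pla_scene(pla_scene_spec(noise_sd = 15, seed = seed))
    res <- quantify_pla_image(s$dapi, s$pla)
    expect_equal(res$n_nuclear + res$n_cytosolic, res$n_total)
    expect_equal(nrow(res$spots), res$n_total)
  }
})

test_that("quantification is deterministic and translation-invariant", {
  s <- make_pla_scene(pla_scene_spec(noise_sd = 10, seed = 6))
  r1 <- quantify_pla_image(s$dapi, s$pla)
  r2 <- quantify_pla_image(s$dapi, s$pla)
  expect_identical(r1$spots, r2$spots)
  expect_identical(r1$n_total, r2$n_total)

  # shift both channels by the same offset (content away from borders)
  shift <- function(m, dr, dc) {
    out <- matrix(median(m), nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  s2 <- make_pla_scene(pla_scene_spec(
    image_shape = c(220L, 220L), n_nuclei = 6L, n_nuclear_spots = 8L,
    n_cytosolic_spots = 12L, noise_sd = 0, seed = 8))
  ra <- quantify_pla_image(s2$dapi, s2$pla)
  rb <- quantify_pla_image(image2d(shift(s2$dapi$pixels, 5, 7)),
                           image2d(shift(s2$pla$pixels, 5, 7)))
  expect_equal(rb$n_nuclei, ra$n_nuclei)
  expect_equal(rb$n_nuclear, ra$n_nuclear)
  expect_equal(rb$n_cytosolic, ra$n_cytosolic)
})

test_that("batch summary aggregates per condition with mean and SD", {
  results <- lapply(1:4, function(i) {
    s <- make_pla_scene(pla_scene_spec(noise_sd = 0, seed = i))
    quantify_pla_image(s$dapi, s$pla, image_id = sprintf("img%02d", i))
  })
  out <- summarize_pla_batch(results, c("wt", "wt", "ko", "ko"))
  expect_equal(nrow(out$per_image), 4L)
  expect_equal(nrow(out$per_condition), 2L)
  expect_true(all(c("mean_nuclear", "sd_cytosolic", "mean_ratio") %in%
                  names(out$per_condition)))
  expect_equal(out$per_condition$n_images, c(2L, 2L))
})

test_that("fill_holes closes enclosed background only", {
  m <- matrix(0L, 20, 20)
  m[5:15, 5:15] <- 1L
  m[9:11, 9:11] <- 0L    # hole
  filled <- fill_holes(binary_mask(m))
  expect_equal(sum(filled), 11L * 11L)
  expect_equal(filled[1, 1], 0L)
})

test_that("measure_spread_area recovers disc areas within 2% and population ratios", {
  sc <- make_disc_scene(c(30, 38, 45, 52), c(420, 420), seed = 5)
  sr <- measure_spread_area(sc$img)
  expect_equal(sr$n_cells, 4L)
  expect_equal(sort(sr$areas_px), sort(sc$truth$area_true_px),
               tolerance = 0.02)

  expect_error(measure_spread_area(image2d(matrix(3, 32, 32))), "degenerate")
})

test_that("spread-area ratio of two populations tracks the true 2.5-fold difference", {
  set.seed(77)
  r_a <- runif(8, 30, 50)
  r_b <- r_a * sqrt(2.5)
  area_of <- function(radii, seed) {
    out <- c()
    for (i in seq_along(radii)) {
      sc <- make_disc_scene(radii[i], c(256, 256), noise_sd = 3,
                            seed = seed + i)
      out <- c(out, measure_spread_area(sc$img)$areas_px)
    }
    out
  }
  a <- area_of(r_a, 10); b <- area_of(r_b, 60)
  expect_equal(mean(b) / mean(a), 2.5, tolerance = 0.04)
})
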