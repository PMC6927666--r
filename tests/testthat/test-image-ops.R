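test_that("gaussian_blur preserves constants, normalizes mass, matches the convolution oracle", {
  const <- image2d(matrix(7, 16, 16))
  expect_equal(gaussian_blur(const, 2)$pixels, const$pixels, tolerance = 1e-12)

  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  expect_equal(sum(gaussian_blur(image2d(imp), 2)$pixels), 1, tolerance = 1e-6)

  set.seed(11)
  m <- matrix(runif(32 * 32, 0, 100), 32, 32)
  expect_equal(gaussian_blur(image2d(m), 2)$pixels, oracle_gaussian_blur(m, 2),
               tolerance = 1e-6)

  expect_error(gaussian_blur(const, 0), "sigma")
})

test_that("gaussian_blur conserves interior-supported intensity", {
  set.seed(4)
  m <- matrix(0, 48, 48)
  m[17:32, 17:32] <- runif(256, 0, 50)
  bl <- gaussian_blur(image2d(m), 2)$pixels
  expect_equal(sum(bl), sum(m), tolerance = 1e-6)
})

test_that("threshold_huang separates modes and matches the exhaustive oracle", {
  two <- matrix(rep(c(10, 200), each = 32), 8, 8)
  thr <- threshold_huang(image2d(two))
  expect_gt(thr, 10); expect_lt(thr, 200)
  expect_identical(sum(two > thr), 32L)

  # two blurred discs on dark background, 8-bit-like values
  m <- make_disc_mask(48, 48, rbind(c(14, 14), c(34, 34)), c(8, 6)) * 180
  m <- round(oracle_gaussian_blur(m + 10, 1.5))
  expect_equal(threshold_huang(image2d(m)), oracle_huang(m), tolerance = 1e-8)

  expect_error(threshold_huang(image2d(matrix(5, 4, 4))), "constant")
})

test_that("threshold_isodata_default finds the intermeans split and matches its oracle", {
  # equal-proportion two-valued image: trimming empties the histogram and
  # the dialect falls back to the midpoint
  two <- matrix(rep(c(0, 100), each = 32), 8, 8)
  expect_equal(threshold_isodata_default(image2d(two)), 50, tolerance = 0.5)

  set.seed(21)
  m <- matrix(sample(0:255, 40 * 40, replace = TRUE,
                     prob = c(rep(4, 120), rep(1, 136))), 40, 40)
  expect_equal(threshold_isodata_default(image2d(m)), oracle_isodata(m),
               tolerance = 1e-8)

  # single-pixel foreground stays finite and below the maximum
  m1 <- matrix(10, 12, 12); m1[5, 7] <- 200
  thr <- threshold_isodata_default(image2d(m1))
  expect_true(is.finite(thr)); expect_lt(thr, 200)

  expect_error(threshold_isodata_default(image2d(matrix(1, 3, 3))),
               "constant")
})

test_that("thresholds lie strictly inside the intensity range on non-constant images", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(round(runif(24 * 24, 0, 255)), 24, 24)
    if (max(m) == min(m)) next
    th <- threshold_huang(image2d(m))
    ti <- threshold_isodata_default(image2d(m))
    expect_gt(th, min(m)); expect_lt(th, max(m))
    expect_gt(ti, min(m)); expect_lt(ti, max(m))
  }
})

test_that("watershed_split keeps convex objects whole, splits touching discs, conserves area", {
  one <- make_disc_mask(40, 40, rbind(c(20, 20)), 15)
  w1 <- watershed_split(binary_mask(one))
  expect_equal(w1$n_labels, 1L)
  expect_equal(sum(w1$pixels > 0), sum(one))

  two <- make_disc_mask(70, 100, rbind(c(35, 35), c(35, 65)), c(20, 20))
  w2 <- watershed_split(binary_mask(two))
  expect_equal(w2$n_labels, 2L)
  expect_equal(sum(w2$pixels > 0), sum(two))
  # split lands near the geometric neck between the centers
  lab_left <- w2$pixels[35, 35]; lab_right <- w2$pixels[35, 65]
  expect_true(lab_left != lab_right)

  empty <- watershed_split(binary_mask(matrix(0L, 10, 10)))
  expect_equal(empty$n_labels, 0L)
})

test_that("rolling_ball_subtract flattens constants and recovers plateaus", {
  const <- image2d(matrix(40, 60, 120))
  expect_equal(max(abs(rolling_ball_subtract(const, 50)$pixels)), 0)

  m <- matrix(40, 60, 120); m[30:32, 60:62] <- 140
  out <- rolling_ball_subtract(image2d(m), 50)$pixels
  expect_equal(mean(out[30:32, 60:62]), 100, tolerance = 1)
  expect_lt(max(out[-(25:37), ]), 1e-6)

  expect_error(rolling_ball_subtract(image2d(matrix(1:4, 2, 2)), 50),
               "exceeds")
})

test_that("rolling_ball_subtract matches the ball-opening oracle and is bounded by the input", {
  set.seed(3)
  for (i in 1:3) {
    m <- matrix(runif(22 * 22, 0, 60), 22, 22)
    bg <- oracle_ball_opening(m, 6)
    expected <- pmax(m - bg, 0)
    out <- rolling_ball_subtract(image2d(m), 6)$pixels
    expect_equal(out, expected, tolerance = 1e-10)
    expect_true(all(out >= 0 & out <= m + 1e-12))
  }
})

test_that("dog_enhance is flat on constants, offset-invariant, and peaks at puncta", {
  expect_equal(max(dog_enhance(image2d(matrix(9, 20, 20)), 2)$pixels), 0)

  set.seed(5)
  m <- matrix(runif(30 * 30, 10, 60), 30, 30)
  a <- dog_enhance(image2d(m), 2)$pixels
  b <- dog_enhance(image2d(m + 25), 2)$pixels
  expect_equal(a, b, tolerance = 1e-9)

  spot <- matrix(20, 41, 41)
  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  spot <- spot + 100 * exp(-d2 / (2 * 1.5^2))
  enh <- dog_enhance(image2d(spot), 2)$pixels
  expect_equal(which(enh == max(enh)), which.max(spot))
})

test_that("median_filter_binary is a majority vote matching the neighbourhood-sort oracle", {
  ones <- binary_mask(matrix(1L, 12, 12))
  expect_equal(unclass(median_filter_binary(ones, 2)), matrix(1L, 12, 12),
               ignore_attr = TRUE)

  lone <- matrix(0L, 15, 15); lone[8, 8] <- 1L
  expect_equal(sum(median_filter_binary(binary_mask(lone), 2)), 0L)

  set.seed(13)
  m <- matrix(as.integer(runif(18 * 18) > 0.5), 18, 18)
  expect_equal(unclass(median_filter_binary(binary_mask(m), 2)),
               oracle_median_binary(m, 2), ignore_attr = TRUE)
})

test_that("analyze_particles measures disjoint squares exactly and counts like flood fill", {
  m <- matrix(0L, 40, 40)
  m[3:7, 3:7] <- 1L; m[20:24, 10:14] <- 1L; m[30:34, 30:34] <- 1L
  p <- analyze_particles(binary_mask(m))
  expect_equal(nrow(p), 3L)
  expect_true(all(p$area_px == 25L))
  expect_equal(p$centroid_r, c(5, 22, 32))
  expect_equal(p$centroid_c, c(5, 12, 32))

  set.seed(17)
  for (i in 1:5) {
    rm <- matrix(as.integer(runif(64 * 64) > 0.7), 64, 64)
    expect_equal(nrow(analyze_particles(binary_mask(rm))),
                 oracle_component_count(rm, 8))
    expect_equal(nrow(analyze_particles(binary_mask(rm), connectivity = 4)),
                 oracle_component_count(rm, 4))
  }

  tiny <- matrix(0L, 8, 8); tiny[4, 4:5] <- 1L
  expect_equal(nrow(analyze_particles(binary_mask(tiny), min_area_px = 3)), 0L)
})

test_that("analyze_particles respects border exclusion, area bounds and pixel size", {
  m <- matrix(0L, 20, 20)
  m[1:3, 5:7] <- 1L        # touches border
  m[10:12, 10:12] <- 1L    # interior, area 9
  p <- analyze_particles(binary_mask(m), exclude_border = TRUE,
                         pixel_size = 0.5)
  expect_equal(nrow(p), 1L)
  expect_equal(p$area_px, 9L)
  expect_equal(p$area_um2, 9 * 0.25)
  expect_equal(nrow(analyze_particles(binary_mask(m), max_area_px = 5)), 0L)
})

test_that("particle counts are invariant under translation away from borders", {
  set.seed(23)
  base <- matrix(0L, 50, 50)
  base[10:14, 10:13] <- 1L; base[30:33, 25:29] <- 1L; base[20, 40] <- 1L
  n0 <- nrow(analyze_particles(binary_mask(base)))
  shifted <- matrix(0L, 50, 50)
  shifted[7:50, 4:50] <- base[1:44, 1:47]
  expect_equal(nrow(analyze_particles(binary_mask(shifted))), n0)
})

test_that("line_profile samples ramps, constants, and an analytic Gaussian correctly", {
  ramp <- image2d(matrix(rep(1:50, each = 30), 30, 50))
  pr <- line_profile(ramp, c(15, 1), c(15, 50), normalize = TRUE)
  expect_equal(pr$intensity[1], 0)
  expect_equal(pr$intensity[nrow(pr)], 100)
  expect_true(all(diff(pr$intensity) >= 0))

  const <- image2d(matrix(3.5, 10, 10))
  pc <- line_profile(const, c(2, 2), c(9, 9))
  expect_equal(pc$intensity, rep(3.5, nrow(pc)))
  expect_error(line_profile(const, c(2, 2), c(9, 9), normalize = TRUE),
               "degenerate")

  d2 <- outer((1:41 - 21)^2, (1:41 - 21)^2, "+")
  g <- image2d(50 * exp(-d2 / (2 * 6^2)))
  pg <- line_profile(g, c(11, 11), c(31, 31))
  # analytic value along the diagonal
  tt <- pg$position / sqrt(2)
  truth <- 50 * exp(-((11 + tt - 21)^2 * 2) / (2 * 6^2))
  expect_equal(pg$intensity, truth, tolerance = 0.02)

  expect_error(line_profile(const, c(0, 2), c(9, 9)), "inside")
})

test_that("roi_mean_intensity averages pixel centers inside the circle", {
  expect_equal(roi_mean_intensity(image2d(matrix(12.5, 20, 20)),
                                  c(10, 10), 5), 12.5)

  half <- matrix(rep(c(10, 30), each = 200), 20, 20)
  expect_equal(roi_mean_intensity(image2d(half), c(10.5, 10.5), 6), 20,
               tolerance = 0.8)

  set.seed(31)
  m <- matrix(runif(25 * 25, 0, 9), 25, 25)
  expect_equal(roi_mean_intensity(image2d(m), c(12, 14), 4.5),
               oracle_roi_mean(m, c(12, 14), 4.5))

  expect_error(roi_mean_intensity(image2d(m), c(-30, -30), 3), "outside")
})

test_that("primitives are deterministic: identical inputs give identical outputs", {
  set.seed(41)
  m <- matrix(runif(40 * 40, 0, 200), 40, 40)
  img <- image2d(m)
  expect_identical(gaussian_blur(img, 2)$pixels, gaussian_blur(img, 2)$pixels)
  expect_identical(threshold_huang(img), threshold_huang(img))
  expect_identical(rolling_ball_subtract(img, 10)$pixels,
                   rolling_ball_subtract(img, 10)$pixels)
  bm <- binary_mask(m > 100)
  expect_identical(unclass(median_filter_binary(bm, 2)),
                   unclass(median_filter_binary(bm, 2)))
  expect_identical(watershed_split(bm)$pixels, watershed_split(bm)$pixels)
})
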