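test_that("straightening a horizontal trace reproduces the axis-aligned crop", {
  set.seed(6)
  img <- matrix(runif(40 * 60), 40, 60)
  tr <- sc_trace(data.frame(x = c(5, 50), y = c(20, 20)))
  band <- straighten(img, tr, band_width_px = 5L)
  expect_equal(ncol(band), 45L)
  crop <- img[(20 - 2):(20 + 2) + 1, (5:49) + 1]
  expect_equal(band, crop, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(straighten(img, tr, band_width_px = 4L), "odd")
  expect_error(straighten(img, data.frame(x = 5, y = 5)), "2 points")
})

test_that("straightening a semicircle yields ~pi*r columns of uniform band", {
  r0 <- 30
  cx <- 64; cy <- 64
  xs <- matrix(rep(0:127, each = 128), 128, 128)
  ys <- matrix(rep(0:127, times = 128), 128, 128)
  rad <- sqrt((xs - cx)^2 + (ys - cy)^2)
  ring <- exp(-(rad - r0)^2 / (2 * 16))     # radially uniform ring
  th <- seq(0, pi, length.out = 37)
  tr <- sc_trace(data.frame(x = cx + r0 * cos(th), y = cy + r0 * sin(th)))
  band <- straighten(t(ring), tr, band_width_px = 9L)
  expect_lt(abs(ncol(band) - pi * r0), 1.5)
  # each offset row should be constant along the arc within 2%
  mid <- band[, 3:(ncol(band) - 2)]
  row_rel_spread <- apply(mid, 1, function(v) diff(range(v)) / mean(v))
  expect_true(all(row_rel_spread < 0.02))
})

test_that("profile sampling uses half-spacing margins and column means", {
  band <- matrix(7, nrow = 5, ncol = 100)
  profs <- sample_profiles(band, n_points = 10L, thickness_px = 3L)
  expect_equal(attr(profs, "centers"), seq(5, 95, by = 10))
  expect_true(all(vapply(profs, function(p) all(p == 7), logical(1))))

  band2 <- matrix(0, nrow = 4, ncol = 30)
  band2[, 15] <- 3
  profs2 <- sample_profiles(band2, n_points = 1L, thickness_px = 3L)
  expect_equal(attr(profs2, "centers"), 15L)
  expect_equal(profs2[[1]], rep(1, 4))
  expect_error(sample_profiles(band2, n_points = 50L), "fewer columns")
})

test_that("double-Gaussian fitting recovers analytic peak separations", {
  x <- 0:20
  prof <- exp(-(x - 8)^2 / 2) + exp(-(x - 12)^2 / 2)
  fit <- fit_profile(prof, pixel_size_nm = 40)
  expect_equal(fit$n_peaks, 2L)
  expect_equal(fit$separation_nm, 160, tolerance = 0.1 / 160)

  single <- exp(-(x - 10)^2 / 8)
  f1 <- fit_profile(single, pixel_size_nm = 40)
  expect_equal(f1$n_peaks, 1L)
  expect_true(is.na(f1$separation_nm))
  expect_error(fit_profile(prof[1:4], 40), "too short")
})

test_that("separation error stays below 0.2 px for close noisy peaks", {
  # peaks 3.3 px apart, 2:1 amplitudes, SNR 10 on the weaker peak; the
  # profile width is chosen so both peaks are genuine local maxima
  x <- 0:20
  clean <- 200 * exp(-(x - 8.85)^2 / (2 * 0.8^2)) +
    100 * exp(-(x - 12.15)^2 / (2 * 0.8^2))
  set.seed(13)
  errs <- replicate(200, {
    fit <- fit_profile(clean + rnorm(length(x), sd = 10), pixel_size_nm = 40)
    if (fit$n_peaks == 2L && fit$converged) {
      abs(fit$separation_nm / 40 - 3.3)
    } else NA_real_
  })
  expect_lt(median(errs, na.rm = TRUE), 0.2)
})

test_that("chromosome distance averages only resolved two-peak fits", {
  two <- function(sep) structure(list(n_peaks = 2L, separation_nm = sep,
                                      converged = TRUE),
                                 class = "profile_fit")
  one <- structure(list(n_peaks = 1L, separation_nm = NA_real_,
                        converged = TRUE), class = "profile_fit")
  r <- chromosome_distance(rep(list(two(132)), 10))
  expect_equal(r$mean_separation_nm, 132)
  expect_equal(r$n_valid, 10L)
  r2 <- chromosome_distance(c(rep(list(two(150)), 5), rep(list(one), 5)))
  expect_equal(r2$mean_separation_nm, 150)
  expect_equal(r2$n_valid, 5L)
  expect_warning(r3 <- chromosome_distance(list(one)), "no profile")
  expect_true(is.na(r3$mean_separation_nm))
  expect_error(chromosome_distance(list()), "no profile fits")
})

test_that("synapsis classification thresholds at 250 nm, boundary unsynapsed", {
  expect_equal(classify_synapsis(150), "synapsed")
  expect_equal(classify_synapsis(365), "unsynapsed")
  expect_equal(classify_synapsis(250), "unsynapsed")
  expect_error(classify_synapsis(-1), ">= 0")
})

test_that("focal projection picks max +/- 2 slices with per-pixel maximum", {
  set.seed(8)
  vox <- array(runif(10 * 12 * 7), c(10, 12, 7))
  vox[, , 4] <- vox[, , 4] + 2          # argmax total at slice 4
  st <- image_stack(vox, 40)
  proj <- select_projection(st)
  manual <- vox[, , 2]
  for (s in 3:6) manual <- pmax(manual, vox[, , s])
  expect_equal(proj, manual)
  # slice 1 and 7 are excluded: a pixel whose max lives only there
  vox2 <- array(0, c(4, 4, 7))
  vox2[, , 3] <- 1                      # argmax slice 3 -> window 1..5
  vox2[1, 1, 1] <- 5
  expect_equal(select_projection(image_stack(vox2, 40))[1, 1], 5)
  # single slice stack returns that slice
  one <- image_stack(array(3, c(4, 4, 1)), 40)
  expect_equal(select_projection(one), matrix(3, 4, 4))
})

test_that("ROI intensity is background-subtracted intensity times area", {
  img <- matrix(4, 30, 30)
  img[6:10, 6:15] <- 10                # 5 x 10 block of value 10
  roi <- data.frame(x = c(4.5, 15.5, 15.5, 4.5), y = c(4.5, 4.5, 10.5, 10.5))
  bg <- data.frame(x = c(19.5, 28.5, 28.5, 19.5), y = c(19.5, 19.5, 28.5, 28.5))
  r <- measure_roi(img, roi, bg)
  expect_equal(r$area_px, 6 * 11)      # pixel centers 5..15 x 5..10
  # roi mean: 50 pixels of 10 plus 16 boundary pixels of 4
  expect_equal(r$integrated, (r$roi_mean - 4) * r$area_px)
  expect_equal(r$background_mean, 4)
  expect_false(r$flag_negative)

  # identical intensities -> integrated 0; adding a constant changes nothing
  flat <- measure_roi(matrix(10, 30, 30), roi, bg)
  expect_equal(flat$integrated, 0)
  r2 <- measure_roi(img + 100, roi, bg)
  expect_equal(r2$integrated, r$integrated, tolerance = 1e-12)
  # darker ROI than background flags negative
  neg <- measure_roi(-img, roi, bg)
  expect_true(neg$flag_negative)
})

test_that("ROI capture of a Gaussian spot recovers its analytic mass", {
  xs <- matrix(rep(0:63, each = 64), 64, 64)
  ys <- matrix(rep(0:63, times = 64), 64, 64)
  sig <- 3
  spot <- 50 * exp(-((t(xs) - 31)^2 + (t(ys) - 31)^2) / (2 * sig^2))
  S <- 50 * 2 * pi * sig^2
  img <- spot + 7
  roi <- data.frame(x = c(15, 47, 47, 15), y = c(15, 15, 47, 47))
  bg <- data.frame(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  r <- measure_roi(img, roi, bg)
  expect_equal(r$integrated, S, tolerance = 0.02)
})

test_that("straightened profiles are equivariant under 90-degree rotation", {
  sy <- synthesize_axis_pair_stack(axis_pair_truth(200, seed = 5))
  proj <- select_projection(sy$stack)
  tr <- sy$trace$points
  band1 <- straighten(proj, sc_trace(tr), band_width_px = 9L)
  p1 <- sample_profiles(band1)

  ny <- nrow(proj)
  proj_rot <- t(proj)[, ny:1]                 # 90-degree rotation
  tr_rot <- data.frame(x = ny - 1 - tr$y, y = tr$x)
  band2 <- straighten(proj_rot, sc_trace(tr_rot), band_width_px = 9L)
  p2 <- sample_profiles(band2)
  for (k in seq_along(p1)) {
    agree <- max(abs(p1[[k]] - p2[[k]])) < 1e-6 ||
      max(abs(p1[[k]] - rev(p2[[k]]))) < 1e-6
    expect_true(agree)
  }
})
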