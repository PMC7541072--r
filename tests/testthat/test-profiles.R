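make_ramp_map <- function(n = 120) {
  # varies only along x: value equals the x coordinate
  matrix(rep(seq_len(n), each = n), n, n)
}

test_that("profiles of a ramp map reproduce the ramp with zero spread", {
  map <- make_ramp_map()
  b <- boundary_polyline(x = rep(60, 100), y = seq(10, 110, length.out = 100))
  pr <- extract_profiles(map, b, cortical_depth = 30, n_profiles = 20,
                         n_samples = 40)
  expect_equal(pr$n_excluded, 0)
  expect_equal(dim(pr$values), c(40, 20))
  # each profile equals the ramp sampled along the normal (x = 60 + depth)
  expected <- 60 + pr$depth_pct / 100 * 30
  for (j in 1:20) expect_equal(pr$values[, j], expected, tolerance = 1e-9)
  expect_equal(pr$se, rep(0, 40), tolerance = 1e-9)
  expect_equal(pr$mean, expected, tolerance = 1e-9)
})

test_that("defaults sample 20 profiles at 40 depths", {
  expect_equal(formals(extract_profiles)$n_profiles, 20)
  expect_equal(formals(extract_profiles)$n_samples, 40)
})

test_that("profiles are equivariant under joint rotation of map and boundary", {
  n <- 121; ctr <- (n + 1) / 2
  xg <- matrix(rep(seq_len(n), each = n), n, n)
  yg <- matrix(rep(seq_len(n), n), n, n)
  # smooth radial map: rotation-invariant about the center
  map <- exp(-((sqrt((xg - ctr)^2 + (yg - ctr)^2) - 25) / 12)^2)
  mk_boundary <- function(phi0) {
    a <- seq(phi0 - 0.5, phi0 + 0.5, length.out = 60)
    boundary_polyline(ctr + 25 * cos(a), ctr + 25 * sin(a))
  }
  p1 <- extract_profiles(map, mk_boundary(0), cortical_depth = 15)
  p2 <- extract_profiles(map, mk_boundary(pi / 3), cortical_depth = 15)
  expect_lt(max(abs(p1$mean - p2$mean)), 0.01)
})

test_that("profiles leaving the map are excluded and counted", {
  map <- make_ramp_map(60)
  yb <- seq(5, 55, length.out = 50)
  b <- boundary_polyline(x = 25 + 18 * sin(2 * pi * yb / 50), y = yb)
  expect_silent(pr <- extract_profiles(map, b, cortical_depth = 15))
  expect_gt(pr$n_excluded, 0)
  expect_lt(pr$n_excluded, 20)
  expect_error(extract_profiles(map, b, cortical_depth = 500), "leaves the map")
})

test_that("band averages recover piecewise-constant band values exactly", {
  # synthetic profile set with known values per band
  ph <- gen_ribbon_phantom(ribbon_phantom_config(noise_sd = 0))
  pf <- extract_profiles(ph$iron, ph$boundary,
                         cortical_depth = ph$truth$cortical_depth_px)
  expect_equal(band_average(pf, "swm")$mean, 55, tolerance = 0.005)
  expect_equal(band_average(pf, "dwm")$mean, 33, tolerance = 0.005)
  expect_equal(band_average(pf, "cortex-upper")$mean, 15.6, tolerance = 0.005)
  expect_equal(band_average(pf, "cortex-middle")$mean, 29.2, tolerance = 0.01)
  expect_gt(band_average(pf, "swm")$mean, band_average(pf, "dwm")$mean)
  # constant map: mean equals the constant, SD zero
  cmap <- matrix(7, 120, 160)
  pc <- extract_profiles(cmap, ph$boundary, cortical_depth = 40)
  swm <- band_average(pc, "swm")
  expect_equal(swm$mean, 7)
  expect_equal(swm$sd, 0)
  expect_error(band_average(pc, c(5, 4)), "lo < hi")
  expect_error(band_average(pc, "nope"), "unknown band")
})

test_that("paired map differences recover band-specific offsets", {
  ph <- gen_ribbon_phantom(ribbon_phantom_config(noise_sd = 0))
  before <- ph$r2s
  after <- before - 12   # constant extraction effect
  d <- paired_map_difference(before, after, ph$boundary,
                             cortical_depth = ph$truth$cortical_depth_px)
  expect_true(all(abs(d$difference_map - 12) < 1e-12))
  expect_equal(d$bands$difference[d$bands$band == "swm"], 12, tolerance = 1e-9)
  expect_equal(d$bands$difference[d$bands$band == "dwm"], 12, tolerance = 1e-9)
  # identical maps: zero differences
  d0 <- paired_map_difference(before, before, ph$boundary, cortical_depth = 40)
  expect_true(all(d0$difference_map == 0))
  expect_equal(d0$bands$difference, c(0, 0))
  expect_error(paired_map_difference(before, after[1:50, ], ph$boundary, 40),
               "same grid")
})

test_that("the linear contrast model recovers noiseless coefficients exactly", {
  set.seed(61)
  fe <- c(15.6, 20, 29.2, 35, 55, 50, 40, 33, 33, 34)
  vm <- c(0.05, 0.08, 0.12, 0.2, 0.3, 0.33, 0.34, 0.33, 0.32, 0.33)
  y <- 0.35 * fe + 47 * vm + 13.7
  fit <- fit_linear_contrast_model(y, fe, vm)
  expect_equal(unname(fit$coefficients), c(0.35, 47, 13.7), tolerance = 1e-9)
  expect_equal(fit$variance_explained, 1, tolerance = 1e-12)
  expect_gte(fit$variance_explained, fit$variance_explained_reduced)
  # zero iron profile: full and reduced models coincide
  y2 <- 47 * vm + 13.7 + rnorm(10, sd = 0.1)
  fit2 <- fit_linear_contrast_model(y2, rep(0, 10), vm)
  expect_equal(fit2$variance_explained, fit2$variance_explained_reduced,
               tolerance = 1e-9)
  expect_error(fit_linear_contrast_model(y[1:3], fe[1:3], vm[1:3]), "at least 4")
  expect_warning(fit_linear_contrast_model(y, vm * 2, vm), "collinear")
})

test_that("profile SE shrinks as 1/sqrt(n) on i.i.d. noise", {
  set.seed(62)
  n <- 160
  base <- matrix(rnorm(n * n), n, n)
  b <- boundary_polyline(x = rep(80, 100), y = seq(20, 140, length.out = 100))
  se_at <- function(np) {
    pr <- extract_profiles(base, b, cortical_depth = 30, n_profiles = np,
                           n_samples = 20)
    mean(pr$se)
  }
  # SE ratio between 10 and 40 profiles approximately 2
  r <- se_at(10) / se_at(40)
  expect_gt(r, 1.4); expect_lt(r, 2.8)
})
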