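test_that("frequency histograms are normalized and symmetric about zero", {
  set.seed(31)
  x <- array(rnorm(8000), c(20, 20, 20))
  h <- frequency_histogram(x, n_bins = 101)
  expect_equal(sum(h$density) * h$bin_width, 1, tolerance = 1e-9)
  expect_equal(min(h$bin_centers), -max(h$bin_centers))
  # histogram of Gaussian samples tracks the generating density
  dens <- dnorm(h$bin_centers)
  expect_lt(max(abs(h$density - dens)), 0.05)
  # constant field: one occupied bin
  hc <- frequency_histogram(array(2, c(5, 5, 2)), n_bins = 11)
  expect_equal(sum(hc$density > 0), 1)
  expect_error(frequency_histogram(x, mask = array(FALSE, c(20, 20, 20))),
               "no voxels")
})

test_that("gaussian line shapes are identified with the right FWHM", {
  set.seed(32)
  x <- array(rnorm(2e5, sd = 3.397), c(100, 100, 20))
  ls <- fit_line_shape(frequency_histogram(x))
  expect_equal(ls$model, "gaussian")
  expect_equal(ls$fwhm, 2 * sqrt(2 * log(2)) * 3.397, tolerance = 0.03)
  expect_equal(ls$fwhm, 8, tolerance = 0.05)
  expect_false(ls$degenerate)
  expect_named(ls$fits, c("gaussian", "lorentzian"))
})

test_that("lorentzian line shapes are identified and the half-width recovered", {
  set.seed(33)
  y <- rcauchy(6e5, scale = 2)
  y <- y[abs(y) < 60][1:2e5]
  ls <- fit_line_shape(frequency_histogram(y))
  expect_equal(ls$model, "lorentzian")
  expect_equal(ls$fwhm, 4, tolerance = 0.1)
})

test_that("degenerate single-bin histograms yield zero width, flagged", {
  ls <- fit_line_shape(frequency_histogram(array(0, c(4, 4, 4))))
  expect_equal(ls$model, "gaussian")
  expect_equal(ls$fwhm, 0)
  expect_true(ls$degenerate)
})

test_that("microscale relaxivity is the linewidth per unit iron", {
  expect_equal(micro_relaxivity(8, 37), 8 / 37)
  expect_equal(round(micro_relaxivity(8, 37), 3), 0.216)
  expect_equal(micro_relaxivity(0, 10), 0)
  expect_equal(micro_relaxivity(3 * 8, 37), 3 * micro_relaxivity(8, 37))
  expect_error(micro_relaxivity(8, 0), "positive")
  expect_error(micro_relaxivity(-1, 5), "nonnegative")
})

test_that("linewidth scales linearly with the iron map (static dephasing)", {
  sc <- gen_cellular_iron_map(cellular_scene_config(fov_um = c(64, 64),
                                                    seed = 41))
  vol <- stack_sections(sc$map, repeats = 3, z_um = 3)
  base <- fit_line_shape(frequency_histogram(dipole_field(vol)))$fwhm
  for (k in c(0.5, 2, 4)) {
    mk <- iron_map(vol$values * k, pixel_size_um = vol$pixel_size_um)
    fw <- fit_line_shape(frequency_histogram(dipole_field(mk)))$fwhm
    expect_equal(fw, k * base, tolerance = 0.01)
  }
})

test_that("orientation spread is small for isotropic textures, larger for stripes", {
  dirs <- list(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))
  # statistically isotropic 3D texture: no axis privileged
  set.seed(43)
  v <- array(rnorm(48^3), c(48, 48, 48))
  iso3d <- iron_map(pmax(30 + 3 * v, 0))
  sweep_iso <- orientation_sweep(iso3d, dirs)
  expect_lt(sweep_iso$relative_spread, 0.15)
  # identical direction twice: identical FWHM
  rep2 <- orientation_sweep(iso3d, list(c(0, 0, 1), c(0, 0, 1)))
  expect_equal(rep2$fwhm[1], rep2$fwhm[2])
  expect_equal(rep2$relative_spread, 0, tolerance = 1e-12)
  # anisotropic striped texture: spread exceeds the isotropic case
  stripes <- gen_cellular_iron_map(cellular_scene_config(
    fov_um = c(48, 48), soma_density_mm2 = 0, stripe_contrast = 0.8,
    stripe_period_um = 8, seed = 44))
  vol_s <- stack_sections(stripes$map, repeats = 3, z_um = 3)
  sweep_s <- orientation_sweep(vol_s, dirs)
  expect_gt(sweep_s$relative_spread, sweep_iso$relative_spread)
})
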