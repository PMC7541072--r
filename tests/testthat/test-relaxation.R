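cst <- swm_constants()

test_that("nanoscale rate is relaxivity times concentration", {
  expect_equal(r2_nano(0), 0)
  expect_equal(r2_nano(55), 1.2375)
  expect_equal(round(r2_nano(55), 1), 1.2)
  expect_equal(r2_nano(33), 0.7425)
  expect_error(r2_nano(-5), "nonnegative")
})

test_that("slab frequency offset has the magic-angle null and hand-checked values", {
  th_magic <- asin(sqrt(2 / 3))
  expect_equal(slab_frequency_offset(slab_geometry(theta = th_magic,
                                                   delta_c_fe = 22)), 0)
  dO_perp <- slab_frequency_offset(slab_geometry(theta = pi / 2, delta_c_fe = 22))
  expect_equal(dO_perp, 2.675e8 * 7 * 1.37e-9 * 22 / 3, tolerance = 1e-12)
  expect_equal(dO_perp, 18.8, tolerance = 1e-3)
  dO_par <- slab_frequency_offset(slab_geometry(theta = 0, delta_c_fe = 22))
  expect_equal(dO_par, -2 * dO_perp)
  # vanishes only at the magic angle for nonzero contrast
  th <- seq(0, pi / 2, length.out = 181)
  dO <- vapply(th, function(t)
    slab_frequency_offset(slab_geometry(theta = t, delta_c_fe = 22)), 1)
  zero_th <- th[abs(dO) < 1e-6]
  expect_true(all(abs(sin(zero_th)^2 - 2 / 3) < 1e-3))
})

test_that("mesoscale rate matches the hand-evaluated quadratic form", {
  expect_equal(r2prime_meso(slab_geometry(theta = pi / 2, p = 0, delta_c_fe = 22)), 0)
  expect_equal(r2prime_meso(slab_geometry(theta = pi / 2, p = 1, delta_c_fe = 22)), 0)
  s <- slab_geometry(theta = pi / 2, delta_c_fe = 22, p = 0.5, te = 0.02)
  expect_equal(r2prime_meso(s), 0.125 * slab_frequency_offset(s)^2 * 0.02)
  expect_equal(r2prime_meso(s), 0.884, tolerance = 1e-3)
  # symmetric in p <-> 1-p; maximal at p = 1/2
  pgrid <- seq(0, 1, by = 0.05)
  rates <- vapply(pgrid, function(p)
    r2prime_meso(slab_geometry(theta = pi / 2, delta_c_fe = 22, p = p)), 1)
  expect_equal(rates, rev(rates))
  expect_equal(pgrid[which.max(rates)], 0.5)
})

test_that("two-compartment signal is the exact oracle for the meso approximation", {
  s0 <- slab_geometry(theta = asin(sqrt(2 / 3)), delta_c_fe = 22)
  expect_equal(two_compartment_signal(s0, c(0.01, 0.03))$magnitude, c(1, 1))
  s1 <- slab_geometry(theta = pi / 2, delta_c_fe = 22, p = 1)
  expect_equal(two_compartment_signal(s1, 0.02)$magnitude, 1)
  # agreement to O((dOmega te)^2) relative error over a (p, dC, te) grid
  for (p in c(0.2, 0.5, 0.8)) for (dc in c(5, 10, 22)) for (te in c(0.002, 0.005, 0.01)) {
    s <- slab_geometry(theta = pi / 2, delta_c_fe = dc, p = p, te = te)
    x <- abs(slab_frequency_offset(s)) * te
    exact <- two_compartment_signal(s, te)$rate
    approx_rate <- r2prime_meso(s)
    expect_lt(abs(approx_rate - exact) / max(exact, 1e-12), 1.5 * x^2)
  }
})

test_that("closed-form in-plane averages match the Monte-Carlo oracle", {
  set.seed(51)
  mc_oracle <- function(theta, n = 1e6) {
    phi <- runif(n, 0, 2 * pi)
    fz <- -cos(phi) * sin(theta)   # fiber z-component for in-plane azimuth phi
    s2 <- 1 - fz^2
    c(mean(s2), mean(s2^2))
  }
  for (th in seq(0, pi / 2, length.out = 20)) {
    mc <- mc_oracle(th)
    cf <- in_plane_average(th)
    expect_lt(abs(cf$mean_sin2 - mc[1]), 1e-3)
    expect_lt(abs(cf$mean_sin4 - mc[2]), 1e-3)
  }
  expect_equal(unlist(in_plane_average(0)), c(mean_sin2 = 1, mean_sin4 = 1))
  av <- in_plane_average(pi / 2)
  expect_equal(av$mean_sin2, 0.5)
  expect_equal(av$mean_sin4, 0.375)
  # sin^4 average never exceeds sin^2 average
  th <- seq(0, pi, length.out = 101)
  avs <- in_plane_average(th)
  expect_true(all(avs$mean_sin4 <= avs$mean_sin2 + 1e-12))
  # empirical-azimuth hook reduces to the closed form for uniform azimuths
  emp <- in_plane_average(0.7, azimuth_sample = runif(2e5, 0, 2 * pi))
  expect_equal(emp$mean_sin2, in_plane_average(0.7)$mean_sin2, tolerance = 2e-3)
})

test_that("averaged myelin law equals its sin-theta polynomial form", {
  m <- myelin_model(c_r2s = 2, a1 = 4, a2 = -1.5)
  th <- seq(0, pi, length.out = 61)
  direct <- r2star_myelin_slab(m, th)
  poly <- m$c_r2s_star + m$a1_star * sin(th)^2 + m$a2_star * sin(th)^4
  expect_equal(direct, poly, tolerance = 1e-12)
  expect_equal(r2star_myelin_slab(m, 0), 2 + 4 - 1.5)
  expect_equal(r2star_myelin_slab(myelin_model(c_r2s = 3), th), rep(3, 61))
})

test_that("forward model composes the mechanisms and preserves their ordering", {
  base <- voxel_composition(c_fe = 0, slab = slab_geometry(delta_c_fe = 1e-9),
                            r2_other = 13.7, micro_relaxivity = 0)
  expect_equal(forward_r2star(base)$total, 13.7, tolerance = 1e-9)
  # paper-like SWM configuration (slab perpendicular to B0, i.e. normal
  # parallel to the field): micro > meso > nano
  vx <- voxel_composition(c_fe = 55,
                          slab = slab_geometry(theta = 0, delta_c_fe = 22,
                                               p = 0.5, te = 0.02),
                          micro_relaxivity = 0.215)
  fw <- forward_r2star(vx)
  br <- fw$breakdown
  expect_gt(br[["micro"]], br[["meso"]])
  expect_gt(br[["meso"]], br[["nano"]])
  expect_equal(br[["meso"]], 3.4, tolerance = 0.05)
  expect_equal(fw$total, sum(br))
  # breakdown items match the standalone operations
  expect_equal(br[["nano"]], r2_nano(55))
  expect_equal(br[["micro"]], 0.215 * 55)
  expect_equal(br[["meso"]], r2prime_meso(vx$slab))
  expect_equal(br[["myelin"]], r2star_myelin_slab(vx$myelin, 0))
  # monotone nondecreasing in iron concentration
  totals <- vapply(seq(0, 80, by = 5), function(cf)
    forward_r2star(voxel_composition(c_fe = cf))$total, 1)
  expect_true(all(diff(totals) >= 0))
})
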