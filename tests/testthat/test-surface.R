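test_that("orientation angles come from normalized dot products and fold", {
  expect_equal(orientation_angle(c(0, 0, 1)), 0)
  expect_equal(orientation_angle(c(1, 0, 0)), pi / 2)
  expect_equal(orientation_angle(c(0, 0, -1)), 0)          # folded
  expect_equal(orientation_angle(c(0, 0, -1), fold = FALSE), pi)
  # fold invariance of the even powers
  th1 <- orientation_angle(c(1, 1, 2), fold = FALSE)
  th2 <- orientation_angle(-c(1, 1, 2), fold = FALSE)
  expect_equal(sin(th1)^2, sin(th2)^2)
  expect_equal(orientation_angle(c(0, 3, 0), b0_direction = c(0, 5, 0)), 0)
  expect_error(orientation_angle(c(0, 0, 0)), "nonzero")
})

test_that("a noise-free generated table is recovered exactly", {
  st <- gen_surface_table(surface_table_config(
    n_vertices = 500, beta = c(20, 3, -1), orientation_share = NULL,
    region_sd = 0, noise_sd = 0, n_regions = 1, seed = 71))
  fit <- fit_orientation_glm(st$table)
  expect_equal(unname(fit$beta), c(20, 3, -1), tolerance = 1e-9)
  expect_equal(fit$fitted + fit$residuals, st$table$r2s, tolerance = 1e-12)
  # correction leaves beta0 + eps exactly
  co <- correct_orientation(st$table, fit)
  expect_equal(co$r2s_corrected, rep(20, 500), tolerance = 1e-9)
})

test_that("beta parameters are recovered within 2 SE on noisy tables", {
  hits <- matrix(FALSE, 20, 3)
  for (i in 1:20) {
    st <- gen_surface_table(surface_table_config(n_vertices = 10000, seed = i))
    fit <- fit_orientation_glm(st$table)
    hits[i, ] <- abs(fit$beta - st$truth$beta) < 2 * fit$se
  }
  expect_gte(mean(hits[, 1]), 0.85)
  expect_gte(mean(hits[, 2]), 0.85)
  expect_gte(mean(hits[, 3]), 0.85)
})

test_that("constant-theta tables are rejected as unidentifiable", {
  tab <- data.frame(vertex = 1:10, r2s = rnorm(10), theta = rep(0.5, 10))
  expect_error(fit_orientation_glm(tab), "unidentifiable")
})

test_that("orientation variance share is recovered and removed by correction", {
  st <- gen_surface_table(surface_table_config(n_vertices = 10000,
                                               orientation_share = 0.08,
                                               seed = 72))
  fit <- fit_orientation_glm(st$table)
  expect_equal(orientation_variance_fraction(st$table, fit), 0.08,
               tolerance = 0.25)
  expect_equal(orientation_variance_fraction(st$table, fit),
               st$truth$orientation_variance_share, tolerance = 0.1)
  # corrected values have zero least-squares slope against sin^2(theta)
  co <- correct_orientation(st$table, fit)
  s2 <- sin(co$theta)^2
  slope_fit <- stats::lm(co$r2s_corrected ~ s2)
  slope <- stats::coef(slope_fit)[2]
  se <- sqrt(diag(stats::vcov(slope_fit)))[2]
  expect_lt(abs(slope), 2 * se)
  # pure orientation signal: share is 1
  pure <- gen_surface_table(surface_table_config(
    n_vertices = 2000, beta = c(10, 5, -2), orientation_share = NULL,
    region_sd = 0, noise_sd = 0, n_regions = 1, seed = 73))
  pfit <- fit_orientation_glm(pure$table)
  expect_equal(orientation_variance_fraction(pure$table, pfit), 1,
               tolerance = 1e-9)
  # no orientation effect: share near zero
  flat <- gen_surface_table(surface_table_config(
    n_vertices = 2000, beta = c(10, 0, 0), orientation_share = NULL,
    region_sd = 0.5, noise_sd = 0.5, seed = 74))
  ffit <- fit_orientation_glm(flat$table)
  expect_lt(orientation_variance_fraction(flat$table, ffit), 0.01)
})

test_that("regional contrast survives orientation correction", {
  st <- gen_surface_table(surface_table_config(n_vertices = 10000, seed = 75))
  fit <- fit_orientation_glm(st$table)
  co <- correct_orientation(st$table, fit)
  tr <- st$truth
  reg_before <- tapply(st$table$r2s, st$table$region, mean)
  reg_after <- tapply(co$r2s_corrected, co$region, mean)
  # contrast between the two most different regions is preserved
  hi <- which.max(tr$region_means); lo <- which.min(tr$region_means)
  true_contrast <- tr$region_means[hi] - tr$region_means[lo]
  expect_equal(unname(reg_after[hi] - reg_after[lo]), true_contrast,
               tolerance = 0.15)
})

test_that("group averaging is vertex-wise with sensible SDs", {
  st <- gen_surface_table(surface_table_config(n_vertices = 300, seed = 76))
  t1 <- st$table
  avg_same <- group_average(list(t1, t1, t1))
  expect_equal(avg_same$r2s, t1$r2s)
  expect_equal(avg_same$r2s_sd, rep(0, 300))
  t2 <- t1; t2$r2s <- t2$r2s + 2
  avg_shift <- group_average(list(t1, t2))
  expect_equal(avg_shift$r2s, t1$r2s + 1)
  # SD across noisy replicates matches the generating SD
  set.seed(77)
  reps <- lapply(1:40, function(i) { t <- t1; t$r2s <- t$r2s + rnorm(300, sd = 0.5); t })
  avg <- group_average(reps)
  expect_equal(mean(avg$r2s_sd), 0.5, tolerance = 0.05)
  t_bad <- t1[1:299, ]
  expect_error(group_average(list(t1, t_bad)), "identical vertex set")
})
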