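# Seeded generators emulating every input the pipeline consumes: cellular
# iron scenes (elemental-microscopy-like), cortical ribbon phantoms and
# per-vertex surface sample tables. Pure functions of (config, seed).

# smooth positive background texture via FFT Gaussian filtering of white noise
smooth_noise_2d <- function(nx, ny, corr_um, pixel_um) {
  z <- matrix(stats::rnorm(nx * ny), ny, nx)
  if (corr_um <= 0) return(z)
  kx <- fft_freq(nx, pixel_um)
  ky <- fft_freq(ny, pixel_um)
  K2 <- outer(ky^2, kx^2, `+`)
  H <- exp(-2 * pi^2 * corr_um^2 * K2)
  f <- Re(fft(fft(z) * H, inverse = TRUE)) / length(z)
  f / stats::sd(f)
}

#' Configuration of a synthetic cellular iron scene
#'
#' Describes an elemental-microscopy-like field of view: a diffuse,
#' fiber-associated iron background plus bright ~5 um soma hotspots
#' (oligodendrocyte bodies). The background amplitude is rescaled so that the
#' soma disks carry a prescribed fraction of the total iron mass (default
#' 0.12, the share measured for oligodendrocyte somata in SWM).
#'
#' @param fov_um Field of view in um, c(x, y) (default 200 x 200).
#' @param pixel_um Pixel size in um (default 1).
#' @param soma_density_mm2 Soma areal density per mm^2 (default 2000, i.e.
#'   ~80 somata in the default field of view, of the order seen for
#'   oligodendrocytes in a 12 um white-matter section).
#' @param soma_peak Nominal peak soma concentration, ug/g wtw (default 100);
#'   rescaled by the mass-fraction calibration, with a warning if the
#'   realized peak falls below the 70 ug/g soma threshold.
#' @param soma_radius_um Soma radius in um (default 2.5, ~5 um extent).
#' @param background_mean Diffuse background concentration, ug/g wtw
#'   (default 30, giving a total mean near the ~37 ug/g measured per SWM
#'   voxel).
#' @param background_cv Coefficient of variation of the background texture
#'   (default 0.1, chosen so simulated full-map linewidths fall in the
#'   ~10 s^-1 range observed for SWM voxels).
#' @param corr_um Background correlation length, um (default 10).
#' @param stripe_contrast Amplitude of an optional oriented (x-modulated)
#'   stripe texture emulating aligned fibers, as a fraction of the background
#'   mean (default 0 = isotropic).
#' @param stripe_period_um Stripe period, um.
#' @param soma_mass_fraction Target fraction of total iron mass inside the
#'   soma disks (default 0.12).
#' @param section_thickness_um Section thickness, um (default 12).
#' @param seed Integer seed.
#' @return An object of class `cellular_scene_config`.
#' @export
cellular_scene_config <- function(fov_um = c(200, 200), pixel_um = 1,
                                  soma_density_mm2 = 2000,
                                  soma_radius_um = 2.5, soma_peak = 100,
                                  background_mean = 30, background_cv = 0.1,
                                  corr_um = 10, stripe_contrast = 0,
                                  stripe_period_um = 12,
                                  soma_mass_fraction = 0.12,
                                  section_thickness_um = 12, seed = 1) {
  cfg <- as.list(environment())
  if (any(unlist(cfg[c("pixel_um", "soma_radius_um", "soma_peak",
                       "background_mean", "section_thickness_um")]) <= 0))
    stop("geometric and concentration parameters must be positive", call. = FALSE)
  if (soma_mass_fraction <= 0 || soma_mass_fraction >= 1)
    stop("soma_mass_fraction must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "cellular_scene_config")
}

#' Generate a synthetic cellular iron map
#'
#' Places non-overlapping soma hotspots (Gaussian bumps of ~5 um extent) on a
#' smooth diffuse background, then rescales the soma component so that the
#' mass inside the ground-truth soma disks matches the configured soma mass
#' fraction exactly while the background keeps its configured mean.
#' Deterministic given (config, seed).
#'
#' @param config A [cellular_scene_config()].
#' @return A list: `map` (an [iron_map()]), `soma_mask` (ground-truth disks),
#'   `soma_centers`, `soma_mass_fraction` (realized), `config`.
#' @export
gen_cellular_iron_map <- function(config = cellular_scene_config()) {
  stopifnot(inherits(config, "cellular_scene_config"))
  set.seed(config$seed)
  nx <- as.integer(round(config$fov_um[1] / config$pixel_um))
  ny <- as.integer(round(config$fov_um[2] / config$pixel_um))
  area_mm2 <- prod(config$fov_um) / 1e6
  n_soma <- as.integer(round(config$soma_density_mm2 * area_mm2))
  r_px <- config$soma_radius_um / config$pixel_um
  if (n_soma * pi * (2 * r_px)^2 > 0.5 * nx * ny)
    stop("infeasible soma density: somata cannot be placed without overlap",
         call. = FALSE)
  # non-overlapping placement by rejection
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(centers) < n_soma) {
    cand <- c(stats::runif(1, 1 + r_px, nx - r_px),
              stats::runif(1, 1 + r_px, ny - r_px))
    if (!nrow(centers) ||
        min((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >
        (2.5 * r_px)^2) {
      centers <- rbind(centers, cand)
    }
    tries <- tries + 1L
    if (tries > 10000L * max(n_soma, 1))
      stop("failed to place somata without overlap", call. = FALSE)
  }
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  soma <- matrix(0, ny, nx)
  truth <- matrix(FALSE, ny, nx)
  sg <- r_px / 1.5  # Gaussian sigma so the bump extent ~ 2 * radius
  if (n_soma > 0) for (i in seq_len(n_soma)) {
    d2 <- (xg - centers[i, 1])^2 + (yg - centers[i, 2])^2
    soma <- soma + config$soma_peak * exp(-d2 / (2 * sg^2)) * (d2 <= (2 * r_px)^2)
    truth <- truth | (d2 <= r_px^2)
  }
  bg <- smooth_noise_2d(nx, ny, config$corr_um, config$pixel_um)
  bg <- config$background_mean * (1 + config$background_cv * bg)
  if (config$stripe_contrast > 0)
    bg <- bg * (1 + config$stripe_contrast *
                  sin(2 * pi * xg * config$pixel_um / config$stripe_period_um))
  bg <- pmax(bg, 0)
  if (n_soma > 0) {
    # scale soma amplitude so soma-disk mass / total mass = target fraction
    f <- config$soma_mass_fraction
    Ms_in <- sum(soma[truth]); Ms_all <- sum(soma)
    Bin <- sum(bg[truth]); Btot <- sum(bg)
    a <- (f * Btot - Bin) / (Ms_in - f * Ms_all)
    if (!is.finite(a) || a <= 0)
      stop("soma mass fraction target infeasible: background inside somata ",
           "already exceeds the target share", call. = FALSE)
    soma <- soma * a
    if (a * config$soma_peak < 70)
      warning(sprintf("realized soma peak %.3g ug/g wtw falls below the 70 ug/g soma threshold",
                      a * config$soma_peak), call. = FALSE)
  }
  vals <- bg + soma
  map <- iron_map(vals, pixel_size_um = config$pixel_um,
                  section_thickness_um = config$section_thickness_um)
  list(map = map, soma_mask = truth, soma_centers = centers,
       soma_mass_fraction = sum(vals[truth]) / sum(vals),
       config = config)
}

#' Configuration of a cortical ribbon phantom
#'
#' A 2D phantom of a cortical ribbon with a gently curved GM-WM boundary.
#' Iron and myelin maps are functions of the signed normal distance to the
#' boundary (depth in percent of cortical depth); band plateaus default to
#' the measured concentrations: upper cortex 15.6, middle cortex 29.2,
#' SWM 55, DWM 33 ug/g wtw. R2* is the linear combination
#' `r_fe * iron + r_m * myelin + offset` (defaults 0.35, 47, 13.7) plus
#' optional Gaussian noise.
#'
#' @param nx,ny Grid size in pixels (x = columns, y = rows).
#' @param cortical_depth_px Cortical depth in pixels.
#' @param boundary_x Mean x-position of the GM-WM boundary (pial side at
#'   smaller x).
#' @param boundary_amplitude_px Sinusoidal boundary amplitude, pixels.
#' @param iron_bands Named vector: `cortex_upper`, `cortex_middle`, `swm`,
#'   `dwm` in ug/g wtw.
#' @param myelin_nodes Data frame (`depth_pct`, `value`) of the myelin
#'   volume-fraction profile nodes, linearly interpolated.
#' @param coefficients Named vector `iron`, `myelin`, `offset` of the R2*
#'   generation model.
#' @param noise_sd SD of additive Gaussian noise on R2*, s^-1.
#' @param seed Integer seed.
#' @return An object of class `ribbon_phantom_config`.
#' @export
ribbon_phantom_config <- function(nx = 160, ny = 120, cortical_depth_px = 40,
                                  boundary_x = 70, boundary_amplitude_px = 4,
                                  iron_bands = c(cortex_upper = 15.6,
                                                 cortex_middle = 29.2,
                                                 swm = 55, dwm = 33),
                                  myelin_nodes = data.frame(
                                    depth_pct = c(-100, -35, 0, 20, 45, 100),
                                    value = c(0.05, 0.12, 0.30, 0.35, 0.33, 0.33)),
                                  coefficients = c(iron = 0.35, myelin = 47,
                                                   offset = 13.7),
                                  noise_sd = 0, seed = 1) {
  cfg <- as.list(environment())
  if (cortical_depth_px <= 0) stop("cortical depth must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  structure(cfg, class = "ribbon_phantom_config")
}

# piecewise-linear iron depth profile with the configured band plateaus
ribbon_iron_profile <- function(depth_pct, bands) {
  nodes_d <- c(-100, -76, -71, -34, 0, 22, 45, 100)
  nodes_v <- c(bands["cortex_upper"], bands["cortex_upper"],
               bands["cortex_middle"], bands["cortex_middle"],
               bands["swm"], bands["swm"], bands["dwm"], bands["dwm"])
  stats::approx(nodes_d, nodes_v, depth_pct, rule = 2)$y
}

#' Generate a cortical ribbon phantom
#'
#' Builds co-registered iron, myelin and R2* maps on one grid plus the GM-WM
#' boundary polyline. Depth is the signed distance to the boundary curve
#' (positive into WM), in percent of cortical depth; band plateaus are wide
#' enough that the named [depth_band()] windows lie entirely on them.
#'
#' @param config A [ribbon_phantom_config()].
#' @return A list: `iron`, `myelin`, `r2s` (matrices), `boundary`
#'   (a [boundary_polyline()]), `truth` (generation coefficients, band
#'   values, noise SD), `config`.
#' @export
gen_ribbon_phantom <- function(config = ribbon_phantom_config()) {
  stopifnot(inherits(config, "ribbon_phantom_config"))
  set.seed(config$seed)
  nx <- config$nx; ny <- config$ny
  yb <- seq(1, ny, by = 0.25)
  xb <- config$boundary_x +
    config$boundary_amplitude_px * sin(2 * pi * yb / ny)
  # signed normal distance of every pixel to the boundary curve
  xg <- matrix(rep(seq_len(nx), each = ny), ny, nx)
  yg <- matrix(rep(seq_len(ny), nx), ny, nx)
  d <- matrix(Inf, ny, nx)
  for (i in seq_along(yb)) {
    di <- sqrt((xg - xb[i])^2 + (yg - yb[i])^2)
    d <- pmin(d, di)
  }
  xbound_at <- stats::approx(yb, xb, pmin(pmax(yg, 1), ny), rule = 2)$y
  d <- d * sign(xg - xbound_at)
  depth_pct <- 100 * d / config$cortical_depth_px
  iron <- matrix(ribbon_iron_profile(depth_pct, config$iron_bands), ny, nx)
  myelin <- matrix(stats::approx(config$myelin_nodes$depth_pct,
                                 config$myelin_nodes$value,
                                 depth_pct, rule = 2)$y, ny, nx)
  cf <- config$coefficients
  r2s <- cf["iron"] * iron + cf["myelin"] * myelin + cf["offset"]
  if (config$noise_sd > 0)
    r2s <- r2s + matrix(stats::rnorm(nx * ny, sd = config$noise_sd), ny, nx)
  bnd <- boundary_polyline(x = stats::approx(yb, xb, seq(1, ny))$y,
                           y = seq(1, ny))
  list(iron = iron, myelin = myelin, r2s = unname(r2s),
       boundary = bnd,
       truth = list(coefficients = cf, iron_bands = config$iron_bands,
                    noise_sd = config$noise_sd,
                    cortical_depth_px = config$cortical_depth_px),
       config = config)
}

#' Configuration of a synthetic per-vertex surface table
#'
#' Per-vertex R2* is generated as
#' `r2s = beta0 + beta1 sin^2(theta) + beta2 sin^4(theta) + eps(region) + noise`
#' with theta drawn sine-weighted (normals of a sphere-like surface). The
#' regional offsets and the noise SD are calibrated from the realized
#' orientation-term variance so that the orientation terms carry the target
#' share of the total variance (default 0.08). Set
#' `orientation_share = NULL` to specify `region_sd` and `noise_sd` directly.
#'
#' @param n_vertices Number of vertices (default 10000).
#' @param beta Named or plain vector (beta0, beta1, beta2), s^-1.
#' @param orientation_share Target fraction of R2* variance carried by the
#'   orientation terms, in (0, 1), or `NULL`.
#' @param noise_fraction When calibrating to `orientation_share`, the share
#'   of the non-orientation variance assigned to i.i.d. noise (the remainder
#'   goes to regional offsets); default 0.5.
#' @param n_regions Number of labelled regions (default 6).
#' @param region_sd,noise_sd Direct SDs, used when `orientation_share` is
#'   `NULL`.
#' @param seed Integer seed.
#' @return An object of class `surface_table_config`.
#' @export
surface_table_config <- function(n_vertices = 10000,
                                 beta = c(beta0 = 20, beta1 = 3, beta2 = -1),
                                 orientation_share = 0.08,
                                 noise_fraction = 0.5, n_regions = 6,
                                 region_sd = 1, noise_sd = 1, seed = 1) {
  if (!is.null(orientation_share) &&
      (orientation_share <= 0 || orientation_share >= 1))
    stop("orientation_share must lie in (0, 1) or be NULL", call. = FALSE)
  beta <- stats::setNames(as.numeric(beta), c("beta0", "beta1", "beta2"))
  structure(list(n_vertices = n_vertices, beta = beta,
                 orientation_share = orientation_share,
                 noise_fraction = noise_fraction, n_regions = n_regions,
                 region_sd = region_sd, noise_sd = noise_sd, seed = seed),
            class = "surface_table_config")
}

#' Generate a synthetic per-vertex surface table
#'
#' @param config A [surface_table_config()].
#' @return A list: `table` (a [surface_table()] with columns vertex, r2s,
#'   theta, region), `truth` (beta, region means, noise SD, realized
#'   orientation variance share), `config`.
#' @export
gen_surface_table <- function(config = surface_table_config()) {
  stopifnot(inherits(config, "surface_table_config"))
  set.seed(config$seed)
  n <- config$n_vertices
  theta <- acos(stats::runif(n, -1, 1))  # sine-weighted, as for sphere normals
  s2 <- sin(theta)^2
  orient <- config$beta["beta1"] * s2 + config$beta["beta2"] * s2^2
  vo <- stats::var(orient)
  if (!is.null(config$orientation_share)) {
    if (vo == 0)
      stop("orientation_share calibration needs nonzero beta1/beta2", call. = FALSE)
    vrest <- vo * (1 / config$orientation_share - 1)
    noise_sd <- sqrt(config$noise_fraction * vrest)
    region_sd <- sqrt((1 - config$noise_fraction) * vrest)
  } else {
    noise_sd <- config$noise_sd
    region_sd <- config$region_sd
  }
  region <- sample.int(config$n_regions, n, replace = TRUE)
  rmeans_raw <- stats::rnorm(config$n_regions)
  rmeans_raw <- rmeans_raw - mean(rmeans_raw)
  eps_reg <- rmeans_raw[region]
  sd0 <- stats::sd(eps_reg)
  region_means <- if (sd0 > 0) rmeans_raw * region_sd / sd0 else rmeans_raw
  eps_reg <- region_means[region]
  noise <- stats::rnorm(n, sd = noise_sd)
  r2s <- as.numeric(config$beta["beta0"] + orient + eps_reg + noise)
  tab <- surface_table(data.frame(vertex = seq_len(n), r2s = r2s,
                                  theta = theta, region = region))
  list(table = tab,
       truth = list(beta = config$beta, region_means = region_means,
                    noise_sd = noise_sd,
                    orientation_variance_share =
                      stats::var(as.numeric(orient)) / stats::var(r2s)),
       config = config)
}
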