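# Closed-form nanoscale, mesoscale and myelin-orientation relaxation
# contributions and their assembly into the voxel-level forward model.

#' Slab geometry of an SWM voxel
#'
#' Describes the superficial-white-matter slab inside an imaging voxel: its
#' orientation to the static field, its iron excess over the surrounding
#' tissue, its partial volume and the echo time of the acquisition.
#'
#' @param theta Angle between the slab surface normal and B0, rad.
#' @param delta_c_fe Iron concentration difference slab minus surround,
#'   ug/g wtw.
#' @param p Slab partial volume fraction in the voxel, in \[0, 1\].
#' @param te Echo time, s (> 0).
#' @return An object of class `slab_geometry`.
#' @export
slab_geometry <- function(theta = 0, delta_c_fe = 22, p = 0.5, te = 0.02) {
  if (p < 0 || p > 1) stop("partial volume p must lie in [0, 1]", call. = FALSE)
  if (te <= 0) stop("echo time must be positive", call. = FALSE)
  structure(list(theta = theta, delta_c_fe = delta_c_fe, p = p, te = te),
            class = "slab_geometry")
}

#' Myelin orientation model coefficients
#'
#' Coefficients of the empirical myelin contribution to R2*:
#' `c_r2s + a1 sin^2(theta*) + a2 sin^4(theta*)` for a single fiber at angle
#' `theta*` to B0. The slab-averaged coefficients `a1_star`, `a2_star` (for
#' fibers uniformly oriented within the SWM plane) are derived deterministically
#' via [in_plane_average()] and stored alongside.
#'
#' @param c_r2s Orientation-independent myelin term, s^-1.
#' @param a1,a2 Single-fiber orientation coefficients, s^-1.
#' @return An object of class `myelin_model` with fields `c_r2s_star`,
#'   `a1_star`, `a2_star` giving the polynomial in sin(theta) of the
#'   slab-normal angle.
#' @export
myelin_model <- function(c_r2s = 0, a1 = 0, a2 = 0) {
  # averaged form: C* = C + a1 + a2, a1* = -a1/2 - a2, a2* = 3/8 a2
  structure(list(c_r2s = c_r2s, a1 = a1, a2 = a2,
                 c_r2s_star = c_r2s + a1 + a2,
                 a1_star = -a1 / 2 - a2,
                 a2_star = 3 / 8 * a2),
            class = "myelin_model")
}

#' Nanoscale iron contribution to R2
#'
#' Water protons exchanging near ferritin cores relax at a rate proportional
#' to the tissue iron concentration: `dR2_nano = r2_nano * c_fe`. With the
#' default relaxivity 0.0225 s^-1/(ug/g wtw) and the SWM concentration
#' 55 ug/g wtw this evaluates to 1.2375 s^-1.
#'
#' @param c_fe Iron concentration, ug/g wtw (nonnegative; vectorized).
#' @param constants A [swm_constants()] object.
#' @return Relaxation rate, s^-1.
#' @export
r2_nano <- function(c_fe, constants = swm_constants()) {
  if (any(c_fe < 0)) stop("iron concentration must be nonnegative", call. = FALSE)
  constants$r2_nano * c_fe
}

#' Frequency offset inside an iron-rich tissue slab
#'
#' An effectively infinite slab with iron excess `delta_c_fe` shifts the
#' Larmor frequency of water inside it by
#' `dOmega = gamma * B0 * chi * (sin^2(theta) - 2/3)`, where `chi` is the
#' volume susceptibility of the iron excess and `theta` the angle between the
#' slab normal and B0. The offset vanishes at the magic angle
#' `sin^2(theta) = 2/3`.
#'
#' @param slab A [slab_geometry()].
#' @param constants A [swm_constants()] object.
#' @return Signed angular frequency offset, rad/s.
#' @export
slab_frequency_offset <- function(slab, constants = swm_constants()) {
  stopifnot(inherits(slab, "slab_geometry"))
  chi <- mass_to_volume_susceptibility(abs(slab$delta_c_fe), constants) *
    sign(slab$delta_c_fe)
  constants$gamma * constants$B0 * chi * (sin(slab$theta)^2 - 2 / 3)
}

#' Mesoscale reversible relaxation from slab partial volume
#'
#' When the voxel is larger than the slab, the frequency offset between slab
#' and surround dephases the voxel signal at the reversible rate
#' `dR2'_meso ~ p (1 - p) / 2 * dOmega^2 * TE`. The quadratic-in-time
#' approximation is valid for small `dOmega * TE`; [two_compartment_signal()]
#' provides the exact two-pool magnitude for checking the regime.
#'
#' @param slab A [slab_geometry()].
#' @param constants A [swm_constants()] object.
#' @return Relaxation rate, s^-1 (nonnegative; zero at p = 0, p = 1 and at
#'   the magic angle).
#' @export
r2prime_meso <- function(slab, constants = swm_constants()) {
  stopifnot(inherits(slab, "slab_geometry"))
  dO <- slab_frequency_offset(slab, constants)
  slab$p * (1 - slab$p) / 2 * dO^2 * slab$te
}

#' Exact two-compartment signal magnitude
#'
#' Magnitude of the net signal of a voxel containing a slab fraction `p`
#' offset by `dOmega`: `|S(t)| = |(1 - p) + p exp(i dOmega t)|`. The
#' effective rate `-log|S(te)| / te` is returned per echo time; for small
#' `dOmega * te` it agrees with [r2prime_meso()] to relative error
#' O((dOmega * te)^2). Serves as the numerical oracle for the quadratic
#' mesoscale approximation.
#'
#' @param slab A [slab_geometry()].
#' @param te_grid Echo times, s (> 0).
#' @param constants A [swm_constants()] object.
#' @return A data.frame with columns `te`, `magnitude` and `rate`.
#' @export
two_compartment_signal <- function(slab, te_grid = slab$te,
                                   constants = swm_constants()) {
  stopifnot(inherits(slab, "slab_geometry"))
  if (any(te_grid <= 0)) stop("echo times must be positive", call. = FALSE)
  dO <- slab_frequency_offset(slab, constants)
  s <- Mod((1 - slab$p) + slab$p * exp(1i * dO * te_grid))
  data.frame(te = te_grid, magnitude = s, rate = -log(s) / te_grid)
}

#' In-plane fiber-orientation average of sin^2 and sin^4 terms
#'
#' For fibers uniformly oriented within a plane whose normal makes angle
#' `theta` with B0, the fiber-to-field angle `theta*` satisfies
#' `cos(theta*) = -cos(phi) sin(theta)` for uniform azimuth `phi`. Averaging
#' over `phi` gives the closed forms
#' `<sin^2 theta*> = 1 - sin^2(theta) / 2` and
#' `<sin^4 theta*> = 1 - sin^2(theta) + 3/8 sin^4(theta)`,
#' each a fixed polynomial in `sin^2(theta)`. Passing an explicit azimuth
#' sample replaces the uniform average by an empirical one (hook for
#' non-uniform in-plane fiber dispersion).
#'
#' @param theta Slab-normal angle(s) to B0, rad (vectorized).
#' @param azimuth_sample Optional numeric vector of in-plane fiber azimuths,
#'   rad; when given, the average is taken over this sample instead of the
#'   closed form.
#' @return A list with `mean_sin2` and `mean_sin4`, same length as `theta`.
#' @export
in_plane_average <- function(theta, azimuth_sample = NULL) {
  s2 <- sin(theta)^2
  if (is.null(azimuth_sample)) {
    list(mean_sin2 = 1 - s2 / 2,
         mean_sin4 = 1 - s2 + 3 / 8 * s2^2)
  } else {
    c2 <- mean(cos(azimuth_sample)^2)
    c4 <- mean(cos(azimuth_sample)^4)
    list(mean_sin2 = 1 - c2 * s2,
         mean_sin4 = 1 - 2 * c2 * s2 + c4 * s2^2)
  }
}

#' Slab-averaged myelin contribution to R2*
#'
#' Evaluates the myelin term for an SWM slab whose fibers are uniformly
#' oriented in-plane, either by averaging the single-fiber law over
#' [in_plane_average()] or equivalently through the derived polynomial
#' `c_r2s_star + a1_star sin^2(theta) + a2_star sin^4(theta)`; the two
#' parameterizations are algebraically identical.
#'
#' @param model A [myelin_model()].
#' @param theta Slab-normal angle(s) to B0, rad.
#' @return Relaxation rate(s), s^-1.
#' @export
r2star_myelin_slab <- function(model, theta) {
  stopifnot(inherits(model, "myelin_model"))
  av <- in_plane_average(theta)
  model$c_r2s + model$a1 * av$mean_sin2 + model$a2 * av$mean_sin4
}

#' Voxel composition for the forward model
#'
#' Bundles everything the forward model needs for one SWM voxel: total iron
#' concentration, slab geometry, myelin coefficients, the microscale
#' relaxivity (a scalar, typically from a field simulation or the reference
#' value 0.215 s^-1/(ug/g wtw)) and the constant rate of other tissue
#' components.
#'
#' @param c_fe Voxel iron concentration, ug/g wtw.
#' @param slab A [slab_geometry()].
#' @param myelin A [myelin_model()].
#' @param r2_other Orientation- and iron-independent rate, s^-1.
#' @param micro_relaxivity Microscale relaxivity, s^-1 per (ug/g wtw).
#' @return An object of class `voxel_composition`.
#' @export
voxel_composition <- function(c_fe = 55, slab = slab_geometry(),
                              myelin = myelin_model(), r2_other = 0,
                              micro_relaxivity = 0.215) {
  if (c_fe < 0 || r2_other < 0 || micro_relaxivity < 0)
    stop("rates and concentrations must be nonnegative", call. = FALSE)
  stopifnot(inherits(slab, "slab_geometry"), inherits(myelin, "myelin_model"))
  structure(list(c_fe = c_fe, slab = slab, myelin = myelin,
                 r2_other = r2_other, micro_relaxivity = micro_relaxivity),
            class = "voxel_composition")
}

#' Forward model of R2* in an SWM voxel
#'
#' Assembles the multiscale contributions into the total effective
#' transverse relaxation rate
#' `R2*_SWM = (r2_nano + r2*_micro) c_fe
#'            + p(1-p)/2 * (gamma B0 chi dC)^2 (sin^2 theta - 2/3)^2 * TE
#'            + C* + a1* sin^2 theta + a2* sin^4 theta + R2*_other`
#' and returns the per-mechanism breakdown alongside the total.
#'
#' @param voxel A [voxel_composition()].
#' @param constants A [swm_constants()] object.
#' @return A list with `total` (s^-1) and `breakdown`, a named numeric vector
#'   with elements `nano`, `micro`, `meso`, `myelin`, `other` summing to the
#'   total.
#' @export
forward_r2star <- function(voxel, constants = swm_constants()) {
  stopifnot(inherits(voxel, "voxel_composition"))
  br <- c(nano = r2_nano(voxel$c_fe, constants),
          micro = voxel$micro_relaxivity * voxel$c_fe,
          meso = r2prime_meso(voxel$slab, constants),
          myelin = r2star_myelin_slab(voxel$myelin, voxel$slab$theta),
          other = voxel$r2_other)
  list(total = sum(br), breakdown = br)
}
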