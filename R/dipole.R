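# Static-dephasing field simulation: susceptibility -> intravoxel Larmor
# frequency offsets by dipole convolution in Fourier space.

fft_freq <- function(n, d = 1) {
  # unit: cycles per physical unit of d; layout matches R's fft ordering
  i <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  i / (n * d)
}

#' Dipole kernel in Fourier space
#'
#' The k-space kernel `D(k) = 1/3 - (k . b)^2 / |k|^2` relating a periodic
#' susceptibility distribution to the induced field offset along the unit
#' field direction `b`. The k = 0 component is set to zero, i.e. the
#' susceptibility map is implicitly referenced to its mean (no Lorentz sphere
#' correction is applied).
#'
#' @param dims Integer grid dimensions (length 3).
#' @param pixel_size Physical voxel size per axis (any consistent unit).
#' @param b0_direction Unit vector of the static field in grid coordinates.
#' @return A 3D array with values in \[-2/3, 1/3\].
#' @export
dipole_kernel <- function(dims, pixel_size = c(1, 1, 1), b0_direction = c(0, 0, 1)) {
  stopifnot(length(dims) == 3L)
  pixel_size <- rep(pixel_size, length.out = 3L)
  b <- as.numeric(b0_direction)
  nb <- sqrt(sum(b^2))
  if (nb == 0) stop("b0_direction must be nonzero", call. = FALSE)
  if (abs(nb - 1) > 1e-8) {
    warning("b0_direction normalized to unit length", call. = FALSE)
  }
  b <- b / nb
  kx <- fft_freq(dims[1], pixel_size[1])
  ky <- fft_freq(dims[2], pixel_size[2])
  kz <- fft_freq(dims[3], pixel_size[3])
  KX <- array(kx, dims)
  KY <- array(rep(ky, each = dims[1]), dims)
  KZ <- array(rep(kz, each = dims[1] * dims[2]), dims)
  k2 <- KX^2 + KY^2 + KZ^2
  kb <- KX * b[1] + KY * b[2] + KZ * b[3]
  D <- 1 / 3 - (kb^2) / k2
  D[k2 == 0] <- 0
  D
}

#' Simulate the intravoxel Larmor frequency offset field
#'
#' Converts a 3D iron concentration volume (or a raw susceptibility array) to
#' the static-dephasing Larmor frequency offset map
#' `dw(r) = gamma * B0 * IFFT[ D(k) * FFT[chi] ](r)` with periodic boundary
#' conditions. The output is demeaned over the full grid (the k = 0 component
#' is zeroed, so the mean susceptibility produces no offset). Water diffusion
#' is neglected throughout: this is the static dephasing limit, an upper
#' bound for the microscale R2*' contribution.
#'
#' @param map An `iron_map` (3D; concentrations converted internally with
#'   [mass_to_volume_susceptibility()]) or a 3D numeric array interpreted
#'   directly as volume susceptibility.
#' @param b0_direction Unit vector of B0 in grid coordinates.
#' @param constants A [swm_constants()] object.
#' @param pixel_size Voxel size per axis; taken from the `iron_map` when one
#'   is supplied.
#' @return An object of class `larmor_field` with elements `values` (rad/s),
#'   `b0_direction`, `demeaned`, `pixel_size_um` and `reference` (a note that
#'   the field is referenced to the mean susceptibility).
#' @export
dipole_field <- function(map, b0_direction = c(0, 0, 1),
                         constants = swm_constants(), pixel_size = NULL) {
  if (inherits(map, "iron_map")) {
    if (length(dim(map$values)) != 3L)
      stop("field simulation needs a 3D volume; use stack_sections() on 2D sections",
           call. = FALSE)
    chi <- mass_to_volume_susceptibility(map$values, constants)
    chi <- array(chi, dim = dim(map$values))
    pixel_size <- map$pixel_size_um
  } else {
    chi <- map
    if (length(dim(chi)) != 3L) stop("susceptibility array must be 3D", call. = FALSE)
    if (is.null(pixel_size)) pixel_size <- c(1, 1, 1)
  }
  if (any(dim(chi) < 2L)) stop("grid needs at least 2 voxels per axis", call. = FALSE)
  if (any(!is.finite(chi))) stop("susceptibility contains non-finite values", call. = FALSE)
  b <- as.numeric(b0_direction)
  b <- b / sqrt(sum(b^2))
  if (all(chi == 0)) {
    field <- array(0, dim(chi))
  } else {
    D <- dipole_kernel(dim(chi), pixel_size, b)
    field <- Re(fft(D * fft(chi), inverse = TRUE)) / length(chi)
    field <- constants$gamma * constants$B0 * field
    field <- field - mean(field)
  }
  structure(list(values = field, b0_direction = b, demeaned = TRUE,
                 pixel_size_um = rep(pixel_size, length.out = 3L),
                 reference = "mean susceptibility (D(k=0) = 0, no Lorentz sphere correction)"),
            class = "larmor_field")
}

#' @export
print.larmor_field <- function(x, ...) {
  cat(sprintf("larmor_field: %s grid, B0 along (%s)\n",
              paste(dim(x$values), collapse = " x "),
              paste(signif(x$b0_direction, 3), collapse = ", ")))
  cat(sprintf("  offsets rad/s: sd %.3g, range [%.3g, %.3g]%s\n",
              stats::sd(x$values), min(x$values), max(x$values),
              if (isTRUE(x$demeaned)) ", demeaned" else ""))
  invisible(x)
}

#' Analytic far field of a magnetized point source
#'
#' Closed-form angular frequency offset of a point dipole of susceptibility
#' `chi` occupying volume `V`:
#' `dw(r) = gamma * B0 * chi * V / (4 pi r^3) * (3 cos^2(beta) - 1)`,
#' with `beta` the angle between the offset vector and B0. Serves as the
#' independent oracle for the Fourier-space simulation; it is exact in the
#' far field of an isolated sphere and vanishes on the magic-angle cone
#' `3 cos^2(beta) = 1`.
#'
#' @param r_vec Matrix of offset vectors from the source (rows), same length
#'   unit as `volume`^(1/3).
#' @param chi Volume susceptibility of the source voxel.
#' @param volume Source volume (e.g. voxel volume).
#' @param b0_direction Unit field direction.
#' @param constants A [swm_constants()] object.
#' @return Angular frequency offsets, rad/s.
#' @export
point_dipole_field <- function(r_vec, chi, volume, b0_direction = c(0, 0, 1),
                               constants = swm_constants()) {
  r_vec <- rbind(r_vec)
  b <- as.numeric(b0_direction); b <- b / sqrt(sum(b^2))
  r <- sqrt(rowSums(r_vec^2))
  cosb <- as.numeric(r_vec %*% b) / r
  constants$gamma * constants$B0 * chi * volume / (4 * pi * r^3) *
    (3 * cosb^2 - 1)
}
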