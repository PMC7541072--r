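#' Physical constants of the SWM relaxation model
#'
#' Bundles every physical constant used by the multiscale forward model of
#' iron-induced R2* relaxation: the proton gyromagnetic ratio, the static
#' field strength, the mass magnetic susceptibility of ferritin-bound iron,
#' the nanoscale relaxivity of ferritin-bound iron, the wet-tissue density and
#' the section shrinkage factor used when converting dehydrated-section
#' concentrations back to wet-tissue mass concentrations.
#'
#' All frequencies in the package are angular (rad/s); quoted relaxation-rate
#' values in "s^-1" follow the same convention. Iron concentrations are in
#' micrograms per gram of wet tissue weight (ug/g wtw); "ppm wtw" is the same
#' unit (1 ppm by mass = 1 ug/g).
#'
#' @param gamma Proton gyromagnetic ratio, rad s^-1 T^-1.
#' @param B0 Static magnetic field strength, tesla.
#' @param chi_mass_fe Mass magnetic susceptibility of ferritin-bound iron,
#'   dimensionless SI per (ug/g wtw). Literature values for brain iron range
#'   from 0.8e-9 to 1.37e-9; the ferritin value 1.37e-9 is the default.
#' @param r2_nano Nanoscale relaxivity of ferritin-bound iron at 7 T,
#'   s^-1 per (ug/g wtw).
#' @param tissue_density Wet brain tissue density, g/ml.
#' @param shrinkage_factor Dimensionless tissue volume shrinkage factor of a
#'   dehydrated histological section relative to wet tissue.
#'
#' @return An object of class `swm_constants` (a named list).
#' @examples
#' cst <- swm_constants()
#' cst$chi_mass_fe * 55   # volume susceptibility of 55 ug/g wtw iron
#' @export
swm_constants <- function(gamma = 2.675e8,
                          B0 = 7.0,
                          chi_mass_fe = 1.37e-9,
                          r2_nano = 0.0225,
                          tissue_density = 1.05,
                          shrinkage_factor = 0.7) {
  cst <- list(gamma = gamma, B0 = B0, chi_mass_fe = chi_mass_fe,
              r2_nano = r2_nano, tissue_density = tissue_density,
              shrinkage_factor = shrinkage_factor)
  for (nm in names(cst)) {
    v <- cst[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("constant '", nm, "' must be a single strictly positive number",
           call. = FALSE)
  }
  structure(cst, class = "swm_constants")
}

#' @export
print.swm_constants <- function(x, ...) {
  cat("SWM model physical constants:\n")
  cat(sprintf("  gamma            %.4g rad/s/T\n", x$gamma))
  cat(sprintf("  B0               %.4g T\n", x$B0))
  cat(sprintf("  chi_mass_fe      %.4g per (ug/g wtw)\n", x$chi_mass_fe))
  cat(sprintf("  r2_nano          %.4g s^-1 per (ug/g wtw)\n", x$r2_nano))
  cat(sprintf("  tissue_density   %.4g g/ml\n", x$tissue_density))
  cat(sprintf("  shrinkage_factor %.4g\n", x$shrinkage_factor))
  invisible(x)
}

#' Load physical constants from a configuration file
#'
#' Reads a YAML or JSON file whose top-level keys are a subset of the
#' arguments of [swm_constants()]; unspecified constants keep their defaults.
#' Unknown keys are an error, so typos cannot silently leave a default in
#' place.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `swm_constants`.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported constants file format: .", ext, call. = FALSE))
  known <- names(formals(swm_constants))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown constant(s) in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(swm_constants, lapply(vals, as.numeric))
}

#' Convert mass iron concentration to volume magnetic susceptibility
#'
#' Multiplies an iron concentration in ug/g wet tissue weight by the mass
#' magnetic susceptibility of ferritin-bound iron, yielding the dimensionless
#' SI volume susceptibility. Linear and shape-preserving, so it applies
#' equally to scalars, vectors and gridded maps.
#'
#' @param c_fe Iron concentration(s), ug/g wtw; must be nonnegative.
#' @param constants A [swm_constants()] object.
#' @return Volume susceptibility, same shape as `c_fe`.
#' @examples
#' mass_to_volume_susceptibility(55)  # 7.535e-08
#' @export
mass_to_volume_susceptibility <- function(c_fe, constants = swm_constants()) {
  stopifnot(inherits(constants, "swm_constants"))
  cv <- as.numeric(c_fe)
  if (anyNA(cv)) stop("iron concentration contains NA", call. = FALSE)
  if (any(cv < 0))
    stop(sprintf("iron concentration must be nonnegative; found values in [%.4g, %.4g]",
                 min(cv), max(cv)), call. = FALSE)
  constants$chi_mass_fe * c_fe
}

#' Convert volume susceptibility back to mass iron concentration
#'
#' Inverse of [mass_to_volume_susceptibility()].
#'
#' @param chi Volume susceptibility (dimensionless SI).
#' @param constants A [swm_constants()] object.
#' @return Iron concentration, ug/g wtw.
#' @export
volume_susceptibility_to_mass <- function(chi, constants = swm_constants()) {
  stopifnot(inherits(constants, "swm_constants"))
  chi / constants$chi_mass_fe
}

#' Convert section concentration to wet-tissue mass concentration
#'
#' Elemental microscopy quantifies iron per volume of a dehydrated,
#' shrunken section. The conversion to mass concentration in wet tissue used
#' throughout the model is
#' `c_wtw = c_section * shrinkage_factor / tissue_density`,
#' with the shrinkage factor and tissue density taken from `constants`. The
#' direction of this convention is fixed here; to apply the inverse, pass the
#' reciprocal factors through a custom [swm_constants()] object.
#'
#' @param c_section Concentration in the dehydrated section, ug/ml;
#'   nonnegative, any shape.
#' @param constants A [swm_constants()] object.
#' @return Concentration in ug/g wtw, same shape.
#' @examples
#' areal_to_mass_concentration(1.05)  # 0.7 with default factors
#' @export
areal_to_mass_concentration <- function(c_section, constants = swm_constants()) {
  stopifnot(inherits(constants, "swm_constants"))
  cv <- as.numeric(c_section)
  if (anyNA(cv)) stop("section concentration contains NA", call. = FALSE)
  if (any(cv < 0))
    stop(sprintf("section concentration must be nonnegative; found values in [%.4g, %.4g]",
                 min(cv), max(cv)), call. = FALSE)
  c_section * constants$shrinkage_factor / constants$tissue_density
}
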