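# Readers and writers: CSV grids with JSON sidecars, single-channel TIFF,
# NIfTI volumes, per-vertex tables and line-shape exports.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Read a gridded quantitative map
#'
#' Reads a 2D/3D quantitative map with its pixel geometry and declared units.
#' Supported formats: CSV grid plus a JSON sidecar (`pixel_size_um`, `units`,
#' optional `section_thickness_um`), single-channel TIFF plus the same
#' sidecar, or NIfTI (pixel size from the header, units from the `descrip`
#' field when present).
#'
#' @param path File path (`.csv`, `.tif`/`.tiff`, `.nii`/`.nii.gz`).
#' @param expect_units Optional unit string; mismatch with the declared units
#'   is an error.
#' @return A list: `values`, `pixel_size_um`, `units`,
#'   `section_thickness_um` (may be NULL).
#' @export
read_quantitative_map <- function(path, expect_units = NULL) {
  if (!file.exists(path)) stop("map file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("nii",  "hdr")) {
    img <- RNifti::readNifti(path)
    hdr <- RNifti::niftiHeader(img)
    nd <- length(dim(img))
    meta <- list(values = array(as.numeric(img), dim = dim(img)),
                 pixel_size_um = hdr$pixdim[2:(1 + nd)] * 1000,
                 units = if (nzchar(hdr$descrip)) hdr$descrip else NA_character_,
                 section_thickness_um = NULL)
  } else if (ext %in% c("csv", "tif", "tiff")) {
    sc <- sidecar_path(path)
    if (!file.exists(sc))
      stop("missing sidecar metadata ", sc,
           " (expected JSON with pixel_size_um and units)", call. = FALSE)
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(side$pixel_size_um))
      stop("sidecar ", sc, " lacks pixel_size_um", call. = FALSE)
    vals <- if (ext == "csv") {
      as.matrix(utils::read.csv(path, header = FALSE))
    } else {
      # float TIFFs are returned as stored; integer TIFFs arrive normalized
      # to [0, 1], so the sidecar's value_scale maps them to physical units
      v <- tiff::readTIFF(path)
      if (length(dim(v)) == 3L) v <- v[, , 1]
      scale <- if (!is.null(side$value_scale)) side$value_scale else 1
      v * scale
    }
    dimnames(vals) <- NULL
    meta <- list(values = vals,
                 pixel_size_um = as.numeric(side$pixel_size_um),
                 units = if (!is.null(side$units)) side$units else NA_character_,
                 section_thickness_um = side$section_thickness_um)
  } else {
    stop("unsupported map format: .", ext, call. = FALSE)
  }
  if (!is.null(expect_units) && !is.na(meta$units) &&
      !identical(meta$units, expect_units))
    stop(sprintf("unit mismatch for %s: declared '%s', expected '%s'",
                 path, meta$units, expect_units), call. = FALSE)
  meta
}

#' Write a gridded quantitative map
#'
#' Writes a 2D map as a headerless CSV grid plus a JSON metadata sidecar, or
#' a 3D volume as NIfTI with the pixel size in the header and the unit string
#' in `descrip`.
#'
#' @param values Matrix or 3D array (an [iron_map()] is accepted).
#' @param path Output path (`.csv` for 2D, `.nii`/`.nii.gz` for 3D).
#' @param pixel_size_um Pixel size per axis, um.
#' @param units Unit string recorded in the metadata.
#' @param section_thickness_um Optional, recorded for 2D sections.
#' @return The path, invisibly.
#' @export
write_quantitative_map <- function(values, path, pixel_size_um = 1,
                                   units = "ug/g wtw",
                                   section_thickness_um = NULL) {
  if (inherits(values, "iron_map")) {
    pixel_size_um <- values$pixel_size_um
    section_thickness_um <- values$section_thickness_um
    values <- values$values
  }
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext == "csv") {
    if (length(dim(values)) != 2L) stop("CSV output supports 2D maps", call. = FALSE)
    utils::write.table(values, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(
      Filter(Negate(is.null),
             list(pixel_size_um = pixel_size_um, units = units,
                  section_thickness_um = section_thickness_um)),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "nii") {
    img <- RNifti::asNifti(values)
    nd <- length(dim(values))
    ps <- rep(pixel_size_um, length.out = nd)
    img <- RNifti::asNifti(values, reference = list(
      pixdim = c(1, ps / 1000, rep(1, 7 - nd)), descrip = units))
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported output format: .", ext, call. = FALSE)
  }
  invisible(path)
}

#' Write a fitted line shape
#'
#' Exports the histogram as a two-column CSV (`frequency_rad_s`, `density`)
#' and the fit summary (model, FWHM, residuals of both candidates) as JSON.
#'
#' @param ls A `line_shape` (ideally after [fit_line_shape()]).
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.csv` and `<prefix>_fit.json`.
#' @return The two paths, invisibly.
#' @export
write_line_shape <- function(ls, path_prefix) {
  stopifnot(inherits(ls, "line_shape"))
  csv <- paste0(path_prefix, ".csv")
  utils::write.csv(data.frame(frequency_rad_s = ls$bin_centers,
                              density = ls$density), csv, row.names = FALSE)
  js <- paste0(path_prefix, "_fit.json")
  summ <- list(model = ls$model, fwhm_rad_s = ls$fwhm,
               fit_residual = ls$fit_residual, n_voxels = ls$n,
               degenerate = isTRUE(ls$degenerate))
  if (!is.null(ls$fits))
    summ$candidates <- lapply(ls$fits, function(f)
      f[c("shape", "amplitude", "width", "fwhm", "residual")])
  jsonlite::write_json(summ, js, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(csv, js))
}

#' Read/write per-vertex surface tables
#'
#' Surface tables travel as plain CSV with a one-line JSON metadata sidecar
#' (B0 direction, SWM sampling depth, smoothing provenance, free-form keys).
#'
#' @param path CSV path.
#' @param table A [surface_table()].
#' @param metadata Named list written to the sidecar.
#' @return `read_surface_table`: a `surface_table` with attribute
#'   `metadata`; `write_surface_table`: the path, invisibly.
#' @export
read_surface_table <- function(path) {
  tab <- surface_table(utils::read.csv(path))
  sc <- sidecar_path(path)
  if (file.exists(sc))
    attr(tab, "metadata") <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tab
}

#' @rdname read_surface_table
#' @export
write_surface_table <- function(table, path, metadata = list()) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  if (length(metadata))
    jsonlite::write_json(metadata, sidecar_path(path), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' Read/write a boundary polyline
#'
#' Two-column CSV (`x`, `y`) in map pixel coordinates.
#'
#' @param path CSV path.
#' @param boundary A [boundary_polyline()].
#' @return `read_boundary`: a `boundary_polyline`; `write_boundary`: the
#'   path, invisibly.
#' @export
read_boundary <- function(path) {
  d <- utils::read.csv(path)
  boundary_polyline(d$x, d$y)
}

#' @rdname read_boundary
#' @export
write_boundary <- function(boundary, path) {
  utils::write.csv(as.data.frame(boundary), path, row.names = FALSE)
  invisible(path)
}
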