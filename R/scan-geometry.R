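# Raster-scan geometry: how the scanner field under the DO maps to pixel
# sizes at the DO object plane and, through the MO lateral magnification,
# at the specimen.

#' Raster-scan geometry of the compound assembly
#'
#' @param base_field_mm scan-field edge length at the DO object plane at
#'   zoom 1 (mm).
#' @param zoom scanner zoom factor (>= 1 shrinks the field).
#' @param npix pixels per frame edge.
#' @param lateral_mag_mo lateral magnification `M_L` of the MO.
#' @param fov_diameter_um diameter of one FOV at the specimen (um).
#' @return an object of class `scan_geometry`.
#' @examples
#' g <- scan_geometry()   # 6 mm field, zoom 1.4, 1200 px, M_L ~7.93
#' pixel_size(g)
#' @export
scan_geometry <- function(base_field_mm = 6, zoom = 1.4, npix = 1200,
                          lateral_mag_mo = lateral_magnification(0.1675),
                          fov_diameter_um = 200) {
  stopifnot(base_field_mm > 0, zoom > 0, npix > 0, lateral_mag_mo > 0,
            fov_diameter_um > 0)
  structure(list(base_field_mm = base_field_mm, zoom = zoom,
                 npix = as.integer(npix), lateral_mag_mo = lateral_mag_mo,
                 fov_diameter_um = fov_diameter_um,
                 effective_field_mm = base_field_mm / zoom),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  px <- pixel_size(x)
  cat(sprintf("Scan geometry: %.3g mm field / zoom %.2g -> %.3g mm, %d px\n",
              x$base_field_mm, x$zoom, x$effective_field_mm, x$npix))
  cat(sprintf("  pixel %.3g um at DO plane, %.3g um at specimen (M_L %.3g)\n",
              px[["do_plane_um"]], px[["specimen_um"]], x$lateral_mag_mo))
  invisible(x)
}

#' Pixel size at the DO object plane and at the specimen
#'
#' The effective field is `base_field / zoom`; dividing by the pixel count
#' gives the pixel size at the DO object plane, and dividing that by the MO
#' lateral magnification gives the pixel size at the specimen inside a FOV.
#'
#' @param geometry a [scan_geometry()].
#' @return named numeric vector `c(do_plane_um, specimen_um)`.
#' @export
pixel_size <- function(geometry) {
  stopifnot(inherits(geometry, "scan_geometry"))
  at_do <- geometry$effective_field_mm * 1000 / geometry$npix
  c(do_plane_um = at_do, specimen_um = at_do / geometry$lateral_mag_mo)
}

#' Diameter of the targetable zone under a dry objective
#'
#' The zone inside which MOs can be placed scales inversely with the DO
#' magnification: `zone = image_side_field / magnification`. The image-side
#' field constant is a calibration value (24 mm reproduces the zone
#' diameters of all four supported DO models).
#'
#' @param do_magnification lateral magnification of the DO.
#' @param image_side_field_mm image-side field constant (mm).
#' @return zone diameter in mm.
#' @examples
#' target_zone_diameter(2)    # 12 mm, about an adult mouse brain
#' target_zone_diameter(2.5)  # 9.6 mm
#' @export
target_zone_diameter <- function(do_magnification, image_side_field_mm = 24) {
  stopifnot(do_magnification > 0, image_side_field_mm > 0)
  image_side_field_mm / do_magnification
}

#' Laser power available per FOV
#'
#' Total post-assembly excitation power is shared among the simultaneously
#' scanned FOVs.
#'
#' @param total_mw measured power under the assembly (mW).
#' @param n_fov number of FOVs.
#' @return per-FOV power in mW.
#' @examples
#' per_fov_power(112, 3)  # ~37 mW
#' @export
per_fov_power <- function(total_mw, n_fov) {
  stopifnot(total_mw >= 0, n_fov >= 1)
  total_mw / n_fov
}

# Measured bead FWHMs (um) per DO model; analytic PSF prediction is
# unreliable for GRIN assemblies, so these calibration values are used by
# the simulator. Keyed by DO magnification.
psf_table <- list(
  `5`   = list(model = "Olympus MPlan N x5",
               on = c(lateral_um = 1.0, axial_um = 35),
               off = c(lateral_um = 1.3, axial_um = 46)),
  `4`   = list(model = "Olympus MPlan N x4",
               on = c(lateral_um = 1.1, axial_um = 37),
               off = c(lateral_um = 1.4, axial_um = 45)),
  `2.5` = list(model = "Olympus MPlan FL N x2.5",
               on = c(lateral_um = 1.4, axial_um = 42),
               off = c(lateral_um = 1.6, axial_um = 48)),
  `2`   = list(model = "Mitutoyo MPlan Apo x2",
               on = c(lateral_um = 1.5, axial_um = 51),
               off = c(lateral_um = 1.8, axial_um = 54))
)

#' Measured point-spread-function FWHM for a supported DO model
#'
#' Returns bead-measured lateral and axial FWHMs for the compound assembly
#' under one of the four calibrated dry objectives, on- or off-axis. These
#' are measured calibration constants, not diffraction-limit predictions:
#' GRIN aberrations make analytic PSF formulas unreliable for this
#' assembly.
#'
#' @param do_spec a [dry_objective_spec()] or a bare magnification value
#'   (one of 2, 2.5, 4, 5).
#' @param off_axis logical; `TRUE` for the off-axis (MO displaced from the
#'   DO axis) measurement.
#' @return named numeric vector `c(lateral_um, axial_um)`.
#' @examples
#' psf_fwhm_lookup(4)                   # on-axis x4: 1.1 um / 37 um
#' psf_fwhm_lookup(2, off_axis = TRUE)  # 1.8 um / 54 um
#' @export
psf_fwhm_lookup <- function(do_spec, off_axis = FALSE) {
  mag <- if (inherits(do_spec, "dry_objective_spec")) {
    do_spec$magnification
  } else if (is.numeric(do_spec) && length(do_spec) == 1) {
    do_spec
  } else {
    stop("`do_spec` must be a dry_objective_spec or a magnification value")
  }
  key <- names(psf_table)[vapply(names(psf_table),
                                 function(k) isTRUE(all.equal(as.numeric(k), mag)),
                                 logical(1))]
  if (length(key) != 1)
    stop("unknown DO model (magnification ", mag, "); supported models: x",
         paste(names(psf_table), collapse = ", x"))
  if (off_axis) psf_table[[key]]$off else psf_table[[key]]$on
}
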