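# Geometry of circular FOVs inside one rectangular raster frame.

#' FOV layout inside a raster frame
#'
#' @param frame_npix frame edge length in pixels.
#' @param fovs data.frame with one row per FOV and columns `region`
#'   (label), `cx`, `cy` (center, pixels, 1-based), `radius_px` and
#'   `um_per_px` (specimen-side pixel size).
#' @return an object of class `fov_layout`.
#' @details FOV disks must lie fully inside the frame and may touch but not
#'   overlap.
#' @export
fov_layout <- function(frame_npix, fovs) {
  stopifnot(is.data.frame(fovs),
            all(c("region", "cx", "cy", "radius_px", "um_per_px") %in%
                  names(fovs)))
  frame_npix <- as.integer(frame_npix)
  if (any(fovs$radius_px <= 0)) stop("FOV radii must be positive")
  if (any(fovs$cx - fovs$radius_px < 0.5 | fovs$cx + fovs$radius_px > frame_npix + 0.5 |
          fovs$cy - fovs$radius_px < 0.5 | fovs$cy + fovs$radius_px > frame_npix + 0.5))
    stop("layout error: FOV disk extends outside the ", frame_npix,
         "-px frame")
  n <- nrow(fovs)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      d <- sqrt((fovs$cx[i] - fovs$cx[j])^2 + (fovs$cy[i] - fovs$cy[j])^2)
      if (d < fovs$radius_px[i] + fovs$radius_px[j] - 1e-9)
        stop("layout error: FOV disks '", fovs$region[i], "' and '",
             fovs$region[j], "' overlap (center distance ", signif(d, 4),
             " px < sum of radii)")
    }
  }
  if (anyDuplicated(fovs$region))
    stop("layout error: duplicated region labels")
  structure(list(frame_npix = frame_npix, fovs = fovs), class = "fov_layout")
}

#' @export
print.fov_layout <- function(x, ...) {
  cat(sprintf("FOV layout: %d x %d px frame, %d FOV(s)\n", x$frame_npix,
              x$frame_npix, nrow(x$fovs)))
  print(x$fovs, row.names = FALSE)
  invisible(x)
}

#' Build the FOV layout implied by an assembly design and scan geometry
#'
#' Each MO becomes one circular FOV: its center is the MO's lateral offset
#' from the DO axis converted to pixels at the DO object plane (origin at
#' the frame center), and its radius is half the specimen-side FOV diameter
#' divided by the specimen-side pixel size.
#'
#' @param design an [assembly_design()].
#' @param geometry a [scan_geometry()].
#' @return a [fov_layout()].
#' @export
build_layout <- function(design, geometry) {
  stopifnot(inherits(design, "assembly_design"),
            inherits(geometry, "scan_geometry"))
  px <- pixel_size(geometry)
  npix <- geometry$npix
  center <- (npix + 1) / 2
  radius_px <- (geometry$fov_diameter_um / 2) / px[["specimen_um"]]
  rows <- lapply(design$mo_entries, function(e) {
    data.frame(region = e$region,
               cx = center + e$lateral_offset_mm[1] * 1000 / px[["do_plane_um"]],
               cy = center + e$lateral_offset_mm[2] * 1000 / px[["do_plane_um"]],
               radius_px = radius_px,
               um_per_px = px[["specimen_um"]])
  })
  fov_layout(npix, do.call(rbind, rows))
}

# logical mask (ny x nx matrix) of one FOV disk
fov_mask <- function(layout, i) {
  n <- layout$frame_npix
  f <- layout$fovs[i, ]
  xs <- matrix(seq_len(n), n, n, byrow = TRUE)
  ys <- matrix(seq_len(n), n, n)
  (xs - f$cx)^2 + (ys - f$cy)^2 <= f$radius_px^2
}

#' Simple multi-FOV layout for simulations
#'
#' Places up to four equal circular FOVs at fixed fractional positions of
#' the frame (1: centered; 2: side by side; 3: triangle; 4: corners), for
#' use when no full assembly design is needed.
#'
#' @param frame_npix frame edge (px).
#' @param regions character vector of region labels (length 1-4).
#' @param fov_diameter_um FOV diameter at the specimen (um); fixes the
#'   specimen-side pixel size given the disk radius in pixels.
#' @return a [fov_layout()].
#' @examples
#' simple_layout(256, c("V1", "M1", "CA1"))
#' @export
simple_layout <- function(frame_npix, regions, fov_diameter_um = 200) {
  n <- length(regions)
  if (n < 1 || n > 4) stop("`regions` must have between 1 and 4 labels")
  pos <- switch(n,
                cbind(0.5, 0.5),
                cbind(c(0.28, 0.72), c(0.5, 0.5)),
                cbind(c(0.28, 0.72, 0.5), c(0.3, 0.3, 0.72)),
                cbind(c(0.28, 0.72, 0.28, 0.72), c(0.28, 0.28, 0.72, 0.72)))
  rfrac <- if (n == 1) 0.35 else 0.21
  radius <- rfrac * frame_npix
  fov_layout(frame_npix,
             data.frame(region = regions,
                        cx = pos[, 1] * frame_npix, cy = pos[, 2] * frame_npix,
                        radius_px = radius,
                        um_per_px = fov_diameter_um / (2 * radius)))
}
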