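# Frame registration and ROI trace extraction. Registration is rigid
# integer-pixel alignment minimizing the sum of squared intensity
# differences (SSD) against a template averaged from selected frames.

get_frames <- function(stack) {
  if (inherits(stack, "movie_stack")) stack$frames
  else if (is.array(stack) && length(dim(stack)) == 3) stack
  else stop("`stack` must be a movie_stack or a time x y x x array")
}

#' Detect circular FOVs from a mean image
#'
#' Recovers the circular FOV disks of a multi-FOV frame when no layout
#' sidecar is available: threshold the mean image, label connected
#' components, and fit a circle to each component via its centroid and
#' area. Prefer the sidecar layout whenever one exists.
#'
#' @param img mean image (y x x matrix), dark between FOVs.
#' @param n_expected optionally, the number of FOVs that must be found.
#' @param threshold intensity threshold; default midway between the image
#'   minimum and maximum.
#' @param min_area_px components smaller than this are ignored.
#' @param um_per_px specimen-side pixel size recorded in the layout.
#' @return a [fov_layout()] with regions labeled `fov1`, `fov2`, ... in
#'   row-major order of their centers.
#' @export
detect_fovs <- function(img, n_expected = NULL, threshold = NULL,
                        min_area_px = 16, um_per_px = 1) {
  stopifnot(is.matrix(img))
  rng <- range(img)
  if (diff(rng) == 0)
    stop("detection error: blank image (no intensity variation)")
  if (is.null(threshold))   # Otsu split of background vs FOV interior
    threshold <- EBImage::otsu(EBImage::Image(img / rng[2])) * rng[2]
  bw <- img > threshold
  if (!any(bw)) stop("detection error: no pixels above threshold ",
                     signif(threshold, 4))
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(lab[lab > 0])
  keep <- which(tab >= min_area_px)
  if (length(keep) == 0)
    stop("detection error: no component reaches the minimum area of ",
         min_area_px, " px")
  ys <- row(lab); xs <- col(lab)
  fovs <- do.call(rbind, lapply(keep, function(k) {
    sel <- lab == k
    data.frame(cx = mean(xs[sel]), cy = mean(ys[sel]),
               radius_px = sqrt(sum(sel) / pi))
  }))
  fovs <- fovs[order(fovs$cy, fovs$cx), , drop = FALSE]
  fovs$region <- paste0("fov", seq_len(nrow(fovs)))
  fovs$um_per_px <- um_per_px
  if (!is.null(n_expected) && nrow(fovs) != n_expected)
    stop("detection error: expected ", n_expected, " FOVs but found ",
         nrow(fovs), "; inspect the thresholded mean image")
  fov_layout(nrow(img), fovs[, c("region", "cx", "cy", "radius_px",
                                 "um_per_px")])
}

#' Rigid motion correction by exhaustive SSD search
#'
#' For every frame, finds the integer shift within `search_radius` px that
#' minimizes the sum of squared intensity differences against a template
#' (the mean of `template_frames` of the raw stack). Ties are broken by
#' smallest shift magnitude, then row-major (dy, dx) order. The aligned
#' stack applies the chosen shifts with edge replication.
#'
#' @param stack a `movie_stack` or time x y x x array with >= 2 frames.
#' @param template_frames indices averaged into the template (default: the
#'   first 100 frames, or all frames if fewer).
#' @param search_radius maximum shift `R` in px; must be smaller than half
#'   the frame edge.
#' @return list with `aligned` (same shape as the input frames) and
#'   `motion`, an object of class `motion_result` with fields `shifts`
#'   (frames x 2, the correction applied to each frame), `template`,
#'   `residual_ssd` and `ssd_at_zero`.
#' @export
motion_correct <- function(stack, template_frames = NULL, search_radius = 10) {
  frames <- get_frames(stack)
  d <- dim(frames)
  nf <- d[1]
  if (nf < 2) stop("motion correction needs at least 2 frames")
  if (search_radius < 0 || 2 * search_radius >= min(d[2], d[3]))
    stop("`search_radius` must be smaller than half the frame edge")
  if (is.null(template_frames)) template_frames <- seq_len(min(100L, nf))
  stopifnot(all(template_frames >= 1), all(template_frames <= nf))
  fm <- matrix(frames, nf, d[2] * d[3])
  templ <- matrix(colMeans(fm[template_frames, , drop = FALSE]), d[2], d[3])
  shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  residual <- numeric(nf)
  ssd0 <- numeric(nf)
  aligned <- array(0, dim = d)
  offs <- seq(-search_radius, search_radius)
  for (t in seq_len(nf)) {
    fr <- matrix(fm[t, ], d[2], d[3])
    ssd <- ssd_shift_search(fr, templ, search_radius)
    ssd0[t] <- ssd[search_radius + 1, search_radius + 1]
    best <- min(ssd)
    cand <- which(ssd == best, arr.ind = TRUE)
    dy <- offs[cand[, 1]]; dx <- offs[cand[, 2]]
    ord <- order(dy^2 + dx^2, cand[, 1], cand[, 2])
    shifts[t, ] <- c(dy[ord[1]], dx[ord[1]])
    residual[t] <- best
    aligned[t, , ] <- if (any(shifts[t, ] != 0L))
      shift_replicate(fr, shifts[t, 1], shifts[t, 2]) else fr
  }
  motion <- structure(list(shifts = shifts, template = templ,
                           residual_ssd = residual, ssd_at_zero = ssd0),
                      class = "motion_result")
  list(aligned = aligned, motion = motion)
}

#' @export
print.motion_result <- function(x, ...) {
  cat(sprintf("Motion result: %d frames, max |shift| %d px, mean residual SSD %.4g\n",
              nrow(x$shifts), max(abs(x$shifts)), mean(x$residual_ssd)))
  invisible(x)
}

#' Region of interest
#'
#' @param id ROI identifier.
#' @param region region label.
#' @param pixels n x 2 matrix of (y, x) pixel coordinates (1-based).
#' @param kind `"soma"` or `"neuropil-annulus"`.
#' @param center,radius_px optional disk parameters (used to derive
#'   annuli).
#' @param paired_soma_id for annuli, the id of the paired soma.
#' @return an object of class `roi`.
#' @export
roi <- function(id, region, pixels, kind = c("soma", "neuropil-annulus"),
                center = NULL, radius_px = NULL, paired_soma_id = NULL) {
  kind <- match.arg(kind)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0) stop("ROI '", id, "' has an empty pixel set")
  if (ncol(pixels) != 2) stop("`pixels` must be an n x 2 (y, x) matrix")
  structure(list(id = id, region = region, pixels = pixels, kind = kind,
                 center = center, radius_px = radius_px,
                 paired_soma_id = paired_soma_id),
            class = "roi")
}

#' Circular soma ROI
#'
#' @param id,region identifiers.
#' @param cx,cy disk center (px, 1-based).
#' @param radius_px disk radius.
#' @param frame_npix frame edge, for bounds checking.
#' @return a soma [roi()].
#' @export
roi_disk <- function(id, region, cx, cy, radius_px, frame_npix) {
  xr <- max(1, floor(cx - radius_px)):min(frame_npix, ceiling(cx + radius_px))
  yr <- max(1, floor(cy - radius_px)):min(frame_npix, ceiling(cy + radius_px))
  grid <- expand.grid(y = yr, x = xr)
  keep <- (grid$y - cy)^2 + (grid$x - cx)^2 <= radius_px^2
  roi(id, region, as.matrix(grid[keep, c("y", "x")]), kind = "soma",
      center = c(x = cx, y = cy), radius_px = radius_px)
}

#' Neuropil annulus paired to a soma ROI
#'
#' A ring starting `gap_px` outside the soma disk, `width_px` wide, clipped
#' to the FOV disk and excluding the pixels of the soma itself and of any
#' other provided soma.
#'
#' @param soma a disk-based soma [roi()].
#' @param layout optional [fov_layout()]; the annulus is clipped to the
#'   soma's FOV disk.
#' @param exclude optional list of other soma [roi()]s whose pixels are
#'   removed.
#' @param gap_px,width_px ring geometry (px).
#' @param frame_npix frame edge.
#' @return a neuropil-annulus [roi()] with `paired_soma_id = soma$id`.
#' @export
neuropil_annulus <- function(soma, frame_npix, layout = NULL, exclude = NULL,
                             gap_px = 1, width_px = 2) {
  stopifnot(inherits(soma, "roi"), soma$kind == "soma",
            !is.null(soma$center))
  r0 <- soma$radius_px + gap_px
  r1 <- r0 + width_px
  cx <- soma$center[["x"]]; cy <- soma$center[["y"]]
  xr <- max(1, floor(cx - r1)):min(frame_npix, ceiling(cx + r1))
  yr <- max(1, floor(cy - r1)):min(frame_npix, ceiling(cy + r1))
  grid <- expand.grid(y = yr, x = xr)
  d2 <- (grid$y - cy)^2 + (grid$x - cx)^2
  keep <- d2 > r0^2 & d2 <= r1^2
  if (!is.null(layout)) {
    f <- layout$fovs[layout$fovs$region == soma$region, ]
    if (nrow(f) == 1)
      keep <- keep & ((grid$y - f$cy)^2 + (grid$x - f$cx)^2 <= f$radius_px^2)
  }
  px <- grid[keep, c("y", "x")]
  for (other in c(list(soma), exclude)) {
    if (nrow(px) == 0) break
    key <- paste(px$y, px$x)
    okey <- paste(other$pixels[, 1], other$pixels[, 2])
    px <- px[!(key %in% okey), , drop = FALSE]
  }
  if (nrow(px) == 0)
    stop("neuropil annulus for soma '", soma$id, "' is empty after clipping")
  roi(paste0(soma$id, "_np"), soma$region, as.matrix(px),
      kind = "neuropil-annulus", paired_soma_id = soma$id)
}

#' Extract the raw fluorescence trace of an ROI
#'
#' Per-frame arithmetic mean of the ROI's pixel values.
#'
#' @param stack a `movie_stack` or time x y x x array (typically the
#'   aligned stack from [motion_correct()]).
#' @param roi an [roi()].
#' @return numeric vector of length `n_frames`.
#' @export
extract_trace <- function(stack, roi) {
  stopifnot(inherits(roi, "roi"))
  frames <- get_frames(stack)
  d <- dim(frames)
  if (any(roi$pixels[, 1] < 1 | roi$pixels[, 1] > d[2] |
          roi$pixels[, 2] < 1 | roi$pixels[, 2] > d[3]))
    stop("ROI '", roi$id, "' has pixels outside the frame")
  fm <- matrix(frames, d[1], d[2] * d[3])
  lin <- (roi$pixels[, 2] - 1) * d[2] + roi$pixels[, 1]
  rowMeans(fm[, lin, drop = FALSE])
}
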