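# Rendering ground-truth activity into a 16-bit multi-FOV raster movie:
# Gaussian somata convolved with the lateral PSF, uniform neuropil inside
# each FOV, inter-FOV crosstalk, rigid jitter and Poisson-Gaussian noise.

MAX_COUNTS <- 65535

# sample non-overlapping cell centers inside one FOV disk
place_cells <- function(n, cx, cy, radius_px, r_cell_px) {
  if (n == 0) return(cbind(x = numeric(0), y = numeric(0)))
  max_r <- radius_px - 2 * r_cell_px
  if (max_r <= 0) stop("FOV too small for the configured cell radius")
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0; tries <- 0
  while (placed < n) {
    if ((tries <- tries + 1) > 5000 * n)
      stop("could not place ", n, " non-overlapping cells in one FOV; ",
           "reduce n_cells or cell_radius_um")
    ang <- runif(1, 0, 2 * pi)
    rad <- sqrt(runif(1)) * max_r
    x <- cx + rad * cos(ang); y <- cy + rad * sin(ang)
    if (placed > 0 &&
        any((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2 <
              (2.5 * r_cell_px)^2)) next
    placed <- placed + 1
    xs[placed] <- x; ys[placed] <- y
  }
  cbind(x = xs, y = ys)
}

# Soma footprint on the frame grid: a uniform disk of radius r_cell blurred
# by the lateral PSF (Gaussian edge, weight pnorm((r_cell - d)/sigma)), so
# core pixels carry the full somatic brightness and an ROI readout of the
# disk is an almost unbiased estimate of the cell's delta-f/f. Returns
# linear (column-major) indices plus weights in [0, 1].
cell_footprint <- function(x, y, r_cell_px, sigma_px, npix) {
  half <- ceiling(r_cell_px + 3.5 * sigma_px)
  xr <- max(1, floor(x - half)):min(npix, ceiling(x + half))
  yr <- max(1, floor(y - half)):min(npix, ceiling(y + half))
  d <- sqrt(outer((yr - y)^2, (xr - x)^2, "+"))
  g <- pnorm((r_cell_px - d) / sigma_px)
  idx <- as.vector(outer(yr, (xr - 1) * npix, "+"))
  keep <- g > 1e-4
  list(idx = idx[keep], w = as.vector(g)[keep])
}

#' Render a ground-truth population into a multi-FOV movie
#'
#' Cells are rendered as 2-D Gaussian spots whose width combines the soma
#' radius with the lateral PSF FWHM (in quadrature); each FOV additionally
#' carries a uniform neuropil signal and receives `crosstalk_frac` times
#' the mean brightness of every other FOV. The per-frame rigid shifts from
#' the ground truth are applied with edge replication, then Poisson photon
#' noise (optional) and Gaussian read noise are added and the frame is
#' clamped to unsigned 16-bit counts.
#'
#' @param truth a [synth_traces()] result.
#' @param layout a [fov_layout()]; region labels must match the truth.
#' @param params the [activity_params()] used to generate `truth`.
#' @param psf_fwhm_um lateral PSF FWHM at the specimen (um), e.g. from
#'   [psf_fwhm_lookup()].
#' @return an object of class `movie_stack`: list with `frames` (time x y
#'   x x array of counts), `frame_rate_hz`, `layout` and `truth` (augmented
#'   with rendered cell centroids and radii).
#' @examples
#' p <- activity_params(regions = data.frame(
#'   region = "V1", n_cells = 2, event_rate_hz = 0.2,
#'   amp_log10_mu = -0.46, amp_log10_sigma = 0.14), seed = 3)
#' gt <- synth_traces(p, duration_s = 5, rate_hz = 10)
#' lay <- fov_layout(64, data.frame(region = "V1", cx = 32.5, cy = 32.5,
#'                                  radius_px = 25, um_per_px = 1.56))
#' mv <- render_movie(gt, lay, p, psf_fwhm_um = 1.4)
#' dim(mv$frames)
#' @export
render_movie <- function(truth, layout, params, psf_fwhm_um = 1.4) {
  stopifnot(inherits(truth, "ground_truth"), inherits(layout, "fov_layout"),
            inherits(params, "activity_params"))
  regions <- unique(truth$cells$region)
  if (!all(regions %in% layout$fovs$region))
    stop("layout has no FOV for region(s): ",
         paste(setdiff(regions, layout$fovs$region), collapse = ", "))
  npix <- layout$frame_npix
  nf <- nrow(truth$traces)
  ncell <- nrow(truth$cells)

  set.seed(derive_seed(params$seed, "positions"))
  centroids <- data.frame(cell = truth$cells$cell,
                          region = truth$cells$region,
                          x = NA_real_, y = NA_real_, radius_px = NA_real_)
  footprints <- vector("list", ncell)
  for (fi in seq_len(nrow(layout$fovs))) {
    f <- layout$fovs[fi, ]
    members <- which(truth$cells$region == f$region)
    if (length(members) == 0) next
    r_cell_px <- params$cell_radius_um / f$um_per_px
    pos <- place_cells(length(members), f$cx, f$cy, f$radius_px, r_cell_px)
    sigma_px <- psf_fwhm_um / 2.355 / f$um_per_px
    for (m in seq_along(members)) {
      j <- members[m]
      centroids$x[j] <- pos[m, "x"]; centroids$y[j] <- pos[m, "y"]
      centroids$radius_px[j] <- r_cell_px
      footprints[[j]] <- cell_footprint(pos[m, "x"], pos[m, "y"],
                                        r_cell_px, sigma_px, npix)
    }
  }

  # total soma coverage per pixel; neuropil fills the complement so that a
  # soma ROI is not diluted by the neuropil baseline
  wimg <- matrix(0, npix, npix)
  for (j in seq_len(ncell)) {
    fp <- footprints[[j]]
    if (!is.null(fp)) wimg[fp$idx] <- pmin(1, wimg[fp$idx] + fp$w)
  }

  masks <- lapply(seq_len(nrow(layout$fovs)), function(i)
    which(fov_mask(layout, i)))
  plate <- params$regions$plate_counts[
    match(layout$fovs$region, params$regions$region)]
  plate[is.na(plate)] <- 0

  static <- matrix(params$bg_counts, npix, npix)
  for (fi in seq_along(masks)) {
    ix <- masks[[fi]]
    static[ix] <- static[ix] + plate[fi]
    if (any(truth$cells$region == layout$fovs$region[fi]))
      static[ix] <- static[ix] +
        params$neuropil_f0_counts * (1 - wimg[ix])
  }
  for (j in seq_len(ncell)) {
    fp <- footprints[[j]]
    if (!is.null(fp)) static[fp$idx] <- static[fp$idx] +
        fp$w * params$cell_f0_counts
  }

  # neuropil trace per FOV: neuropil_amp x mean somatic delta-f/f
  np_dff <- matrix(0, nf, nrow(layout$fovs))
  for (fi in seq_len(nrow(layout$fovs))) {
    members <- which(truth$cells$region == layout$fovs$region[fi])
    if (length(members) > 0)
      np_dff[, fi] <- params$neuropil_amp *
        rowMeans(truth$traces[, members, drop = FALSE])
  }

  frames <- array(0, dim = c(nf, npix, npix))
  read_sd <- params$noise_sd * params$cell_f0_counts
  set.seed(derive_seed(params$seed, "noise"))
  for (t in seq_len(nf)) {
    img <- static
    for (j in seq_len(ncell)) {
      fp <- footprints[[j]]
      if (!is.null(fp))
        img[fp$idx] <- img[fp$idx] +
          fp$w * params$cell_f0_counts * truth$traces[t, j]
    }
    for (fi in seq_along(masks))
      if (np_dff[t, fi] != 0)
        img[masks[[fi]]] <- img[masks[[fi]]] +
          params$neuropil_f0_counts * np_dff[t, fi] *
            (1 - wimg[masks[[fi]]])
    if (params$crosstalk_frac > 0 && length(masks) > 1) {
      m <- vapply(masks, function(ix) mean(img[ix]), numeric(1))
      for (fi in seq_along(masks))
        img[masks[[fi]]] <- img[masks[[fi]]] +
          params$crosstalk_frac * sum(m[-fi])
    }
    if (any(truth$shifts[t, ] != 0L))
      img <- shift_replicate(img, truth$shifts[t, 1], truth$shifts[t, 2])
    img[img < 0] <- 0
    if (max(img) > 0.95 * MAX_COUNTS)
      stop("intensity overflow: pre-noise maximum ", round(max(img)),
           " counts exceeds 95% of the 16-bit range; reduce baseline ",
           "counts or amplitudes")
    if (params$shot_noise)
      img <- matrix(rpois(npix * npix, img), npix, npix)
    if (read_sd > 0)
      img <- img + matrix(rnorm(npix * npix, 0, read_sd), npix, npix)
    img <- round(img)
    img[img < 0] <- 0
    img[img > MAX_COUNTS] <- MAX_COUNTS
    frames[t, , ] <- img
  }
  truth$centroids <- centroids
  structure(list(frames = frames, frame_rate_hz = truth$rate_hz,
                 layout = layout, truth = truth),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Movie stack: %d frames of %d x %d px at %g Hz, %d FOV(s)\n",
              d[1], d[2], d[3], x$frame_rate_hz, nrow(x$layout$fovs)))
  invisible(x)
}

#' Mean image of a movie stack
#'
#' @param stack a `movie_stack` or a time x y x x array.
#' @return y x x matrix of per-pixel temporal means.
#' @export
mean_image <- function(stack) {
  frames <- if (inherits(stack, "movie_stack")) stack$frames else stack
  d <- dim(frames)
  matrix(colMeans(matrix(frames, d[1], d[2] * d[3])), d[2], d[3])
}
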