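# Fixture I/O: 16-bit multi-page TIFF movie plus a JSON sidecar carrying
# the layout, ground truth and configuration echo. Pixel coordinates in the
# sidecar are 0-based (row-major, origin top-left, y down); in-memory R
# objects are 1-based.

sidecar_required <- c("format_version", "seed", "frame_rate_hz", "layout",
                      "cells", "events", "shifts", "config")

#' Write a simulated movie and its ground truth to disk
#'
#' The movie is written as an uncompressed 16-bit grayscale multi-page TIFF
#' (page order = time); layout, ground truth and the generating
#' configuration (with its seed) go to a JSON sidecar. Identical inputs
#' produce byte-identical files.
#'
#' @param stack a [render_movie()] result.
#' @param dir output directory (created if missing).
#' @param basename file stem for `<basename>.tif` / `<basename>.json`.
#' @return invisibly, named character vector of the two paths.
#' @export
write_fixture <- function(stack, dir, basename = "movie") {
  stopifnot(inherits(stack, "movie_stack"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory: ", dir)
  tif <- file.path(dir, paste0(basename, ".tif"))
  json <- file.path(dir, paste0(basename, ".json"))
  nf <- dim(stack$frames)[1]
  pages <- lapply(seq_len(nf), function(t) stack$frames[t, , ] / MAX_COUNTS)
  ok <- tryCatch(tiff::writeTIFF(pages, tif, bits.per.sample = 16,
                                 compression = "none"),
                 error = function(e) stop("failed to write TIFF '", tif,
                                          "': ", conditionMessage(e)))
  truth <- stack$truth
  p <- truth$params
  sidecar <- list(
    format_version = 1L,
    seed = p$seed,
    frame_rate_hz = stack$frame_rate_hz,
    layout = list(frame_npix = stack$layout$frame_npix,
                  fovs = data.frame(region = stack$layout$fovs$region,
                                    cx = stack$layout$fovs$cx - 1,
                                    cy = stack$layout$fovs$cy - 1,
                                    radius_px = stack$layout$fovs$radius_px,
                                    um_per_px = stack$layout$fovs$um_per_px)),
    cells = data.frame(cell = truth$centroids$cell,
                       region = truth$centroids$region,
                       x = truth$centroids$x - 1,
                       y = truth$centroids$y - 1,
                       radius_px = truth$centroids$radius_px),
    events = lapply(truth$events, function(e)
      list(onset_frame = e$onset_frame - 1L, amplitude = e$amplitude)),
    shifts = truth$shifts,
    corr_targets = truth$corr_targets,
    config = list(regions = p$regions, rise_tau_s = p$rise_tau_s,
                  decay_tau_s = p$decay_tau_s,
                  driver_weights = p$driver_weights,
                  driver_amp = p$driver_amp, driver_tau_s = p$driver_tau_s,
                  neuropil_amp = p$neuropil_amp, noise_sd = p$noise_sd,
                  crosstalk_frac = p$crosstalk_frac,
                  motion_sd_px = p$motion_sd_px, shot_noise = p$shot_noise,
                  cell_f0_counts = p$cell_f0_counts,
                  neuropil_f0_counts = p$neuropil_f0_counts,
                  bg_counts = p$bg_counts,
                  cell_radius_um = p$cell_radius_um))
  jsonlite::write_json(sidecar, json, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", matrix = "rowmajor")
  invisible(c(tif = tif, json = json))
}

#' Read a movie fixture written by [write_fixture()]
#'
#' @param dir directory containing the fixture.
#' @param basename file stem used at write time.
#' @return a `movie_stack` with the sidecar truth attached (coordinates
#'   converted back to 1-based).
#' @export
read_fixture <- function(dir, basename = "movie") {
  tif <- file.path(dir, paste0(basename, ".tif"))
  json <- file.path(dir, paste0(basename, ".json"))
  for (f in c(tif, json)) if (!file.exists(f)) stop("missing fixture file: ", f)
  pages <- tiff::readTIFF(tif, all = TRUE)
  nf <- length(pages)
  npix <- nrow(pages[[1]])
  frames <- array(0, dim = c(nf, npix, ncol(pages[[1]])))
  for (t in seq_len(nf)) frames[t, , ] <- round(pages[[t]] * MAX_COUNTS)
  sc <- jsonlite::read_json(json, simplifyVector = TRUE)
  validate_sidecar(sc)
  sc$layout$fovs <- as.data.frame(sc$layout$fovs)
  sc$cells <- as.data.frame(sc$cells)
  lay <- fov_layout(sc$layout$frame_npix,
                    within_df(sc$layout$fovs, cx = sc$layout$fovs$cx + 1,
                              cy = sc$layout$fovs$cy + 1))
  shifts <- matrix(as.integer(sc$shifts), ncol = 2,
                   dimnames = list(NULL, c("dy", "dx")))
  events <- lapply(sc$events, function(e)
    data.frame(onset_frame = as.integer(unlist(e$onset_frame)) + 1L,
               amplitude = as.numeric(unlist(e$amplitude))))
  truth <- list(cells = sc$cells[, c("cell", "region")],
                centroids = within_df(sc$cells, x = sc$cells$x + 1,
                                      y = sc$cells$y + 1),
                events = events, shifts = shifts,
                corr_targets = sc$corr_targets, rate_hz = sc$frame_rate_hz,
                config = sc$config, seed = sc$seed)
  structure(list(frames = frames, frame_rate_hz = sc$frame_rate_hz,
                 layout = lay, truth = truth),
            class = "movie_stack")
}

# base-safe column replacement (avoids NSE of within())
within_df <- function(df, ...) {
  repl <- list(...)
  for (nm in names(repl)) df[[nm]] <- repl[[nm]]
  df
}

#' Validate a fixture sidecar against the shipped schema
#'
#' Checks required top-level fields and the layout/cell tables of a parsed
#' sidecar JSON.
#'
#' @param sidecar parsed sidecar (list).
#' @return invisibly `TRUE`; otherwise an error naming the missing field.
#' @export
validate_sidecar <- function(sidecar) {
  miss <- setdiff(sidecar_required, names(sidecar))
  if (length(miss) > 0)
    stop("sidecar is missing required field(s): ",
         paste(miss, collapse = ", "))
  if (!all(c("frame_npix", "fovs") %in% names(sidecar$layout)))
    stop("sidecar layout must contain `frame_npix` and `fovs`")
  if (!all(c("region", "cx", "cy", "radius_px", "um_per_px") %in%
             names(sidecar$layout$fovs)))
    stop("sidecar layout$fovs is missing columns")
  if (!all(c("cell", "region", "x", "y") %in% names(sidecar$cells)))
    stop("sidecar cells table is missing columns")
  invisible(TRUE)
}
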