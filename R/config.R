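# Configuration, presets and reproducible seed fan-out.

seed_streams <- c(general = 1L, traces = 101L, motion = 307L,
                  positions = 211L, noise = 401L, layout = 503L,
                  amplitudes = 601L)

#' Derive a child seed for a named random stream
#'
#' One global seed fans out deterministically to per-module streams so
#' modules can re-seed independently without coupling their draws. The
#' result always fits a 32-bit integer.
#'
#' @param seed global integer seed.
#' @param stream one of `"general"`, `"traces"`, `"motion"`, `"positions"`,
#'   `"noise"`, `"layout"`, `"amplitudes"`.
#' @return integer child seed.
#' @export
derive_seed <- function(seed, stream = "general") {
  if (!stream %in% names(seed_streams))
    stop("unknown seed stream '", stream, "'")
  as.integer((as.numeric(seed) * 7919 + seed_streams[[stream]]) %%
               2147483647)
}

#' Read a GRIN lens parameter file
#'
#' Flat key-value YAML (or JSON) file with keys named after the lens
#' symbols: `n0_axial`, `pitch`, `sqrt_a`, `length_mm`, `front_wd_mm`,
#' `n_front`, `n_back`, plus optional `na_mo`, `angular_mag`, `label`.
#'
#' @param path file path.
#' @return a [grin_lens_spec()].
#' @export
read_lens_file <- function(path) {
  if (!file.exists(path)) stop("lens file not found: ", path)
  vals <- yaml::read_yaml(path)
  allowed <- c("n0_axial", "pitch", "sqrt_a", "length_mm", "front_wd_mm",
               "n_front", "n_back", "na_mo", "angular_mag", "label")
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0)
    stop("unknown key(s) in lens file: ", paste(unknown, collapse = ", "))
  do.call(grin_lens_spec, vals)
}

#' Shipped lens templates
#'
#' `"table1_standard"` (cortex, pitch 0.261) and `"table1_long_coupling"`
#' (hippocampus, pitch 0.259).
#'
#' @param name template name.
#' @return a [grin_lens_spec()].
#' @examples
#' lens_template("table1_standard")
#' @export
lens_template <- function(name = c("table1_standard",
                                   "table1_long_coupling")) {
  name <- match.arg(name)
  read_lens_file(system.file("extdata", "presets", paste0(name, ".yaml"),
                             package = "matriex", mustWork = TRUE))
}

default_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    version = as.character(packageVersion("matriex")),
    design = list(template = "table1_standard", do_magnification = 4,
                  do_na = 0.1, depth_mm = 0.5, conjugate_height_mm = 21.4,
                  image_side_field_mm = 24,
                  depth_sweep_mm = c(0.15, 1.5), sweep_points = 28L),
    simulate = list(state = "anesthetized", n_cells_per_region = 6,
                    event_rate_hz = 0.2, duration_s = 60, rate_hz = 10,
                    frame_npix = 256L, fov_diameter_um = 200,
                    neuropil_amp = 0.15, noise_sd = 0.02,
                    crosstalk_frac = 0.001, motion_sd_px = 0,
                    shot_noise = TRUE),
    analyze = list(k_sigma = 3, min_separation_s = 1, search_radius = 10,
                   template_frames = 100L)
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults))
      stop("unknown configuration key: '", here, "'")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stop("configuration key '", here, "' must be a section")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]],
                                      c(path, key))
    } else if (!is.null(user[[key]])) {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration with sections `design`, `simulate`
#' and `analyze` plus global keys `seed`, `output_dir` and `version`,
#' fills in defaults, and rejects unknown keys by name. An empty file (or
#' no file) yields the all-defaults configuration. Shipped presets:
#' `"fig4_three_region"` (three-FOV V1/M1/CA1 demo).
#'
#' @param path path to a configuration file, or `NULL` for defaults.
#' @param preset name of a shipped preset configuration.
#' @return an object of class `run_config`.
#' @export
load_config <- function(path = NULL, preset = NULL) {
  cfg <- default_config()
  if (!is.null(preset)) {
    pfile <- system.file("extdata", "presets", paste0(preset, ".yaml"),
                         package = "matriex")
    if (!nzchar(pfile)) stop("unknown preset: '", preset, "'")
    path <- pfile
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- merge_config(cfg, user)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config v%s (seed %d, output '%s')\n", x$version, x$seed,
              x$output_dir))
  invisible(x)
}

#' Activity parameters implied by a run configuration
#'
#' @param config a [load_config()] result.
#' @return an [activity_params()].
#' @export
config_activity_params <- function(config) {
  s <- config$simulate
  activity_params(state = s$state,
                  n_cells_per_region = s$n_cells_per_region,
                  event_rate_hz = s$event_rate_hz,
                  neuropil_amp = s$neuropil_amp, noise_sd = s$noise_sd,
                  crosstalk_frac = s$crosstalk_frac,
                  motion_sd_px = s$motion_sd_px, shot_noise = s$shot_noise,
                  seed = config$seed)
}
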