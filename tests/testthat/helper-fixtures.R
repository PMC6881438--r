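# Small in-code fixtures shared across tests.

standard_lens <- function() grin_lens_spec(0.261, 0.299, label = "standard")

long_lens <- function() grin_lens_spec(0.259, 0.311, label = "long-coupling")

# one-region parameter set with quiet defaults suited to exact checks
quiet_params <- function(region = "V1", n_cells = 2, event_rate_hz = 0,
                         seed = 1, ...) {
  activity_params(regions = data.frame(region = region, n_cells = n_cells,
                                       event_rate_hz = event_rate_hz,
                                       amp_log10_mu = -0.46,
                                       amp_log10_sigma = 0.14),
                  driver_weights = matrix(0, length(region), 1,
                                          dimnames = list(region, "d1")),
                  driver_amp = 0, noise_sd = 0, shot_noise = FALSE,
                  seed = seed, ...)
}

# deterministic smooth random scene for registration tests: a few Gaussian
# blobs away from the border
blob_scene <- function(npix, n_blobs = 4, margin = 10, seed = 1) {
  set.seed(seed)
  img <- matrix(0, npix, npix)
  xs <- matrix(seq_len(npix), npix, npix, byrow = TRUE)
  ys <- matrix(seq_len(npix), npix, npix)
  for (b in seq_len(n_blobs)) {
    cx <- runif(1, margin, npix - margin)
    cy <- runif(1, margin, npix - margin)
    s <- runif(1, 1.5, 3)
    img <- img + runif(1, 50, 200) *
      exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  }
  img
}

# fresh scratch directory for fixture I/O tests
make_tempdir <- function() {
  d <- tempfile("fx")
  dir.create(d)
  d
}

# pixel values of a t x y x x array under a y x x logical mask
mask_vals <- function(frames, mask) {
  d <- dim(frames)
  matrix(frames, d[1], d[2] * d[3])[, which(mask), drop = FALSE]
}
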