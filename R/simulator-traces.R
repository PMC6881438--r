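# Ground-truth activity generation: Poisson event trains with log-normal
# amplitudes, a GCaMP6f-like double-exponential transient kernel, and a
# latent-driver construction that induces a prescribed intra-/inter-regional
# Pearson correlation structure.

# printed log-normal amplitude laws per region and state (base-10 exponents)
amplitude_laws <- list(
  anesthetized = data.frame(
    region = c("V1", "M1", "CA1"),
    amp_log10_mu = c(-0.46, -0.30, -0.13),
    amp_log10_sigma = c(0.14, 0.31, 0.41),
    n_events = c(125L, 211L, 342L)),
  awake = data.frame(
    region = c("V1", "M1", "CA1"),
    amp_log10_mu = c(-0.13, -0.03, -0.04),
    amp_log10_sigma = c(0.35, 0.44, 0.45),
    n_events = c(430L, 483L, 493L))
)

#' Published event-amplitude laws per region and state
#'
#' Log-normal amplitude parameters (base-10 exponents of the location
#' `mu` and scale `sigma`) and pooled event counts for V1, M1 and CA1 in
#' the anesthetized and awake states.
#'
#' @param state `"anesthetized"` or `"awake"`.
#' @return data.frame with columns `region`, `amp_log10_mu`,
#'   `amp_log10_sigma`, `n_events`.
#' @examples
#' amplitude_law("anesthetized")
#' @export
amplitude_law <- function(state = c("anesthetized", "awake")) {
  amplitude_laws[[match.arg(state)]]
}

#' Simulation parameters for multi-FOV activity
#'
#' Collects per-region activity statistics and global rendering parameters
#' for the synthetic movie generator.
#'
#' @param regions data.frame with columns `region`, `n_cells`,
#'   `event_rate_hz`, `amp_log10_mu`, `amp_log10_sigma` and optionally
#'   `plate_counts` (uniform brightness for resolution/crosstalk test
#'   scenes; 0 disables).
#' @param state convenience alternative to `regions`: use the published
#'   three-region amplitude law for this state with `n_cells_per_region`
#'   cells and `event_rate_hz` events per cell.
#' @param n_cells_per_region,event_rate_hz used with `state`.
#' @param rise_tau_s,decay_tau_s transient kernel time constants (s);
#'   GCaMP6f-like defaults 0.05 and 0.4.
#' @param driver_weights matrix (regions x latent drivers) of shared-driver
#'   weights; row names must match `regions$region`. The correlation
#'   between cells of regions r and s converges to
#'   `sum_k W[r,k] W[s,k]` (rows are required to sum to at most 1).
#'   Default: one private driver per region plus one driver shared by the
#'   cortical regions, giving intra > cortico-cortical > cortico-hippocampal
#'   correlations.
#' @param driver_amp amplitude (delta-f/f units) of the unit-variance
#'   latent fluctuation added to each cell trace.
#' @param driver_tau_s correlation time of the latent AR(1) drivers (s).
#' @param neuropil_amp neuropil signal as a fraction of the mean somatic
#'   delta-f/f of the FOV.
#' @param noise_sd additive Gaussian read noise, as a fraction of the
#'   somatic baseline brightness.
#' @param crosstalk_frac inter-FOV leakage fraction (in [0, 0.05]).
#' @param motion_sd_px SD of the zero-mean integer rigid jitter (px).
#' @param shot_noise logical; add Poisson photon noise when rendering.
#' @param cell_f0_counts,neuropil_f0_counts,bg_counts baseline intensities
#'   (detector counts) of somata, neuropil and inter-FOV background.
#' @param cell_radius_um soma radius at the specimen (um).
#' @param seed integer RNG seed; all generator randomness derives from it.
#' @return an object of class `activity_params`.
#' @examples
#' p <- activity_params(state = "anesthetized", n_cells_per_region = 5)
#' @export
activity_params <- function(regions = NULL,
                            state = c("anesthetized", "awake"),
                            n_cells_per_region = 10, event_rate_hz = 0.2,
                            rise_tau_s = 0.05, decay_tau_s = 0.4,
                            driver_weights = NULL, driver_amp = 0.1,
                            driver_tau_s = 2, neuropil_amp = 0.15,
                            noise_sd = 0.02, crosstalk_frac = 0.001,
                            motion_sd_px = 0, shot_noise = TRUE,
                            cell_f0_counts = 300, neuropil_f0_counts = 120,
                            bg_counts = 2, cell_radius_um = 5, seed = 1L) {
  if (is.null(regions)) {
    law <- amplitude_law(match.arg(state))
    regions <- data.frame(region = law$region,
                          n_cells = n_cells_per_region,
                          event_rate_hz = event_rate_hz,
                          amp_log10_mu = law$amp_log10_mu,
                          amp_log10_sigma = law$amp_log10_sigma)
  }
  stopifnot(is.data.frame(regions),
            all(c("region", "n_cells", "event_rate_hz", "amp_log10_mu",
                  "amp_log10_sigma") %in% names(regions)))
  if (is.null(regions$plate_counts)) regions$plate_counts <- 0
  if (any(regions$n_cells < 0) || any(regions$event_rate_hz < 0))
    stop("cell counts and event rates must be non-negative")
  if (any(regions$amp_log10_sigma < 0))
    stop("`amp_log10_sigma` must be non-negative")
  if (crosstalk_frac < 0 || crosstalk_frac > 0.05)
    stop("`crosstalk_frac` must lie in [0, 0.05]")
  if (neuropil_amp < 0 || noise_sd < 0 || motion_sd_px < 0 ||
      driver_amp < 0 || driver_tau_s <= 0 || rise_tau_s <= 0 ||
      decay_tau_s <= rise_tau_s)
    stop("kinetic and noise parameters must be non-negative, with ",
         "decay_tau_s > rise_tau_s > 0")
  nr <- nrow(regions)
  if (is.null(driver_weights)) {
    # private driver per region + one driver shared by the first two
    # (cortical) regions
    driver_weights <- cbind(diag(0.55, nr),
                            shared = c(0.3, 0.3, rep(0.15, max(0, nr - 2)))[seq_len(nr)])
    rownames(driver_weights) <- regions$region
  }
  driver_weights <- as.matrix(driver_weights)
  if (is.null(rownames(driver_weights)) ||
      !identical(sort(rownames(driver_weights)), sort(regions$region)))
    stop("`driver_weights` row names must match the region labels")
  driver_weights <- driver_weights[regions$region, , drop = FALSE]
  if (any(driver_weights < 0) || any(rowSums(driver_weights) > 1 + 1e-12))
    stop("`driver_weights` must be non-negative with row sums <= 1")
  structure(list(regions = regions, rise_tau_s = rise_tau_s,
                 decay_tau_s = decay_tau_s, driver_weights = driver_weights,
                 driver_amp = driver_amp, driver_tau_s = driver_tau_s,
                 neuropil_amp = neuropil_amp, noise_sd = noise_sd,
                 crosstalk_frac = crosstalk_frac,
                 motion_sd_px = motion_sd_px, shot_noise = shot_noise,
                 cell_f0_counts = cell_f0_counts,
                 neuropil_f0_counts = neuropil_f0_counts,
                 bg_counts = bg_counts, cell_radius_um = cell_radius_um,
                 seed = as.integer(seed)),
            class = "activity_params")
}

#' Draw event amplitudes from a base-10 log-normal law
#'
#' Amplitudes are `10^N(mu, sigma)` on the delta-f/f scale, i.e. the base-10
#' logarithm of the amplitude is Gaussian with mean `mu_log10` and SD
#' `sigma_log10`.
#'
#' @param n number of draws.
#' @param mu_log10,sigma_log10 exponents of the location and scale.
#' @return numeric vector of positive amplitudes.
#' @examples
#' set.seed(1); a <- sample_event_amplitudes(5, -0.46, 0.14)
#' @export
sample_event_amplitudes <- function(n, mu_log10, sigma_log10) {
  stopifnot(n >= 0, sigma_log10 >= 0)
  10^rnorm(n, mu_log10, sigma_log10)
}

#' Discretized double-exponential calcium transient kernel
#'
#' `k(t) = exp(-t/decay) - exp(-t/rise)` sampled on the frame grid and
#' normalized so its sampled maximum is 1; an event of amplitude `a` then
#' contributes a sampled peak of exactly `a` to the trace.
#'
#' @param rate_hz frame rate (Hz).
#' @param rise_tau_s,decay_tau_s time constants (s).
#' @return numeric kernel vector (first sample, at the onset frame, is 0).
#' @export
transient_kernel <- function(rate_hz, rise_tau_s = 0.05, decay_tau_s = 0.4) {
  stopifnot(rate_hz > 0, rise_tau_s > 0, decay_tau_s > rise_tau_s)
  t <- seq(0, 8 * decay_tau_s, by = 1 / rate_hz)
  k <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  k / max(k)
}

# unit-variance AR(1) series, stationary start; innovations drawn
# column-wise so a (nf x m) matrix of independent series is produced
ar1_series <- function(nf, m, a) {
  x <- matrix(0, nf, m)
  x[1, ] <- rnorm(m)
  if (nf > 1) {
    innov <- matrix(rnorm((nf - 1) * m, sd = sqrt(1 - a^2)), nf - 1, m)
    for (t in 2:nf) x[t, ] <- a * x[t - 1, ] + innov[t - 1, ]
  }
  x
}

#' Generate ground-truth traces for a multi-region population
#'
#' Per cell, event times follow a Poisson process at the region's rate and
#' event amplitudes the region's base-10 log-normal law; the somatic
#' delta-f/f trace is the event train convolved with the transient kernel
#' plus a latent-driver fluctuation `driver_amp * (W[r,] . D(t) +
#' sqrt(1 - sum(W[r,]^2)) e_i(t))` with unit-variance AR(1) drivers `D` and
#' cell-private residuals `e_i`, which makes the expected Pearson
#' correlation between cells of regions r and s equal to
#' `sum_k W[r,k] W[s,k]`. Rigid-motion jitter (zero-mean, integer) is also
#' drawn here so that the whole ground truth is fixed by the seed.
#'
#' @param params an [activity_params()].
#' @param duration_s recording duration (s).
#' @param rate_hz frame rate (Hz).
#' @return an object of class `ground_truth`: list with `cells`
#'   (data.frame `cell`, `region`), `traces` (frames x cells delta-f/f),
#'   `events` (per-cell data.frames `onset_frame`, `amplitude`), `shifts`
#'   (frames x 2 integer jitter, columns `dy`, `dx`), `corr_targets`
#'   (region x region expected Pearson matrix), `rate_hz`, `params`.
#' @examples
#' p <- activity_params(state = "anesthetized", n_cells_per_region = 3,
#'                      seed = 7)
#' gt <- synth_traces(p, duration_s = 30, rate_hz = 10)
#' dim(gt$traces)
#' @export
synth_traces <- function(params, duration_s = 300, rate_hz = 10) {
  stopifnot(inherits(params, "activity_params"),
            duration_s > 0, rate_hz > 0)
  nf <- round(duration_s * rate_hz)
  set.seed(derive_seed(params$seed, "traces"))
  k <- transient_kernel(rate_hz, params$rise_tau_s, params$decay_tau_s)
  W <- params$driver_weights
  a <- exp(-1 / (rate_hz * params$driver_tau_s))
  drivers <- ar1_series(nf, ncol(W), a)
  cells <- do.call(rbind, lapply(seq_len(nrow(params$regions)), function(i) {
    r <- params$regions[i, ]
    if (r$n_cells == 0) return(NULL)
    data.frame(cell = paste0(r$region, "_", seq_len(r$n_cells)),
               region = r$region)
  }))
  if (is.null(cells)) stop("no cells configured")
  ncell <- nrow(cells)
  traces <- matrix(0, nf, ncell, dimnames = list(NULL, cells$cell))
  events <- vector("list", ncell)
  names(events) <- cells$cell
  for (j in seq_len(ncell)) {
    r <- params$regions[match(cells$region[j], params$regions$region), ]
    nev <- rpois(1, r$event_rate_hz * duration_s)
    ev <- data.frame(onset_frame = integer(0), amplitude = numeric(0))
    tr <- numeric(nf)
    if (nev > 0) {
      onsets <- sort(sample.int(nf, min(nev, nf), replace = FALSE))
      amps <- sample_event_amplitudes(length(onsets), r$amp_log10_mu,
                                      r$amp_log10_sigma)
      for (e in seq_along(onsets)) {
        idx <- onsets[e]:min(nf, onsets[e] + length(k) - 1)
        tr[idx] <- tr[idx] + amps[e] * k[seq_along(idx)]
      }
      ev <- data.frame(onset_frame = onsets, amplitude = amps)
    }
    w <- W[cells$region[j], ]
    resid_sd <- sqrt(max(0, 1 - sum(w^2)))
    fluct <- drivers %*% w + resid_sd * ar1_series(nf, 1, a)
    traces[, j] <- tr + params$driver_amp * fluct
    events[[j]] <- ev
  }
  set.seed(derive_seed(params$seed, "motion"))
  shifts <- matrix(0L, nf, 2, dimnames = list(NULL, c("dy", "dx")))
  if (params$motion_sd_px > 0) {
    s <- matrix(as.integer(round(rnorm(2 * nf, 0, params$motion_sd_px))),
                nf, 2)
    s <- sweep(s, 2, as.integer(round(colMeans(s))))
    shifts[, ] <- s
  }
  corr_targets <- W %*% t(W)
  structure(list(cells = cells, traces = traces, events = events,
                 shifts = shifts, corr_targets = corr_targets,
                 rate_hz = rate_hz, params = params),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  nev <- sum(vapply(x$events, nrow, integer(1)))
  cat(sprintf("Ground truth: %d cells, %d frames at %g Hz, %d events\n",
              nrow(x$cells), nrow(x$traces), x$rate_hz, nev))
  invisible(x)
}
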