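# Delta-f/f computation, calcium event detection and log-normal amplitude
# fitting.

#' Relative fluorescence change of a trace
#'
#' `dff = (f - f0) / f0` with the baseline `f0` estimated as the 25th
#' percentile of the entire recording (linearly interpolated between order
#' statistics).
#'
#' @param f raw fluorescence trace (mean ROI intensity per frame).
#' @param frame_rate_hz acquisition rate (Hz).
#' @param probs baseline percentile (default 0.25).
#' @return an object of class `dff_trace`: list with `f`, `f0`, `dff`,
#'   `frame_rate_hz`.
#' @examples
#' compute_dff(c(1, 1, 1, 3))$dff   # 0 0 0 2
#' @export
compute_dff <- function(f, frame_rate_hz = 10, probs = 0.25) {
  if (!is.numeric(f) || length(f) < 2) stop("`f` must be a numeric trace")
  if (any(!is.finite(f))) stop("`f` contains non-finite values")
  f0 <- unname(quantile(f, probs, type = 7))
  if (f0 <= 0)
    stop("baseline f0 = ", signif(f0, 4), " is not positive; delta-f/f is ",
         "undefined. Add the detector offset back to the trace before ",
         "computing delta-f/f.")
  structure(list(f = f, f0 = f0, dff = (f - f0) / f0,
                 frame_rate_hz = frame_rate_hz),
            class = "dff_trace")
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("dff trace: %d frames at %g Hz, f0 = %.4g, dff range [%.3g, %.3g]\n",
              length(x$f), x$frame_rate_hz, x$f0, min(x$dff), max(x$dff)))
  invisible(x)
}

#' Detect calcium events in a delta-f/f trace
#'
#' Event onsets are upward crossings of `k_sigma` times a robust noise SD
#' (median absolute deviation of the trace) that stay above threshold for
#' at least 2 frames; onsets closer than `min_separation_s` are merged into
#' the preceding event. The amplitude is the peak delta-f/f between an
#' onset and the next onset (or the end of the trace).
#'
#' @param dff a [compute_dff()] result, or a numeric delta-f/f vector.
#' @param k_sigma threshold multiplier (default 3).
#' @param min_separation_s minimum event separation (s, default 1).
#' @param frame_rate_hz needed if `dff` is a bare numeric vector.
#' @param roi_id label written into the output rows.
#' @return an `event_table` data.frame with columns `roi_id`,
#'   `onset_frame`, `peak_frame`, `amplitude`, and the noise SD as
#'   attribute `noise_sd`.
#' @export
detect_events <- function(dff, k_sigma = 3, min_separation_s = 1,
                          frame_rate_hz = NULL, roi_id = "roi") {
  if (inherits(dff, "dff_trace")) {
    x <- dff$dff
    rate <- dff$frame_rate_hz
  } else {
    x <- as.numeric(dff)
    rate <- frame_rate_hz
    if (is.null(rate)) stop("`frame_rate_hz` is required for a bare trace")
  }
  if (any(!is.finite(x))) stop("trace contains non-finite values")
  nf <- length(x)
  noise_sd <- mad(x)
  thr <- k_sigma * noise_sd
  up <- which(x[-1] > thr & x[-nf] <= thr) + 1L
  up <- up[up < nf & x[pmin(nf, up + 1L)] > thr]   # stays above >= 2 frames
  min_sep <- max(1L, round(min_separation_s * rate))
  onsets <- integer(0)
  for (o in up) {
    if (length(onsets) == 0 || o - onsets[length(onsets)] >= min_sep)
      onsets <- c(onsets, o)
  }
  if (length(onsets) == 0) {
    out <- data.frame(roi_id = character(0), onset_frame = integer(0),
                      peak_frame = integer(0), amplitude = numeric(0))
  } else {
    ends <- c(onsets[-1] - 1L, nf)
    rows <- lapply(seq_along(onsets), function(i) {
      win <- onsets[i]:ends[i]
      pk <- win[which.max(x[win])]
      data.frame(roi_id = roi_id, onset_frame = onsets[i],
                 peak_frame = pk, amplitude = x[pk])
    })
    out <- do.call(rbind, rows)
  }
  attr(out, "noise_sd") <- noise_sd
  class(out) <- c("event_table", "data.frame")
  out
}

#' Fit a base-10 log-normal law to event amplitudes
#'
#' Gaussian fit on the log10 scale: `mu10 = 10^mean(log10 a)` and
#' `sigma10 = 10^sd(log10 a)` (sample SD, denominator n-1); equivalent to
#' the maximum-likelihood Gaussian fit up to the SD denominator.
#'
#' @param amplitudes positive event amplitudes, length >= 2.
#' @return an object of class `lognormal_fit` with fields `mu10`,
#'   `sigma10`, `n`, and the underlying exponents `log10_mu`, `log10_sigma`.
#' @examples
#' fit_lognormal(c(1, 10, 100))  # mu10 = 10, sigma10 = 10
#' @export
fit_lognormal <- function(amplitudes) {
  a <- as.numeric(amplitudes)
  if (length(a) < 2) stop("need at least 2 amplitudes")
  if (any(!is.finite(a)) || any(a <= 0))
    stop("all amplitudes must be positive and finite")
  l <- log10(a)
  structure(list(mu10 = 10^mean(l), sigma10 = 10^sd(l), n = length(a),
                 log10_mu = mean(l), log10_sigma = sd(l)),
            class = "lognormal_fit")
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("log-normal fit: mu = 10^%.3f (= %.3f), sigma = 10^%.3f, N = %d\n",
              x$log10_mu, x$mu10, x$log10_sigma, x$n))
  invisible(x)
}
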