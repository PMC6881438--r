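# Population statistics: pairwise Pearson correlations bucketed by region
# pair, neuron-versus-neuropil comparison, and between-state tests.

#' Format a summary as median\\25th-75th percentiles
#'
#' @param x numeric vector.
#' @param digits significant digits.
#' @return character scalar like `"0.7\\0.4-1.0"`.
#' @export
format_median_iqr <- function(x, digits = 2) {
  q <- quantile(x, c(0.5, 0.25, 0.75), type = 7)
  sprintf("%s\\%s-%s", signif(q[1], digits), signif(q[2], digits),
          signif(q[3], digits))
}

#' Pairwise Pearson correlations bucketed by region pair
#'
#' Computes `corrcoef(X, Y) = cov(X, Y) / (sd(X) sd(Y))` for every
#' unordered pair of cells and buckets the coefficients into
#' intra-regional (e.g. V1-V1) and inter-regional (e.g. V1-CA1)
#' categories. Cells with zero variance have undefined correlations; their
#' pairs are excluded and counted.
#'
#' @param traces frames x cells matrix of delta-f/f traces (>= 3 frames,
#'   >= 2 cells).
#' @param regions character vector of region labels, one per column.
#' @return an object of class `correlation_result`: list with `pairs`
#'   (data.frame `cell_i`, `cell_j`, `category`, `r`), `summary` (per
#'   category: n, median, q25, q75), `n_excluded` and `excluded_cells`.
#' @examples
#' tr <- cbind(a = c(1, 2, 3), b = c(6, 4, 2), c = c(1, 1, 2))
#' pairwise_correlations(tr, c("V1", "V1", "M1"))$pairs
#' @export
pairwise_correlations <- function(traces, regions) {
  traces <- as.matrix(traces)
  nf <- nrow(traces); nc <- ncol(traces)
  if (nc < 2) stop("need at least 2 traces")
  if (nf < 3) stop("traces must have length >= 3")
  if (length(regions) != nc)
    stop("`regions` must have one label per trace")
  ids <- colnames(traces)
  if (is.null(ids)) ids <- paste0("cell", seq_len(nc))
  sds <- apply(traces, 2, sd)
  flat <- which(sds == 0)
  valid <- setdiff(seq_len(nc), flat)
  n_excluded <- (nc * (nc - 1)) %/% 2 -
    (length(valid) * (length(valid) - 1)) %/% 2
  pairs <- NULL
  if (length(valid) >= 2) {
    C <- cor(traces[, valid, drop = FALSE])
    ij <- which(upper.tri(C), arr.ind = TRUE)
    ri <- regions[valid][ij[, 1]]
    rj <- regions[valid][ij[, 2]]
    category <- vapply(seq_len(nrow(ij)), function(k)
      paste(sort(c(ri[k], rj[k])), collapse = "-"), character(1))
    pairs <- data.frame(cell_i = ids[valid][ij[, 1]],
                        cell_j = ids[valid][ij[, 2]],
                        region_i = ri, region_j = rj,
                        category = category, r = C[upper.tri(C)])
  } else {
    pairs <- data.frame(cell_i = character(0), cell_j = character(0),
                        region_i = character(0), region_j = character(0),
                        category = character(0), r = numeric(0))
  }
  summ <- NULL
  if (nrow(pairs) > 0) {
    summ <- do.call(rbind, lapply(split(pairs$r, pairs$category), function(r)
      data.frame(n = length(r), median = median(r),
                 q25 = unname(quantile(r, 0.25)),
                 q75 = unname(quantile(r, 0.75)))))
    summ$category <- rownames(summ)
    rownames(summ) <- NULL
    summ <- summ[, c("category", "n", "median", "q25", "q75")]
  }
  structure(list(pairs = pairs, summary = summ, n_excluded = n_excluded,
                 excluded_cells = ids[flat]),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pairwise correlations: %d pairs (%d excluded, zero variance)\n",
              nrow(x$pairs), x$n_excluded))
  if (!is.null(x$summary)) {
    for (i in seq_len(nrow(x$summary)))
      cat(sprintf("  %-12s n = %4d, r = %s\n", x$summary$category[i],
                  x$summary$n[i],
                  format_median_iqr(x$pairs$r[x$pairs$category ==
                                                x$summary$category[i]])))
  }
  invisible(x)
}

#' Compare somatic event amplitudes with adjacent neuropil signals
#'
#' For every soma, the somatic value is the median of its event amplitudes
#' and the neuropil value is the median, over the same event windows, of
#' the peak delta-f/f of the paired annulus. The paired comparison across
#' somata uses the Wilcoxon signed-rank test.
#'
#' @param events an `event_table` covering the somata (column `roi_id`).
#' @param annulus_dff named list of [compute_dff()] results (or numeric
#'   delta-f/f vectors), one per soma id.
#' @param n_frames trace length used to close the last event window
#'   (defaults to the annulus trace length).
#' @return an object of class `neuropil_comparison`: list with `per_soma`
#'   (data.frame `roi_id`, `soma_amp`, `neuropil_amp`), formatted
#'   `soma_summary` / `neuropil_summary` strings, `statistic`, `p_value`,
#'   `n`.
#' @export
neuropil_comparison <- function(events, annulus_dff, n_frames = NULL) {
  stopifnot(is.data.frame(events))
  soma_ids <- unique(events$roi_id)
  if (length(soma_ids) == 0) stop("no somatic events to compare")
  rows <- lapply(soma_ids, function(id) {
    if (!id %in% names(annulus_dff))
      stop("missing paired neuropil annulus for soma '", id, "'")
    np <- annulus_dff[[id]]
    npx <- if (inherits(np, "dff_trace")) np$dff else as.numeric(np)
    nfr <- if (is.null(n_frames)) length(npx) else n_frames
    ev <- events[events$roi_id == id, , drop = FALSE]
    onsets <- sort(ev$onset_frame)
    ends <- c(onsets[-1] - 1L, nfr)
    np_peaks <- vapply(seq_along(onsets), function(i)
      max(npx[onsets[i]:ends[i]]), numeric(1))
    data.frame(roi_id = id, soma_amp = median(ev$amplitude),
               neuropil_amp = median(np_peaks))
  })
  per_soma <- do.call(rbind, rows)
  d <- per_soma$soma_amp - per_soma$neuropil_amp
  if (all(d == 0)) {
    stat <- 0; pval <- 1
  } else {
    wt <- suppressWarnings(wilcox.test(per_soma$soma_amp,
                                       per_soma$neuropil_amp,
                                       paired = TRUE))
    stat <- unname(wt$statistic); pval <- wt$p.value
  }
  structure(list(per_soma = per_soma,
                 soma_summary = format_median_iqr(per_soma$soma_amp),
                 neuropil_summary = format_median_iqr(per_soma$neuropil_amp),
                 statistic = stat, p_value = pval, n = nrow(per_soma)),
            class = "neuropil_comparison")
}

#' @export
print.neuropil_comparison <- function(x, ...) {
  cat(sprintf("Neuron vs neuropil (N = %d): neurons %s, neuropils %s, P = %.3g\n",
              x$n, x$soma_summary, x$neuropil_summary, x$p_value))
  invisible(x)
}

#' Compare event amplitudes and correlations between two conditions
#'
#' Per region, a two-sample Wilcoxon rank-sum test on event amplitudes
#' between conditions and the shift of the median log10 amplitude; per
#' correlation category, the shift of the median Pearson coefficient.
#' Positive shifts mean condition B exceeds condition A.
#'
#' @param amps_a,amps_b named lists (region -> positive amplitude vector)
#'   for conditions A and B, analyzed with identical settings.
#' @param corr_a,corr_b optional [pairwise_correlations()] results.
#' @param conditions length-2 character vector of condition names.
#' @return an object of class `state_comparison`: list with `amplitudes`
#'   (data.frame `region`, `shift_log10`, `p_value`, `n_a`, `n_b`),
#'   optional `correlations` (data.frame `category`, `shift`), and
#'   `conditions`.
#' @export
state_comparison <- function(amps_a, amps_b, corr_a = NULL, corr_b = NULL,
                             conditions = c("anesthetized", "awake")) {
  regions <- union(names(amps_a), names(amps_b))
  if (length(regions) == 0) stop("no regions supplied")
  amp_rows <- lapply(regions, function(r) {
    a <- amps_a[[r]]; b <- amps_b[[r]]
    if (is.null(a) || length(a) == 0 || is.null(b) || length(b) == 0)
      stop("empty condition for region '", r, "'")
    if (any(a <= 0) || any(b <= 0)) stop("amplitudes must be positive")
    wt <- suppressWarnings(wilcox.test(b, a))
    data.frame(region = r,
               shift_log10 = median(log10(b)) - median(log10(a)),
               p_value = wt$p.value, n_a = length(a), n_b = length(b))
  })
  corr <- NULL
  if (!is.null(corr_a) && !is.null(corr_b)) {
    stopifnot(inherits(corr_a, "correlation_result"),
              inherits(corr_b, "correlation_result"))
    cats <- union(corr_a$summary$category, corr_b$summary$category)
    corr <- do.call(rbind, lapply(cats, function(cc) {
      ra <- corr_a$pairs$r[corr_a$pairs$category == cc]
      rb <- corr_b$pairs$r[corr_b$pairs$category == cc]
      if (length(ra) == 0 || length(rb) == 0)
        stop("empty condition for correlation category '", cc, "'")
      data.frame(category = cc, shift = median(rb) - median(ra))
    }))
  }
  structure(list(amplitudes = do.call(rbind, amp_rows),
                 correlations = corr, conditions = conditions),
            class = "state_comparison")
}

#' @export
print.state_comparison <- function(x, ...) {
  cat(sprintf("State comparison (%s -> %s):\n", x$conditions[1],
              x$conditions[2]))
  for (i in seq_len(nrow(x$amplitudes)))
    cat(sprintf("  %-5s amplitude shift %+.3f log10 units, P = %.3g\n",
                x$amplitudes$region[i], x$amplitudes$shift_log10[i],
                x$amplitudes$p_value[i]))
  if (!is.null(x$correlations))
    for (i in seq_len(nrow(x$correlations)))
      cat(sprintf("  %-8s correlation shift %+.3f\n",
                  x$correlations$category[i], x$correlations$shift[i]))
  invisible(x)
}
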