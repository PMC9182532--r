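# Burst (peak) detection in single-channel photon time traces.
#
# Baseline fluorescence arises from monomeric protein; assemblies
# transiting the confocal volume produce supra-baseline deflections.  The
# detector thresholds at baseline + k_sigma * sigma with a robust baseline
# (median) and a robust scale floored at the Poisson shot-noise level, so
# that a burst-heavy upper tail cannot inflate the threshold.

#' Burst-detection parameters
#'
#' @param k_sigma Threshold multiplier: a bin is supra-threshold when its
#'   count exceeds `baseline + k_sigma * sigma`.  The default of 5 makes
#'   chance crossings negligible at millisecond-binned Poisson backgrounds.
#' @param min_width_bins Minimum peak width in bins; shorter runs are
#'   discarded (after merging).
#' @param merge_gap_bins Runs separated by at most this many sub-threshold
#'   bins are merged into one peak.  Default 0: no merging.
#' @return An object of class `detection_params`.
#' @export
detection_params <- function(k_sigma = 5, min_width_bins = 1L,
                             merge_gap_bins = 0L) {
  if (!is.numeric(k_sigma) || length(k_sigma) != 1L || k_sigma <= 0)
    stop("`k_sigma` must be a single positive number", call. = FALSE)
  if (!is.numeric(min_width_bins) || min_width_bins < 1)
    stop("`min_width_bins` must be >= 1", call. = FALSE)
  if (!is.numeric(merge_gap_bins) || merge_gap_bins < 0)
    stop("`merge_gap_bins` must be >= 0", call. = FALSE)
  structure(
    list(k_sigma = k_sigma,
         min_width_bins = as.integer(min_width_bins),
         merge_gap_bins = as.integer(merge_gap_bins)),
    class = "detection_params"
  )
}

#' Robust baseline and noise scale of a photon count series
#'
#' The baseline is the median count per bin, which one or a few bursts
#' cannot move.  The noise scale is the scaled median absolute deviation,
#' floored at `sqrt(max(baseline, 1))` — the Poisson shot-noise standard
#' deviation implied by the baseline — so that a pathologically quiet
#' series still yields a usable threshold.
#'
#' @param counts Non-empty numeric vector of per-bin photon counts.
#' @return A list with elements `baseline` and `sigma` (both photon
#'   counts per bin, finite and >= 0).
#' @examples
#' estimate_baseline(rpois(1000, 5))
#' @export
estimate_baseline <- function(counts) {
  if (length(counts) == 0L || !is.numeric(counts))
    stop("`counts` must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(counts)) stop("`counts` must not contain NA", call. = FALSE)
  baseline <- median(counts)
  sigma <- max(mad(counts), sqrt(max(baseline, 1)))
  list(baseline = baseline, sigma = sigma)
}

empty_peak_table <- function(channel = character(0)) {
  data.frame(channel = channel[0], start_bin = integer(0),
             end_bin = integer(0), apex_bin = integer(0),
             max_intensity = numeric(0), integrated_photons = numeric(0),
             stringsAsFactors = FALSE)
}

#' Detect bursts in one channel of a time trace
#'
#' A peak is a maximal run of bins whose count exceeds
#' `baseline + k_sigma * sigma`; runs separated by at most
#' `merge_gap_bins` sub-threshold bins are merged, and merged runs
#' narrower than `min_width_bins` are discarded.  Returned peaks are
#' sorted by `start_bin` and never overlap.
#'
#' @param trace A [time_trace()].
#' @param channel `"green"` or `"red"`.
#' @param params A [detection_params()].
#' @return A data frame with one row per peak and columns `channel`,
#'   `start_bin`, `end_bin`, `apex_bin` (1-based, inclusive),
#'   `max_intensity` (photons/ms at the apex) and `integrated_photons`
#'   (sum of baseline-subtracted counts over the span).  The baseline,
#'   sigma and threshold used are attached as attributes.
#' @examples
#' tr <- time_trace(green = c(2, 2, 2, 50, 60, 50, 2, 2), red = rep(2, 8))
#' detect_peaks(tr, "green", detection_params(k_sigma = 3))
#' @export
detect_peaks <- function(trace, channel = c("green", "red"),
                         params = detection_params()) {
  if (!inherits(trace, "time_trace"))
    stop("`trace` must be a time_trace", call. = FALSE)
  channel <- match.arg(channel)
  if (!inherits(params, "detection_params"))
    stop("`params` must be a detection_params", call. = FALSE)
  counts <- trace[[channel]]
  bl <- estimate_baseline(counts)
  threshold <- bl$baseline + params$k_sigma * bl$sigma

  above <- counts > threshold
  out <- empty_peak_table()
  if (any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    # merge runs separated by <= merge_gap_bins sub-threshold bins
    if (nrow(runs) > 1L && params$merge_gap_bins > 0L) {
      gap <- runs$start[-1L] - runs$end[-nrow(runs)] - 1L
      grp <- cumsum(c(0L, as.integer(gap > params$merge_gap_bins)))
      runs <- data.frame(start = tapply(runs$start, grp, min),
                         end = tapply(runs$end, grp, max))
    }
    runs <- runs[runs$end - runs$start + 1L >= params$min_width_bins, ,
                 drop = FALSE]
    if (nrow(runs) > 0L) {
      apex <- integer(nrow(runs))
      maxi <- numeric(nrow(runs))
      integ <- numeric(nrow(runs))
      for (i in seq_len(nrow(runs))) {
        span <- runs$start[i]:runs$end[i]
        apex[i] <- span[which.max(counts[span])]
        maxi[i] <- counts[apex[i]] / trace$bin_ms
        integ[i] <- max(0, sum(counts[span] - bl$baseline))
      }
      out <- data.frame(channel = channel, start_bin = as.integer(runs$start),
                        end_bin = as.integer(runs$end), apex_bin = apex,
                        max_intensity = maxi, integrated_photons = integ,
                        stringsAsFactors = FALSE)
      rownames(out) <- NULL
    }
  }
  attr(out, "baseline") <- bl$baseline
  attr(out, "sigma") <- bl$sigma
  attr(out, "threshold") <- threshold
  attr(out, "bin_ms") <- trace$bin_ms
  out
}
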