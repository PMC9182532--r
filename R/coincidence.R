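# Cross-channel peak alignment and the colourQ coincidence statistic.
#
# colourQ = (number of Colour A peaks aligned with Colour B peaks) /
#           (total number of Colour A peaks)
#
# RedQ is colourQ with A = green, B = red: the proportion of green peaks
# aligned with red peaks.  Two peaks are "aligned" when their spans, each
# dilated by tolerance_bins, intersect: bursts are extended objects, so
# span overlap (not apex distance) is the alignment criterion.

#' Align peaks across two channels
#'
#' A peak from list A and a peak from list B are aligned iff their spans,
#' each dilated by `tolerance_bins` on both sides, intersect.  Every
#' qualifying pair is reported.  Both lists must be sorted by start and
#' non-overlapping within a channel (as [detect_peaks()] guarantees), which
#' allows a single linear sweep over the two lists.
#'
#' @param peaks_a,peaks_b Peak data frames as returned by
#'   [detect_peaks()] (columns `start_bin`, `end_bin` are required).
#' @param tolerance_bins Non-negative integer dilation applied to every
#'   span in both lists before testing intersection.
#' @return A data frame with columns `idx_a`, `idx_b`: row indices of the
#'   aligned peaks in the two inputs.
#' @export
align_peaks <- function(peaks_a, peaks_b, tolerance_bins = 0L) {
  if (!is.numeric(tolerance_bins) || length(tolerance_bins) != 1L ||
      is.na(tolerance_bins) || tolerance_bins < 0)
    stop("`tolerance_bins` must be a single non-negative integer", call. = FALSE)
  tol <- as.integer(tolerance_bins)
  na <- nrow(peaks_a)
  nb <- nrow(peaks_b)
  out_a <- integer(0)
  out_b <- integer(0)
  if (na > 0L && nb > 0L) {
    sa <- peaks_a$start_bin - tol; ea <- peaks_a$end_bin + tol
    sb <- peaks_b$start_bin - tol; eb <- peaks_b$end_bin + tol
    j0 <- 1L
    for (i in seq_len(na)) {
      # skip B peaks that end before this A peak starts
      while (j0 <= nb && eb[j0] < sa[i]) j0 <- j0 + 1L
      j <- j0
      while (j <= nb && sb[j] <= ea[i]) {
        out_a <- c(out_a, i)
        out_b <- c(out_b, j)
        j <- j + 1L
      }
    }
  }
  data.frame(idx_a = out_a, idx_b = out_b)
}

#' The colourQ coincidence statistic
#'
#' Fraction of Colour A peaks aligned with at least one Colour B peak.  An
#' A peak overlapping several B peaks counts once: the statistic counts
#' distinct A peaks, not pairs.  RedQ is `colour_q(green_peaks,
#' red_peaks)`; GreenQ swaps the arguments.
#'
#' @inheritParams align_peaks
#' @return A single number in `[0, 1]`, or `NA_real_` (with a warning)
#'   when `peaks_a` is empty, for which the statistic is undefined.
#' @examples
#' a <- data.frame(start_bin = c(10, 30), end_bin = c(12, 33))
#' b <- data.frame(start_bin = 11, end_bin = 11)
#' colour_q(a, b)  # 0.5
#' @export
colour_q <- function(peaks_a, peaks_b, tolerance_bins = 0L) {
  if (nrow(peaks_a) == 0L) {
    warning("colourQ is undefined: no Colour A peaks", call. = FALSE)
    return(NA_real_)
  }
  pairs <- align_peaks(peaks_a, peaks_b, tolerance_bins)
  length(unique(pairs$idx_a)) / nrow(peaks_a)
}

#' Expected chance-coincidence fraction under independence
#'
#' If the B-channel peaks were placed uniformly at random and
#' independently of the A channel, the probability that a given A peak is
#' aligned with at least one of them is approximately
#' `1 - exp(-n_b * (mean_width_b + 2 * tolerance) / n_bins)`.
#' This diagnostic is reported alongside colourQ so users can judge how
#' much coincidence random co-occupancy alone would produce; it is never
#' subtracted from the statistic.
#'
#' @param n_b_peaks Number of B-channel peaks.
#' @param mean_width_b Mean B peak width in bins.
#' @param n_bins Record length in bins.
#' @param tolerance_bins Alignment tolerance as in [align_peaks()].
#' @return Expected chance-aligned fraction in `[0, 1]`, monotone
#'   non-decreasing in every argument.
#' @export
chance_coincidence <- function(n_b_peaks, mean_width_b, n_bins,
                               tolerance_bins = 0L) {
  if (!is.numeric(n_bins) || length(n_bins) != 1L || n_bins <= 0)
    stop("`n_bins` must be a single positive number", call. = FALSE)
  if (n_b_peaks < 0 || mean_width_b < 0 || tolerance_bins < 0)
    stop("peak count, width and tolerance must be >= 0", call. = FALSE)
  if (n_b_peaks == 0) return(0)
  1 - exp(-n_b_peaks * (mean_width_b + 2 * tolerance_bins) / n_bins)
}

#' Full confocal-coincidence analysis of one trace
#'
#' Composes [estimate_baseline()] and [detect_peaks()] on both channels,
#' [align_peaks()] across channels, and [colour_q()] in both directions,
#' and reports the analytic chance-coincidence diagnostic.  Deterministic
#' for a fixed trace.
#'
#' @param trace A [time_trace()].
#' @param det A [detection_params()] applied to both channels.
#' @param tolerance_bins Alignment tolerance as in [align_peaks()].
#' @return An object of class `ccs_result`: a list with peak counts per
#'   channel (`n_green`, `n_red`), aligned-peak counts (`n_green_aligned`,
#'   `n_red_aligned`), `redQ` (fraction of green peaks aligned with red
#'   peaks; `NA` when no green peaks), `greenQ` (symmetric), the aligned
#'   `pairs` (columns `green`, `red`), the `chance_rate` diagnostic, and
#'   the per-channel peak tables.
#' @examples
#' tr <- simulate_mixture(0.9, 100, trace_config(duration_s = 30, seed = 7))
#' run_ccs(tr)
#' @export
run_ccs <- function(trace, det = detection_params(), tolerance_bins = 0L) {
  gp <- detect_peaks(trace, "green", det)
  rp <- detect_peaks(trace, "red", det)
  pairs <- align_peaks(gp, rp, tolerance_bins)
  names(pairs) <- c("green", "red")
  n_green <- nrow(gp)
  n_red <- nrow(rp)
  n_green_aligned <- length(unique(pairs$green))
  n_red_aligned <- length(unique(pairs$red))
  redQ <- if (n_green > 0L) n_green_aligned / n_green else NA_real_
  greenQ <- if (n_red > 0L) n_red_aligned / n_red else NA_real_
  mean_w_red <- if (n_red > 0L) mean(rp$end_bin - rp$start_bin + 1) else 0
  chance <- chance_coincidence(n_red, mean_w_red, length(trace$green),
                               tolerance_bins)
  structure(
    list(n_green = n_green, n_red = n_red,
         n_green_aligned = n_green_aligned, n_red_aligned = n_red_aligned,
         redQ = redQ, greenQ = greenQ, pairs = pairs, chance_rate = chance,
         green_peaks = gp, red_peaks = rp,
         params = det, tolerance_bins = as.integer(tolerance_bins)),
    class = "ccs_result"
  )
}

#' @export
print.ccs_result <- function(x, ...) {
  cat("<ccs_result>\n")
  cat(sprintf("  peaks: %d green, %d red\n", x$n_green, x$n_red))
  cat(sprintf("  aligned: %d green, %d red (%d pairs)\n",
              x$n_green_aligned, x$n_red_aligned, nrow(x$pairs)))
  cat(sprintf("  RedQ   = %s\n", format(x$redQ, digits = 3)))
  cat(sprintf("  GreenQ = %s\n", format(x$greenQ, digits = 3)))
  cat(sprintf("  chance-coincidence rate = %.4g\n", x$chance_rate))
  invisible(x)
}
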