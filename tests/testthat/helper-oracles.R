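# Independent brute-force oracles, deliberately written as dumb bin-by-bin
# scanners so they share no code path with the package implementations.

# Peak detection by walking the trace one bin at a time.
bf_detect_peaks <- function(counts, bin_ms = 1,
                            params = detection_params()) {
  baseline <- median(counts)
  sigma <- max(mad(counts), sqrt(max(baseline, 1)))
  thr <- baseline + params$k_sigma * sigma

  runs <- list()
  in_run <- FALSE
  run_start <- NA_integer_
  for (i in seq_along(counts)) {
    if (counts[i] > thr) {
      if (!in_run) { in_run <- TRUE; run_start <- i }
    } else if (in_run) {
      runs[[length(runs) + 1L]] <- c(run_start, i - 1L)
      in_run <- FALSE
    }
  }
  if (in_run) runs[[length(runs) + 1L]] <- c(run_start, length(counts))

  # merge pass, again bin-counting the gaps one run at a time
  merged <- list()
  for (r in runs) {
    k <- length(merged)
    if (k > 0L && r[1] - merged[[k]][2] - 1L <= params$merge_gap_bins) {
      merged[[k]][2] <- r[2]
    } else {
      merged[[length(merged) + 1L]] <- r
    }
  }

  out <- empty_bf_peaks()
  for (r in merged) {
    if (r[2] - r[1] + 1L < params$min_width_bins) next
    span <- r[1]:r[2]
    apex <- span[which.max(counts[span])]
    out <- rbind(out, data.frame(
      start_bin = r[1], end_bin = r[2], apex_bin = apex,
      max_intensity = counts[apex] / bin_ms,
      integrated_photons = max(0, sum(counts[span] - baseline))))
  }
  rownames(out) <- NULL
  out
}

empty_bf_peaks <- function() {
  data.frame(start_bin = integer(0), end_bin = integer(0),
             apex_bin = integer(0), max_intensity = numeric(0),
             integrated_photons = numeric(0))
}

# All-against-all O(n^2) alignment oracle.
bf_align <- function(peaks_a, peaks_b, tol = 0L) {
  ia <- integer(0); ib <- integer(0)
  for (i in seq_len(nrow(peaks_a))) {
    for (j in seq_len(nrow(peaks_b))) {
      a_lo <- peaks_a$start_bin[i] - tol; a_hi <- peaks_a$end_bin[i] + tol
      b_lo <- peaks_b$start_bin[j] - tol; b_hi <- peaks_b$end_bin[j] + tol
      if (a_lo <= b_hi && b_lo <= a_hi) { ia <- c(ia, i); ib <- c(ib, j) }
    }
  }
  data.frame(idx_a = ia, idx_b = ib)
}

# A random sorted, non-overlapping peak list on [1, n_bins].
random_peak_list <- function(n_bins = 500, channel = "green") {
  n <- sample(0:12, 1)
  if (n == 0) return(detect_peaks(time_trace(rep(1L, 10), rep(1L, 10)),
                                  channel)[0, ])
  cuts <- sort(sample.int(n_bins, 2 * n))
  starts <- cuts[seq(1, 2 * n, by = 2)]
  ends <- cuts[seq(2, 2 * n, by = 2)]
  keep <- !duplicated(starts) & c(TRUE, starts[-1] > ends[-n] )
  data.frame(channel = channel, start_bin = starts[keep],
             end_bin = ends[keep], apex_bin = starts[keep],
             max_intensity = runif(sum(keep), 10, 100),
             integrated_photons = runif(sum(keep), 10, 1000),
             stringsAsFactors = FALSE)
}

# A short random trace with a Poisson background and a few square bursts.
random_burst_trace <- function(n_bins = 1500, lambda = 2) {
  g <- rpois(n_bins, lambda)
  n_burst <- sample(0:6, 1)
  for (b in seq_len(n_burst)) {
    w <- sample(1:4, 1)
    s <- sample.int(n_bins - w, 1)
    g[s:(s + w - 1L)] <- g[s:(s + w - 1L)] + rpois(w, sample(c(15, 40, 80), 1))
  }
  g
}

# Green-visible ground-truth dual fraction of a simulated mixture trace.
gt_dual_fraction <- function(trace) {
  gt <- trace$ground_truth
  gv <- gt$species %in% c("green_homo", "dual")
  mean(gt$is_dual[gv])
}
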