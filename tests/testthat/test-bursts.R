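test_that("baseline estimation is robust and floored at shot noise", {
  b <- estimate_baseline(rep(3, 100))
  expect_equal(b$baseline, 3)
  expect_equal(b$sigma, sqrt(3))   # MAD is 0, the Poisson floor applies

  b <- estimate_baseline(c(0, 0, 0, 0, 100))
  expect_equal(b$baseline, 0)      # one burst cannot move the median

  withr::with_seed(42, {
    x <- rpois(1e5, 5)
    b <- estimate_baseline(x)
    expect_equal(b$baseline, 5)
    # at lambda = 5 the scaled MAD of the discrete counts sits at
    # 1.4826 * 2, above the sqrt(5) floor
    expect_lt(abs(b$sigma - 1.4826 * 2), 0.1 * 1.4826 * 2)
  })

  expect_error(estimate_baseline(numeric(0)), "non-empty")
})

test_that("detect_peaks matches the hand-worked example", {
  tr <- time_trace(green = c(2, 2, 2, 50, 60, 50, 2, 2), red = rep(2, 8))
  p <- detect_peaks(tr, "green")   # threshold = 2 + 5*sqrt(2) ~ 9.07
  expect_equal(nrow(p), 1L)
  expect_equal(p$start_bin, 4L)
  expect_equal(p$end_bin, 6L)
  expect_equal(p$apex_bin, 5L)
  expect_equal(p$max_intensity, 60)
  expect_equal(p$integrated_photons, 50 + 60 + 50 - 3 * 2)

  flat <- time_trace(green = rep(4L, 50), red = rep(4L, 50))
  expect_equal(nrow(detect_peaks(flat, "green")), 0L)
  expect_equal(nrow(detect_peaks(flat, "red")), 0L)
})

test_that("gap merging and the width filter behave as documented", {
  counts <- c(rep(2, 5), 50, 2, 55, rep(2, 5))
  tr <- time_trace(counts, rep(2L, length(counts)))
  two <- detect_peaks(tr, "green", detection_params(merge_gap_bins = 0))
  expect_equal(nrow(two), 2L)
  one <- detect_peaks(tr, "green", detection_params(merge_gap_bins = 1))
  expect_equal(nrow(one), 1L)
  expect_equal(one$start_bin, 6L)
  expect_equal(one$end_bin, 8L)
  expect_equal(one$apex_bin, 8L)

  wide_only <- detect_peaks(tr, "green",
                            detection_params(min_width_bins = 2))
  expect_equal(nrow(wide_only), 0L)  # both runs are single bins
  merged_wide <- detect_peaks(tr, "green",
                              detection_params(min_width_bins = 2,
                                               merge_gap_bins = 1))
  expect_equal(nrow(merged_wide), 1L)
})

test_that("detected peaks are sorted, non-overlapping, and fewer at higher k", {
  withr::with_seed(314, {
    for (rep in 1:20) {
      tr <- time_trace(random_burst_trace(), random_burst_trace())
      for (ch in c("green", "red")) {
        p <- detect_peaks(tr, ch)
        if (nrow(p) > 1L) {
          expect_true(all(diff(p$start_bin) > 0))
          expect_true(all(p$start_bin[-1] > p$end_bin[-nrow(p)]))
        }
        expect_true(all(p$start_bin <= p$apex_bin & p$apex_bin <= p$end_bin))
        # raising the threshold shrinks the supra-threshold region, and
        # every peak at a higher k nests inside a peak found at a lower k
        # (a stricter threshold can split a plateau, so the peak *count*
        # itself need not decrease)
        ks <- c(3, 5, 8, 12)
        plist <- lapply(ks, function(k)
          detect_peaks(tr, ch, detection_params(k_sigma = k)))
        area <- vapply(plist, function(p)
          sum(p$end_bin - p$start_bin + 1L), 0L)
        expect_true(all(diff(area) <= 0))
        for (j in seq_along(ks)[-1]) {
          hi <- plist[[j]]; lo <- plist[[j - 1L]]
          nested <- vapply(seq_len(nrow(hi)), function(i)
            any(lo$start_bin <= hi$start_bin[i] &
                  hi$end_bin[i] <= lo$end_bin), TRUE)
          expect_true(all(nested))
        }
      }
    }
  })
})

test_that("detect_peaks agrees with the brute-force scanner", {
  withr::with_seed(2718, {
    for (rep in 1:25) {
      params <- detection_params(
        k_sigma = sample(c(3, 5, 8), 1),
        min_width_bins = sample(1:2, 1),
        merge_gap_bins = sample(0:2, 1))
      g <- random_burst_trace()
      tr <- time_trace(g, rep(1L, length(g)))
      mine <- detect_peaks(tr, "green", params)
      oracle <- bf_detect_peaks(g, 1, params)
      expect_equal(mine[, names(oracle)], oracle, ignore_attr = TRUE)
    }
  })
})

test_that("bright simulated bursts are recovered near-completely", {
  cfg <- trace_config(duration_s = 120, seed = 55)
  tr <- simulate_trace(list(species_model("dual", 2, 120, 120)), cfg)
  gp <- detect_peaks(tr, "green")
  # apex amplitude (120 + background) is far above 2x the ~8.4 threshold
  apex <- tr$ground_truth$apex_bin
  inside <- vapply(apex, function(a)
    any(gp$start_bin <= a & a <= gp$end_bin), TRUE)
  expect_gte(mean(inside), 0.99)
})

test_that("false-positive bins on pure background follow the Poisson tail", {
  cfg <- trace_config(duration_s = 100, background_green = 5,
                      background_red = 5, seed = 66)
  tr <- simulate_trace(list(), cfg)
  params <- detection_params(k_sigma = 3)   # low threshold: measurable tail
  p <- detect_peaks(tr, "green", params)
  thr <- attr(p, "threshold")
  n <- length(tr$green)
  expected <- ppois(floor(thr), 5, lower.tail = FALSE)
  observed <- sum(tr$green > thr) / n
  mc_tol <- 4 * sqrt(expected * (1 - expected) / n)
  expect_lt(abs(observed - expected), mc_tol + 0.2 * expected)
  # and every supra-threshold bin belongs to some reported peak
  expect_equal(sum(p$end_bin - p$start_bin + 1L), sum(tr$green > thr))
})
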