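test_that("background-only traces are Poisson around the stated background", {
  cfg <- trace_config(duration_s = 10, background_green = 2,
                      background_red = 3, seed = 101)
  tr <- simulate_trace(list(), cfg)
  n <- length(tr$green)
  expect_equal(n, 10000L)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(tr$green) - 2), 3 * se)
  expect_lt(abs(mean(tr$red) - 3), 3 * sqrt(3 / n))
  # Poisson: variance tracks the mean
  expect_lt(abs(var(tr$green) / mean(tr$green) - 1), 0.1)
  expect_lt(abs(var(tr$red) / mean(tr$red) - 1), 0.1)
  expect_equal(nrow(tr$ground_truth), 0L)
})

test_that("simulation is bit-identical under a fixed seed", {
  sp <- list(species_model("dual", 1, 80, 80, transit_ms = 2),
             species_model("g", 2, 60, 0, transit_ms = 1))
  cfg <- trace_config(duration_s = 20, seed = 11)
  a <- simulate_trace(sp, cfg)
  b <- simulate_trace(sp, cfg)
  expect_identical(a$green, b$green)
  expect_identical(a$red, b$red)
  expect_identical(a$ground_truth, b$ground_truth)
})

test_that("a green-only species never elevates the red channel", {
  cfg <- trace_config(duration_s = 30, background_green = 1,
                      background_red = 1, seed = 5)
  tr <- simulate_trace(list(species_model("g", 3, 100, 0)), cfg)
  n <- length(tr$red)
  # red stays a pure Poisson background: mean at background, no burst tail
  expect_lt(abs(mean(tr$red) - 1), 3 * sqrt(1 / n))
  expect_lt(max(tr$red), 10)          # P(Poisson(1) >= 10) ~ 1e-8 per bin
  expect_gt(max(tr$green), 50)        # while green carries real bursts
})

test_that("heteromeric bursts are reproducible and elevate both channels", {
  cfg <- trace_config(duration_s = 180, background_green = 1,
                      background_red = 1, seed = 77)
  sp <- species_model("dual", 50 / 180, 100, 100, transit_ms = 1)
  tr <- simulate_trace(list(sp), cfg)
  tr2 <- simulate_trace(list(sp), cfg)
  expect_identical(tr$ground_truth, tr2$ground_truth)
  n_ev <- nrow(tr$ground_truth)
  expect_gt(n_ev, qpois(0.0005, 50))   # a plausible Poisson(50) draw
  expect_lt(n_ev, qpois(0.9995, 50))
  # recompute the expected envelope at apex bins: amplitude 100 + background
  apex <- tr$ground_truth$apex_bin
  expect_true(all(tr$green[apex] > 50))
  expect_true(all(tr$red[apex] > 50))
})

test_that("burst envelopes never cross the record boundary", {
  cfg <- trace_config(duration_s = 5, seed = 9)
  sp <- species_model("slow", 20, 50, 0, transit_ms = 40)  # wide envelope
  tr <- simulate_trace(list(sp), cfg)
  half <- ceiling(3 * 40 / 4)
  apex <- tr$ground_truth$apex_bin
  expect_true(all(apex - half >= 1))
  expect_true(all(apex + half <= length(tr$green)))
})

test_that("simulate_mixture splits events by the heteromer fraction", {
  cfg <- trace_config(duration_s = 60, seed = 21)
  all_dual <- simulate_mixture(1, 200, cfg)
  expect_true(all(all_dual$ground_truth$is_dual))

  none_dual <- simulate_mixture(0, 200, cfg)
  expect_false(any(none_dual$ground_truth$is_dual))
  expect_setequal(unique(none_dual$ground_truth$species),
                  c("green_homo", "red_homo"))

  mid <- simulate_mixture(0.4, 500, trace_config(duration_s = 180, seed = 22))
  gt <- mid$ground_truth
  gv <- gt$species %in% c("green_homo", "dual")
  # realised dual fraction within the binomial 99% interval of 0.4
  n_gv <- sum(gv)
  half_ci <- qnorm(0.995) * sqrt(0.4 * 0.6 / n_gv)
  expect_lt(abs(mean(gt$is_dual[gv]) - 0.4), half_ci + 1e-12)
})

test_that("configuration and species validation reject bad inputs", {
  expect_error(trace_config(duration_s = 1, bin_ms = 3), "whole number")
  expect_error(species_model("x", -1, 10), "arrival_rate")
  expect_error(species_model("x", 1, 0, 0), "at least one channel")
  expect_error(species_model("x", 1, -5, 0), "brightness")
  expect_error(simulate_trace(list(), trace_config(background_green = 0,
                                                   background_red = 0)),
               "at least one species")
})

test_that("synthetic digests honour their configuration", {
  prot <- trif_rhim_synthetic()

  full <- simulate_digest(digest_config(core_prevalence = 1, n_reads = 60,
                                        seed = 2))
  expect_true(all(full$covers_core))
  expect_true(all(full$start <= 654 & full$end >= 709))

  d <- simulate_digest(digest_config(n_reads = 150, seed = 12))
  # exact substrings inside the construct span
  expect_true(all(d$start >= prot$start & d$end <= prot$end))
  expect_true(all(mapply(function(pep, s) {
    substr(prot$residues, s - prot$offset + 1, s - prot$offset + nchar(pep)) == pep
  }, d$peptide, d$start)))
  # length bounds
  len <- d$end - d$start + 1
  cfg <- attr(d, "config")
  expect_true(all(len >= cfg$length_range[1] & len <= cfg$length_range[2]))
  # tetrad contained in every read
  expect_true(all(d$start <= 663 & d$end >= 666))
  # determinism
  expect_identical(d, simulate_digest(digest_config(n_reads = 150, seed = 12)))
  # oxidation annotations point at methionines
  ann <- d[nzchar(d$modifications), ]
  for (i in seq_len(nrow(ann))) {
    for (tok in strsplit(ann$modifications[i], ";")[[1]]) {
      pos <- as.integer(sub(":.*", "", tok))
      expect_identical(substr(ann$peptide[i], pos, pos), "M")
    }
  }
})

test_that("digest coverage decays outside the core and is flat without decay", {
  prot <- trif_rhim_synthetic()
  d <- simulate_digest(digest_config(n_reads = 400, decay_per_residue = 0.3,
                                     seed = 31))
  prof <- build_profile(d, prot, trif_tetrad())
  prev <- prof$prevalence
  pos <- prof$positions
  # geometric decay: prevalence k residues outside the core is close to
  # core_prevalence * (1 - decay)^k
  core_prev <- mean(d$covers_core)
  for (k in 1:3) {   # construct ends at 712, so flanks reach 709 + 3
    expected <- core_prev * 0.7^k
    expect_lt(abs(prev[pos == 654 - k] - expected), 0.1)
    expect_lt(abs(prev[pos == 709 + k] - expected), 0.1)
  }
  # with decay 0 and full-length peptides allowed, core reads span the
  # whole construct: uniform coverage at 1 for core_prevalence 1
  flat <- simulate_digest(digest_config(core_prevalence = 1, n_reads = 50,
                                        length_range = c(8L, 112L),
                                        decay_per_residue = 0, seed = 4))
  pf <- build_profile(flat, prot, trif_tetrad())
  expect_true(all(pf$prevalence == 1))
})

test_that("digest configuration errors are raised", {
  expect_error(digest_config(core_start = 500), "protein span")
  expect_error(digest_config(length_range = c(8L, 40L)),
               "core longer than the maximum peptide length")
  expect_error(digest_config(core_prevalence = 1.2), "core_prevalence")
})
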