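# Simulation of dual-channel photon time traces from diffusing species.
#
# Model: each species generates burst events as a homogeneous Poisson
# process over the record.  A burst adds a Gaussian intensity envelope
# (apex amplitude = brightness in photons/ms, sd = transit_ms/4, truncated
# at +/- 3 sd) to the deterministic channel intensity.  Per-bin counts are
# independent Poisson draws around intensity x bin width (photon shot
# noise); the two channels are realised independently, as they are
# physically separate detectors.

#' Define a diffusing fluorescent species
#'
#' A species is characterised by how often it transits the confocal volume
#' (`arrival_rate`), how bright it appears at the burst apex in each
#' detection channel, and how long it dwells in the volume.  A homomeric
#' species is bright in exactly one channel; a heteromeric (dual-labelled)
#' species is bright in both and therefore produces coincident bursts.
#'
#' @param name Species label carried into the trace ground truth.
#' @param arrival_rate Expected burst events per second (homogeneous
#'   Poisson process); must be >= 0.
#' @param brightness_green,brightness_red Mean photons/ms contributed at
#'   the burst apex in each channel; at least one must be positive.
#' @param transit_ms Mean dwell time in the confocal volume, in
#'   milliseconds; sets the burst envelope width (sd = `transit_ms/4`).
#' @return An object of class `species_model`.
#' @examples
#' species_model("dual", arrival_rate = 2, brightness_green = 100,
#'               brightness_red = 100, transit_ms = 1)
#' @export
species_model <- function(name, arrival_rate, brightness_green = 0,
                          brightness_red = 0, transit_ms = 1) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("`name` must be a single non-empty string", call. = FALSE)
  for (arg in c("arrival_rate", "brightness_green", "brightness_red", "transit_ms")) {
    v <- get(arg)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || !is.finite(v))
      stop(sprintf("`%s` must be a single finite number", arg), call. = FALSE)
  }
  if (arrival_rate < 0) stop("`arrival_rate` must be >= 0", call. = FALSE)
  if (brightness_green < 0 || brightness_red < 0)
    stop("brightnesses must be >= 0", call. = FALSE)
  if (transit_ms <= 0) stop("`transit_ms` must be > 0", call. = FALSE)
  if (brightness_green == 0 && brightness_red == 0)
    stop("a species must be bright in at least one channel", call. = FALSE)
  structure(
    list(name = name, arrival_rate = arrival_rate,
         brightness_green = brightness_green, brightness_red = brightness_red,
         transit_ms = transit_ms),
    class = "species_model"
  )
}

is_dual_species <- function(sp) sp$brightness_green > 0 && sp$brightness_red > 0

#' Acquisition settings for a simulated CCS record
#'
#' Defaults mirror a standard acquisition: a three-minute record binned at
#' 1 ms, with a dilute-monomer background of 1 photon/ms in each channel.
#'
#' @param duration_s Record length in seconds.
#' @param bin_ms Bin width in milliseconds; `duration_s * 1000 / bin_ms`
#'   must be a whole number of bins.
#' @param background_green,background_red Mean background (monomer
#'   baseline) photons/ms per channel.
#' @param seed Integer seed making the simulated trace reproducible;
#'   `NULL` uses the current RNG state.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(duration_s = 180, bin_ms = 1,
                         background_green = 1, background_red = 1,
                         seed = NULL) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0)
    stop("`duration_s` must be a single positive number", call. = FALSE)
  if (!is.numeric(bin_ms) || length(bin_ms) != 1L || bin_ms <= 0)
    stop("`bin_ms` must be a single positive number", call. = FALSE)
  n_bins <- duration_s * 1000 / bin_ms
  if (abs(n_bins - round(n_bins)) > 1e-9)
    stop("`duration_s * 1000 / bin_ms` must be a whole number of bins",
         call. = FALSE)
  if (background_green < 0 || background_red < 0)
    stop("backgrounds must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop("`seed` must be a single integer or NULL", call. = FALSE)
    seed <- as.integer(seed)
  }
  structure(
    list(duration_s = duration_s, bin_ms = bin_ms,
         background_green = background_green,
         background_red = background_red,
         n_bins = as.integer(round(n_bins)), seed = seed),
    class = "trace_config"
  )
}

#' Construct a dual-channel time trace
#'
#' @param green,red Non-negative integer photon counts per bin; equal
#'   length.
#' @param bin_ms Bin width in milliseconds.
#' @param ground_truth Optional data frame of simulated burst placements
#'   with columns `species`, `apex_bin`, `is_dual`.
#' @return An object of class `time_trace`.
#' @export
time_trace <- function(green, red, bin_ms = 1, ground_truth = NULL) {
  green <- as.integer(green)
  red <- as.integer(red)
  if (length(green) != length(red))
    stop("`green` and `red` must have equal length", call. = FALSE)
  if (length(green) == 0L) stop("trace must contain at least one bin", call. = FALSE)
  if (anyNA(green) || anyNA(red) || any(green < 0L) || any(red < 0L))
    stop("counts must be non-negative integers", call. = FALSE)
  if (!is.null(ground_truth))
    stopifnot(is.data.frame(ground_truth),
              all(c("species", "apex_bin", "is_dual") %in% names(ground_truth)))
  structure(
    list(bin_ms = bin_ms, green = green, red = red,
         ground_truth = ground_truth),
    class = "time_trace"
  )
}

#' @export
print.time_trace <- function(x, ...) {
  cat(sprintf("<time_trace> %d bins x %g ms (%.1f s)\n",
              length(x$green), x$bin_ms, length(x$green) * x$bin_ms / 1000))
  cat(sprintf("  green: mean %.2f, max %d counts/bin\n",
              mean(x$green), max(x$green)))
  cat(sprintf("  red:   mean %.2f, max %d counts/bin\n",
              mean(x$red), max(x$red)))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d bursts (%d dual)\n",
                nrow(x$ground_truth), sum(x$ground_truth$is_dual)))
  invisible(x)
}

# Run `code` under `seed` without disturbing the caller's RNG stream.
with_sim_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Simulate a dual-channel photon time trace
#'
#' Places burst events for each species by a homogeneous Poisson process
#' (apex bins uniform over the record), adds a truncated Gaussian intensity
#' envelope per event, and draws per-bin Poisson photon counts around
#' background-plus-envelope intensity, independently per channel.  A
#' dual-labelled species writes its envelope into both channels at the same
#' apex bin, so its photon realisations in the two channels are
#' independent Poisson draws around a common envelope.  Events whose
#' truncated envelope would cross a record boundary are re-drawn, keeping
#' the ground-truth burst count exact.
#'
#' @param species List of [species_model()] objects (may be empty if a
#'   background is set).
#' @param config A [trace_config()].
#' @return A [time_trace()] whose `ground_truth` lists every placed burst
#'   (`species`, `apex_bin`, `is_dual`), sorted by apex bin.
#' @examples
#' sp <- species_model("dual", 0.5, 100, 100, transit_ms = 1)
#' tr <- simulate_trace(list(sp), trace_config(duration_s = 10, seed = 1))
#' tr
#' @export
simulate_trace <- function(species, config) {
  if (inherits(species, "species_model")) species <- list(species)
  if (!is.list(species) || !all(vapply(species, inherits, TRUE, "species_model")))
    stop("`species` must be a list of species_model objects", call. = FALSE)
  if (!inherits(config, "trace_config"))
    stop("`config` must be a trace_config", call. = FALSE)
  if (length(species) == 0L &&
      config$background_green == 0 && config$background_red == 0)
    stop("need at least one species or a nonzero background", call. = FALSE)

  n_bins <- config$n_bins
  with_sim_seed(config$seed, {
    lambda_g <- rep(config$background_green, n_bins)
    lambda_r <- rep(config$background_red, n_bins)
    gt_species <- character(0)
    gt_apex <- integer(0)
    gt_dual <- logical(0)

    for (sp in species) {
      n_ev <- rpois(1L, sp$arrival_rate * config$duration_s)
      if (n_ev == 0L) next
      sd_bins <- (sp$transit_ms / 4) / config$bin_ms
      half <- as.integer(ceiling(3 * sd_bins))
      if (2L * half + 1L > n_bins)
        stop("burst envelope wider than the record; shorten `transit_ms`",
             call. = FALSE)
      # uniform apexes, re-drawn until the +/-3 sd envelope fits the record
      apex <- integer(0)
      need <- n_ev
      while (need > 0L) {
        cand <- sample.int(n_bins, need, replace = TRUE)
        ok <- cand - half >= 1L & cand + half <= n_bins
        apex <- c(apex, cand[ok])
        need <- sum(!ok)
      }
      off <- -half:half
      env <- exp(-off^2 / (2 * sd_bins^2))
      for (a in apex) {
        idx <- a + off
        lambda_g[idx] <- lambda_g[idx] + sp$brightness_green * env
        lambda_r[idx] <- lambda_r[idx] + sp$brightness_red * env
      }
      gt_species <- c(gt_species, rep(sp$name, n_ev))
      gt_apex <- c(gt_apex, apex)
      gt_dual <- c(gt_dual, rep(is_dual_species(sp), n_ev))
    }

    green <- rpois(n_bins, lambda_g * config$bin_ms)
    red <- rpois(n_bins, lambda_r * config$bin_ms)

    ord <- order(gt_apex, gt_species)
    gt <- data.frame(species = gt_species[ord], apex_bin = gt_apex[ord],
                     is_dual = gt_dual[ord], stringsAsFactors = FALSE)
    time_trace(green, red, bin_ms = config$bin_ms, ground_truth = gt)
  })
}

#' Simulate a two-protein co-incubation with a known heteromer fraction
#'
#' Convenience wrapper for the canonical CCS experiment: two labelled
#' proteins mixed under assembly-permissive conditions, forming green-only,
#' red-only and dual-labelled assemblies.  Arrival rates are split so the
#' dual species carries `hetero_fraction` of the green-visible events (and,
#' symmetrically, of the red-visible events): with `f = hetero_fraction`
#' and `N = n_events_target` total expected events, the dual rate carries
#' `f N / (2 - f)` events and each single-colour species `(1-f) N / (2-f)`.
#'
#' @param hetero_fraction Fraction in `[0, 1]` of green-visible events that
#'   are dual-labelled; the ground-truth value that [run_ccs()] estimates
#'   as RedQ.
#' @param n_events_target Expected total number of burst events over the
#'   record (all three species combined).
#' @param config A [trace_config()].
#' @param brightness Apex brightness in photons/ms used for every labelled
#'   channel of every species.
#' @param transit_ms Dwell time passed to each species.
#' @return A [time_trace()]; `ground_truth$is_dual` flags the dual events.
#' @export
simulate_mixture <- function(hetero_fraction, n_events_target, config,
                             brightness = 120, transit_ms = 1) {
  if (!is.numeric(hetero_fraction) || length(hetero_fraction) != 1L ||
      is.na(hetero_fraction) || hetero_fraction < 0 || hetero_fraction > 1)
    stop("`hetero_fraction` must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(n_events_target) || n_events_target <= 0)
    stop("`n_events_target` must be positive", call. = FALSE)
  f <- hetero_fraction
  green_visible <- n_events_target / (2 - f)
  n_dual <- f * green_visible
  n_single <- (1 - f) * green_visible
  dur <- config$duration_s
  species <- list()
  if (n_single > 0) {
    species <- c(species, list(
      species_model("green_homo", n_single / dur,
                    brightness_green = brightness, transit_ms = transit_ms),
      species_model("red_homo", n_single / dur,
                    brightness_red = brightness, transit_ms = transit_ms)))
  }
  if (n_dual > 0) {
    species <- c(species, list(
      species_model("dual", n_dual / dur,
                    brightness_green = brightness, brightness_red = brightness,
                    transit_ms = transit_ms)))
  }
  simulate_trace(species, config)
}
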