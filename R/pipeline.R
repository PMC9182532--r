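# Reproducible pipeline commands.  Each command validates and computes
# first, then writes its outputs together with a YAML run manifest
# recording every parameter and seed, so any output can be regenerated
# from its manifest alone.  No partial files are left behind on a
# validation failure.

write_manifest <- function(dir, command, params) {
  manifest <- list(tool = "coinspec",
                   version = as.character(utils::packageVersion("coinspec")),
                   command = command, params = params)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
}

ensure_dir <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  dir
}

#' Simulate a mixture trace and write it to disk
#'
#' Runs [simulate_mixture()] and writes `trace.tsv`, its ground-truth
#' sidecar and a run manifest into `out_dir` (created if missing).
#' Identical parameters and seed give byte-identical outputs.
#'
#' @param out_dir Output directory.
#' @param hetero_fraction,n_events_target,brightness,transit_ms Passed to
#'   [simulate_mixture()].
#' @param config A [trace_config()]; give it a seed for reproducibility.
#' @return Invisibly, the path of the written trace.
#' @export
cmd_simulate <- function(out_dir, hetero_fraction = 0.5,
                         n_events_target = 500, config = trace_config(),
                         brightness = 120, transit_ms = 1) {
  trace <- simulate_mixture(hetero_fraction, n_events_target, config,
                            brightness = brightness, transit_ms = transit_ms)
  ensure_dir(out_dir)
  path <- file.path(out_dir, "trace.tsv")
  write_trace(trace, path)
  write_manifest(out_dir, "simulate",
                 list(hetero_fraction = hetero_fraction,
                      n_events_target = n_events_target,
                      duration_s = config$duration_s, bin_ms = config$bin_ms,
                      background_green = config$background_green,
                      background_red = config$background_red,
                      brightness = brightness, transit_ms = transit_ms,
                      seed = config$seed))
  invisible(path)
}

#' Run the coincidence analysis on a trace file
#'
#' Reads a trace TSV, runs [run_ccs()], and writes `report.txt` (flat
#' `key: value` lines), `peaks.csv`, `pairs.csv` and a manifest.
#'
#' @param trace_file Trace TSV as written by [cmd_simulate()] /
#'   [write_trace()].
#' @param out_dir Output directory.
#' @param det A [detection_params()].
#' @param tolerance_bins Alignment tolerance.
#' @param bin_ms Bin width of the trace file, milliseconds.
#' @return Invisibly, the `ccs_result`.
#' @export
cmd_ccs <- function(trace_file, out_dir, det = detection_params(),
                    tolerance_bins = 0L, bin_ms = 1) {
  trace <- read_trace(trace_file, bin_ms = bin_ms)
  res <- run_ccs(trace, det, tolerance_bins)
  ensure_dir(out_dir)
  rep_lines <- c(
    sprintf("n_green: %d", res$n_green),
    sprintf("n_red: %d", res$n_red),
    sprintf("n_green_aligned: %d", res$n_green_aligned),
    sprintf("n_red_aligned: %d", res$n_red_aligned),
    sprintf("redQ: %s", format(res$redQ, digits = 15)),
    sprintf("greenQ: %s", format(res$greenQ, digits = 15)),
    sprintf("chance_rate: %s", format(res$chance_rate, digits = 15)))
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  write_peaks(rbind(res$green_peaks, res$red_peaks),
              file.path(out_dir, "peaks.csv"))
  write.csv(res$pairs, file.path(out_dir, "pairs.csv"), row.names = FALSE,
            quote = FALSE)
  write_manifest(out_dir, "ccs",
                 list(trace_file = trace_file, k_sigma = det$k_sigma,
                      min_width_bins = det$min_width_bins,
                      merge_gap_bins = det$merge_gap_bins,
                      tolerance_bins = as.integer(tolerance_bins),
                      bin_ms = bin_ms))
  invisible(res)
}

#' Build a photon-counting histogram from a peaks file
#'
#' @param peaks_file CSV as written by [write_peaks()].
#' @param out_dir Output directory; receives `pch.csv` and a manifest.
#' @param bin_width,max_intensity,statistic Passed to [build_pch()].
#' @param channel Restrict to `"green"` or `"red"` peaks, or `"either"`
#'   (default) for all.
#' @return Invisibly, the `pch` object.
#' @export
cmd_pch <- function(peaks_file, out_dir, bin_width = 100,
                    max_intensity = NULL, statistic = "max",
                    channel = "either") {
  peaks <- read_peaks(peaks_file)
  if (channel != "either") peaks <- peaks[peaks$channel == channel, ,
                                          drop = FALSE]
  h <- build_pch(peaks, bin_width = bin_width, max_intensity = max_intensity,
                 statistic = statistic)
  ensure_dir(out_dir)
  write_pch(h, file.path(out_dir, "pch.csv"))
  write_manifest(out_dir, "pch",
                 list(peaks_file = peaks_file, bin_width = bin_width,
                      max_intensity = max_intensity, statistic = statistic,
                      channel = channel))
  invisible(h)
}

#' Map a peptide digest onto a protein and delineate the protected core
#'
#' Reads a single-record FASTA and a peptide CSV, builds the per-residue
#' prevalence profile, delineates the protected core, and writes
#' `profile.tsv`, `report.txt` and a manifest.
#'
#' @param fasta_file Parent protein FASTA (one record).
#' @param reads_file Peptide CSV (see [read_peptides()]).
#' @param out_dir Output directory.
#' @param offset Full-length position of the construct's first residue.
#' @param tetrad Integer `c(start, end)` of the core tetrad, full-length
#'   numbering.
#' @param threshold Prevalence threshold for [delineate_core()].
#' @param weight Prevalence weighting mode, see [build_profile()].
#' @return Invisibly, the `protection_profile` with `core_interval`
#'   filled in.
#' @export
cmd_coremap <- function(fasta_file, reads_file, out_dir, offset = 1L,
                        tetrad, threshold = 0.7, weight = "count") {
  protein <- read_protein_fasta(fasta_file, offset = offset)
  reads <- read_peptides(reads_file)
  profile <- build_profile(reads, protein, tetrad, weight = weight)
  core <- delineate_core(profile, threshold)
  profile$core_interval <- core
  ensure_dir(out_dir)
  write_profile(profile, file.path(out_dir, "profile.tsv"))
  rep_lines <- c(
    sprintf("n_mapped: %s", format(profile$n_mapped)),
    sprintf("n_excluded: %s", format(profile$n_excluded)),
    sprintf("tetrad: %d-%d", profile$tetrad_interval[1],
            profile$tetrad_interval[2]),
    sprintf("tetrad_prevalence: %s",
            format(profile$tetrad_prevalence, digits = 15)),
    if (is.null(core)) "core: none" else
      sprintf("core: %d-%d", core[1], core[2]))
  writeLines(rep_lines, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, "coremap",
                 list(fasta_file = fasta_file, reads_file = reads_file,
                      offset = as.integer(offset),
                      tetrad = as.integer(tetrad), threshold = threshold,
                      weight = weight))
  invisible(profile)
}
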