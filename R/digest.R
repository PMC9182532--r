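# Synthetic limited-proteolysis digests with known ground truth.
#
# The generator emulates the peptide list produced by LC-MS of a
# protease-resistant amyloid core: every emitted read is an exact
# substring of the parent construct, every read contains the core tetrad
# (the motif residues observed in every detected sequence), a controlled
# fraction of reads spans the full protected core, and coverage decays
# multiplicatively per residue outside the core.

# Synthetic 112-residue TRIF-like RHIM construct, full-length numbering
# 601-712.  The true TRIF sequence is not redistributed here; this stand-in
# preserves the features the analysis relies on: the VQLG core tetrad at
# 663-666, the amyloidogenic nonapeptide PLIIHHAQM immediately N-terminal
# of it (654-662), five methionines for oxidation annotations, and unique
# k-mers (k >= 6) so that peptide reads map unambiguously.
TRIF_SYNTH <- paste0(
  "SELVMQKMHCAKVRNNGICRYDSWMHYQHIVSNYYLHPYIAWCNYIPRWSNQQ",
  "PLIIHHAQM", "VQLG",
  "TREFGYCGIKSPELNVASYSSHPEMGVTSCGKPPATNLPSYIHNIT")

#' Synthetic TRIF-like RHIM construct
#'
#' A 112-residue synthetic stand-in for the C-terminal RHIM-containing
#' construct (full-length positions 601-712) used as the default parent
#' protein of [simulate_digest()].  It places the VQLG core tetrad at
#' positions 663-666 with the amyloidogenic nonapeptide PLIIHHAQM at
#' 654-662; the remaining residues are arbitrary and every substring of
#' length >= 6 is unique, so peptide reads map unambiguously.  The same
#' sequence ships as `inst/extdata/trif_rhim_synthetic.fasta`.
#'
#' @return A [protein_sequence()] with offset 601.
#' @examples
#' trif_rhim_synthetic()
#' @export
trif_rhim_synthetic <- function() protein_sequence(TRIF_SYNTH, offset = 601L)

#' Tetrad interval of the synthetic TRIF-like construct
#' @return Integer `c(start, end)` = `c(663, 666)` (the VQLG motif).
#' @export
trif_tetrad <- function() c(start = 663L, end = 666L)

#' Configuration for a synthetic protease-protection digest
#'
#' @param protein A [protein_sequence()] (or plain residue string, taken
#'   with `offset`); defaults to [trif_rhim_synthetic()].
#' @param offset Used only when `protein` is a plain string.
#' @param core_start,core_end Full-length endpoints (inclusive) of the
#'   protected core the digest should encode; defaults 654 and 709.
#' @param core_prevalence Target fraction of reads fully covering the
#'   core, in `[0, 1]`.
#' @param n_reads Number of peptide reads to emit.
#' @param length_range Integer `c(min, max)` peptide length.
#' @param decay_per_residue Per-residue multiplicative drop in coverage
#'   probability outside the core: the chance that a core-spanning read
#'   extends `k` residues past a core boundary is `(1 -
#'   decay_per_residue)^k`.  Zero means extensions are limited only by the
#'   construct bounds and `length_range`.
#' @param oxidation_fraction Fraction of methionines, per read, that carry
#'   an oxidation annotation (the only modification expected from
#'   electrospray ionisation).
#' @param tetrad_start,tetrad_end Full-length tetrad interval the
#'   generator anchors every read on; `NULL` uses [trif_tetrad()] when the
#'   default protein is used, otherwise the centred 4-mer of the core.
#' @param seed Integer seed; the digest is deterministic under it.
#' @return An object of class `digest_config`.
#' @export
digest_config <- function(protein = trif_rhim_synthetic(), offset = 601L,
                          core_start = 654L, core_end = 709L,
                          core_prevalence = 0.7, n_reads = 200L,
                          length_range = c(8L, 90L),
                          decay_per_residue = 0.2,
                          oxidation_fraction = 0.1,
                          tetrad_start = NULL, tetrad_end = NULL,
                          seed = NULL) {
  if (is.character(protein)) protein <- protein_sequence(protein, offset)
  if (!inherits(protein, "protein_sequence"))
    stop("`protein` must be a protein_sequence or residue string", call. = FALSE)
  core_start <- as.integer(core_start); core_end <- as.integer(core_end)
  if (core_start > core_end || core_start < protein$start ||
      core_end > protein$end)
    stop("core interval must lie within the protein span", call. = FALSE)
  if (core_prevalence < 0 || core_prevalence > 1)
    stop("`core_prevalence` must be in [0, 1]", call. = FALSE)
  if (!is.numeric(n_reads) || n_reads < 1)
    stop("`n_reads` must be positive", call. = FALSE)
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1] < 1L ||
      length_range[1] > length_range[2])
    stop("`length_range` must be c(min, max) with 1 <= min <= max", call. = FALSE)
  core_len <- core_end - core_start + 1L
  if (core_prevalence > 0 && core_len > length_range[2])
    stop("core longer than the maximum peptide length", call. = FALSE)
  if (decay_per_residue < 0 || decay_per_residue > 1)
    stop("`decay_per_residue` must be in [0, 1]", call. = FALSE)
  if (oxidation_fraction < 0 || oxidation_fraction > 1)
    stop("`oxidation_fraction` must be in [0, 1]", call. = FALSE)
  if (is.null(tetrad_start) || is.null(tetrad_end)) {
    if (identical(protein$residues, TRIF_SYNTH) && protein$offset == 601L &&
        core_start <= 663L && core_end >= 666L) {
      tet <- trif_tetrad()
    } else {
      mid <- core_start + (core_len - 4L) %/% 2L
      tet <- c(mid, min(mid + 3L, core_end))
    }
  } else {
    tet <- as.integer(c(tetrad_start, tetrad_end))
  }
  if (tet[1] < core_start || tet[2] > core_end || tet[1] > tet[2])
    stop("tetrad must lie within the core interval", call. = FALSE)
  if (core_prevalence < 1) {
    if (length_range[1] > core_len - 1L)
      stop("minimum peptide length too large for partial (non-core) reads",
           call. = FALSE)
    if (tet[1] <= core_start || tet[2] >= core_end)
      stop("tetrad must lie strictly inside the core when partial reads are requested",
           call. = FALSE)
  }
  structure(
    list(protein = protein, core_start = core_start, core_end = core_end,
         core_prevalence = core_prevalence, n_reads = as.integer(n_reads),
         length_range = length_range, decay_per_residue = decay_per_residue,
         oxidation_fraction = oxidation_fraction,
         tetrad = c(start = tet[1], end = tet[2]),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "digest_config"
  )
}

# geometric flank extension: P(ext >= k) = (1 - decay)^k; decay 0 -> Inf
draw_extension <- function(n, decay) {
  if (decay >= 1) return(rep(0L, n))
  if (decay == 0) return(rep(Inf, n))
  rgeom(n, prob = decay)
}

#' Simulate a limited-proteolysis peptide digest
#'
#' Emits `n_reads` peptides, each an exact substring of the parent protein
#' containing the whole core tetrad.  Exactly
#' `round(core_prevalence * n_reads)` reads span the full protected core,
#' extended past each core boundary by a geometric flank (`P(ext >= k) =
#' (1 - decay_per_residue)^k`, clamped to the construct bounds and the
#' maximum peptide length); the remaining reads start and end strictly
#' inside the core, so they contain the tetrad but not the full core.
#' Per-read methionines carry an `ox` annotation with probability
#' `oxidation_fraction`.  Deterministic under the config seed.
#'
#' @param config A [digest_config()].
#' @return A data frame with one row per read: `peptide`, `count` (always
#'   1), `modifications` (semicolon-separated `pos:ox` tokens,
#'   position-in-peptide), plus ground-truth columns `start`, `end`
#'   (full-length interval) and `covers_core`.  The config is attached as
#'   attribute `"config"`.
#' @examples
#' d <- simulate_digest(digest_config(n_reads = 50, seed = 1))
#' head(d)
#' mean(d$covers_core)
#' @export
simulate_digest <- function(config) {
  if (!inherits(config, "digest_config"))
    stop("`config` must be a digest_config", call. = FALSE)
  p <- config$protein
  min_len <- config$length_range[1]; max_len <- config$length_range[2]
  tet <- config$tetrad
  n_core <- round(config$core_prevalence * config$n_reads)
  n_part <- config$n_reads - n_core

  with_sim_seed(config$seed, {
    starts <- integer(0); ends <- integer(0); covers <- logical(0)

    if (n_core > 0L) {
      extL <- draw_extension(n_core, config$decay_per_residue)
      extR <- draw_extension(n_core, config$decay_per_residue)
      s <- pmax(p$start, config$core_start - extL)
      e <- pmin(p$end, config$core_end + extR)
      # trim symmetric flank overshoot beyond the maximum peptide length,
      # never shrinking below the core itself
      for (i in seq_len(n_core)) {
        over <- (e[i] - s[i] + 1L) - max_len
        while (over > 0L) {
          left_flank <- config$core_start - s[i]
          right_flank <- e[i] - config$core_end
          if (right_flank >= left_flank) e[i] <- e[i] - 1L else s[i] <- s[i] + 1L
          over <- over - 1L
        }
        # pad to the minimum length if the bare core is shorter
        while (e[i] - s[i] + 1L < min_len) {
          if (e[i] < p$end) e[i] <- e[i] + 1L
          else if (s[i] > p$start) s[i] <- s[i] - 1L
          else break
        }
      }
      starts <- c(starts, s); ends <- c(ends, e)
      covers <- c(covers, rep(TRUE, n_core))
    }

    if (n_part > 0L) {
      # strictly inside the core on both sides, always containing the tetrad
      lo_s <- config$core_start + 1L; hi_s <- tet[1]
      lo_e <- tet[2]; hi_e <- config$core_end - 1L
      s <- lo_s + floor(runif(n_part) * (hi_s - lo_s + 1L))
      e <- lo_e + floor(runif(n_part) * (hi_e - lo_e + 1L))
      for (i in seq_len(n_part)) {
        while (e[i] - s[i] + 1L < min_len) {
          if (e[i] < hi_e) e[i] <- e[i] + 1L
          else if (s[i] > lo_s) s[i] <- s[i] - 1L
          else break
        }
        while (e[i] - s[i] + 1L > max_len) {
          if (e[i] > lo_e) e[i] <- e[i] - 1L else s[i] <- s[i] + 1L
        }
      }
      starts <- c(starts, s); ends <- c(ends, e)
      covers <- c(covers, rep(FALSE, n_part))
    }

    starts <- as.integer(starts); ends <- as.integer(ends)
    loc_s <- starts - p$offset + 1L
    loc_e <- ends - p$offset + 1L
    peptide <- substring(p$residues, loc_s, loc_e)

    mods <- character(length(peptide))
    for (i in seq_along(peptide)) {
      mpos <- which(strsplit(peptide[i], "")[[1]] == "M")
      if (length(mpos)) {
        flag <- runif(length(mpos)) < config$oxidation_fraction
        if (any(flag))
          mods[i] <- paste(sprintf("%d:ox", mpos[flag]), collapse = ";")
      }
    }

    out <- data.frame(peptide = peptide, count = 1L, modifications = mods,
                      start = starts, end = ends, covers_core = covers,
                      stringsAsFactors = FALSE)
    attr(out, "config") <- config
    out
  })
}
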