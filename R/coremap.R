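# Mapping limited-proteolysis peptide reads onto a parent protein.
#
# Amyloid fibrils digested with a non-specific protease retain an
# insoluble, protease-resistant core; LC-MS of the residual peptides
# reports which residues were protected.  Mapping each peptide read back
# onto the parent sequence gives a per-residue prevalence profile, and the
# protected core is the contiguous run of high-prevalence residues that
# contains the motif's core tetrad.
#
# Coordinates are 1-based, inclusive, numbered on the full-length protein
# via the construct offset (e.g. a 112-residue construct spanning residues
# 601-712 has offset 601).

# 20 standard residues plus the IUPAC ambiguity and rare codes (B, Z, X,
# U, O, J), as accepted by common sequence toolkits.
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYBZXUOJ", "")[[1]]

#' A protein construct with full-length numbering
#'
#' @param residues One-letter amino-acid string (standard 20-letter
#'   alphabet; IUPAC ambiguity codes are tolerated).
#' @param offset Full-length-protein position of the first residue
#'   (1-based).
#' @return An object of class `protein_sequence` with fields `residues`,
#'   `offset`, `start`, `end` (full-length span).
#' @export
protein_sequence <- function(residues, offset = 1L) {
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues))
    stop("`residues` must be a single non-empty string", call. = FALSE)
  residues <- toupper(residues)
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), AA_ALPHABET)
  if (length(bad))
    stop("invalid residue letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset < 1)
    stop("`offset` must be a single integer >= 1", call. = FALSE)
  offset <- as.integer(offset)
  structure(
    list(residues = residues, offset = offset,
         start = offset, end = offset + nchar(residues) - 1L),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %d residues, positions %d-%d\n",
              nchar(x$residues), x$start, x$end))
  invisible(x)
}

#' Locate a peptide read on the parent protein
#'
#' The read must occur as an exact substring of the construct sequence
#' exactly once.  Modifications must already be stripped (see
#' [read_peptides()], which strips bracketed annotations such as
#' `M[ox]`).
#'
#' @param read Peptide sequence (one-letter string), or a one-row entry
#'   with a `peptide` field.
#' @param protein A [protein_sequence()].
#' @return Integer vector `c(start, end)`: the 1-based inclusive
#'   full-length interval.
#' @section Errors: a read not found in the protein raises a condition of
#'   class `coinspec_unmapped`; a read matching at more than one position
#'   raises `coinspec_ambiguous`.  Both inherit from `error`.
#' @examples
#' p <- protein_sequence("ACDEFGH", offset = 601)
#' map_read("DEF", p)  # c(start = 603, end = 605)
#' @export
map_read <- function(read, protein) {
  if (is.list(read) || is.data.frame(read)) read <- read$peptide
  if (!is.character(read) || length(read) != 1L || !nzchar(read))
    stop("`read` must be a single non-empty peptide string", call. = FALSE)
  if (!inherits(protein, "protein_sequence"))
    stop("`protein` must be a protein_sequence", call. = FALSE)
  # sliding exact match; finds overlapping occurrences, unlike gregexpr
  m <- nchar(read)
  n <- nchar(protein$residues)
  hits <- if (m > n) integer(0) else
    which(substring(protein$residues, 1:(n - m + 1L), m:n) == read)
  if (length(hits) == 0L)
    stop(structure(
      class = c("coinspec_unmapped", "error", "condition"),
      list(message = sprintf("read '%s' not found in protein", read),
           call = NULL)))
  if (length(hits) > 1L)
    stop(structure(
      class = c("coinspec_ambiguous", "error", "condition"),
      list(message = sprintf("read '%s' matches protein at %d positions",
                             read, length(hits)),
           call = NULL)))
  start <- as.integer(hits) + protein$offset - 1L
  c(start = start, end = start + nchar(read) - 1L)
}

#' Per-residue prevalence profile of a peptide digest
#'
#' Maps every read onto the protein and computes, for each residue
#' position, the fraction of mapped reads (weighted by spectral count, or
#' unweighted over unique peptides) whose interval covers that position.
#' Unmapped and ambiguously mapping reads are excluded and reported via a
#' warning and the `excluded` field.
#'
#' @param reads Data frame with columns `peptide` and optionally `count`
#'   (default 1 per row); as produced by [simulate_digest()] or
#'   [read_peptides()].
#' @param protein A [protein_sequence()].
#' @param tetrad Integer `c(start, end)`: full-length interval of the
#'   core tetrad (e.g. the VQLG motif), used for `tetrad_prevalence` and
#'   later by [delineate_core()].
#' @param weight `"count"` weights each peptide by its read count;
#'   `"unique"` counts each distinct peptide sequence once.
#' @return An object of class `protection_profile`: `positions`
#'   (full-length), `residues`, `prevalence` (in `[0, 1]`),
#'   `tetrad_interval`, `tetrad_prevalence` (weighted fraction of mapped
#'   reads containing the whole tetrad), `n_mapped` / `n_excluded`
#'   (weighted totals), `excluded` (data frame with a `reason` column) and
#'   `core_interval` (`NULL` until [delineate_core()] is applied).
#' @export
build_profile <- function(reads, protein, tetrad,
                          weight = c("count", "unique")) {
  weight <- m_weight <- match.arg(weight)
  if (!is.data.frame(reads) || !"peptide" %in% names(reads))
    stop("`reads` must be a data frame with a `peptide` column", call. = FALSE)
  if (!inherits(protein, "protein_sequence"))
    stop("`protein` must be a protein_sequence", call. = FALSE)
  tetrad <- as.integer(tetrad)
  if (length(tetrad) != 2L || anyNA(tetrad) || tetrad[1] > tetrad[2] ||
      tetrad[1] < protein$start || tetrad[2] > protein$end)
    stop("`tetrad` must be an interval within the protein span", call. = FALSE)

  counts <- if ("count" %in% names(reads)) as.numeric(reads$count) else
    rep(1, nrow(reads))
  if (anyNA(counts) || any(counts < 1))
    stop("`count` values must be >= 1", call. = FALSE)
  if (weight == "unique") {
    # one vote per distinct peptide sequence
    keep <- !duplicated(reads$peptide)
    reads <- reads[keep, , drop = FALSE]
    counts <- rep(1, nrow(reads))
  }

  n_res <- nchar(protein$residues)
  cov <- numeric(n_res)
  tetrad_w <- 0
  mapped_w <- 0
  excl_pep <- character(0); excl_cnt <- numeric(0); excl_reason <- character(0)
  for (i in seq_len(nrow(reads))) {
    iv <- tryCatch(map_read(reads$peptide[i], protein), error = identity)
    if (inherits(iv, "condition")) {
      reason <- if (inherits(iv, "coinspec_ambiguous")) "ambiguous" else "unmapped"
      excl_pep <- c(excl_pep, reads$peptide[i])
      excl_cnt <- c(excl_cnt, counts[i])
      excl_reason <- c(excl_reason, reason)
      next
    }
    loc <- iv - protein$offset + 1L
    cov[loc[1]:loc[2]] <- cov[loc[1]:loc[2]] + counts[i]
    if (iv[1] <= tetrad[1] && iv[2] >= tetrad[2]) tetrad_w <- tetrad_w + counts[i]
    mapped_w <- mapped_w + counts[i]
  }
  if (mapped_w == 0)
    stop("no read could be mapped onto the protein", call. = FALSE)
  if (length(excl_pep))
    warning(sprintf("%d read(s) excluded (%s)", length(excl_pep),
                    paste(unique(excl_reason), collapse = ", ")),
            call. = FALSE)

  structure(
    list(positions = protein$start:protein$end,
         residues = strsplit(protein$residues, "")[[1]],
         prevalence = cov / mapped_w,
         tetrad_interval = tetrad,
         tetrad_prevalence = tetrad_w / mapped_w,
         n_mapped = mapped_w,
         n_excluded = sum(excl_cnt),
         excluded = data.frame(peptide = excl_pep, count = excl_cnt,
                               reason = excl_reason, stringsAsFactors = FALSE),
         weight = m_weight,
         core_interval = NULL),
    class = "protection_profile"
  )
}

#' Delineate the protease-protected core
#'
#' Returns the maximal contiguous run of residue positions whose
#' prevalence is at least `threshold` and which contains the whole core
#' tetrad, or `NULL` when no such run reaches the threshold.  The default
#' threshold of 0.7 marks residues conserved in at least 70% of peptide
#' reads.
#'
#' @param profile A `protection_profile` from [build_profile()].
#' @param threshold Prevalence threshold in `(0, 1]`.
#' @return Integer `c(start, end)` in full-length numbering, or `NULL`.
#' @export
delineate_core <- function(profile, threshold = 0.7) {
  if (!inherits(profile, "protection_profile"))
    stop("`profile` must be a protection_profile", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold <= 0 || threshold > 1)
    stop("`threshold` must be in (0, 1]", call. = FALSE)
  ok <- profile$prevalence >= threshold
  t_loc <- match(profile$tetrad_interval, profile$positions)
  if (anyNA(t_loc)) stop("tetrad lies outside the profile", call. = FALSE)
  if (!all(ok[t_loc[1]:t_loc[2]])) return(NULL)
  lo <- t_loc[1]
  while (lo > 1L && ok[lo - 1L]) lo <- lo - 1L
  hi <- t_loc[2]
  while (hi < length(ok) && ok[hi + 1L]) hi <- hi + 1L
  c(start = profile$positions[lo], end = profile$positions[hi])
}

#' @export
print.protection_profile <- function(x, ...) {
  cat(sprintf("<protection_profile> positions %d-%d, %s mapped reads (%s weighting)\n",
              min(x$positions), max(x$positions),
              format(x$n_mapped), x$weight))
  cat(sprintf("  tetrad %d-%d prevalence: %.3f\n",
              x$tetrad_interval[1], x$tetrad_interval[2], x$tetrad_prevalence))
  if (!is.null(x$core_interval))
    cat(sprintf("  protected core: %d-%d\n",
                x$core_interval[1], x$core_interval[2]))
  if (x$n_excluded > 0)
    cat(sprintf("  excluded reads (weighted): %s\n", format(x$n_excluded)))
  invisible(x)
}
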