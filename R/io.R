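# Plain-text interchange formats.  Every stage reads and writes
# inspectable tabular text:
#   trace        TSV: bin_index, green_counts, red_counts (header line)
#   ground truth TSV: apex_bin, species, is_dual
#   peaks        CSV: channel, start_bin, end_bin, apex_bin,
#                     max_intensity, integrated_photons
#   peptides     CSV: peptide, count, modifications
#   profile      TSV: position, residue, prevalence
#   PCH          CSV: bin_low, bin_high, count

#' Write / read a dual-channel time trace
#'
#' Tab-separated, three columns (`bin_index`, `green_counts`,
#' `red_counts`) with a header line.  Ground truth, when present, goes to
#' a sidecar table `<path>.truth.tsv` (`apex_bin`, `species`, `is_dual`).
#'
#' @param trace A [time_trace()].
#' @param path Output file; the sidecar name is derived from it.
#' @param bin_ms Bin width to attach on reading.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a [time_trace()] (with ground truth if the sidecar exists).
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(bin_index = seq_along(trace$green),
                   green_counts = trace$green, red_counts = trace$red)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(trace$ground_truth)) {
    gt <- trace$ground_truth[, c("apex_bin", "species", "is_dual")]
    write.table(gt, truth_path(path), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

truth_path <- function(path) paste0(sub("\\.tsv$", "", path), ".truth.tsv")

#' @rdname write_trace
#' @export
read_trace <- function(path, bin_ms = 1) {
  df <- read.table(path, header = TRUE, sep = "\t")
  need <- c("bin_index", "green_counts", "red_counts")
  if (!all(need %in% names(df)))
    stop("trace file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("trace file is empty", call. = FALSE)
  gt <- NULL
  tp <- truth_path(path)
  if (file.exists(tp)) {
    gt <- read.table(tp, header = TRUE, sep = "\t",
                     colClasses = c("integer", "character", "logical"))
    gt <- gt[, c("species", "apex_bin", "is_dual")]
  }
  time_trace(df$green_counts, df$red_counts, bin_ms = bin_ms,
             ground_truth = gt)
}

#' Write / read a detected-peak table
#' @param peaks Peak data frame from [detect_peaks()] (or several
#'   channels' tables row-bound).
#' @param path CSV file.
#' @return `write_peaks()` returns `path` invisibly; `read_peaks()` the
#'   data frame.
#' @export
write_peaks <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks
#' @export
read_peaks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel", "start_bin", "end_bin", "apex_bin",
            "max_intensity", "integrated_photons")
  if (!all(need %in% names(df)))
    stop("peaks file must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Read a single-record protein FASTA
#'
#' @param path FASTA file with exactly one record.
#' @param offset Full-length position of the first residue (the construct
#'   offset is metadata the FASTA itself does not carry).
#' @return A [protein_sequence()].
#' @export
read_protein_fasta <- function(path, offset = 1L) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) != 1L)
    stop("expected exactly one FASTA record, found ", length(aa),
         call. = FALSE)
  protein_sequence(as.character(aa[[1]]), offset = offset)
}

# Strip bracketed inline modifications ("M[ox]") from a peptide string,
# returning the bare sequence and "pos:name" tokens.
strip_inline_mods <- function(x) {
  mods <- character(0)
  repeat {
    m <- regexpr("\\[([^]]*)\\]", x)
    if (m == -1L) break
    pos <- as.integer(m) - 1L  # residue preceding the bracket
    name <- substr(x, m + 1L, m + attr(m, "match.length") - 2L)
    mods <- c(mods, sprintf("%d:%s", pos, name))
    x <- paste0(substr(x, 1L, m - 1L),
                substr(x, m + attr(m, "match.length"), nchar(x)))
  }
  list(sequence = x, modifications = paste(mods, collapse = ";"))
}

#' Read a peptide-read CSV
#'
#' Columns: `peptide` (required), `count` (optional, default 1),
#' `modifications` (optional; semicolon-separated `pos:name` tokens with
#' `pos` the 1-based position in the peptide).  Inline bracket
#' annotations in the peptide column (e.g. `AM[ox]K` for an oxidised
#' methionine) are stripped into the modification list, matching the only
#' modification class expected from electrospray ionisation.
#'
#' @param path CSV file.
#' @return Data frame with columns `peptide`, `count`, `modifications`.
#' @export
read_peptides <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(peptide = "character"))
  if (!"peptide" %in% names(df))
    stop("peptides file must have a `peptide` column", call. = FALSE)
  if (!"count" %in% names(df)) df$count <- 1L
  if (!"modifications" %in% names(df)) df$modifications <- ""
  df$modifications[is.na(df$modifications)] <- ""
  stripped <- lapply(df$peptide, strip_inline_mods)
  inline <- vapply(stripped, `[[`, "", "modifications")
  df$peptide <- vapply(stripped, `[[`, "", "sequence")
  has_both <- nzchar(df$modifications) & nzchar(inline)
  df$modifications <- ifelse(nzchar(inline),
                             ifelse(has_both,
                                    paste(df$modifications, inline, sep = ";"),
                                    inline),
                             df$modifications)
  df[, c("peptide", "count", "modifications")]
}

#' Write a peptide-read table as CSV
#' @param reads Data frame with at least `peptide`; `count` and
#'   `modifications` are filled with defaults when absent.  Ground-truth
#'   columns from [simulate_digest()] are not written.
#' @param path CSV file.
#' @export
write_peptides <- function(reads, path) {
  if (!"count" %in% names(reads)) reads$count <- 1L
  if (!"modifications" %in% names(reads)) reads$modifications <- ""
  write.csv(reads[, c("peptide", "count", "modifications")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a protection profile as TSV
#'
#' Columns `position`, `residue`, `prevalence`; one row per construct
#' residue in full-length numbering.
#'
#' @param profile A `protection_profile`.
#' @param path TSV file.
#' @export
write_profile <- function(profile, path) {
  df <- data.frame(position = profile$positions, residue = profile$residues,
                   prevalence = profile$prevalence)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a photon-counting histogram as CSV
#' @param pch A `pch` object.
#' @param path CSV file with columns `bin_low`, `bin_high`, `count`.
#' @export
write_pch <- function(pch, path) {
  df <- data.frame(bin_low = head(pch$bin_edges, -1),
                   bin_high = tail(pch$bin_edges, -1),
                   count = pch$counts)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
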