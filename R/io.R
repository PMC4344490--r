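provenance_line <- function(seed = NULL, params = NULL) {
  bits <- c(
    sprintf("tractpm %s", as.character(utils::packageVersion("tractpm"))),
    sprintf("seed=%s", if (is.null(seed)) "NA" else as.character(seed)),
    params
  )
  paste0("# ", paste(bits, collapse = " | "))
}

write_with_provenance <- function(df, path, delim, seed = NULL, params = NULL) {
  body <- readr::format_delim(df, delim = delim)
  writeLines(c(paste0(provenance_line(seed, params), "\n"), body), path, sep = "")
  invisible(path)
}

#' Read and write probe tables
#'
#' Probe tables are TSV files with header columns `probe_id`, `sequence`,
#' `signal`. Lines starting with `#` (the provenance header written by
#' [write_probes()]) are skipped on read.
#'
#' @param path File path.
#' @return `read_probes()` returns a tibble with the three probe columns
#'   (plus any extra columns present).
#' @export
read_probes <- function(path) {
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  required_cols(df, c("probe_id", "sequence", "signal"), "read_probes()")
  df
}

#' @rdname read_probes
#' @param probes Probe data frame to write.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_probes <- function(probes, path, seed = NULL) {
  required_cols(probes, c("probe_id", "sequence", "signal"), "write_probes()")
  write_with_provenance(probes, path, "\t", seed = seed)
}

#' Read sequences from FASTA
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequence case is preserved. `read_aligned_fasta()` additionally enforces
#' that all records have equal length, naming the offending record
#' otherwise, and returns a table ready for the alignment functions.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `seq_id`, `sequence` (or `aligned_seq` for
#'   the aligned reader).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(sprintf("No sequences found in '%s'.", path))
  ids <- stringr::str_split_i(names(set), "\\s+", 1)
  tibble::tibble(seq_id = ids, sequence = unname(as.character(set)))
}

#' @rdname read_fasta
#' @export
read_aligned_fasta <- function(path) {
  df <- read_fasta(path)
  names(df)[names(df) == "sequence"] <- "aligned_seq"
  validate_msa(df, "read_aligned_fasta()")
}

#' @rdname read_fasta
#' @param seqs Data frame with `seq_id` and `sequence` (or `aligned_seq`).
#' @export
write_fasta <- function(seqs, path) {
  seqs <- tibble::as_tibble(seqs)
  seq_col <- intersect(c("sequence", "aligned_seq"), names(seqs))[1]
  if (is.na(seq_col)) abort("write_fasta() needs a `sequence` or `aligned_seq` column.")
  required_cols(seqs, "seq_id", "write_fasta()")
  set <- Biostrings::BStringSet(setNames(seqs[[seq_col]], seqs$seq_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read and write bead trajectories
#'
#' Trajectories are CSV files with header columns `t` (seconds), `x`, `y`
#' (nm) and optionally `bead_id` for multi-bead files; `#` comment lines
#' are skipped. On read, the frame interval of each bead is checked for
#' uniformity: steps deviating more than 1% from the median step are an
#' error, and rows with missing or non-finite values are reported with
#' their line numbers.
#'
#' @param path CSV file path.
#' @return A trajectory tibble (`bead_id`, `t`, `x`, `y`) suitable for
#'   [tpm_qc()] and [tpm_rms()].
#' @export
read_trajectories <- function(path) {
  raw <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  required_cols(raw, c("t", "x", "y"), "read_trajectories()")
  bad <- which(!is.finite(raw$t) | !is.finite(raw$x) | !is.finite(raw$y))
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite trajectory values at data row(s): %s.",
                  paste(bad, collapse = ", ")))
  }
  if (!"bead_id" %in% names(raw)) raw$bead_id <- "bead1"
  beads <- split_beads(raw, "read_trajectories()")
  purrr::walk(beads, function(b) infer_dt(b, NULL, "read_trajectories()"))
  dplyr::select(raw, "bead_id", "t", "x", "y")
}

#' @rdname read_trajectories
#' @param traj Trajectory data frame to write.
#' @param seed Optional seed recorded in the provenance header.
#' @export
write_trajectories <- function(traj, path, seed = NULL) {
  required_cols(traj, c("t", "x", "y"), "write_trajectories()")
  write_with_provenance(traj, path, ",", seed = seed)
}

#' @rdname read_probes
#' @param df Data frame (e.g. feature rows, bin summaries, QC or RMS
#'   tables) to write as TSV with a provenance header.
#' @export
write_tsv_provenance <- function(df, path, seed = NULL) {
  write_with_provenance(tibble::as_tibble(df), path, "\t", seed = seed)
}
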