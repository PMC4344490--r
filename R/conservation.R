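#' Pairwise identity of two aligned sequences
#'
#' Identity is the number of matching residues divided by the number of
#' comparable columns, where a column is comparable when at least one of the
#' two sequences has a residue there. Columns gapped in both sequences are
#' ignored; a one-sided gap counts as a mismatch. Comparison is
#' case-insensitive.
#'
#' @param a,b Aligned sequences (equal-length strings over the residue
#'   alphabet plus `-`).
#' @return Identity fraction in `[0, 1]`.
#' @examples
#' pairwise_identity("AR-K", "AK-K")
#' @export
pairwise_identity <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("Aligned sequences must have equal length.")
  }
  ca <- toupper(strsplit(a, "", fixed = TRUE)[[1]])
  cb <- toupper(strsplit(b, "", fixed = TRUE)[[1]])
  comparable <- !(ca == "-" & cb == "-")
  if (!any(comparable)) {
    abort("No comparable columns: both sequences are all-gap.")
  }
  matches <- comparable & ca == cb
  sum(matches) / sum(comparable)
}

validate_msa <- function(msa, where = "msa") {
  msa <- tibble::as_tibble(msa)
  required_cols(msa, c("seq_id", "aligned_seq"), where)
  if (nrow(msa) == 0L) abort("Alignment is empty.")
  if (anyDuplicated(msa$seq_id)) abort("`seq_id` values must be unique.")
  len <- nchar(msa$aligned_seq)
  if (length(unique(len)) != 1L) {
    bad <- msa$seq_id[len != len[1]][1]
    abort(sprintf("Alignment is ragged: record '%s' has length %d, expected %d.",
                  bad, nchar(msa$aligned_seq[msa$seq_id == bad][1]), len[1]))
  }
  msa
}

msa_matrix <- function(msa) {
  m <- matrix(toupper(unlist(strsplit(msa$aligned_seq, "", fixed = TRUE))),
              nrow = nrow(msa), byrow = TRUE)
  rownames(m) <- msa$seq_id
  m
}

#' Remove near-identical alignment entries
#'
#' Greedy dereplication: entries are scanned in input order and an entry is
#' dropped when its [pairwise_identity()] to any already-retained entry is
#' `>=` the threshold. The reference entry, when given, is scanned first and
#' therefore always retained — mirroring the removal of redundant
#' same-species homologues before consensus building so they do not bias
#' conservation scores. The greedy-in-order rule makes the result
#' deterministic; it is also idempotent.
#'
#' @param msa Data frame with columns `seq_id`, `aligned_seq`.
#' @param threshold Identity at or above which an entry is considered
#'   redundant; must be in `(0, 1]`. Default 0.99.
#' @param ref_id Optional identifier of the protected reference entry.
#' @return The retained rows, in original input order.
#' @export
dereplicate <- function(msa, threshold = 0.99, ref_id = NULL) {
  msa <- validate_msa(msa, "dereplicate()")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  n <- nrow(msa)
  order_idx <- seq_len(n)
  if (!is.null(ref_id)) {
    ref_pos <- match(ref_id, msa$seq_id)
    if (is.na(ref_pos)) abort(sprintf("Reference '%s' not found in alignment.", ref_id))
    order_idx <- c(ref_pos, setdiff(order_idx, ref_pos))
  }
  retained <- integer(0)
  for (i in order_idx) {
    redundant <- any(purrr::map_lgl(retained, function(j) {
      pairwise_identity(msa$aligned_seq[i], msa$aligned_seq[j]) >= threshold
    }))
    if (!redundant) retained <- c(retained, i)
  }
  msa[sort(retained), ]
}

#' Consensus sequence and per-column conservation profile
#'
#' For each alignment column: the consensus symbol is the most frequent
#' non-gap residue (ties broken toward the lexicographically smaller
#' residue), except that a gap is emitted when more than half the entries
#' are gapped. Conservation is the fraction of *all* entries carrying the
#' most frequent non-gap residue — gaps count as mismatches — so
#' `conservation <= 1 - gap_fraction` always holds.
#'
#' @inheritParams dereplicate
#' @return A tibble of class `conservation_profile` with columns `column`,
#'   `consensus`, `conservation`, `gap_fraction`.
#' @examples
#' msa <- tibble::tibble(seq_id = c("a", "b", "c", "d"),
#'                       aligned_seq = c("RK", "RK", "RK", "KK"))
#' consensus_profile(msa)
#' @export
consensus_profile <- function(msa) {
  msa <- validate_msa(msa, "consensus_profile()")
  m <- msa_matrix(msa)
  n <- nrow(m)
  cols <- purrr::map(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    gap_fraction <- sum(col == "-") / n
    residues <- col[col != "-"]
    if (length(residues) == 0L) {
      return(tibble::tibble(column = j, consensus = "-", conservation = 0,
                            gap_fraction = gap_fraction))
    }
    tab <- table(residues)
    top <- sort(names(tab)[tab == max(tab)])[1]  # lexicographic tie-break
    tibble::tibble(
      column = j,
      consensus = if (gap_fraction > 0.5) "-" else top,
      conservation = as.numeric(tab[top]) / n,
      gap_fraction = gap_fraction
    )
  })
  out <- dplyr::bind_rows(cols)
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Map a reference residue position to an alignment column
#'
#' Residue positions in the literature are numbered on the ungapped
#' reference sequence (e.g. "R116"); this returns the 1-based alignment
#' column holding that residue.
#'
#' @inheritParams dereplicate
#' @param ref_id Identifier of the reference entry.
#' @param ungapped_pos 1-based position in the ungapped reference sequence.
#' @return 1-based alignment column index.
#' @examples
#' msa <- tibble::tibble(seq_id = "ref", aligned_seq = "A-RG")
#' map_position(msa, "ref", 2)  # the R lands in column 3
#' @export
map_position <- function(msa, ref_id, ungapped_pos) {
  msa <- validate_msa(msa, "map_position()")
  ref <- msa$aligned_seq[match(ref_id, msa$seq_id)]
  if (is.na(ref)) abort(sprintf("Reference '%s' not found in alignment.", ref_id))
  chars <- strsplit(ref, "", fixed = TRUE)[[1]]
  non_gap <- which(chars != "-")
  ungapped_pos <- as.integer(ungapped_pos)
  if (ungapped_pos < 1L || ungapped_pos > length(non_gap)) {
    abort(sprintf("Position %d is outside the ungapped reference (length %d).",
                  ungapped_pos, length(non_gap)))
  }
  non_gap[ungapped_pos]
}

#' Conservation of a reference residue across homologues
#'
#' Fraction of non-reference entries whose residue at the alignment column
#' of the given reference position equals the reference residue (gaps count
#' as mismatches). This is the statistic behind statements such as "this
#' arginine is conserved in 81% of homologues".
#'
#' @inheritParams map_position
#' @return Conservation fraction in `[0, 1]`.
#' @export
residue_conservation <- function(msa, ref_id, ungapped_pos) {
  msa <- validate_msa(msa, "residue_conservation()")
  col <- map_position(msa, ref_id, ungapped_pos)
  m <- msa_matrix(msa)
  ref_row <- match(ref_id, msa$seq_id)
  others <- m[-ref_row, col]
  if (length(others) == 0L) {
    abort("Alignment has no non-reference entries.")
  }
  sum(others == m[ref_row, col]) / length(others)
}
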