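#' Generate a synthetic probe set with a planted AT-tract preference
#'
#' Emulates a ChIP-microarray probe table in which the binding signal peaks
#' at a particular AT-tract length. Each probe is a random background
#' sequence of the given GC composition into which one contiguous A/T tract
#' of random length is written at a random position. The signal is a
#' deterministic Gaussian bump in the probe's *realised* longest AT run L
#' (background bases can extend a planted tract, so L >= the planted
#' length) plus Gaussian noise:
#'
#' `signal = baseline + effect_size * exp(-(L - L*)^2 / (2 * effect_width^2)) + N(0, noise_sd)`
#'
#' A bump rather than a plateau is planted because the emulated biology
#' shows an optimum tract length, not a monotone trend.
#'
#' @param n_probes Number of probes. Default 2000.
#' @param probe_length Probe length in bp. Default 60.
#' @param background_gc GC fraction of the background composition, in
#'   `(0, 1)`. Default 0.5.
#' @param tract_lengths Integer vector of candidate planted tract lengths,
#'   sampled uniformly. Default `2:12`.
#' @param optimal_tract Tract length `L*` at which the signal peaks.
#'   Default 6.
#' @param effect_size Height of the signal bump. Default 2.
#' @param effect_width Width (sd, in run-length units) of the bump.
#'   Default 0.75.
#' @param noise_sd Gaussian noise sd added to each signal. Default 0.5.
#' @param baseline Baseline signal. Default 1.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with columns `probe_id`, `sequence`, `signal`,
#'   `planted_tract` (the planted, not realised, tract length).
#' @examples
#' generate_probe_set(n_probes = 5, seed = 1)
#' @export
generate_probe_set <- function(n_probes = 2000, probe_length = 60,
                               background_gc = 0.5, tract_lengths = 2:12,
                               optimal_tract = 6, effect_size = 2,
                               effect_width = 0.75, noise_sd = 0.5,
                               baseline = 1, seed = NULL) {
  if (n_probes < 1L) abort("`n_probes` must be positive.")
  if (background_gc <= 0 || background_gc >= 1) {
    abort("`background_gc` must be strictly between 0 and 1.")
  }
  tract_lengths <- as.integer(tract_lengths)
  if (any(tract_lengths < 1L) || max(tract_lengths) > probe_length) {
    abort("Planted tract lengths must be in [1, probe_length].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (effect_width <= 0) abort("`effect_width` must be positive.")
  if (!is.null(seed)) set.seed(seed)

  base_prob <- c(A = (1 - background_gc) / 2, C = background_gc / 2,
                 G = background_gc / 2, T = (1 - background_gc) / 2)
  planted <- sample(tract_lengths, n_probes, replace = TRUE)
  sequences <- purrr::map_chr(seq_len(n_probes), function(i) {
    s <- sample(names(base_prob), probe_length, replace = TRUE, prob = base_prob)
    len <- planted[i]
    start <- sample.int(probe_length - len + 1L, 1L)
    s[start:(start + len - 1L)] <- sample(c("A", "T"), len, replace = TRUE)
    paste(s, collapse = "")
  })
  realised <- longest_at_run(sequences)
  signal <- baseline +
    effect_size * exp(-(realised - optimal_tract)^2 / (2 * effect_width^2)) +
    rnorm(n_probes, 0, noise_sd)
  tibble::tibble(
    probe_id = sprintf("probe%05d", seq_len(n_probes)),
    sequence = sequences,
    signal = signal,
    planted_tract = planted
  )
}

#' Generate a synthetic homologue alignment with planted conservation
#'
#' Emulates a BLAST-derived alignment of protein homologues: a reference
#' sequence first, followed by background rows, with chosen columns
#' carrying the reference residue in an exact fraction of the non-reference
#' rows. Conservation is planted by exact count — `round(fraction * (n-1))`
#' non-reference rows carry the residue, all others are guaranteed not to —
#' so [residue_conservation()] recovers the planted value exactly
#' (up to the rounding inherent in an integer count). Optional extra
#' gap-bearing columns are appended after the core columns (so planted
#' column indices are unaffected), and optional near-identical copies of
#' the reference emulate redundant same-species database hits for
#' [dereplicate()] to remove.
#'
#' @param n_sequences Number of rows including the reference. Default 500.
#' @param length Number of core alignment columns. Default 120.
#' @param planted Data frame with columns `column`, `residue`,
#'   `conservation` describing the planted positions.
#' @param n_gap_columns Extra columns appended in which each non-reference
#'   row is gapped with probability `gap_rate` (the reference keeps a
#'   residue). Default 0.
#' @param gap_rate Per-cell gap probability in the appended columns.
#'   Default 0.5.
#' @param n_duplicates Near-identical copies of the reference appended at
#'   the end (each differs at no more than 1% of columns, so pairwise
#'   identity to the reference is >= 0.99). Default 0.
#' @param ref_id Identifier of the reference row. Default `"ref"`.
#' @param seed Optional integer seed.
#' @return An alignment tibble with columns `seq_id`, `aligned_seq`; the
#'   reference row comes first.
#' @examples
#' msa <- generate_msa(n_sequences = 10, length = 30,
#'                     planted = tibble::tibble(column = 5, residue = "R",
#'                                              conservation = 0.8),
#'                     seed = 1)
#' residue_conservation(msa, "ref", 5)
#' @export
generate_msa <- function(n_sequences = 500, length = 120,
                         planted = NULL, n_gap_columns = 0, gap_rate = 0.5,
                         n_duplicates = 0, ref_id = "ref", seed = NULL) {
  if (n_sequences < 2L) abort("`n_sequences` must be at least 2.")
  if (length < 1L) abort("`length` must be positive.")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (!is.null(planted)) {
    required_cols(planted, c("column", "residue", "conservation"), "generate_msa()")
    if (any(planted$column < 1L | planted$column > length)) {
      abort("Planted columns must lie within `length`.")
    }
    if (any(planted$conservation < 0 | planted$conservation > 1)) {
      abort("Planted conservation fractions must be in [0, 1].")
    }
    if (anyDuplicated(planted$column)) abort("Planted columns must be unique.")
  }
  if (!is.null(seed)) set.seed(seed)

  n_bg <- n_sequences - 1L
  m <- matrix(sample(aa, n_sequences * length, replace = TRUE),
              nrow = n_sequences, ncol = length)
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      col <- planted$column[k]
      res <- toupper(planted$residue[k])
      m[1L, col] <- res
      carriers <- sample.int(n_bg, round(planted$conservation[k] * n_bg))
      m[1L + carriers, col] <- res
      non_carriers <- setdiff(seq_len(n_bg), carriers)
      if (length(non_carriers) > 0L) {
        m[1L + non_carriers, col] <- sample(setdiff(aa, res),
                                            length(non_carriers), replace = TRUE)
      }
    }
  }
  if (n_gap_columns > 0L) {
    extra <- matrix(sample(aa, n_sequences * n_gap_columns, replace = TRUE),
                    nrow = n_sequences)
    gap_mask <- matrix(runif(n_bg * n_gap_columns) < gap_rate, nrow = n_bg)
    extra[-1L, ][gap_mask] <- "-"
    m <- cbind(m, extra)
  }
  seqs <- apply(m, 1L, paste, collapse = "")
  ids <- c(ref_id, sprintf("hom%04d", seq_len(n_bg)))

  if (n_duplicates > 0L) {
    max_sub <- floor(0.01 * ncol(m))
    dup_seqs <- purrr::map_chr(seq_len(n_duplicates), function(i) {
      s <- strsplit(seqs[1], "", fixed = TRUE)[[1]]
      n_sub <- if (max_sub > 0L) sample(0:max_sub, 1L) else 0L
      if (n_sub > 0L) {
        pos <- sample.int(length(s), n_sub)
        s[pos] <- purrr::map_chr(s[pos], function(r) sample(setdiff(aa, r), 1L))
      }
      paste(s, collapse = "")
    })
    seqs <- c(seqs, dup_seqs)
    ids <- c(ids, sprintf("dup%03d", seq_len(n_duplicates)))
  }
  tibble::tibble(seq_id = ids, aligned_seq = seqs)
}
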