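#' AT fraction of DNA sequences
#'
#' Fraction of unambiguous bases (A, C, G, T) that are A or T. Ambiguity
#' codes such as N are excluded from both numerator and denominator, so the
#' value reflects only the bases whose identity is known. Case-insensitive.
#'
#' @param sequence Character vector of DNA sequences over `{A,C,G,T,N,...}`.
#' @return Numeric vector in `[0, 1]`, one value per sequence.
#' @examples
#' at_fraction(c("ATAT", "GCGC", "ATGC"))
#' @export
at_fraction <- function(sequence) {
  check_sequences(sequence)
  s <- toupper(sequence)
  at <- stringr::str_count(s, "[AT]")
  acgt <- stringr::str_count(s, "[ACGT]")
  if (any(acgt == 0)) {
    abort("at_fraction() is undefined for sequences with no unambiguous A/C/G/T base.")
  }
  at / acgt
}

#' Longest contiguous AT tract
#'
#' Length of the longest substring consisting only of A and/or T
#' (case-insensitive). Any other character, including N, breaks a run.
#' AT tracts narrow the DNA minor groove, the feature recognised by
#' minor-groove-binding proteins, so this is the key per-probe statistic.
#'
#' @inheritParams at_fraction
#' @return Integer vector; 0 for sequences containing no A or T.
#' @examples
#' longest_at_run(c("GCATATGC", "CCCC", "ATTTA"))
#' @export
longest_at_run <- function(sequence) {
  check_sequences(sequence)
  runs <- stringr::str_extract_all(toupper(sequence), "[AT]+")
  purrr::map_int(runs, function(r) if (length(r) == 0L) 0L else max(nchar(r)))
}

check_sequences <- function(sequence) {
  if (length(sequence) == 0L) return(invisible(sequence))
  if (!is.character(sequence) || anyNA(sequence) || any(!nzchar(sequence))) {
    abort("`sequence` must be a character vector of non-empty DNA strings.")
  }
  invisible(sequence)
}

#' Per-probe AT features
#'
#' Adds `at_fraction` and `longest_at_run` columns to a probe table, one row
#' per probe, preserving order and any existing columns (in particular the
#' binding `signal`), so the result pipes straight into [bin_signal()].
#'
#' @param probes Data frame with columns `probe_id` and `sequence`
#'   (and typically a numeric `signal`).
#' @return A tibble: the input columns plus `at_fraction` and
#'   `longest_at_run`.
#' @examples
#' probes <- tibble::tibble(probe_id = "p1", sequence = "ATGC", signal = 1)
#' probe_features(probes)
#' @export
probe_features <- function(probes) {
  probes <- tibble::as_tibble(probes)
  required_cols(probes, c("probe_id", "sequence"), "probe_features()")
  if (anyDuplicated(probes$probe_id)) {
    abort("`probe_id` values must be unique.")
  }
  if (nrow(probes) == 0L) {
    return(dplyr::mutate(probes, at_fraction = numeric(), longest_at_run = integer()))
  }
  if ("signal" %in% names(probes) && any(!is.finite(probes$signal))) {
    abort("`signal` must be finite for every probe.")
  }
  dplyr::mutate(
    probes,
    at_fraction = at_fraction(.data$sequence),
    longest_at_run = longest_at_run(.data$sequence)
  )
}

required_cols <- function(df, cols, where) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    abort(sprintf("%s requires column(s): %s.", where,
                  paste0("`", missing, "`", collapse = ", ")))
  }
  invisible(df)
}

#' Group probes by an AT feature and average the binding signal
#'
#' Assigns every probe to exactly one bin of the chosen feature and returns
#' the per-bin probe count, mean and standard deviation of the binding
#' signal. For `at_fraction` the default scheme is half-open 5-percentage-
#' point bins `[0, 0.05), [0.05, 0.10), ...` with the final bin closed at 1.
#' For `longest_at_run` the default is one bin per integer run length with a
#' single open-ended bin `>= max_run` pooling the sparse long-tract tail.
#' Probes whose feature value falls outside explicit `edges` are collected
#' in an `"out of range"` bin; empty bins are reported with `n_probes = 0`
#' and `NA` mean.
#'
#' @param features Data frame from [probe_features()]: must contain the
#'   chosen feature column and `signal`.
#' @param feature Which feature to bin on: `"longest_at_run"` (default) or
#'   `"at_fraction"`.
#' @param edges Optional strictly increasing numeric vector of bin edges for
#'   half-open bins `[e_i, e_{i+1})` (last bin closed). Ignored for the
#'   integer scheme of `longest_at_run`.
#' @param max_run Pooling threshold K for the `longest_at_run` scheme: runs
#'   `>= K` share one bin. Default 12.
#' @return A tibble of class `tract_bins` with columns `bin` (ordered
#'   factor), `n_probes`, `mean_signal`, `sd_signal` (`NA` when `n < 2`).
#' @examples
#' probes <- generate_probe_set(n_probes = 200, seed = 1)
#' probes |> probe_features() |> bin_signal()
#' @export
bin_signal <- function(features, feature = c("longest_at_run", "at_fraction"),
                       edges = NULL, max_run = 12L) {
  feature <- match.arg(feature)
  features <- tibble::as_tibble(features)
  required_cols(features, c(feature, "signal"), "bin_signal()")
  x <- features[[feature]]

  if (feature == "longest_at_run" && is.null(edges)) {
    max_run <- as.integer(max_run)
    if (max_run < 1L) abort("`max_run` must be >= 1.")
    levels <- c(as.character(0:(max_run - 1L)), paste0(">=", max_run))
    bin <- factor(ifelse(x >= max_run, paste0(">=", max_run), as.character(x)),
                  levels = levels, ordered = TRUE)
  } else {
    if (is.null(edges)) edges <- seq(0, 1, by = 0.05)
    if (length(edges) < 2L || any(diff(edges) <= 0)) {
      abort("`edges` must be strictly increasing with at least two values.")
    }
    bin <- cut(x, breaks = edges, right = FALSE, include.lowest = TRUE,
               ordered_result = TRUE)
    levels(bin) <- c(levels(bin), "out of range")
    bin[is.na(bin)] <- "out of range"
  }

  out <- tibble::tibble(bin = bin, signal = features$signal) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(
      n_probes = dplyr::n(),
      mean_signal = ifelse(dplyr::n() == 0L, NA_real_, mean(.data$signal)),
      sd_signal = ifelse(dplyr::n() < 2L, NA_real_, sd(.data$signal)),
      .groups = "drop"
    )
  attr(out, "feature") <- feature
  class(out) <- c("tract_bins", class(out))
  out
}

#' Feature bin with the strongest mean binding signal
#'
#' Returns the label of the non-empty bin whose mean signal is maximal —
#' e.g. the optimal AT-tract length for binding. Ties are broken toward the
#' lower (earlier) bin label so the result is deterministic.
#'
#' @param summaries A `tract_bins` tibble from [bin_signal()] (any data
#'   frame with `bin`, `n_probes`, `mean_signal` columns works).
#' @return The winning bin label as a character scalar.
#' @examples
#' probes <- generate_probe_set(n_probes = 2000, optimal_tract = 6, seed = 1)
#' probes |> probe_features() |> bin_signal() |> optimum_bin()
#' @export
optimum_bin <- function(summaries) {
  required_cols(summaries, c("bin", "n_probes", "mean_signal"), "optimum_bin()")
  occupied <- summaries[summaries$n_probes > 0L, ]
  if (nrow(occupied) == 0L) abort("All bins are empty; no optimum is defined.")
  as.character(occupied$bin[which.max(occupied$mean_signal)])
}
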