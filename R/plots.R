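#' Plot binned binding signal against the AT feature
#'
#' Mean binding signal per feature bin with the per-bin standard deviation
#' as error bars — the standard view for locating the optimal AT-tract
#' length.
#'
#' @param object A `tract_bins` tibble from [bin_signal()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tract_bins <- function(object, ...) {
  feature <- attr(object, "feature") %||% "feature"
  df <- object[object$n_probes > 0L, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean_signal)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_signal - .data$sd_signal,
                   ymax = .data$mean_signal + .data$sd_signal),
      width = 0.25, na.rm = TRUE
    ) +
    ggplot2::labs(x = feature, y = "mean binding signal") +
    ggplot2::theme_minimal()
}

#' Plot a per-column conservation profile
#'
#' Conservation fraction per alignment column, with the gap fraction shown
#' as a light underlay.
#'
#' @param object A `conservation_profile` tibble from [consensus_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$column)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$gap_fraction),
                      fill = "grey85", width = 1) +
    ggplot2::geom_line(ggplot2::aes(y = .data$conservation), colour = "steelblue") +
    ggplot2::labs(x = "alignment column", y = "conservation (gap fraction in grey)") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a two-population RMS split
#'
#' Histogram of the RMS values coloured by assigned component, with the
#' split boundary as a dashed line — the usual bound/unbound tether view.
#'
#' @param object A `tpm_split` object from [split_populations()].
#' @param binwidth Histogram bin width in nm. Default 5.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tpm_split <- function(object, binwidth = 5, ...) {
  df <- tibble::tibble(rms_nm = object$values, component = object$labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rms_nm, fill = .data$component)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, colour = "white") +
    ggplot2::labs(x = "RMS motion (nm)", y = "count") +
    ggplot2::theme_minimal()
  if (!object$single_population) {
    p <- p + ggplot2::geom_vline(xintercept = object$boundary, linetype = "dashed")
  }
  p
}

#' Plot an RMS-versus-length calibration sweep
#'
#' @param object A `tether_sweep` tibble from [rms_vs_length()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tether_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$contour_length_nm, y = .data$rms_nm)) +
    ggplot2::geom_line(colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "contour length (nm)", y = "equilibrium RMS (nm)") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
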