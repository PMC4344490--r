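#' Anchor point of a bead trajectory
#'
#' Arithmetic mean of the x and y coordinates over a frame window — the
#' estimated tether attachment point the RMS motion is measured about.
#'
#' @param traj Data frame with numeric columns `x`, `y` (nm).
#' @param frames Optional integer vector of frame indices to average over;
#'   defaults to all frames.
#' @return Named numeric vector `c(x = ..., y = ...)`.
#' @examples
#' anchor_point(tibble::tibble(x = c(0, 2), y = c(0, 0)))
#' @export
anchor_point <- function(traj, frames = NULL) {
  required_cols(traj, c("x", "y"), "anchor_point()")
  if (is.null(frames)) frames <- seq_len(nrow(traj))
  if (length(frames) == 0L) abort("Anchor window is empty.")
  if (any(frames < 1L | frames > nrow(traj))) {
    abort("Anchor window extends beyond the trajectory.")
  }
  c(x = mean(traj$x[frames]), y = mean(traj$y[frames]))
}

#' Scatter eccentricity of a bead trajectory
#'
#' The ratio of major- to minor-axis standard deviation of the positional
#' scatter: `sqrt(lambda_max / lambda_min)` of the 2x2 covariance matrix of
#' `(x, y)`. An isotropic ("spherical") scatter gives 1; drifting or
#' doubly-tethered beads give larger values and are excluded by the
#' conventional gate of 1.3. A degenerate (collinear) scatter yields `Inf`
#' rather than an error so QC reports can flag it.
#'
#' @inheritParams anchor_point
#' @return Eccentricity `>= 1` (possibly `Inf`).
#' @export
eccentricity <- function(traj) {
  required_cols(traj, c("x", "y"), "eccentricity()")
  if (nrow(traj) < 3L) abort("Eccentricity needs at least 3 frames.")
  ev <- eigen(cov(cbind(traj$x, traj$y)), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) return(Inf)
  sqrt(ev[1] / ev[2])
}

split_beads <- function(traj, where) {
  traj <- tibble::as_tibble(traj)
  required_cols(traj, c("x", "y"), where)
  if (!"bead_id" %in% names(traj)) traj$bead_id <- "bead1"
  split(traj, factor(traj$bead_id, levels = unique(traj$bead_id)))
}

#' Quality-filter tethered beads by scatter eccentricity
#'
#' Computes the anchor point and scatter eccentricity per bead and marks
#' beads as selected when eccentricity is at most `max_ecc`. All beads are
#' reported; none are silently dropped.
#'
#' @param traj Data frame of frames with columns `x`, `y` and optionally
#'   `bead_id` (a single bead is assumed otherwise).
#' @param max_ecc Selection gate on eccentricity. Default 1.3.
#' @return A tibble with one row per bead: `bead_id`, `x_anchor`,
#'   `y_anchor`, `eccentricity`, `selected`.
#' @export
tpm_qc <- function(traj, max_ecc = 1.3) {
  beads <- split_beads(traj, "tpm_qc()")
  purrr::map(beads, function(b) {
    anchor <- anchor_point(b)
    ecc <- eccentricity(b)
    tibble::tibble(bead_id = b$bead_id[1], x_anchor = anchor[["x"]],
                   y_anchor = anchor[["y"]], eccentricity = ecc,
                   selected = is.finite(ecc) && ecc <= max_ecc)
  }) |> dplyr::bind_rows()
}

infer_dt <- function(traj, dt, where) {
  if (!is.null(dt)) {
    if (!is.numeric(dt) || dt <= 0) abort("`dt` must be a positive number of seconds.")
    return(dt)
  }
  if ("t" %in% names(traj) && nrow(traj) >= 2L) {
    steps <- diff(traj$t)
    dt <- stats::median(steps)
    if (any(abs(steps - dt) > 0.01 * dt)) {
      abort(sprintf("%s: time base is non-uniform beyond 1%% of the median step.", where))
    }
    return(dt)
  }
  abort(sprintf("%s: supply `dt` or a `t` column to establish the frame interval.", where))
}

#' Windowed root-mean-square bead motion
#'
#' Splits each bead's trajectory into consecutive non-overlapping windows of
#' `window_s` seconds (trailing partial window discarded) and computes, per
#' window, `RMS = sqrt(mean((x - xbar)^2 + (y - ybar)^2))` with the anchor
#' `(xbar, ybar)` the within-window mean position. This is the standard TPM
#' excursion statistic: protein-induced tether compaction shortens it.
#' The mean is taken over frames (1/n, matching the formula as written),
#' not the n-1 sample-variance convention.
#'
#' @inheritParams tpm_qc
#' @param window_s Window length in seconds. Default 40.
#' @param dt Frame interval in seconds; inferred from a `t` column when
#'   present (default acquisition rate in this assay is 25 Hz).
#' @return A tibble with columns `bead_id`, `window`, `n_frames`, `rms_nm`.
#' @export
tpm_rms <- function(traj, window_s = 40, dt = NULL) {
  beads <- split_beads(traj, "tpm_rms()")
  purrr::map(beads, function(b) {
    step <- infer_dt(b, dt, "tpm_rms()")
    frames_per_window <- floor(window_s / step)
    if (frames_per_window < 1L) abort("`window_s` is shorter than one frame interval.")
    n_windows <- floor(nrow(b) / frames_per_window)
    if (n_windows < 1L) {
      abort(sprintf("Trajectory '%s' is shorter than one %g s window.",
                    b$bead_id[1], window_s))
    }
    rms <- purrr::map_dbl(seq_len(n_windows), function(w) {
      idx <- ((w - 1L) * frames_per_window + 1L):(w * frames_per_window)
      xs <- b$x[idx] - mean(b$x[idx])
      ys <- b$y[idx] - mean(b$y[idx])
      sqrt(mean(xs^2 + ys^2))
    })
    tibble::tibble(bead_id = b$bead_id[1], window = seq_len(n_windows),
                   n_frames = frames_per_window, rms_nm = rms)
  }) |> dplyr::bind_rows()
}

#' Separate bound and unbound tether populations
#'
#' Deterministic two-class split of 1-D RMS values: an exhaustive search
#' over all thresholds between sorted adjacent values picks the partition
#' minimising the within-class sum of squares (the 1-D two-means solution,
#' with no random initialisation). When all values are identical a
#' single-population marker is returned instead of a degenerate split.
#'
#' @param rms_values Numeric vector of per-window or per-bead RMS values
#'   (nm); at least 2.
#' @return An object of class `tpm_split`: a list with `labels` (factor
#'   `low`/`high` aligned to the input order), `means` (named low/high
#'   component means), `boundary` (midpoint threshold, nm), `wss`
#'   (within-class sum of squares) and `single_population`. [tidy()] and
#'   [glance()] methods return tibbles; [autoplot()] draws the histogram
#'   with the boundary.
#' @examples
#' split_populations(c(100, 100, 150, 150))
#' @export
split_populations <- function(rms_values) {
  x <- rms_values
  if (!is.numeric(x) || length(x) < 2L || anyNA(x)) {
    abort("`rms_values` must be a numeric vector of length >= 2 with no NA.")
  }
  if (diff(range(x)) == 0) {
    out <- list(labels = factor(rep("low", length(x)), levels = c("low", "high")),
                means = c(low = x[1], high = NA_real_),
                boundary = NA_real_, wss = 0, single_population = TRUE,
                values = x)
    class(out) <- "tpm_split"
    return(out)
  }
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  csum <- cumsum(xs)
  csq <- cumsum(xs^2)
  # within-class SS for split after position k (1..n-1), each class's SS by
  # the sum-of-squares identity
  k <- seq_len(n - 1L)
  ss_low <- csq[k] - csum[k]^2 / k
  ss_high <- (csq[n] - csq[k]) - (csum[n] - csum[k])^2 / (n - k)
  wss <- ss_low + ss_high
  valid <- xs[k] < xs[k + 1L]  # thresholds must fall between distinct values
  wss[!valid] <- Inf
  best <- which.min(wss)
  boundary <- (xs[best] + xs[best + 1L]) / 2
  labels <- factor(ifelse(x <= boundary, "low", "high"), levels = c("low", "high"))
  out <- list(
    labels = labels,
    means = c(low = mean(x[labels == "low"]), high = mean(x[labels == "high"])),
    boundary = boundary,
    wss = wss[best],
    single_population = FALSE,
    values = x
  )
  class(out) <- "tpm_split"
  out
}

#' @export
print.tpm_split <- function(x, ...) {
  if (x$single_population) {
    cat("Single tether population: mean", format(x$means[["low"]]), "nm\n")
  } else {
    cat("Two tether populations (nm):\n")
    cat(sprintf("  low  %8.2f  (n = %d)\n", x$means[["low"]], sum(x$labels == "low")))
    cat(sprintf("  high %8.2f  (n = %d)\n", x$means[["high"]], sum(x$labels == "high")))
    cat(sprintf("  boundary %.2f, within-class SS %.2f\n", x$boundary, x$wss))
  }
  invisible(x)
}

#' @describeIn split_populations One row per component: `component`, `mean`, `n`.
#' @param x A `tpm_split` object.
#' @param ... Unused.
#' @export
tidy.tpm_split <- function(x, ...) {
  tibble::tibble(
    component = c("low", "high"),
    mean = c(x$means[["low"]], x$means[["high"]]),
    n = c(sum(x$labels == "low", na.rm = TRUE),
          sum(x$labels == "high", na.rm = TRUE))
  )
}

#' @describeIn split_populations One-row summary: `boundary`, `wss`,
#'   `separation` (difference of component means), `single_population`.
#' @export
glance.tpm_split <- function(x, ...) {
  tibble::tibble(
    boundary = x$boundary,
    wss = x$wss,
    separation = x$means[["high"]] - x$means[["low"]],
    single_population = x$single_population
  )
}
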