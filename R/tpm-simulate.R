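#' Physical model of a surface-tethered DNA-bead system
#'
#' Bundles the parameters of the Monte-Carlo tether simulator. Defaults
#' reproduce the experimental TPM geometry for a 687 bp tether: contour
#' length `bp * 0.34` nm, persistence length 50 nm (standard B-DNA),
#' polystyrene bead of 460 nm diameter (radius 230 nm), frames acquired at
#' 25 Hz. `compaction_factor` scales the effective contour length to
#' emulate protein-induced tether compaction (1 = naked DNA).
#'
#' @param bp Tether length in base pairs. Default 687.
#' @param rise_per_bp Helical rise, nm per bp. Default 0.34.
#' @param contour_length_nm Contour length in nm; default `bp * rise_per_bp`.
#' @param persistence_length_nm Bending persistence length, nm. Default 50.
#' @param bead_radius_nm Bead radius, nm. Default 230.
#' @param compaction_factor Multiplier in `(0, 1]` on the effective contour
#'   length. Default 1.
#' @param segment_length_nm Discretisation length of the chain, nm; must not
#'   exceed the persistence length. Default 10.
#' @param frames Number of frames per emitted trajectory. Default 2000.
#' @param dt Frame interval, seconds. Default `1/25`.
#' @param correlation_time_s Positional relaxation time of the bead used
#'   when threading equilibrium samples into a time series. Default 0.05.
#' @param attachment Bead attachment model: `"swivel"` (default; the bead
#'   pivots freely about the DNA attachment point on its surface, the
#'   orientation being a thermal degree of freedom) or `"tangent"` (bead
#'   centre rigidly along the final chain tangent).
#' @param seed Optional integer seed; when set, sampling from this model is
#'   bit-reproducible.
#' @return An object of class `tether_model` (a named list).
#' @examples
#' tether_model()
#' @export
tether_model <- function(bp = 687, rise_per_bp = 0.34,
                         contour_length_nm = bp * rise_per_bp,
                         persistence_length_nm = 50,
                         bead_radius_nm = 230,
                         compaction_factor = 1,
                         segment_length_nm = 10,
                         frames = 2000,
                         dt = 1 / 25,
                         correlation_time_s = 0.05,
                         attachment = c("swivel", "tangent"),
                         seed = NULL) {
  attachment <- match.arg(attachment)
  if (contour_length_nm <= 0) abort("`contour_length_nm` must be positive.")
  if (compaction_factor <= 0 || compaction_factor > 1) {
    abort("`compaction_factor` must be in (0, 1].")
  }
  if (segment_length_nm > persistence_length_nm) {
    abort("`segment_length_nm` must not exceed `persistence_length_nm`.")
  }
  if (dt <= 0) abort("`dt` must be positive.")
  if (correlation_time_s < 0) abort("`correlation_time_s` must be non-negative.")
  if (round(contour_length_nm * compaction_factor / segment_length_nm) < 2) {
    abort("Effective contour length must cover at least 2 segments.")
  }
  model <- list(
    contour_length_nm = contour_length_nm,
    persistence_length_nm = persistence_length_nm,
    bead_radius_nm = bead_radius_nm,
    compaction_factor = compaction_factor,
    segment_length_nm = segment_length_nm,
    frames = as.integer(frames),
    dt = dt,
    correlation_time_s = correlation_time_s,
    attachment = attachment,
    seed = seed
  )
  class(model) <- "tether_model"
  model
}

#' @export
print.tether_model <- function(x, ...) {
  cat("Tethered DNA-bead model\n")
  cat(sprintf("  contour %.1f nm (x %.2f compaction => %.1f nm effective)\n",
              x$contour_length_nm, x$compaction_factor,
              x$contour_length_nm * x$compaction_factor))
  cat(sprintf("  persistence length %.0f nm, segment %.0f nm, bead radius %.0f nm (%s attachment)\n",
              x$persistence_length_nm, x$segment_length_nm, x$bead_radius_nm,
              x$attachment))
  cat(sprintf("  acquisition: %d frames at %.0f Hz, correlation time %.3f s\n",
              x$frames, 1 / x$dt, x$correlation_time_s))
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Equilibrium bead positions of a tethered DNA-bead system
#'
#' Metropolis sampling of a discrete worm-like chain anchored at the origin
#' on the z = 0 surface, with bending energy `(Lp/l) * (1 - cos theta)` per
#' joint (kT units), a hard bead of radius R at the distal end, and hard
#' half-space exclusion: every chain vertex must have `z >= 0` and the bead
#' centre `z >= R`. Pivot moves rotate the chain; in the default swivel
#' attachment the bead orientation is an extra thermal degree of freedom
#' moved alongside, so chain states are weighted by the bead's allowed
#' orientation entropy. Samples are taken after a burn-in, thinned by a few
#' sweeps; the returned coordinates are instantaneous bead-centre positions.
#'
#' @param model A [tether_model()].
#' @param n_samples Number of equilibrium samples to return.
#' @param burnin_sweeps,thin_sweeps,max_angle Sampler controls: burn-in
#'   sweeps discarded, sweeps between retained samples and maximum pivot
#'   rotation angle (radians).
#' @return A tibble with columns `x`, `y`, `z` (nm); attributes
#'   `n_segments` and `acceptance_rate` describe the run.
#' @examples
#' head(sample_tether(tether_model(seed = 1), 100))
#' @export
sample_tether <- function(model, n_samples,
                          burnin_sweeps = 2000, thin_sweeps = 5,
                          max_angle = 1) {
  stopifnot(inherits(model, "tether_model"))
  if (n_samples < 1L) abort("`n_samples` must be at least 1.")
  eff_contour <- model$contour_length_nm * model$compaction_factor
  if (round(eff_contour / model$segment_length_nm) < 2) {
    abort("Effective contour length must cover at least 2 segments.")
  }
  if (!is.null(model$seed)) set.seed(model$seed)
  res <- wlc_sample_cpp(
    n_samples = as.integer(n_samples),
    contour = eff_contour,
    lp = model$persistence_length_nm,
    ell_target = model$segment_length_nm,
    bead_r = model$bead_radius_nm,
    attachment = if (model$attachment == "tangent") 0L else 1L,
    burnin_sweeps = as.integer(burnin_sweeps),
    thin_sweeps = as.integer(thin_sweeps),
    max_angle = max_angle
  )
  out <- tibble::tibble(x = res$x, y = res$y, z = res$z)
  attr(out, "n_segments") <- res$n_segments
  attr(out, "acceptance_rate") <- res$acceptance_rate
  out
}

# Thread a pool of equilibrium samples into `n` time points with exponential
# autocorrelation: hold the current draw with probability exp(-dt/tau),
# otherwise take a fresh draw from the pool. Returns row indices into the
# pool, so the marginal distribution is exactly the pool's.
thread_renewal <- function(n_pool, n, p_hold) {
  renew <- c(TRUE, runif(n - 1L) >= p_hold)
  draws <- sample.int(n_pool, sum(renew), replace = TRUE)
  draws[cumsum(renew)]
}

#' Emit a TPM bead trajectory from the tether model
#'
#' Draws an equilibrium ensemble with [sample_tether()] and threads it into
#' a time series whose autocorrelation decays with the model's
#' `correlation_time_s` (renewal resampling: each instant keeps the current
#' position or takes a fresh equilibrium draw).
#'
#' With `exposure = "integrate"` (default) each emitted frame is the
#' time-average of the position over the full frame interval, as a camera
#' with full-frame exposure records it; the resulting motion blur lowers
#' the apparent excursion below the instantaneous equilibrium value, which
#' is exactly what tracked TPM data show. With `exposure = "instant"`
#' frames are instantaneous snapshots and the marginal distribution of the
#' equilibrium ensemble is preserved exactly.
#'
#' @inheritParams sample_tether
#' @param bead_id Identifier for the emitted bead. Default `"bead1"`.
#' @param exposure `"integrate"` (camera model) or `"instant"`.
#' @param n_equilibrium Size of the equilibrium pool backing the series.
#' @param substeps Sub-frame time resolution of the exposure integral.
#' @return A trajectory tibble with columns `bead_id`, `t`, `x`, `y`,
#'   ready for [tpm_qc()] and [tpm_rms()].
#' @examples
#' traj <- simulate_trajectory(tether_model(frames = 1000, seed = 1))
#' tpm_rms(traj)
#' @export
simulate_trajectory <- function(model, bead_id = "bead1",
                                exposure = c("integrate", "instant"),
                                n_equilibrium = 5000, substeps = 8) {
  stopifnot(inherits(model, "tether_model"))
  exposure <- match.arg(exposure)
  if (model$frames < 2L) abort("`frames` must be at least 2.")
  pool <- sample_tether(model, n_equilibrium)  # consumes model$seed if set
  emit_from_pool(pool, model, bead_id, exposure, substeps)
}

emit_from_pool <- function(pool, model, bead_id, exposure, substeps) {
  n <- model$frames
  tau <- model$correlation_time_s
  if (exposure == "instant") {
    p_hold <- if (tau <= 0) 0 else exp(-model$dt / tau)
    idx <- thread_renewal(nrow(pool), n, p_hold)
    x <- pool$x[idx]
    y <- pool$y[idx]
  } else {
    dts <- model$dt / substeps
    p_hold <- if (tau <= 0) 0 else exp(-dts / tau)
    idx <- thread_renewal(nrow(pool), n * substeps, p_hold)
    x <- colMeans(matrix(pool$x[idx], nrow = substeps))
    y <- colMeans(matrix(pool$y[idx], nrow = substeps))
  }
  tibble::tibble(bead_id = bead_id, t = (seq_len(n) - 1L) * model$dt, x = x, y = y)
}

#' Simulate a cohort of beads under one condition
#'
#' Emits `n_beads` independent trajectories threaded from a single shared
#' equilibrium ensemble (the beads experience the same physics; only their
#' Brownian histories differ). Convenient for building RMS histograms over
#' many particles per condition.
#'
#' @inheritParams simulate_trajectory
#' @param n_beads Number of beads. Default 100.
#' @return A combined trajectory tibble with distinct `bead_id`s.
#' @export
simulate_cohort <- function(model, n_beads = 100,
                            exposure = c("integrate", "instant"),
                            n_equilibrium = 20000, substeps = 8) {
  stopifnot(inherits(model, "tether_model"))
  exposure <- match.arg(exposure)
  pool <- sample_tether(model, n_equilibrium)
  purrr::map(seq_len(n_beads), function(i) {
    emit_from_pool(pool, model, sprintf("bead%03d", i), exposure, substeps)
  }) |> dplyr::bind_rows()
}

#' RMS excursion as a function of tether length
#'
#' Calibration sweep: equilibrium RMS of the bead centre about its mean,
#' computed with [sample_tether()] at each contour length with all other
#' model parameters held fixed. RMS grows monotonically with tether length
#' over the TPM working range, which is what makes the assay a reporter of
#' effective tether length.
#'
#' @inheritParams sample_tether
#' @param contour_lengths_nm Positive contour lengths (nm) to sweep.
#' @param n_samples Equilibrium samples per length. Default 5000.
#' @return A tibble of class `tether_sweep` with columns
#'   `contour_length_nm`, `rms_nm`, `n`.
#' @export
rms_vs_length <- function(model, contour_lengths_nm, n_samples = 5000) {
  stopifnot(inherits(model, "tether_model"))
  if (any(contour_lengths_nm <= 0)) abort("Contour lengths must be positive.")
  rows <- purrr::map(seq_along(contour_lengths_nm), function(i) {
    m <- model
    m$contour_length_nm <- contour_lengths_nm[i]
    if (!is.null(model$seed)) m$seed <- model$seed + i - 1L
    s <- sample_tether(m, n_samples)
    tibble::tibble(
      contour_length_nm = contour_lengths_nm[i],
      rms_nm = sqrt(mean((s$x - mean(s$x))^2 + (s$y - mean(s$y))^2)),
      n = n_samples
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tether_sweep", class(out))
  out
}
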