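# Voxelwise phase-locking between the gastric-band EGG and BOLD, and
# its chance level from circularly time-shifted surrogates.

#' Instantaneous phase and amplitude via the analytic signal
#'
#' FFT-based analytic signal of a narrowband real series.  Phase is in
#' (-pi, pi]; amplitude is the envelope.  Apply this to the padded
#' (untrimmed) series and trim afterwards, so the transform's edge
#' effects fall in the discarded samples.
#'
#' @param x numeric series or voxels x T matrix.
#' @return list of class `phase_series` with `phase` and `amplitude`
#'   (same shape as the input).
#' @export
analytic_phase <- function(x) {
  was_vec <- !is.matrix(x)
  X <- if (was_vec) matrix(x, nrow = 1L) else x
  if (all(X == 0)) stop("phase undefined for an all-zero series")
  A <- t(analytic_matrix(t(X)))
  out <- list(phase = if (was_vec) drop(Arg(A)) else Arg(A),
              amplitude = if (was_vec) drop(Mod(A)) else Mod(A))
  class(out) <- "phase_series"
  out
}

#' Phase-locking value
#'
#' \deqn{PLV_{x,y} = \left|\frac{1}{T}\sum_{t=1}^{T} e^{i(\phi_x(t) - \phi_y(t))}\right|}
#'
#' The resultant length of the phase-difference distribution: 1 when
#' the two series keep a constant phase relation (at any lag), 0 when
#' their phases are unrelated.  Invariant to amplitudes and to adding
#' any constant to either phase.
#'
#' @param phase_x,phase_y phase vectors in radians (or `phase_series`
#'   objects, in which case their `phase` field is used).
#' @return scalar in \[0, 1\].
#' @examples
#' t <- seq(0, 838, by = 2)
#' p1 <- 2 * pi * 0.05 * t
#' plv(p1, p1 + pi / 3)   # 1: constant lag
#' @export
plv <- function(phase_x, phase_y) {
  if (inherits(phase_x, "phase_series")) phase_x <- phase_x$phase
  if (inherits(phase_y, "phase_series")) phase_y <- phase_y$phase
  if (length(phase_x) != length(phase_y)) {
    stop("phase series lengths differ (", length(phase_x), " vs ",
         length(phase_y), ")")
  }
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

#' Admissible circular time shifts for surrogate data
#'
#' All integer circular shifts of at least `min_shift` seconds,
#' enumerated half-open at the wrap boundary: `s` in
#' `[m, T - m - 1]` with `m = min_shift / tr`.  Samples shifted past
#' the end wrap to the beginning.  For a 420-sample series at TR 2 s
#' and a 60 s minimum shift this yields 360 offsets.  With
#' `min_shift = 0` the zero shift is excluded, giving all `T - 1`
#' nonzero shifts.
#'
#' @param n_samples series length T.
#' @param tr sampling interval in seconds.
#' @param min_shift minimum shift magnitude in seconds (default 60).
#' @return integer vector of shifts (in samples).
#' @export
surrogate_offsets <- function(n_samples, tr, min_shift = 60) {
  m <- as.integer(ceiling(min_shift / tr))
  if (n_samples * tr <= 2 * min_shift) {
    stop("series too short: need T * tr > 2 * min_shift")
  }
  s <- seq.int(m, n_samples - m - 1L)
  s[s != 0L]
}

#' @noRd
plv_all_shifts <- function(unit_vox, unit_egg) {
  # PLV of every voxel against every circular shift of the EGG phase,
  # via FFT cross-correlation.  unit_vox: V x T complex unit phasors;
  # unit_egg: length-T complex unit phasor.  Returns T x V matrix whose
  # row s+1 is the PLV at shift s (EGG delayed by s samples, wrapped).
  Tn <- length(unit_egg)
  Fv <- stats::mvfft(t(unit_vox))
  Fe <- stats::fft(unit_egg)
  Z <- stats::mvfft(Fv * Conj(Fe), inverse = TRUE) / Tn
  Mod(Z) / Tn
}

#' Chance-level PLV from time-shifted surrogates
#'
#' For each voxel, the PLV is recomputed with the EGG phase series
#' circularly shifted by every admissible offset (the BOLD series stays
#' fixed); the chance level is the median of that surrogate
#' distribution.  Every surrogate uses exactly the same number of
#' samples as the empirical PLV.
#'
#' @param bold_phase voxels x T matrix of BOLD phases (radians).
#' @param egg_phase length-T EGG phase (radians).
#' @param offsets integer shifts from [surrogate_offsets()].
#' @param keep_distribution return the full voxel x offset surrogate
#'   matrix (default FALSE).
#' @param quantiles also return the per-voxel 2.5% and 97.5% surrogate
#'   quantiles (default FALSE).
#' @return list with `chance` (per-voxel median), and optionally
#'   `quantiles` (voxels x 2 matrix) and `surrogates`.
#' @export
chance_plv_map <- function(bold_phase, egg_phase, offsets,
                           keep_distribution = FALSE, quantiles = FALSE) {
  if (length(offsets) == 0L) stop("offsets must be nonempty")
  bold_phase <- if (is.matrix(bold_phase)) bold_phase else
    matrix(bold_phase, nrow = 1L)
  if (ncol(bold_phase) != length(egg_phase)) {
    stop("BOLD and EGG phase lengths differ")
  }
  P <- plv_all_shifts(exp(1i * bold_phase), exp(1i * egg_phase))
  S <- t(P[offsets + 1L, , drop = FALSE])  # voxels x offsets
  out <- list(chance = apply(S, 1L, stats::median))
  if (quantiles) {
    out$quantiles <- t(apply(S, 1L, stats::quantile, probs = c(0.025, 0.975)))
  }
  if (keep_distribution) out$surrogates <- S
  out
}

#' Empirical PLV map
#'
#' @param bold_phase voxels x T matrix of BOLD phases.
#' @param egg_phase length-T EGG phase.
#' @return numeric vector, one PLV per voxel.
#' @export
empirical_plv_map <- function(bold_phase, egg_phase) {
  bold_phase <- if (is.matrix(bold_phase)) bold_phase else
    matrix(bold_phase, nrow = 1L)
  if (ncol(bold_phase) != length(egg_phase)) {
    stop("BOLD and EGG phase lengths differ")
  }
  Mod(exp(1i * bold_phase) %*% exp(-1i * egg_phase))[, 1L] /
    length(egg_phase)
}

#' Coupling-strength map: empirical minus chance PLV
#'
#' @param empirical per-voxel empirical PLV.
#' @param chance per-voxel chance-level PLV (same length).
#' @param participant_id optional identifier stored with the maps.
#' @return object of class `coupling_maps` with `empirical_plv`,
#'   `chance_plv`, `coupling_strength`, `participant_id`.
#' @export
coupling_strength_map <- function(empirical, chance, participant_id = NA) {
  if (length(empirical) != length(chance)) {
    stop("empirical and chance maps have different voxel counts")
  }
  structure(list(empirical_plv = empirical, chance_plv = chance,
                 coupling_strength = empirical - chance,
                 participant_id = participant_id),
            class = "coupling_maps")
}
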