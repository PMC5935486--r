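# Characterisation of significant clusters ("nodes"): shared variance
# with the EGG, phase-locking angles and their consistency across
# participants, circular ANOVA, and delayed vs instantaneous
# functional connectivity.

#' Mean time series of a cluster
#'
#' Arithmetic mean across the cluster's voxels at each time point;
#' averaging raises the signal-to-noise ratio before region-level
#' statistics.
#'
#' @param bold a [bold_series()] (or a plain voxels x T matrix).
#' @param voxels indices into the in-mask voxel rows.
#' @return numeric series of length T.
#' @export
extract_node_series <- function(bold, voxels) {
  X <- if (inherits(bold, "bold_series")) bold$data else bold
  if (length(voxels) == 0L) stop("empty voxel set")
  if (any(voxels < 1L | voxels > nrow(X))) stop("voxel indices out of range")
  colMeans(X[voxels, , drop = FALSE])
}

#' @noRd
coherence_spectrum <- function(x, y, fs, window_s, overlap_s) {
  sx <- windowed_spectrum(x, fs, window_s, overlap_s)
  sy <- windowed_spectrum(y, fs, window_s, overlap_s)
  cross <- rowSums(sx$spectra * Conj(sy$spectra))
  px <- rowSums(Mod(sx$spectra)^2)
  py <- rowSums(Mod(sy$spectra)^2)
  coh <- Mod(cross) / sqrt(px * py)
  list(freqs = sx$freqs, coherence = coh, n_windows = sx$n_windows)
}

#' Shared variance between EGG and a node at the gastric frequency
#'
#' Magnitude-squared coherence from windowed spectra of the full-band
#' (0.01-0.1 Hz) series:
#' \deqn{coh_{xy}(\omega) = \frac{|\sum_t A_x A_y e^{i(\varphi_x-\varphi_y)}|}{\sqrt{\sum_t A_x^2 \sum_t A_y^2}}}
#' evaluated at the frequency bin nearest the participant's gastric
#' peak, then squared.  Because coherence tolerates a fixed delay, its
#' square measures delay-tolerant shared variance.  The realised
#' window count is derived from the data length and reported.
#'
#' @param egg full-band EGG reference series (at BOLD sampling).
#' @param node full-band node series, same length.
#' @param gastric_freq participant's gastric peak frequency (Hz).
#' @param fs sampling rate (Hz), default 0.5.
#' @param window_s,overlap_s Welch geometry in seconds (120, 20).
#' @return list with `shared_variance` (in \[0, 1\]), `freq_used`,
#'   `n_windows`.
#' @export
shared_variance_coherence <- function(egg, node, gastric_freq, fs = 0.5,
                                      window_s = 120, overlap_s = 20) {
  if (length(egg) != length(node)) stop("series lengths differ")
  cs <- coherence_spectrum(egg, node, fs, window_s, overlap_s)
  i <- which.min(abs(cs$freqs - gastric_freq))
  list(shared_variance = cs$coherence[i]^2, freq_used = cs$freqs[i],
       n_windows = cs$n_windows)
}

#' Phase-locking angles of nodes relative to the network mean
#'
#' For each node k, the lock angle is the argument of the mean complex
#' phase difference with the EGG,
#' \eqn{\Phi_k = \arg\left(\frac{1}{T}\sum_t e^{i(\phi_x(t)-\phi_y(t))}\right)};
#' relative angles subtract the circular mean across nodes (computed on
#' unit vectors), because only delays relative to the network are
#' interpretable when the EGG-to-pacemaker delay is unknown.
#'
#' @param node_phase K x T matrix of node phases (or list of phase
#'   vectors / `phase_series`).
#' @param egg_phase length-T EGG phase.
#' @return list with `lock_angle` (\eqn{\Phi_k}) and `relative_angle`
#'   per node, both in (-pi, pi].
#' @export
phase_angles <- function(node_phase, egg_phase) {
  if (is.list(node_phase)) {
    node_phase <- do.call(rbind, lapply(node_phase, function(p) {
      if (inherits(p, "phase_series")) p$phase else p
    }))
  }
  if (!is.matrix(node_phase)) node_phase <- matrix(node_phase, nrow = 1L)
  if (ncol(node_phase) != length(egg_phase)) stop("phase lengths differ")
  z <- exp(1i * (node_phase - matrix(egg_phase, nrow(node_phase),
                                     length(egg_phase), byrow = TRUE)))
  lock <- Arg(rowMeans(z))
  if (length(lock) < 2L) {
    warning("single node: relative angle set to 0")
    return(list(lock_angle = lock, relative_angle = 0 * lock))
  }
  mean_dir <- Arg(mean(exp(1i * lock)))
  list(lock_angle = wrap_angle(lock),
       relative_angle = wrap_angle(lock - mean_dir))
}

#' Between-participant phase-delay consistency
#'
#' Resultant length of the participants' unit vectors at each node,
#' \eqn{|\frac{1}{P}\sum_p e^{i\phi_{k,p}}|}: 1 when all participants
#' lock at the same relative angle, near 0 when angles are uniform.
#'
#' @param angles participants x nodes matrix of relative lock angles
#'   (radians), or a vector for a single node.
#' @return numeric vector, consistency in \[0, 1\] per node.
#' @export
angle_consistency <- function(angles) {
  if (!is.matrix(angles)) angles <- matrix(angles, ncol = 1L)
  if (nrow(angles) < 2L) stop("need at least 2 participants")
  Mod(colMeans(exp(1i * angles)))
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analog of one-way ANOVA: tests whether K groups of angles
#' share a common mean direction, using the classical F approximation
#' with the concentration correction factor \eqn{1 + 3/(8\hat\kappa)}.
#' The approximation assumes reasonably concentrated samples; a warning
#' is issued when the mean resultant length falls below 0.45.
#'
#' @param angles numeric vector of angles in radians.
#' @param groups factor/vector of group labels, same length.
#' @return list with `F`, `p`, `df1`, `df2`, `kappa`, `r_bar`.
#' @export
watson_williams <- function(angles, groups) {
  groups <- as.factor(groups)
  if (length(angles) != length(groups)) stop("angles/groups lengths differ")
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs at least 2 angles")
  N <- length(angles)
  K <- nlevels(groups)
  z <- exp(1i * angles)
  Rk <- vapply(levels(groups), function(g) Mod(sum(z[groups == g])), 0)
  R <- Mod(sum(z))
  r_bar <- sum(Rk) / N
  kappa <- est_kappa(r_bar)
  if (r_bar < 0.45) {
    warning("mean resultant length ", signif(r_bar, 3),
            " < 0.45: Watson-Williams F approximation may be unreliable")
  }
  corr <- 1 + 3 / (8 * kappa)
  Fstat <- corr * ((N - K) * (sum(Rk) - R)) / ((K - 1) * (N - sum(Rk)))
  p <- stats::pf(Fstat, K - 1, N - K, lower.tail = FALSE)
  list(F = Fstat, p = p, df1 = K - 1, df2 = N - K, kappa = kappa,
       r_bar = r_bar)
}

#' @noRd
est_kappa <- function(r) {
  # maximum-likelihood von Mises concentration from the mean resultant
  # length (standard piecewise approximation)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

#' Instantaneous vs delayed functional connectivity of a node pair
#'
#' Instantaneous FC is the squared Pearson correlation of the
#' gastric-band filtered series (blind to delays); delayed FC is the
#' squared coherence at the gastric frequency (tolerant to a fixed
#' delay).  Both are shared-variance fractions in \[0, 1\].
#'
#' @param x,y full-band node series (same length, at `fs`).
#' @param gastric_freq gastric peak frequency (Hz).
#' @param fs sampling rate (default 0.5 Hz).
#' @param half_width gastric filter half-width (Hz).
#' @param window_s,overlap_s coherence window geometry (seconds).
#' @return list with `instantaneous` and `delayed`.
#' @export
node_fc <- function(x, y, gastric_freq, fs = 0.5, half_width = 0.015,
                    window_s = 120, overlap_s = 20) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant series")
  }
  xb <- bandpass_zero_phase(x, fs, gastric_freq, half_width)
  yb <- bandpass_zero_phase(y, fs, gastric_freq, half_width)
  inst <- stats::cor(xb, yb)^2
  del <- shared_variance_coherence(x, y, gastric_freq, fs,
                                   window_s, overlap_s)$shared_variance
  list(instantaneous = inst, delayed = del)
}
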