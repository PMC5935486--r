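# Synthetic EGG + BOLD cohorts with planted gastric-BOLD coupling.
# The generator is the ground-truth bench for the whole pipeline: a
# narrow-band gastric oscillator with a drifting instantaneous
# frequency, and BOLD volumes in which chosen clusters follow the
# oscillator's phase at planted delays, embedded in 1/f-type noise.

#' Parameters of the synthetic gastric oscillator
#'
#' @param base_freq gastric frequency in Hz, inside the normogastric
#'   band 0.033-0.066 Hz.
#' @param freq_jitter_sd innovation rate of the instantaneous-frequency
#'   drift, in Hz per sqrt(second): the frequency performs a
#'   mean-reverting Gaussian random walk (Ornstein-Uhlenbeck) around
#'   `base_freq`, reflected at the normogastric band edges, with
#'   per-sample innovation SD `freq_jitter_sd / sqrt(fs)`.
#' @param freq_tau mean-reversion time constant of the frequency drift
#'   in seconds; together with `freq_jitter_sd` it sets the stationary
#'   drift SD `freq_jitter_sd * sqrt(freq_tau / 2)`.
#' @param amplitude oscillator amplitude in microvolts.
#' @param n_channels number of EGG channels.
#' @param channel_gains per-channel multiplicative gains (recycled).
#' @param noise_sd additive white measurement noise per channel (uV).
#' @param fs sampling rate in Hz (10 Hz, the post-decimation EGG rate).
#' @param duration recording length in seconds; must cover the scan
#'   plus 30 s padding at each end.
#' @param seed integer RNG seed.
#' @return object of class `egg_sim_params`.
#' @export
egg_sim_params <- function(base_freq = 0.05, freq_jitter_sd = 7e-4,
                           freq_tau = 100, amplitude = 100, n_channels = 4,
                           channel_gains = c(1, 0.7, 0.5, 0.35),
                           noise_sd = 20, fs = 10, duration = 960,
                           seed = 1L) {
  if (base_freq < 0.033 || base_freq > 0.066) {
    stop("base_freq must lie in the normogastric band [0.033, 0.066] Hz")
  }
  if (fs < 10 * base_freq) stop("fs must be at least 10 x base_freq")
  if (duration <= 0 || fs <= 0) stop("invalid fs/duration")
  channel_gains <- rep_len(channel_gains, n_channels)
  structure(list(base_freq = base_freq, freq_jitter_sd = freq_jitter_sd,
                 freq_tau = freq_tau,
                 amplitude = amplitude, n_channels = n_channels,
                 channel_gains = channel_gains, noise_sd = noise_sd,
                 fs = fs, duration = duration, seed = as.integer(seed)),
            class = "egg_sim_params")
}

#' @noRd
reflect_into <- function(x, lo, hi) {
  w <- hi - lo
  m <- (x - lo) %% (2 * w)
  lo + ifelse(m > w, 2 * w - m, m)
}

#' Simulate a multichannel EGG recording
#'
#' The instantaneous frequency follows a mean-reverting Gaussian random
#' walk around `base_freq`, reflected at the normogastric band edges,
#' so the oscillator speeds up and slows down the way a real gastric
#' rhythm does while its long-run spectral peak stays at `base_freq`.  Channels share the oscillator with different gains plus
#' independent white noise.  The returned recording carries the true
#' oscillator phase (`phase_true`) and instantaneous frequency
#' (`freq_inst`) as simulation ground truth.
#'
#' @param params an [egg_sim_params()].
#' @param tr BOLD repetition time used to lay down volume triggers; the
#'   first volume starts 30 s into the recording and volumes fill the
#'   recording up to 30 s before its end.
#' @return an [egg_recording()] with extra fields `phase_true`,
#'   `freq_inst` and `params`.
#' @export
simulate_egg <- function(params, tr = 2) {
  stopifnot(inherits(params, "egg_sim_params"))
  set.seed(params$seed)
  n <- round(params$duration * params$fs)
  dt <- 1 / params$fs
  w <- stats::rnorm(n, 0, params$freq_jitter_sd * sqrt(dt))
  drift <- as.numeric(stats::filter(w, 1 - dt / params$freq_tau,
                                    method = "recursive"))
  f <- reflect_into(params$base_freq + drift, 0.033, 0.066)
  phase <- 2 * pi * cumsum(f) / params$fs
  s <- params$amplitude * cos(phase)
  data <- matrix(0, params$n_channels, n)
  for (ch in seq_len(params$n_channels)) {
    data[ch, ] <- params$channel_gains[ch] * s +
      stats::rnorm(n, 0, params$noise_sd)
  }
  n_vol <- floor((params$duration - 60) / tr)
  onsets <- 30 + (seq_len(n_vol) - 1L) * tr
  egg <- egg_recording(data, fs = params$fs,
                       trigger_index = round(onsets * params$fs) + 1L)
  egg$phase_true <- phase
  egg$freq_inst <- f
  egg$params <- params
  egg
}

#' @noRd
default_mask <- function(grid_dim, radius = NULL) {
  if (is.null(radius)) radius <- min(grid_dim) * 0.4
  ctr <- (grid_dim + 1) / 2
  co <- arrayInd(seq_len(prod(grid_dim)), grid_dim)
  d2 <- (co[, 1] - ctr[1])^2 + (co[, 2] - ctr[2])^2 + (co[, 3] - ctr[3])^2
  array(d2 <= radius^2, grid_dim)
}

#' Ground truth for a planted-coupling simulation
#'
#' Defines which voxels are phase-locked to the gastric oscillator, at
#' which per-cluster phase delay, and how strongly.  Cluster strength is
#' expressed as a signal-to-noise ratio: the coupled sinusoid's
#' amplitude in units of the noise standard deviation inside the
#' gastric band, so detectability does not depend on the broadband
#' noise level chosen.
#'
#' @param grid_dim integer(3) voxel grid (default 20 x 20 x 20).
#' @param mask 3D logical brain mask (default: centred sphere).
#' @param cluster_centers matrix (clusters x 3) of cluster centre voxel
#'   coordinates; defaults to three well-separated in-mask sites.
#' @param cluster_half cubic cluster half-side in voxels (1 -> 3x3x3).
#' @param planted_delay radians per cluster, in (-pi, pi]: phase of the
#'   BOLD response relative to the EGG.
#' @param snr per-cluster coupling amplitude in units of in-band noise
#'   SD (recycled).
#' @param egg_params an [egg_sim_params()] template for the cohort.
#' @return object of class `synthetic_truth` with fields `coupled_mask`,
#'   `cluster_id` (3D integer array, 0 outside clusters),
#'   `planted_delay`, `coupling_amplitude` (the SNR values), `mask`,
#'   `egg_params`.
#' @export
synthetic_truth <- function(grid_dim = c(20, 20, 20), mask = NULL,
                            cluster_centers = NULL, cluster_half = 1,
                            planted_delay = c(0, pi / 2, pi),
                            snr = 2, egg_params = egg_sim_params()) {
  if (is.null(mask)) mask <- default_mask(grid_dim)
  stopifnot(all(dim(mask) == grid_dim))
  if (is.null(cluster_centers)) {
    fr <- rbind(c(0.35, 0.35, 0.5), c(0.7, 0.7, 0.5), c(0.5, 0.5, 0.75))
    cluster_centers <- round(fr[seq_along(planted_delay), , drop = FALSE] *
                               matrix(grid_dim, length(planted_delay), 3,
                                      byrow = TRUE))
  }
  k <- nrow(cluster_centers)
  stopifnot(length(planted_delay) == k)
  if (any(planted_delay <= -pi | planted_delay > pi)) {
    stop("planted delays must lie in (-pi, pi]")
  }
  snr <- rep_len(snr, k)
  cluster_id <- array(0L, grid_dim)
  for (c_i in seq_len(k)) {
    rng <- lapply(1:3, function(d) {
      pmax(1L, cluster_centers[c_i, d] - cluster_half):
        pmin(grid_dim[d], cluster_centers[c_i, d] + cluster_half)
    })
    cluster_id[rng[[1]], rng[[2]], rng[[3]]] <- c_i
  }
  cluster_id[!mask] <- 0L
  if (any(tabulate(cluster_id[cluster_id > 0], k) == 0L)) {
    stop("every planted cluster must contain at least one in-mask voxel")
  }
  structure(list(grid_dim = grid_dim, mask = mask,
                 coupled_mask = cluster_id > 0L, cluster_id = cluster_id,
                 planted_delay = planted_delay, coupling_amplitude = snr,
                 egg_params = egg_params),
            class = "synthetic_truth")
}

#' @noRd
noise_envelope <- function(n_volumes, tr, exponent) {
  f <- pmin(seq_len(n_volumes) - 1L, n_volumes - (seq_len(n_volumes) - 1L)) /
    (n_volumes * tr)
  e <- numeric(n_volumes)
  e[f > 0] <- f[f > 0]^(-exponent / 2)
  e / sqrt(mean(e^2))
}

#' @noRd
inband_noise_sd <- function(noise_sd, n_volumes, tr, exponent, band) {
  e <- noise_envelope(n_volumes, tr, exponent)
  f <- pmin(seq_len(n_volumes) - 1L, n_volumes - (seq_len(n_volumes) - 1L)) /
    (n_volumes * tr)
  noise_sd * sqrt(mean(e^2 * (f >= band[1] & f <= band[2])))
}

#' Simulate a 4D BOLD acquisition coupled to a simulated EGG
#'
#' Coupled voxels receive `A * g(t) * cos(phase_egg(t) + delay)` on top
#' of 1/f-shaped noise; background voxels receive noise only.  `A` is
#' the cluster SNR times the noise standard deviation inside the
#' gastric band, so planted clusters have a controlled in-band
#' signal-to-noise ratio.  `g(t)` is a slowly varying coupling gain
#' (constant 1 unless `comodulation > 0`), used to study co-fluctuation
#' of coupling strength and BOLD amplitude.
#'
#' @param truth a [synthetic_truth()].
#' @param egg a simulated [egg_recording()] carrying `phase_true`.
#' @param noise_model list with `exponent` (spectral slope of the 1/f
#'   noise, default 1), `sd` (time-domain noise SD, default 1) and
#'   `comodulation` (gain modulation depth, default 0).
#' @param tr repetition time in seconds.
#' @param n_volumes number of volumes (default 450).
#' @param seed integer RNG seed.
#' @return a [bold_series()]; attribute `coupling_gain` holds `g(t)`
#'   and `realized_amplitude` the per-cluster amplitudes in signal units.
#' @export
simulate_bold <- function(truth, egg, noise_model = list(), tr = 2,
                          n_volumes = 450, seed = 1L) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(egg, "egg_recording"))
  nm <- utils::modifyList(list(exponent = 1, sd = 1, comodulation = 0),
                          noise_model)
  if (is.null(egg$phase_true)) {
    stop("simulate_bold needs a simulated EGG carrying its true phase")
  }
  dur_needed <- n_volumes * tr + 60
  if (ncol(egg$data) / egg$fs < dur_needed) {
    stop("EGG duration must cover n_volumes * tr plus 30 s padding per end")
  }
  if (length(egg$trigger_index) < n_volumes) {
    stop("EGG recording has fewer volume triggers than n_volumes")
  }
  set.seed(seed)
  mask <- truth$mask
  V <- sum(mask)
  # 1/f-shaped noise: spectrally shaped white noise, normalized to sd
  env <- noise_envelope(n_volumes, tr, nm$exponent)
  W <- matrix(stats::rnorm(n_volumes * V), n_volumes, V)
  N <- Re(stats::mvfft(stats::mvfft(W) * env, inverse = TRUE)) / n_volumes
  N <- N * nm$sd
  X <- t(N)  # voxels x T

  phase_vol <- egg$phase_true[egg$trigger_index[seq_len(n_volumes)]]
  band <- egg$params$base_freq + c(-0.015, 0.015)
  sd_band <- inband_noise_sd(nm$sd, n_volumes, tr, nm$exponent, band)
  g <- rep(1, n_volumes)
  if (nm$comodulation > 0) {
    u <- stats::filter(stats::rnorm(n_volumes + 50), rep(1 / 25, 25),
                       sides = 1)
    u <- as.numeric(u)[-(1:50)]
    u <- (u - mean(u)) / stats::sd(u)
    g <- pmax(1 + nm$comodulation * u, 0.05)
  }

  ids <- truth$cluster_id[mask]
  # noiseless runs: fall back to absolute amplitudes
  amp <- if (sd_band > 0) truth$coupling_amplitude * sd_band else
    truth$coupling_amplitude
  for (c_i in seq_along(amp)) {
    vox <- which(ids == c_i)
    if (length(vox) == 0L) next
    sig <- amp[c_i] * g * cos(phase_vol + truth$planted_delay[c_i])
    X[vox, ] <- X[vox, , drop = FALSE] +
      matrix(sig, length(vox), n_volumes, byrow = TRUE)
  }
  out <- bold_series(X, mask, tr = tr)
  attr(out, "coupling_gain") <- g
  attr(out, "realized_amplitude") <- amp
  out
}

#' Simulate a cohort of EGG + BOLD participants
#'
#' Participants share the planted coupling geometry but draw their own
#' gastric base frequency (uniformly within `base_freq_range`, matching
#' the spread of peak frequencies seen across healthy adults) and their
#' own noise realisations.  Per-participant seeds are derived
#' deterministically from the master seed.
#'
#' @param n_participants cohort size (default 30).
#' @param truth_template a [synthetic_truth()] shared by the cohort.
#' @param seed master integer seed.
#' @param base_freq_range numeric(2) Hz, default `c(0.041, 0.053)`.
#' @param tr repetition time (s).
#' @param n_volumes volumes per participant (default 450).
#' @param noise_model passed to [simulate_bold()].
#' @return object of class `gastro_cohort`: list with `participants`
#'   (each `list(egg, bold)`), `truth`, `seed`.
#' @export
make_cohort <- function(n_participants = 30,
                        truth_template = synthetic_truth(),
                        seed = 1L, base_freq_range = c(0.041, 0.053),
                        tr = 2, n_volumes = 450, noise_model = list()) {
  if (n_participants < 2L) stop("a cohort needs at least 2 participants")
  set.seed(seed)
  bf <- stats::runif(n_participants, base_freq_range[1], base_freq_range[2])
  seeds <- sample.int(2^30, 2 * n_participants)
  participants <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    p0 <- truth_template$egg_params
    params <- egg_sim_params(base_freq = bf[i],
                             freq_jitter_sd = p0$freq_jitter_sd,
                             freq_tau = p0$freq_tau,
                             amplitude = p0$amplitude,
                             n_channels = p0$n_channels,
                             channel_gains = p0$channel_gains,
                             noise_sd = p0$noise_sd, fs = p0$fs,
                             duration = p0$duration,
                             seed = seeds[2 * i - 1L])
    egg <- simulate_egg(params, tr = tr)
    bold <- simulate_bold(truth_template, egg, noise_model = noise_model,
                          tr = tr, n_volumes = n_volumes,
                          seed = seeds[2 * i])
    participants[[i]] <- list(egg = egg, bold = bold)
  }
  structure(list(participants = participants, truth = truth_template,
                 seed = seed, base_freqs = bf),
            class = "gastro_cohort")
}

#' @export
print.gastro_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d participants, grid %s, ",
                     "%d planted cluster(s)\n"),
              length(x$participants),
              paste(x$truth$grid_dim, collapse = "x"),
              length(x$truth$planted_delay)))
  invisible(x)
}
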