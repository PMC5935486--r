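# Internal signal-processing primitives shared by the EGG and BOLD paths.
# All matrix helpers take time along rows (T x n series); user-facing
# containers store voxels x T and transpose at the boundary.

as_time_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, ncol = 1L)
}

#' @noRd
pad_reflect <- function(X, n) {
  # odd (point-symmetric) reflection padding, as used by filtfilt-style
  # zero-phase filtering; keeps level and slope continuous at the edges
  Tn <- nrow(X)
  n <- min(n, Tn - 1L)
  if (n <= 0L) return(X)
  top <- 2 * X[rep(1L, n), , drop = FALSE] - X[seq(n + 1L, 2L), , drop = FALSE]
  bot <- 2 * X[rep(Tn, n), , drop = FALSE] - X[seq(Tn - 1L, Tn - n), , drop = FALSE]
  rbind(top, X, bot)
}

#' @noRd
filtfilt_iir <- function(b, a, X, pad = NULL) {
  # zero-phase (forward-backward) IIR filtering of each column of X
  X <- as_time_matrix(X)
  Tn <- nrow(X)
  if (is.null(pad)) pad <- min(Tn - 1L, 6L * max(length(a), length(b)))
  Xp <- pad_reflect(X, pad)
  one_pass <- function(M) {
    nb <- length(b)
    v <- stats::filter(M, b, method = "convolution", sides = 1)
    v <- as.matrix(v)
    # leading samples lost to the one-sided convolution: compute directly
    for (t in seq_len(min(nb - 1L, nrow(M)))) {
      k <- seq_len(t)
      v[t, ] <- colSums(M[t - k + 1L, , drop = FALSE] * b[k])
    }
    if (length(a) > 1L) {
      v <- stats::filter(v, -a[-1L] / a[1L], method = "recursive")
      v <- as.matrix(v) / a[1L]
    }
    v
  }
  Y <- one_pass(Xp)
  Y <- one_pass(Y[rev(seq_len(nrow(Y))), , drop = FALSE])
  Y <- Y[rev(seq_len(nrow(Y))), , drop = FALSE]
  n <- (nrow(Y) - Tn) / 2L
  Y[seq(n + 1L, n + Tn), , drop = FALSE]
}

#' @noRd
filtfilt_fir <- function(h, X) {
  # forward-backward application of a linear-phase FIR filter; for the
  # symmetric taps used here this equals one symmetric convolution with
  # conv(h, h), which is what is applied (single pass, zero phase)
  X <- as_time_matrix(X)
  Tn <- nrow(X)
  h2 <- stats::convolve(h, rev(h), type = "open")
  half <- (length(h2) - 1L) / 2L
  Xp <- pad_reflect(X, min(Tn - 1L, half + 1L))
  npad <- (nrow(Xp) - Tn) / 2L
  if (ncol(Xp) >= 16L) {
    # FFT overlap-free convolution (zero-padded), faster for many series
    nfull <- nrow(Xp) + length(h2) - 1L
    nf <- stats::nextn(nfull, 2)
    H <- stats::fft(c(h2, numeric(nf - length(h2))))
    Z <- stats::mvfft(rbind(Xp, matrix(0, nf - nrow(Xp), ncol(Xp))))
    Y <- Re(stats::mvfft(Z * H, inverse = TRUE)) / nf
    Y <- Y[seq(half + 1L, half + nrow(Xp)), , drop = FALSE]
  } else {
    Y <- as.matrix(stats::filter(Xp, h2, method = "convolution", sides = 2))
    # samples where the kernel overhangs the padded ends: zero-pad convention
    Y[is.na(Y)] <- 0
  }
  Y[seq(npad + 1L, npad + Tn), , drop = FALSE]
}

#' @noRd
gastric_fir <- function(center, half_width, fs) {
  # Window-design FIR bandpass around the gastric peak. The order is set
  # from the Hamming transition-width rule so that the response is flat
  # (< 1 dB ripple) over center +/- half_width and attenuated by >= 40 dB
  # at center +/- 3 * half_width.
  stopifnot(half_width > 0, fs > 0)
  if (fs <= 2 * (center + half_width)) {
    stop("gastric band [", center - half_width, ", ", center + half_width,
         "] Hz is not below the Nyquist frequency ", fs / 2, " Hz")
  }
  if (center <= half_width) {
    stop("centre frequency must exceed the filter half-width")
  }
  # transition narrows near the low band edge so the design stays
  # feasible for low gastric peaks (order grows accordingly)
  trans <- min(2 * half_width, center - half_width)
  lo <- center - half_width - trans / 2
  hi <- center + half_width + trans / 2
  if (lo <= 0 || hi >= fs / 2) {
    stop("filter band [", lo, ", ", hi, "] Hz falls outside (0, Nyquist)")
  }
  n <- ceiling(3.3 * fs / trans)
  if (n %% 2L == 1L) n <- n + 1L  # even order -> odd, symmetric tap count
  signal::fir1(n, c(lo, hi) / (fs / 2), type = "pass")
}

#' @noRd
analytic_matrix <- function(X) {
  # analytic signal (FFT one-sided doubling) of each column of X
  X <- as_time_matrix(X)
  Tn <- nrow(X)
  if (Tn < 4L) stop("series too short for analytic-signal extraction")
  F <- stats::mvfft(X)
  h <- numeric(Tn)
  if (Tn %% 2L == 0L) {
    h[1L] <- 1; h[Tn / 2L + 1L] <- 1; h[2L:(Tn / 2L)] <- 2
  } else {
    h[1L] <- 1; h[2L:((Tn + 1L) / 2L)] <- 2
  }
  stats::mvfft(F * h, inverse = TRUE) / Tn
}

#' @noRd
wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  w <- ((x + pi) %% (2 * pi)) - pi
  w[w == -pi] <- pi
  w
}

#' @noRd
hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' @noRd
segment_starts <- function(n_samples, win, step) {
  n_win <- floor((n_samples - win) / step) + 1L
  if (n_win < 1L) stop("series shorter than one analysis window")
  1L + (seq_len(n_win) - 1L) * step
}

#' Windowed complex spectra of a series
#'
#' Splits a series into overlapping segments, applies a Hann taper
#' (after per-segment linear detrending when `detrend = TRUE`) and
#' returns the complex DFT of every segment.  This is the estimation
#' backbone for both the Welch power spectrum and the windowed
#' coherence used for shared-variance estimates.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds.
#' @param overlap_s overlap between consecutive segments in seconds.
#' @param detrend remove a per-segment linear trend before tapering.
#' @return list with `freqs` (Hz, one-sided), `spectra` (complex matrix,
#'   frequencies x windows, scaled so a unit-amplitude sinusoid on a bin
#'   has modulus 1/2), `window_s`, `overlap_s`, `n_windows`.
#' @export
windowed_spectrum <- function(x, fs, window_s, overlap_s, detrend = TRUE) {
  stopifnot(is.numeric(x), fs > 0, window_s > 0, overlap_s >= 0)
  if (overlap_s >= window_s) stop("overlap must be smaller than the window")
  win <- round(window_s * fs)
  step <- round((window_s - overlap_s) * fs)
  if (win < 4L) stop("window shorter than 4 samples")
  starts <- segment_starts(length(x), win, step)
  w <- hann_window(win)
  segs <- vapply(starts, function(s) {
    seg <- x[s:(s + win - 1L)]
    if (detrend) seg <- stats::lsfit(seq_along(seg), seg)$residuals
    seg * w
  }, numeric(win))
  S <- stats::mvfft(as_time_matrix(segs)) / sum(w)
  nf <- floor(win / 2) + 1L
  list(freqs = (seq_len(nf) - 1L) * fs / win,
       spectra = S[seq_len(nf), , drop = FALSE],
       window_s = window_s, overlap_s = overlap_s,
       n_windows = length(starts))
}
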