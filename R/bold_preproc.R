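# BOLD voxel-series conditioning ahead of phase extraction. The order
# is fixed: polynomial detrend -> broadband bandpass -> nuisance
# regression -> gastric-band filter (same band as the EGG) -> trim.

#' Remove linear and quadratic trends from voxel time series
#'
#' Least-squares residual of each series on \{1, t, t^2\}.
#'
#' @param x numeric series or voxels x T matrix.
#' @return detrended series, same shape; constant series come back as
#'   zeros with a warning.
#' @export
detrend_poly2 <- function(x) {
  was_vec <- !is.matrix(x)
  X <- if (was_vec) matrix(x, nrow = 1L) else x
  Tn <- ncol(X)
  if (Tn < 3L) stop("need at least 3 time points to remove a quadratic trend")
  tt <- seq_len(Tn)
  M <- cbind(1, tt, tt^2)
  R <- t(qr.resid(qr(M), t(X)))
  cons <- apply(X, 1L, stats::sd) == 0
  if (any(cons)) {
    warning(sum(cons), " constant series detrended to zeros")
    R[cons, ] <- 0
  }
  if (was_vec) drop(R) else R
}

#' Broadband Butterworth bandpass for BOLD series
#'
#' Zero-phase (forward-backward) 4th-order Butterworth bandpass,
#' 0.01-0.1 Hz by default.  Series are demeaned before filtering so a
#' DC offset is removed exactly.
#'
#' @param x numeric series or voxels x T matrix.
#' @param tr repetition time in seconds.
#' @param band numeric(2) passband in Hz.
#' @return filtered series, same shape.
#' @export
bandpass_bold <- function(x, tr, band = c(0.01, 0.1)) {
  fs <- 1 / tr
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2]) {
    stop("band [", band[1], ", ", band[2], "] Hz invalid for Nyquist ",
         fs / 2, " Hz")
  }
  was_vec <- !is.matrix(x)
  X <- if (was_vec) matrix(x, nrow = 1L) else x
  mu <- rowMeans(X)
  bt <- signal::butter(4, band / (fs / 2), type = "pass")
  Y <- t(filtfilt_iir(bt$b, bt$a, t(X - mu)))
  if (was_vec) drop(Y) else Y
}

#' Regress nuisance series out of voxel time series
#'
#' OLS residual on the supplied regressors plus an intercept (e.g. the
#' mean signal of a CSF sphere).  Collinear columns are dropped with a
#' warning.
#'
#' @param x numeric series or voxels x T matrix.
#' @param regressors numeric vector or T x k matrix.
#' @return residual series, same shape as `x`.
#' @export
regress_nuisance <- function(x, regressors) {
  was_vec <- !is.matrix(x)
  X <- if (was_vec) matrix(x, nrow = 1L) else x
  R <- as_time_matrix(regressors)
  if (nrow(R) != ncol(X)) stop("regressor length must equal the series length")
  M <- cbind(1, R)
  qrM <- qr(M)
  if (qrM$rank < ncol(M)) {
    warning(ncol(M) - qrM$rank, " collinear regressor column(s) dropped")
    M <- M[, qrM$pivot[seq_len(qrM$rank)], drop = FALSE]
    qrM <- qr(M)
  }
  Y <- t(qr.resid(qrM, t(X)))
  if (was_vec) drop(Y) else Y
}

#' Discard volumes at both ends of a series
#'
#' Removes filter/transform transients: `n_trim` volumes (15 by
#' default, i.e. 30 s at TR 2 s) are dropped from each end, identically
#' for BOLD and EGG-derived series, leaving e.g. 420 of 450 volumes.
#'
#' @param x numeric vector, complex vector, or voxels x T matrix
#'   (time along columns / along the vector).
#' @param n_trim volumes removed per end.
#' @return trimmed series, same type.
#' @export
trim_series <- function(x, n_trim = 15) {
  n_trim <- as.integer(n_trim)
  if (n_trim == 0L) return(x)
  if (is.matrix(x)) {
    Tn <- ncol(x)
    if (Tn <= 2L * n_trim) stop("series too short to trim ", n_trim,
                                " volumes per end")
    x[, seq(n_trim + 1L, Tn - n_trim), drop = FALSE]
  } else {
    Tn <- length(x)
    if (Tn <= 2L * n_trim) stop("series too short to trim ", n_trim,
                                " volumes per end")
    x[seq(n_trim + 1L, Tn - n_trim)]
  }
}

#' Full BOLD conditioning chain
#'
#' Applies, in fixed order: quadratic detrend, broadband Butterworth
#' bandpass, optional nuisance regression, zero-phase gastric-band FIR
#' filter centred on the participant's gastric peak.  Returns the
#' untrimmed gastric-band series plus the applied-step record; phase
#' extraction and trimming happen downstream so the analytic transform
#' sees the padded series.
#'
#' @param bold a [bold_series()].
#' @param center gastric peak frequency in Hz.
#' @param half_width gastric filter half-width (Hz).
#' @param nuisance optional T x k regressor matrix or vector.
#' @param band broadband filter band (Hz).
#' @return a [bold_series()] whose `data` is gastric-band filtered;
#'   attribute `preproc_chain` lists the applied steps.
#' @export
preprocess_bold <- function(bold, center, half_width = 0.015,
                            nuisance = NULL, band = c(0.01, 0.1)) {
  stopifnot(inherits(bold, "bold_series"))
  steps <- c("detrend_poly2", "bandpass_bold")
  X <- detrend_poly2(bold$data)
  X <- bandpass_bold(X, tr = bold$tr, band = band)
  if (!is.null(nuisance)) {
    X <- regress_nuisance(X, nuisance)
    steps <- c(steps, "regress_nuisance")
  }
  fs <- 1 / bold$tr
  X <- t(filtfilt_fir(gastric_fir(center, half_width, fs), t(X)))
  steps <- c(steps, "gastric_band_filter")
  out <- bold_series(X, bold$mask, tr = bold$tr, affine = bold$affine)
  attr(out, "preproc_chain") <- list(steps = steps,
                                     band = c(center - half_width,
                                              center + half_width))
  out
}
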