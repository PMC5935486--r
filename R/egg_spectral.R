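#' Welch power spectral density
#'
#' Averaged modified periodogram (Hann taper, per-segment linear
#' detrend).  Power is scaled so that a pure sinusoid of amplitude
#' \eqn{A} whose frequency falls on a bin carries peak power
#' \eqn{A^2/2} — i.e. the units are the squared units of the input
#' (\eqn{\mu V^2} for an EGG in \eqn{\mu V}), not a density per Hz.
#' This matches the convention in which a gastric spectral peak is
#' required to exceed 15 \eqn{\mu V^2}.
#'
#' @param x numeric series.
#' @param fs sampling rate (Hz).
#' @param window_s segment length in seconds (default 200).
#' @param overlap_s segment overlap in seconds (default 150).
#' @param detrend remove per-segment linear trends (default TRUE).
#' @return list with `freqs` (Hz), `power` (one-sided), `n_windows`.
#' @examples
#' x <- 10 * cos(2 * pi * 0.05 * seq(0, 899.9, by = 0.1))
#' p <- welch_psd(x, fs = 10)
#' p$freqs[which.max(p$power)]   # 0.05
#' @export
welch_psd <- function(x, fs, window_s = 200, overlap_s = 150, detrend = TRUE) {
  if (length(x) < round(window_s * fs)) {
    stop("series shorter than one Welch window")
  }
  ws <- windowed_spectrum(x, fs, window_s, overlap_s, detrend = detrend)
  P <- Mod(ws$spectra)^2
  pw <- rowMeans(P)
  # one-sided scaling: double everything except DC (and Nyquist, even n)
  scale <- rep(2, length(pw))
  scale[1L] <- 1
  win <- round(window_s * fs)
  if (win %% 2L == 0L) scale[length(pw)] <- 1
  list(freqs = ws$freqs, power = pw * scale, n_windows = ws$n_windows)
}

#' @noRd
peak_prominence <- function(power, i) {
  # prominence of a local maximum within the supplied (in-band) profile:
  # height above the higher of the two deepest minima separating it from
  # the band edges or a higher peak
  n <- length(power)
  left <- if (i > 1L) min(power[1:(i - 1L)]) else power[i]
  right <- if (i < n) min(power[(i + 1L):n]) else power[i]
  power[i] - max(left, right)
}

#' Select the gastric spectral peak across EGG channels
#'
#' Scans each channel's Welch spectrum for the largest local maximum in
#' the normogastric band and applies the acceptance rule: the peak power
#' must exceed `power_floor` (otherwise the recording is rejected, as
#' done for participants without a well-defined gastric peak).  Among
#' passing channels, the most powerful channel is selected, unless
#' another passing channel has a peak more than twice as sharp
#' (prominence relative to median in-band power), in which case the
#' sharper channel wins.  `override` forces a specific channel,
#' mirroring manual channel selection.
#'
#' @param psd list of per-channel spectra as returned by [welch_psd()],
#'   or a single such list for one channel.
#' @param band numeric(2), normogastric frequency band in Hz.
#' @param power_floor minimum acceptable peak power (\eqn{\mu V^2}).
#' @param override optional channel index or label to force.
#' @param channel_labels optional character labels (defaults to
#'   `chan1..chanN`).
#' @return object of class `gastric_peak`: `channel`, `peak_freq`,
#'   `peak_power`, `band` (peak +/- 0.015 Hz by convention downstream),
#'   `selection_mode`, `sharpness`.
#' @export
select_gastric_peak <- function(psd, band = c(0.033, 0.066),
                                power_floor = 15, override = NULL,
                                channel_labels = NULL) {
  if (!is.null(psd$freqs)) psd <- list(psd)
  n_chan <- length(psd)
  if (n_chan < 1L) stop("at least one channel spectrum is required")
  if (is.null(channel_labels)) channel_labels <- paste0("chan", seq_len(n_chan))

  per_chan <- lapply(psd, function(p) {
    sel <- p$freqs >= band[1] & p$freqs <= band[2]
    if (sum(sel) < 1L) stop("no frequency bins inside the normogastric band")
    f <- p$freqs[sel]
    pw <- p$power[sel]
    # local maxima within the band (band-edge bins count as candidates)
    n <- length(pw)
    is_max <- rep(TRUE, n)
    if (n > 1L) {
      is_max[-1L] <- is_max[-1L] & (pw[-1L] >= pw[-n])
      is_max[-n] <- is_max[-n] & (pw[-n] >= pw[-1L])
    }
    if (!any(is_max)) return(NULL)
    cand <- which(is_max)
    i <- cand[which.max(pw[cand])]
    list(freq = f[i], power = pw[i],
         sharpness = peak_prominence(pw, i) / stats::median(pw))
  })

  powers <- vapply(per_chan, function(z) if (is.null(z)) -Inf else z$power, 0)
  sharps <- vapply(per_chan, function(z) if (is.null(z)) -Inf else z$sharpness, 0)
  passing <- which(powers > power_floor)

  if (!is.null(override)) {
    ch <- if (is.character(override)) match(override, channel_labels) else as.integer(override)
    if (is.na(ch) || ch < 1L || ch > n_chan) stop("override channel not found")
    if (!(ch %in% passing)) {
      stop("override channel has no in-band peak above ", power_floor, " uV^2")
    }
    mode <- "manual-override"
  } else {
    if (length(passing) == 0L) {
      stop("gastric peak not well defined: no channel has an in-band peak ",
           "above ", power_floor, " uV^2; recording rejected")
    }
    ch <- passing[which.max(powers[passing])]
    sharper <- passing[sharps[passing] > 2 * sharps[ch]]
    if (length(sharper) > 0L) ch <- sharper[which.max(sharps[sharper])]
    mode <- "auto"
  }

  pk <- per_chan[[ch]]
  structure(list(channel = channel_labels[ch],
                 channel_index = ch,
                 peak_freq = pk$freq,
                 peak_power = pk$power,
                 band = c(pk$freq - 0.015, pk$freq + 0.015),
                 sharpness = pk$sharpness,
                 selection_mode = mode),
            class = "gastric_peak")
}

#' @export
print.gastric_peak <- function(x, ...) {
  cat(sprintf("Gastric peak: %.4f Hz (%.1f uV^2) on %s [%s]\n",
              x$peak_freq, x$peak_power, x$channel, x$selection_mode))
  invisible(x)
}

#' Zero-phase FIR bandpass around the gastric peak
#'
#' Narrow linear-phase FIR bandpass (window design) applied without
#' phase distortion.  The filter order is chosen automatically so that
#' the response is flat (< 1 dB) over `center +/- half_width` and
#' attenuated by at least 40 dB at `center +/- 3 * half_width`; the
#' narrow band, rather than any particular order, is the contract.
#'
#' @param x numeric series or T x n matrix (series in columns).
#' @param fs sampling rate (Hz).
#' @param center centre frequency in Hz (the gastric peak).
#' @param half_width half band width in Hz (default 0.015).
#' @return filtered series, same shape as the input.
#' @export
bandpass_zero_phase <- function(x, fs, center, half_width = 0.015) {
  was_vec <- !is.matrix(x)
  h <- gastric_fir(center, half_width, fs)
  y <- filtfilt_fir(h, as_time_matrix(x))
  if (was_vec) drop(y) else y
}

#' Resample a series to one sample per BOLD volume
#'
#' Takes the (already narrowband) series at the volume-trigger sample
#' positions so that the EGG reference and the BOLD series share one
#' time base.  Without triggers, falls back to uniform decimation by
#' `fs * tr` with a warning.
#'
#' @param x numeric series sampled at `fs`.
#' @param fs input sampling rate (Hz).
#' @param tr BOLD repetition time in seconds (default 2).
#' @param trigger_index integer sample indices of volume onsets.
#' @return numeric series at `1/tr` Hz.
#' @export
downsample_to_tr <- function(x, fs, tr = 2, trigger_index = NULL) {
  if (is.null(trigger_index) || length(trigger_index) == 0L) {
    warning("no volume triggers supplied; uniform decimation by fs*tr")
    idx <- seq(1L, length(x), by = round(fs * tr))
  } else {
    idx <- round(trigger_index)
    if (any(idx < 1L) || any(idx > length(x))) {
      stop("volume triggers fall outside the recorded series")
    }
  }
  x[idx]
}
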