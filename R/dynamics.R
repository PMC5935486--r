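# Time-resolved coupling: sliding-window PLV, its relation to the BOLD
# amplitude envelope, and covariation of coupling across nodes.

#' Sliding-window phase-locking value
#'
#' PLV recomputed in a window slid along the series (60 s windows every
#' 10 s by default); the window count is
#' `floor((duration - window) / step) + 1`, and windows never cross the
#' series boundaries.
#'
#' @param phase_x,phase_y phase vectors in radians (or `phase_series`).
#' @param window_s window length in seconds (default 60).
#' @param step_s step between window onsets in seconds (default 10).
#' @param tr sampling interval in seconds.
#' @return object of class `sliding_plv`: list with `plv` (one value
#'   per window), `centers` (window centre times, s), `window_s`,
#'   `step_s`.
#' @export
sliding_plv <- function(phase_x, phase_y, window_s = 60, step_s = 10,
                        tr = 2) {
  if (inherits(phase_x, "phase_series")) phase_x <- phase_x$phase
  if (inherits(phase_y, "phase_series")) phase_y <- phase_y$phase
  if (length(phase_x) != length(phase_y)) stop("phase lengths differ")
  win <- round(window_s / tr)
  step <- round(step_s / tr)
  if (win < 2L) stop("window must span at least 2 samples")
  if (step < 1L) stop("step must be at least one sample")
  starts <- segment_starts(length(phase_x), win, step)
  z <- exp(1i * (phase_x - phase_y))
  pl <- vapply(starts, function(s) Mod(mean(z[s:(s + win - 1L)])), 0)
  structure(list(plv = pl,
                 centers = (starts - 1L) * tr + window_s / 2,
                 window_s = window_s, step_s = step_s),
            class = "sliding_plv")
}

#' Window-aggregated amplitude envelope
#'
#' Aggregates a Hilbert amplitude envelope over the same windows used
#' by [sliding_plv()] (mean by default, RMS optionally).
#'
#' @param amplitude envelope series.
#' @param window_s,step_s,tr window geometry as in [sliding_plv()].
#' @param agg `"mean"` or `"rms"`.
#' @return numeric vector, one value per window.
#' @export
window_amplitude <- function(amplitude, window_s = 60, step_s = 10,
                             tr = 2, agg = c("mean", "rms")) {
  agg <- match.arg(agg)
  win <- round(window_s / tr)
  step <- round(step_s / tr)
  starts <- segment_starts(length(amplitude), win, step)
  vapply(starts, function(s) {
    seg <- amplitude[s:(s + win - 1L)]
    if (agg == "mean") mean(seg) else sqrt(mean(seg^2))
  }, 0)
}

#' @noRd
fisher_z <- function(r) atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))

#' @noRd
safe_t_test <- function(z) {
  # one-sample t that tolerates zero spread (e.g. identical correlations)
  if (stats::sd(z) == 0) {
    if (mean(z) == 0) return(list(t = 0, p = 1, df = length(z) - 1L))
    return(list(t = sign(mean(z)) * Inf, p = 0, df = length(z) - 1L))
  }
  tt <- stats::t.test(z)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Correlation between time-varying PLV and BOLD amplitude
#'
#' Per participant, the Pearson correlation between the window PLV and
#' the window-aggregated amplitude envelope; at the group level, a
#' one-sample t test on the Fisher-z transformed correlations.
#'
#' @param plv_windows list (one per participant) of window-PLV vectors
#'   (or `sliding_plv` objects).
#' @param amp_windows list of window-amplitude vectors on the same
#'   window grid.
#' @return list with `r` (per participant), `t`, `p`, `df`,
#'   `mean_z`.
#' @export
plv_amplitude_corr <- function(plv_windows, amp_windows) {
  stopifnot(length(plv_windows) == length(amp_windows))
  r <- mapply(function(pl, am) {
    if (inherits(pl, "sliding_plv")) pl <- pl$plv
    if (length(pl) != length(am)) stop("window grids differ")
    if (length(pl) < 3L) stop("need at least 3 windows")
    if (stats::sd(am) == 0) stop("constant amplitude: correlation undefined")
    stats::cor(pl, am)
  }, plv_windows, amp_windows)
  z <- fisher_z(r)
  tt <- safe_t_test(z)
  list(r = r, t = tt$t, p = tt$p, df = tt$df, mean_z = mean(z))
}

#' Covariation of time-varying coupling across nodes
#'
#' Pearson correlation between the window-PLV series of every node
#' pair, per participant; Fisher-z one-sample t tests per pair with
#' Bonferroni correction over pairs, and an overall test on each
#' participant's mean z across pairs.
#'
#' @param plv_by_node list (one per participant) of windows x nodes
#'   matrices of window PLV.
#' @return list with `r` (participants x pairs matrix), `pairs`
#'   (2-column index matrix), `pair_t`, `pair_p_bonf`, `overall_t`,
#'   `overall_p`.
#' @export
cross_node_covariation <- function(plv_by_node) {
  K <- ncol(plv_by_node[[1L]])
  if (K < 2L) stop("need at least 2 nodes")
  pairs <- t(utils::combn(K, 2L))
  r <- t(vapply(plv_by_node, function(M) {
    apply(pairs, 1L, function(pr) stats::cor(M[, pr[1L]], M[, pr[2L]]))
  }, numeric(nrow(pairs))))
  if (nrow(pairs) == 1L) r <- matrix(r, ncol = 1L)
  z <- fisher_z(r)
  pair_t <- apply(z, 2L, function(col) safe_t_test(col)$t)
  pair_p <- apply(z, 2L, function(col) safe_t_test(col)$p)
  ov <- safe_t_test(rowMeans(z))
  list(r = r, pairs = pairs, pair_t = pair_t,
       pair_p_bonf = pmin(1, pair_p * nrow(pairs)),
       overall_t = ov$t, overall_p = ov$p)
}
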