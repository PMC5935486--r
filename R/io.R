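#' EGG recording container
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector.
#' @param trigger_index integer sample indices of BOLD volume onsets
#'   (may be empty when no scanner triggers were recorded).
#' @return object of class `egg_recording`.
#' @export
egg_recording <- function(data, fs, channel_labels = NULL,
                          trigger_index = integer(0)) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), fs > 0)
  if (is.null(channel_labels)) channel_labels <- paste0("chan", seq_len(nrow(data)))
  stopifnot(length(channel_labels) == nrow(data))
  trigger_index <- as.integer(trigger_index)
  if (length(trigger_index) &&
      (min(trigger_index) < 1L || max(trigger_index) > ncol(data))) {
    stop("trigger indices outside the recording")
  }
  structure(list(data = data, fs = fs, channel_labels = channel_labels,
                 trigger_index = trigger_index),
            class = "egg_recording")
}

#' @export
print.egg_recording <- function(x, ...) {
  cat(sprintf("EGG recording: %d channel(s), %.1f s at %g Hz, %d triggers\n",
              nrow(x$data), ncol(x$data) / x$fs, x$fs, length(x$trigger_index)))
  invisible(x)
}

#' Write an EGG recording as TSV
#'
#' Columns: `time_s`, one column per channel, and `volume_trigger`
#' (1 at volume-onset samples, else 0).
#'
#' @param egg an [egg_recording()].
#' @param path output file path.
#' @export
write_egg_tsv <- function(egg, path) {
  n <- ncol(egg$data)
  trig <- integer(n)
  trig[egg$trigger_index] <- 1L
  df <- data.table::data.table(time_s = (seq_len(n) - 1L) / egg$fs)
  for (i in seq_len(nrow(egg$data))) df[[egg$channel_labels[i]]] <- egg$data[i, ]
  df$volume_trigger <- trig
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read an EGG recording from TSV
#'
#' Expects a `time_s` column (uniform steps, used to infer the sampling
#' rate), one column per channel and optionally a `volume_trigger`
#' column; a missing trigger column yields an empty trigger index with
#' a warning.
#'
#' @param path TSV file path.
#' @return an [egg_recording()].
#' @export
read_egg_tsv <- function(path) {
  if (!file.exists(path)) stop("EGG file not found: ", path)
  df <- data.table::fread(path, sep = "\t")
  if (!"time_s" %in% names(df)) stop("EGG TSV lacks a time_s column")
  tm <- df$time_s
  if (length(tm) < 3L) stop("EGG TSV too short")
  dt <- diff(tm)
  if (any(dt <= 0)) stop("time_s is not strictly increasing")
  if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
    stop("time_s steps are non-uniform beyond 1%")
  }
  fs <- 1 / stats::median(dt)
  chan_cols <- setdiff(names(df), c("time_s", "volume_trigger"))
  if (length(chan_cols) == 0L) stop("EGG TSV has no channel columns")
  if ("volume_trigger" %in% names(df)) {
    trig <- which(df$volume_trigger > 0)
  } else {
    warning("no volume_trigger column; triggers left empty")
    trig <- integer(0)
  }
  egg_recording(t(as.matrix(df[, chan_cols, with = FALSE])), fs = fs,
                channel_labels = chan_cols, trigger_index = trig)
}

#' BOLD series container (masked voxel x time matrix)
#'
#' @param data voxels x T numeric matrix, rows ordered as `which(mask)`
#'   (column-major over the 3D grid).
#' @param mask 3D logical array (the brain mask).
#' @param tr repetition time in seconds.
#' @param affine 4x4 voxel-to-world matrix (defaults to 3 mm isotropic).
#' @return object of class `bold_series`.
#' @export
bold_series <- function(data, mask, tr, affine = NULL) {
  data <- as.matrix(data)
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, tr > 0)
  if (nrow(data) != sum(mask)) {
    stop("data rows (", nrow(data), ") do not match mask voxel count (",
         sum(mask), ")")
  }
  if (ncol(data) < 60L) stop("BOLD series must have at least 60 volumes")
  if (anyNA(data)) stop("NaN/NA values inside the mask")
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  structure(list(data = data, mask = mask, dim = dim(mask),
                 tr = tr, affine = affine),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("BOLD series: %d voxels x %d volumes (TR %g s, grid %s)\n",
              nrow(x$data), ncol(x$data), x$tr,
              paste(x$dim, collapse = "x")))
  invisible(x)
}

#' @noRd
nifti_from_array <- function(arr, affine, tr = NULL) {
  img <- RNifti::asNifti(arr)
  vx <- sqrt(colSums(affine[1:3, 1:3]^2))
  pd <- if (length(dim(arr)) == 4L && !is.null(tr)) c(vx, tr) else vx
  RNifti::pixdim(img) <- pd
  img
}

#' Write a masked 4D BOLD series (plus its mask) as NIfTI-1
#'
#' @param bold a [bold_series()].
#' @param path output 4D NIfTI path.
#' @param mask_path optional path for the binary mask volume.
#' @export
write_bold_nifti <- function(bold, path, mask_path = NULL) {
  arr <- array(0, c(bold$dim, ncol(bold$data)))
  idx <- which(bold$mask)
  nvox <- prod(bold$dim)
  for (t in seq_len(ncol(bold$data))) {
    arr[idx + (t - 1L) * nvox] <- bold$data[, t]
  }
  RNifti::writeNifti(nifti_from_array(arr, bold$affine, bold$tr), path,
                     datatype = "float")
  if (!is.null(mask_path)) {
    RNifti::writeNifti(nifti_from_array(array(as.integer(bold$mask), bold$dim),
                                        bold$affine), mask_path,
                       datatype = "uint8")
  }
  invisible(path)
}

#' Read a 4D BOLD NIfTI plus mask into a masked voxel x time matrix
#'
#' The repetition time is taken from the 4th pixdim entry of the header.
#'
#' @param path 4D NIfTI file.
#' @param mask_path binary mask NIfTI on the same grid.
#' @param tr optional TR override (seconds) when the header is missing it.
#' @return a [bold_series()].
#' @export
read_bold_nifti <- function(path, mask_path, tr = NULL) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L) stop("expected a 4D NIfTI, got ",
                                   length(dim(img)), "D")
  msk <- RNifti::readNifti(mask_path)
  if (!all(dim(msk)[1:3] == dim(img)[1:3])) {
    stop("mask grid ", paste(dim(msk), collapse = "x"),
         " does not match BOLD grid ", paste(dim(img)[1:3], collapse = "x"))
  }
  mask <- array(as.array(msk) > 0, dim(img)[1:3])
  if (!any(mask)) stop("mask contains no voxels")
  if (is.null(tr)) {
    pd <- RNifti::pixdim(img)
    if (length(pd) >= 4L && pd[4] > 0) tr <- pd[4] else
      stop("TR not present in NIfTI header; pass tr explicitly")
  }
  arr <- as.array(img)
  nvox <- prod(dim(img)[1:3])
  idx <- which(mask)
  Tn <- dim(img)[4]
  data <- matrix(0, length(idx), Tn)
  for (t in seq_len(Tn)) data[, t] <- arr[idx + (t - 1L) * nvox]
  aff <- tryCatch(structure(RNifti::xform(img), dimnames = NULL),
                  error = function(e) diag(c(3, 3, 3, 1)))
  bold_series(data, mask, tr = tr, affine = aff)
}

#' Write a per-voxel statistic map as 3D NIfTI
#'
#' @param values numeric vector, one value per in-mask voxel (order of
#'   `which(mask)`).
#' @param mask 3D logical array.
#' @param path output path.
#' @param affine 4x4 voxel-to-world matrix.
#' @param background value outside the mask (0 by default, or NA).
#' @export
write_stat_map <- function(values, mask, path, affine = NULL,
                           background = 0) {
  if (length(values) != sum(mask)) {
    stop("values length (", length(values),
         ") does not match mask voxel count (", sum(mask), ")")
  }
  if (is.null(affine)) affine <- diag(c(3, 3, 3, 1))
  arr <- array(background, dim(mask))
  arr[which(mask)] <- values
  RNifti::writeNifti(nifti_from_array(arr, affine), path, datatype = "float")
  invisible(path)
}

#' Read a 3D statistic map back to an in-mask vector
#'
#' @param path 3D NIfTI file.
#' @param mask 3D logical array on the same grid.
#' @export
read_stat_map <- function(path, mask) {
  img <- RNifti::readNifti(path)
  if (!all(dim(img)[1:3] == dim(mask))) stop("map grid does not match mask")
  as.array(img)[which(mask)]
}

#' Analysis configuration
#'
#' Houses the fixed constants of the analysis: the normogastric search
#' band, the gastric filter half-width, the surrogate minimum shift, the
#' voxel- and cluster-level thresholds, the permutation count, the
#' sliding-window geometry, trimming, and the BOLD broadband filter.
#'
#' @param normogastric_band numeric(2) Hz, default `c(0.033, 0.066)`.
#' @param half_width gastric filter half-width in Hz (0.015).
#' @param power_floor minimum gastric peak power in uV^2 (15).
#' @param min_shift minimum surrogate time shift in seconds (60).
#' @param voxel_p first-level two-sided voxel threshold (0.01).
#' @param cluster_alpha cluster-level Monte-Carlo threshold (0.05).
#' @param n_perm number of label permutations (10000).
#' @param plv_window,plv_step sliding-window PLV geometry, seconds (60, 10).
#' @param n_trim volumes discarded at each end (15).
#' @param bold_band broadband BOLD filter in Hz (`c(0.01, 0.1)`).
#' @param connectivity cluster neighbourhood: 6, 18 or 26.
#' @param coh_window,coh_overlap coherence window/overlap, seconds (120, 20).
#' @param welch_window,welch_overlap EGG Welch geometry, seconds (200, 150).
#' @param seed optional integer seed recorded with results.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(normogastric_band = c(0.033, 0.066),
                       half_width = 0.015, power_floor = 15,
                       min_shift = 60, voxel_p = 0.01,
                       cluster_alpha = 0.05, n_perm = 10000,
                       plv_window = 60, plv_step = 10, n_trim = 15,
                       bold_band = c(0.01, 0.1), connectivity = 26,
                       coh_window = 120, coh_overlap = 20,
                       welch_window = 200, welch_overlap = 150,
                       seed = NULL) {
  stopifnot(normogastric_band[1] < normogastric_band[2],
            voxel_p > 0, voxel_p < 1,
            cluster_alpha > 0, cluster_alpha < 1,
            connectivity %in% c(6, 18, 26))
  structure(list(normogastric_band = normogastric_band,
                 half_width = half_width, power_floor = power_floor,
                 min_shift = min_shift, voxel_p = voxel_p,
                 cluster_alpha = cluster_alpha, n_perm = n_perm,
                 plv_window = plv_window, plv_step = plv_step,
                 n_trim = n_trim, bold_band = bold_band,
                 connectivity = connectivity,
                 coh_window = coh_window, coh_overlap = coh_overlap,
                 welch_window = welch_window, welch_overlap = welch_overlap,
                 seed = seed),
            class = "run_config")
}

#' Write / read a run configuration as YAML
#' @param config a [run_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}
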