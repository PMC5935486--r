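# Mid-level per-participant and cohort orchestration shared by the
# main pipeline and the control analyses.

#' Gastric peak of an EGG recording
#'
#' Welch spectra of every channel followed by the peak-selection rule.
#'
#' @param egg an [egg_recording()].
#' @param config a [run_config()].
#' @param override optional channel index/label forcing the selection.
#' @return a `gastric_peak`.
#' @export
egg_peak <- function(egg, config = run_config(), override = NULL) {
  psd <- lapply(seq_len(nrow(egg$data)), function(ch) {
    welch_psd(egg$data[ch, ], fs = egg$fs,
              window_s = config$welch_window,
              overlap_s = config$welch_overlap)
  })
  select_gastric_peak(psd, band = config$normogastric_band,
                      power_floor = config$power_floor,
                      override = override,
                      channel_labels = egg$channel_labels)
}

#' Gastric-band EGG phase reference at the BOLD sampling rate
#'
#' Bandpass-filters the selected EGG channel around the gastric peak
#' (zero phase), resamples it at the volume triggers, extracts the
#' analytic phase and amplitude on the padded series, and trims.
#'
#' @param egg an [egg_recording()].
#' @param peak a `gastric_peak` (from [egg_peak()]).
#' @param config a [run_config()].
#' @param center_offset optional frequency offset in Hz added to the
#'   peak frequency (used by the frequency-specificity control).
#' @return list with `phase`, `amplitude` (length T - 2 * n_trim),
#'   `center`, `series` (trimmed gastric-band series).
#' @export
egg_phase_series <- function(egg, peak, config = run_config(),
                             center_offset = 0) {
  center <- peak$peak_freq + center_offset
  x <- bandpass_zero_phase(egg$data[peak$channel_index, ], egg$fs,
                           center, config$half_width)
  tr <- if (length(egg$trigger_index) > 1L) {
    stats::median(diff(egg$trigger_index)) / egg$fs
  } else 2
  xd <- downsample_to_tr(x, egg$fs, tr = tr,
                         trigger_index = egg$trigger_index)
  ap <- analytic_phase(xd)
  list(phase = trim_series(ap$phase, config$n_trim),
       amplitude = trim_series(ap$amplitude, config$n_trim),
       center = center,
       series = trim_series(xd, config$n_trim))
}

#' Gastric-band BOLD phases for one participant
#'
#' Runs the conditioning chain ([preprocess_bold()]) at the given
#' centre frequency, extracts analytic phases on the padded series and
#' trims.
#'
#' @param bold a [bold_series()].
#' @param center gastric centre frequency (Hz).
#' @param config a [run_config()].
#' @param nuisance optional nuisance regressors (T x k).
#' @return list with `phase`, `amplitude` (voxels x trimmed T).
#' @export
bold_phase_series <- function(bold, center, config = run_config(),
                              nuisance = NULL) {
  bp <- preprocess_bold(bold, center, half_width = config$half_width,
                        nuisance = nuisance, band = config$bold_band)
  ap <- analytic_phase(bp$data)
  list(phase = trim_series(ap$phase, config$n_trim),
       amplitude = trim_series(ap$amplitude, config$n_trim))
}

#' Empirical, chance and coupling-strength maps for one participant
#'
#' @param egg an [egg_recording()].
#' @param bold a [bold_series()].
#' @param config a [run_config()].
#' @param peak optional precomputed `gastric_peak`.
#' @param center_offset frequency offset in Hz (both EGG and BOLD are
#'   refiltered at `peak + offset`).
#' @param nuisance optional nuisance regressors.
#' @param participant_id identifier stored with the maps.
#' @return a [coupling_strength_map()] result; attributes `egg_phase`
#'   and `bold_phase` carry the trimmed phase series.
#' @export
participant_coupling <- function(egg, bold, config = run_config(),
                                 peak = NULL, center_offset = 0,
                                 nuisance = NULL, participant_id = NA) {
  if (is.null(peak)) peak <- egg_peak(egg, config)
  ep <- egg_phase_series(egg, peak, config, center_offset)
  bp <- bold_phase_series(bold, ep$center, config, nuisance)
  emp <- empirical_plv_map(bp$phase, ep$phase)
  offs <- surrogate_offsets(length(ep$phase), bold$tr, config$min_shift)
  ch <- chance_plv_map(bp$phase, ep$phase, offs)
  maps <- coupling_strength_map(emp, ch$chance, participant_id)
  attr(maps, "egg_phase") <- ep
  attr(maps, "bold_phase") <- bp$phase
  attr(maps, "bold_amplitude") <- bp$amplitude
  attr(maps, "peak") <- peak
  maps
}

#' Full group analysis of a cohort
#'
#' Per-participant coupling maps followed by the group cluster test.
#'
#' @param cohort a `gastro_cohort` (from [make_cohort()]) or a list of
#'   `list(egg, bold)` participants.
#' @param config a [run_config()].
#' @param seed RNG seed for the permutation null.
#' @param keep_phases keep per-participant phase series in the result
#'   (needed for node-level follow-ups; default TRUE).
#' @return list with `maps` (per participant), `result`
#'   (a `group_cluster_result`), `mask`, `config`.
#' @export
analyze_cohort <- function(cohort, config = run_config(), seed = 1L,
                           keep_phases = TRUE) {
  parts <- if (inherits(cohort, "gastro_cohort")) cohort$participants else cohort
  mask <- parts[[1L]]$bold$mask
  maps <- lapply(seq_along(parts), function(i) {
    m <- participant_coupling(parts[[i]]$egg, parts[[i]]$bold, config,
                              participant_id = i)
    if (!keep_phases) {
      attr(m, "bold_phase") <- NULL
      attr(m, "bold_amplitude") <- NULL
    }
    m
  })
  res <- group_cluster_test(maps, mask = mask, n_perm = config$n_perm,
                            voxel_p = config$voxel_p,
                            alpha = config$cluster_alpha,
                            connectivity = config$connectivity,
                            seed = seed)
  list(maps = maps, result = res, mask = mask, config = config)
}
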