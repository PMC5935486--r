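# Robustness controls: frequency specificity, group-level
# false-positive calibration, EGG-swap chance level, and confound
# correlations.

#' Frequency-specificity scan
#'
#' Refilters both the EGG and the BOLD series at frequencies offset
#' from each participant's gastric peak, reruns the coupling and the
#' voxelwise paired t map, and summarises each offset by the sum of
#' |t| over the whole brain (or over a supplied network mask).  With
#' genuine gastric coupling the curve peaks at offset 0.
#'
#' @param cohort a `gastro_cohort` or list of `list(egg, bold)`.
#' @param offsets numeric vector of offsets in Hz; must include 0.
#' @param config a [run_config()].
#' @param network_voxels optional indices (into the in-mask vector)
#'   restricting the summary to a network.
#' @return data.frame with columns `offset_hz` and `sum_abs_t`
#'   (NA for offsets skipped because the band left the broadband
#'   filter range).
#' @export
frequency_offset_scan <- function(cohort, offsets = c(-0.02, -0.015, -0.01,
                                                      -0.005, 0, 0.005,
                                                      0.01, 0.015, 0.02),
                                  config = run_config(),
                                  network_voxels = NULL) {
  if (!any(offsets == 0)) stop("offsets must include 0")
  parts <- if (inherits(cohort, "gastro_cohort")) cohort$participants else cohort
  peaks <- lapply(parts, function(p) egg_peak(p$egg, config))
  out <- vapply(offsets, function(off) {
    centers <- vapply(peaks, function(pk) pk$peak_freq + off, 0)
    lo <- min(centers) - config$half_width
    hi <- max(centers) + config$half_width
    if (lo < config$bold_band[1] || hi > config$bold_band[2]) {
      warning("offset ", off, " Hz pushes the band outside [",
              config$bold_band[1], ", ", config$bold_band[2],
              "] Hz; skipped")
      return(NA_real_)
    }
    maps <- lapply(seq_along(parts), function(i) {
      participant_coupling(parts[[i]]$egg, parts[[i]]$bold, config,
                           peak = peaks[[i]], center_offset = off,
                           participant_id = i)
    })
    t_map <- suppressWarnings(paired_t_map(maps))
    if (!is.null(network_voxels)) t_map <- t_map[network_voxels]
    sum(abs(t_map))
  }, 0)
  data.frame(offset_hz = offsets, sum_abs_t = out)
}

#' Group-level time-shift null of the summary statistic
#'
#' Draws surrogate cohorts in which each participant's EGG phase is
#' circularly shifted by a random admissible offset, recomputes the
#' voxelwise paired t map against the standard chance level, and
#' records the whole-brain sum of |t|.  The empirical summary is
#' referred to this distribution.
#'
#' @param cohort_maps list of [participant_coupling()] results carrying
#'   `egg_phase` and `bold_phase` attributes (e.g. `analyze_cohort()$maps`).
#' @param n_datasets surrogate cohorts to draw (default 1000; >= 50).
#' @param config a [run_config()].
#' @param seed RNG seed.
#' @param tr sampling interval of the trimmed series in seconds.
#' @return list with `null` (surrogate summaries), `empirical`,
#'   `p` (with the +1 correction).
#' @export
group_timeshift_null <- function(cohort_maps, n_datasets = 1000,
                                 config = run_config(), seed = 1L,
                                 tr = 2) {
  if (n_datasets < 50L) stop("n_datasets must be at least 50")
  P <- length(cohort_maps)
  unit_vox <- lapply(cohort_maps, function(m) {
    bp <- attr(m, "bold_phase")
    if (is.null(bp)) stop("cohort maps must carry bold_phase attributes")
    exp(1i * bp)
  })
  unit_egg <- lapply(cohort_maps, function(m) {
    exp(-1i * attr(m, "egg_phase")$phase)
  })
  Tn <- length(unit_egg[[1L]])
  offs <- surrogate_offsets(Tn, tr = tr, min_shift = config$min_shift)
  chance <- do.call(rbind, lapply(cohort_maps, function(m) m$chance_plv))
  emp <- do.call(rbind, lapply(cohort_maps, function(m) m$empirical_plv))
  empirical <- sum(abs(suppressWarnings(paired_t_map(emp, chance))))
  set.seed(seed)
  null <- vapply(seq_len(n_datasets), function(d) {
    sh <- sample(offs, P, replace = TRUE)
    surr <- do.call(rbind, lapply(seq_len(P), function(i) {
      e <- unit_egg[[i]]
      es <- c(e[(Tn - sh[i] + 1L):Tn], e[seq_len(Tn - sh[i])])
      Mod(unit_vox[[i]] %*% es)[, 1L] / Tn
    }))
    sum(abs(suppressWarnings(paired_t_map(surr, chance))))
  }, 0)
  list(null = null, empirical = empirical,
       p = (1 + sum(null >= empirical)) / (n_datasets + 1))
}

#' EGG-swap chance level
#'
#' Alternative chance estimate: each participant's BOLD phases are
#' compared against every other participant's EGG phase, and the
#' chance PLV is the median over those swap surrogates.  Feeds the same
#' group cluster test as the time-shift chance level.
#'
#' @param cohort_maps list of [participant_coupling()] results with
#'   phase attributes.
#' @param mask 3D logical array.
#' @param config a [run_config()].
#' @param seed RNG seed for the cluster permutation.
#' @return list with `chance` (participants x voxels), `result`
#'   (a `group_cluster_result`).
#' @export
egg_swap_chance <- function(cohort_maps, mask, config = run_config(),
                            seed = 1L) {
  P <- length(cohort_maps)
  if (P < 3L) stop("EGG swap needs at least 3 participants")
  egg_unit <- lapply(cohort_maps, function(m) {
    exp(-1i * attr(m, "egg_phase")$phase)
  })
  lens <- vapply(egg_unit, length, 0L)
  Tn <- min(lens)
  if (any(lens != Tn)) {
    warning("EGG phase lengths differ; truncating all to ", Tn, " samples")
    egg_unit <- lapply(egg_unit, function(e) e[seq_len(Tn)])
  }
  emp <- do.call(rbind, lapply(cohort_maps, function(m) m$empirical_plv))
  chance <- do.call(rbind, lapply(seq_len(P), function(i) {
    vox <- exp(1i * attr(cohort_maps[[i]], "bold_phase")[, seq_len(Tn),
                                                         drop = FALSE])
    others <- setdiff(seq_len(P), i)
    S <- vapply(others, function(q) Mod(vox %*% egg_unit[[q]])[, 1L] / Tn,
                numeric(nrow(vox)))
    apply(S, 1L, stats::median)
  }))
  res <- group_cluster_test(emp, chance, mask = mask,
                            n_perm = config$n_perm,
                            voxel_p = config$voxel_p,
                            alpha = config$cluster_alpha,
                            connectivity = config$connectivity, seed = seed)
  list(chance = chance, result = res)
}

#' Voxelwise confound-coupling correlations
#'
#' For a per-voxel confound map (e.g. gastric-band BOLD power or a
#' motion-susceptibility map), correlates the confound with coupling
#' strength across voxels within each participant, then tests the
#' Fisher-z correlations against zero at the group level.  For a
#' per-participant scalar confound (e.g. EGG peak power), correlates
#' the scalar with each node's coupling across participants.
#'
#' @param coupling list (per participant) of coupling-strength vectors,
#'   or a participants x nodes matrix for scalar confounds.
#' @param confound list of per-voxel confound vectors (voxelwise mode)
#'   or a per-participant numeric vector (scalar mode).
#' @return voxelwise mode: list with `r`, `t`, `p`, `mean_z`.
#'   Scalar mode: list with per-node `r` and `p`.
#' @export
confound_correlations <- function(coupling, confound) {
  if (is.list(confound)) {
    stopifnot(length(coupling) == length(confound))
    r <- mapply(function(cs, cf) {
      if (inherits(cs, "coupling_maps")) cs <- cs$coupling_strength
      stats::cor(cs, cf)
    }, coupling, confound)
    z <- fisher_z(r)
    tt <- safe_t_test(z)
    list(mode = "voxelwise", r = r, t = tt$t, p = tt$p, mean_z = mean(z))
  } else {
    M <- if (is.matrix(coupling)) coupling else do.call(rbind, coupling)
    stopifnot(nrow(M) == length(confound))
    tests <- apply(M, 2L, function(col) {
      ct <- stats::cor.test(col, confound)
      c(r = unname(ct$estimate), p = ct$p.value)
    })
    list(mode = "scalar", r = tests["r", ], p = tests["p", ])
  }
}
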