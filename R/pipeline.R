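# End-to-end orchestration: simulate or load a cohort, run the full
# coupling/cluster/node/dynamics analysis, and write results plus a
# reproducibility manifest.

#' Node-level follow-up of a group cluster result
#'
#' For every significant cluster: lock angle and relative angle per
#' participant, between-participant phase-delay consistency, shared
#' variance with the EGG, and the Watson-Williams test of equal mean
#' directions across nodes.
#'
#' @param analysis output of [analyze_cohort()] (phases kept).
#' @param cohort the cohort the analysis was run on.
#' @param min_size smallest cluster size to follow up (default 1).
#' @return list with `nodes` (per-node summaries), `angles`
#'   (participants x nodes relative angles), `consistency`,
#'   `watson_williams`, `shared_variance` (participants x nodes).
#' @export
node_summaries <- function(analysis, cohort, min_size = 1L) {
  parts <- if (inherits(cohort, "gastro_cohort")) cohort$participants else cohort
  sig <- Filter(function(cl) cl$significant && cl$size >= min_size,
                analysis$result$clusters)
  if (length(sig) == 0L) {
    return(list(nodes = list(), angles = NULL, consistency = NULL,
                watson_williams = NULL, shared_variance = NULL))
  }
  P <- length(parts)
  K <- length(sig)
  config <- analysis$config
  lock <- matrix(NA_real_, P, K)
  shared <- matrix(NA_real_, P, K)
  for (p in seq_len(P)) {
    bp <- attr(analysis$maps[[p]], "bold_phase")
    ep <- attr(analysis$maps[[p]], "egg_phase")
    pk <- attr(analysis$maps[[p]], "peak")
    node_phase <- do.call(rbind, lapply(sig, function(cl) {
      # circular mean of voxel phasors within the cluster
      Arg(colMeans(exp(1i * bp[cl$voxels, , drop = FALSE])))
    }))
    ang <- phase_angles(node_phase, ep$phase)
    lock[p, ] <- ang$lock_angle
    # shared variance on full-band (broadband-filtered) node series
    bb <- detrend_poly2(parts[[p]]$bold$data[unlist(lapply(sig, `[[`,
                                                           "voxels")), ,
                                             drop = FALSE])
    bb <- bandpass_bold(bb, tr = parts[[p]]$bold$tr, band = config$bold_band)
    sizes <- vapply(sig, `[[`, 0L, "size")
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    egg_full <- trim_series(downsample_to_tr(
      parts[[p]]$egg$data[pk$channel_index, ], parts[[p]]$egg$fs,
      tr = parts[[p]]$bold$tr,
      trigger_index = parts[[p]]$egg$trigger_index), config$n_trim)
    for (k in seq_len(K)) {
      node_full <- trim_series(colMeans(bb[starts[k]:stops[k], ,
                                           drop = FALSE]), config$n_trim)
      shared[p, k] <- shared_variance_coherence(
        egg_full, node_full, pk$peak_freq, fs = 1 / parts[[p]]$bold$tr,
        window_s = config$coh_window,
        overlap_s = config$coh_overlap)$shared_variance
    }
  }
  # relative angles recomputed per participant against the node mean
  rel <- t(apply(lock, 1L, function(lk) {
    wrap_angle(lk - Arg(mean(exp(1i * lk))))
  }))
  if (K == 1L) rel <- matrix(rel, ncol = 1L)
  cons <- angle_consistency(rel)
  ww <- if (K >= 2L) {
    watson_williams(as.vector(rel), rep(seq_len(K), each = P))
  } else NULL
  nodes <- lapply(seq_len(K), function(k) {
    list(node_id = k, voxels = sig[[k]]$voxels, size = sig[[k]]$size,
         sum_t = sig[[k]]$sum_t, monte_carlo_p = sig[[k]]$monte_carlo_p,
         mean_relative_angle = Arg(mean(exp(1i * rel[, k]))),
         consistency = cons[k],
         shared_variance = mean(shared[, k]))
  })
  list(nodes = nodes, angles = rel, consistency = cons,
       watson_williams = ww, shared_variance = shared)
}

#' Run the full gastric-network pipeline
#'
#' Orchestrates: gastric peak detection, EGG/BOLD conditioning,
#' voxelwise PLV and chance level, group cluster inference, node
#' summaries, and sliding-window dynamics, writing NIfTI/JSON/CSV
#' outputs and a manifest to `out_dir`.  Re-running with the same
#' seed reproduces the results.
#'
#' @param out_dir output directory (created if needed).
#' @param cohort a `gastro_cohort` or list of `list(egg, bold)`; if
#'   `NULL`, a synthetic cohort is simulated.
#' @param config a [run_config()].
#' @param simulate list of arguments for [make_cohort()] used when
#'   `cohort` is NULL (e.g. `list(n_participants = 12)`).
#' @param seed master RNG seed.
#' @return (invisibly) list with `analysis`, `nodes`, `dynamics`,
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, cohort = NULL, config = run_config(),
                         simulate = list(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(cohort)) {
      cohort <- do.call(make_cohort, utils::modifyList(list(seed = seed),
                                                       simulate))
    }
    stage <- "analyze_cohort"
    analysis <- analyze_cohort(cohort, config, seed = seed)
    stage <- "node_summaries"
    nodes <- node_summaries(analysis, cohort)
    stage <- "dynamics"
    parts <- if (inherits(cohort, "gastro_cohort")) cohort$participants
             else cohort
    tr <- parts[[1L]]$bold$tr
    dyn <- NULL
    if (length(nodes$nodes) > 0L) {
      spl <- lapply(seq_along(parts), function(p) {
        bp <- attr(analysis$maps[[p]], "bold_phase")
        ep <- attr(analysis$maps[[p]], "egg_phase")$phase
        vapply(nodes$nodes, function(nd) {
          ph <- Arg(colMeans(exp(1i * bp[nd$voxels, , drop = FALSE])))
          sliding_plv(ph, ep, config$plv_window, config$plv_step, tr)$plv
        }, numeric(floor((length(ep) * tr - config$plv_window) /
                           config$plv_step) + 1L))
      })
      dyn <- list(window_plv = spl)
      if (length(nodes$nodes) >= 2L) {
        dyn$cross_node <- cross_node_covariation(spl)
      }
    }
    stage <- "write_outputs"
    mask <- analysis$mask
    aff <- parts[[1L]]$bold$affine
    write_stat_map(analysis$result$t_map, mask,
                   file.path(out_dir, "t_map.nii.gz"), affine = aff)
    lab <- numeric(sum(mask))
    for (k in seq_along(nodes$nodes)) lab[nodes$nodes[[k]]$voxels] <- k
    write_stat_map(lab, mask, file.path(out_dir, "cluster_labels.nii.gz"),
                   affine = aff)
    cl_json <- lapply(analysis$result$clusters, function(cl) {
      cl[c("sign", "sum_t", "size", "monte_carlo_p", "significant")]
    })
    manifest <- list(package_version = as.character(
                       utils::packageVersion("gastrosync")),
                     seed = seed, config = unclass(config),
                     n_participants = length(parts),
                     timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(list(clusters = cl_json,
                              threshold_t = analysis$result$threshold_t,
                              n_perm = analysis$result$n_perm),
                         file.path(out_dir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    if (length(nodes$nodes) > 0L) {
      nd <- data.frame(node = seq_along(nodes$nodes),
                       consistency = nodes$consistency,
                       relative_angle = vapply(nodes$nodes, `[[`, 0,
                                               "mean_relative_angle"),
                       shared_variance = vapply(nodes$nodes, `[[`, 0,
                                                "shared_variance"))
      utils::write.csv(nd, file.path(out_dir, "nodes.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(analysis = analysis, nodes = nodes, dynamics = dyn,
         manifest = manifest)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
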