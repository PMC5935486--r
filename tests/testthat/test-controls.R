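# Shared small planted cohort for the control analyses (built once).
ctrl_env <- new.env()
get_ctrl_cohort <- function() {
  if (is.null(ctrl_env$cohort)) {
    tt <- tiny_truth(delays = c(0, pi / 2), snr = 3)
    ctrl_env$truth <- tt
    ctrl_env$cohort <- make_cohort(6, tt, seed = 101)
    ctrl_env$config <- run_config(n_perm = 300)
    ctrl_env$analysis <- analyze_cohort(ctrl_env$cohort, ctrl_env$config,
                                        seed = 5)
  }
  ctrl_env
}

test_that("the offset-0 point of the frequency scan equals the main analysis", {
  e <- get_ctrl_cohort()
  sc <- frequency_offset_scan(e$cohort, offsets = 0, config = e$config)
  expect_equal(sc$sum_abs_t, sum(abs(e$analysis$result$t_map)),
               tolerance = 1e-9)
  expect_error(frequency_offset_scan(e$cohort, offsets = c(0.01, 0.02)),
               "include 0")
})

test_that("coupling is specific to the gastric frequency", {
  e <- get_ctrl_cohort()
  ids <- e$truth$cluster_id[e$truth$mask]
  sc <- frequency_offset_scan(e$cohort,
                              offsets = c(0, 0.005, 0.01, 0.02, 0.03),
                              config = e$config,
                              network_voxels = which(ids > 0))
  s <- sc$sum_abs_t
  # PLV is amplitude-invariant, so offsets whose band still contains
  # the (drifting) oscillator stay near the peak; the summary decays
  # monotonically once the band slides off the gastric rhythm
  expect_gt(s[1], s[4])          # 0 vs 0.02
  expect_gt(s[4], s[5])          # 0.02 vs 0.03
  expect_true(all(s < 1.05 * s[1]))
})

test_that("offsets that push the band out of range are skipped with warning", {
  e <- get_ctrl_cohort()
  expect_warning(
    sc <- frequency_offset_scan(e$cohort, offsets = c(0, 0.06),
                                config = e$config),
    "skipped")
  expect_true(is.na(sc$sum_abs_t[sc$offset_hz == 0.06]))
})

test_that("the group time-shift null separates planted coupling from chance", {
  e <- get_ctrl_cohort()
  gn <- group_timeshift_null(e$analysis$maps, n_datasets = 60,
                             config = e$config, seed = 11)
  expect_equal(gn$p, 1 / 61, tolerance = 1e-9)  # empirical beats all
  expect_gt(gn$empirical, max(gn$null))
  gn2 <- group_timeshift_null(e$analysis$maps, n_datasets = 60,
                              config = e$config, seed = 11)
  expect_identical(gn$null, gn2$null)
})

test_that("the time-shift null covers the empirical value on null cohorts", {
  tt0 <- tiny_truth(grid = c(8, 8, 8), delays = 0, snr = 0,
                    mask = array(TRUE, c(8, 8, 8)))
  co0 <- make_cohort(5, tt0, seed = 202)
  an0 <- analyze_cohort(co0, run_config(n_perm = 200), seed = 6)
  gn0 <- group_timeshift_null(an0$maps, n_datasets = 80,
                              config = run_config(), seed = 12)
  expect_gt(gn0$p, 0.025)
  expect_gt(gn0$empirical, quantile(gn0$null, 0.001))
})

test_that("EGG-swap chance reproduces the shift-based network", {
  e <- get_ctrl_cohort()
  sw <- egg_swap_chance(e$analysis$maps, e$truth$mask, config = e$config,
                        seed = 7)
  expect_equal(nrow(sw$chance), 6)
  # own EGG excluded: chance of participant 1 must differ from the
  # median over all participants including itself
  vox <- which(e$truth$cluster_id[e$truth$mask] > 0)
  expect_true(all(sw$chance[1, vox] < e$analysis$maps[[1]]$empirical_plv[vox]))
  sig_sw <- unlist(lapply(Filter(function(cl) cl$significant && cl$sign > 0,
                                 sw$result$clusters), `[[`, "voxels"))
  sig_sh <- unlist(lapply(Filter(function(cl) cl$significant && cl$sign > 0,
                                 e$analysis$result$clusters), `[[`,
                          "voxels"))
  dice <- 2 * length(intersect(sig_sw, sig_sh)) /
    (length(sig_sw) + length(sig_sh))
  expect_gt(dice, 0.5)
})

test_that("with three participants the swap chance is the mean of two PLVs", {
  tt <- tiny_truth(grid = c(6, 6, 6), delays = 0, snr = 2,
                   mask = array(TRUE, c(6, 6, 6)))
  co <- make_cohort(3, tt, seed = 33)
  an <- analyze_cohort(co, run_config(n_perm = 200), seed = 3)
  sw <- egg_swap_chance(an$maps, tt$mask, run_config(n_perm = 200), seed = 3)
  # direct: PLV of participant 1's voxels against EGG of 2 and 3
  ph1 <- attr(an$maps[[1]], "bold_phase")
  p12 <- empirical_plv_map(ph1, attr(an$maps[[2]], "egg_phase")$phase)
  p13 <- empirical_plv_map(ph1, attr(an$maps[[3]], "egg_phase")$phase)
  expect_equal(sw$chance[1, ], (p12 + p13) / 2, tolerance = 1e-12)
  expect_error(egg_swap_chance(an$maps[1:2], tt$mask), "3 participants")
})

test_that("confound correlations behave at their fixed points", {
  e <- get_ctrl_cohort()
  cs <- lapply(e$analysis$maps, function(m) m$coupling_strength)
  self <- confound_correlations(cs, cs)
  expect_true(all(abs(self$r - 1) < 1e-12))
  set.seed(18)
  shuf <- lapply(cs, sample)
  r0 <- confound_correlations(cs, shuf)
  expect_lt(abs(mean(r0$r)), 0.1)
  # independent confound: group test calibrated
  hits <- replicate(40, {
    fake_cs <- lapply(1:6, function(i) rnorm(200))
    fake_cf <- lapply(1:6, function(i) rnorm(200))
    confound_correlations(fake_cs, fake_cf)$p < 0.05
  })
  expect_lt(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 40))
  # scalar mode: per-node covariate test
  M <- matrix(rnorm(6 * 2), 6, 2)
  sc <- confound_correlations(M, rnorm(6))
  expect_length(sc$r, 2)
  expect_true(all(sc$p >= 0 & sc$p <= 1))
})
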