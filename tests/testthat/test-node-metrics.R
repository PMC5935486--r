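test_that("node series extraction is the voxel mean", {
  X <- rbind(a = 1:10, b = -(1:10), c = rep(2, 10))
  expect_equal(extract_node_series(X, 1L), as.numeric(1:10))
  expect_equal(extract_node_series(X, c(1L, 2L)), rep(0, 10))
  expect_error(extract_node_series(X, integer(0)), "empty")
  expect_error(extract_node_series(X, 9L), "out of range")
})

test_that("ROI averaging raises PLV over single noisy voxels", {
  gains <- replicate(10, {
    s <- sample.int(1e6, 1)
    egg <- simulate_egg(egg_sim_params(base_freq = 0.047, seed = s))
    truth <- tiny_truth(delays = 0, snr = 1)
    bold <- simulate_bold(truth, egg, tr = 2, n_volumes = 450, seed = s + 1)
    ep <- egg_phase_series(egg, egg_peak(egg))
    bp <- bold_phase_series(bold, ep$center)
    vox <- which(truth$cluster_id[truth$mask] == 1L)
    roi_phase <- Arg(colMeans(exp(1i * bp$phase[vox, ])))
    roi <- plv(roi_phase, ep$phase)
    single <- mean(apply(bp$phase[vox, ], 1, plv, ep$phase))
    roi - single
  })
  expect_gt(mean(gains), 0)
})

test_that("squared coherence is 1 for identical and purely delayed series", {
  set.seed(8)
  tr <- 2
  x <- bandpass_bold(rnorm(500), tr)  # full-band 0.01-0.1 Hz signal
  x <- x[41:460]
  sv <- shared_variance_coherence(x, x, gastric_freq = 0.05)
  expect_equal(sv$shared_variance, 1, tolerance = 1e-6)
  expect_equal(sv$n_windows, floor((840 - 120) / 100) + 1)  # from length
  # narrowband series delayed by 4 s: coherence ~ 1, Pearson^2 < coherence
  t <- (0:419) * tr
  g <- sin(2 * pi * 0.05 * t)
  gd <- sin(2 * pi * 0.05 * (t - 4))
  svd <- shared_variance_coherence(g, gd, gastric_freq = 0.05)
  expect_gt(svd$shared_variance, 0.95)
  expect_lt(cor(g, gd)^2, svd$shared_variance)
  expect_error(shared_variance_coherence(g, gd[1:10], 0.05),
               "lengths differ")
})

test_that("independent-noise coherence sits at the small-sample bias floor", {
  # Monte-Carlo oracle at the same window count
  set.seed(12)
  draws <- replicate(150, {
    shared_variance_coherence(rnorm(420), rnorm(420),
                              gastric_freq = 0.05)$shared_variance
  })
  # with W windows the expected null coherence^2 is near 1/W (here 8)
  expect_lt(abs(median(draws) - 1 / 8), 0.08)
  expect_gt(mean(draws < 0.6), 0.95)
})

test_that("phase angles and relative angles follow their identities", {
  Tn <- 200
  base <- runif(Tn, -pi, pi)
  mk <- function(off) gastrosync:::wrap_angle(base + off)
  # all nodes identical: relative angles all 0
  ang <- phase_angles(rbind(mk(1), mk(1), mk(1)), base)
  expect_equal(ang$relative_angle, rep(0, 3), tolerance = 1e-9)
  # symmetric pair at +/- pi/6
  ang2 <- phase_angles(rbind(mk(pi / 6), mk(-pi / 6)), base)
  expect_equal(sort(ang2$relative_angle), c(-pi / 6, pi / 6),
               tolerance = 1e-9)
  expect_equal(ang2$lock_angle, c(pi / 6, -pi / 6), tolerance = 1e-9)
  expect_warning(a1 <- phase_angles(matrix(mk(0.3), 1), base), "single node")
  expect_equal(a1$relative_angle, 0)
})

test_that("between-participant consistency is the resultant length", {
  expect_equal(angle_consistency(matrix(0.7, 20, 2)), c(1, 1))
  expect_equal(angle_consistency(matrix(c(0, pi), 2, 1)), 0,
               tolerance = 1e-12)
  set.seed(2)
  u <- matrix(runif(100, -pi, pi), 100, 1)
  expect_lt(angle_consistency(u), 0.2)
  expect_error(angle_consistency(matrix(1, 1, 2)), "2 participants")
})

test_that("Watson-Williams matches an independent textbook implementation", {
  # independent oracle, written directly from the F formula
  ww_oracle <- function(theta, grp) {
    grp <- as.factor(grp)
    N <- length(theta); K <- nlevels(grp)
    C <- tapply(cos(theta), grp, sum); S <- tapply(sin(theta), grp, sum)
    Rk <- sqrt(C^2 + S^2)
    Rall <- sqrt(sum(cos(theta))^2 + sum(sin(theta))^2)
    rb <- sum(Rk) / N
    kap <- if (rb < 0.53) 2 * rb + rb^3 + 5 * rb^5 / 6 else
      if (rb < 0.85) -0.4 + 1.39 * rb + 0.43 / (1 - rb) else
        1 / (rb^3 - 4 * rb^2 + 3 * rb)
    Fv <- (1 + 3 / (8 * kap)) * (N - K) * (sum(Rk) - Rall) /
      ((K - 1) * (N - sum(Rk)))
    list(F = Fv, p = pf(Fv, K - 1, N - K, lower.tail = FALSE))
  }
  set.seed(31)
  theta <- c(rnorm(15, 0, 0.4), rnorm(15, 0.8, 0.4), rnorm(12, -0.3, 0.4))
  grp <- rep(1:3, c(15, 15, 12))
  ours <- watson_williams(theta, grp)
  orc <- ww_oracle(theta, grp)
  expect_equal(ours$F, orc$F, tolerance = 1e-10)
  expect_equal(ours$p, orc$p, tolerance = 1e-10)
  # concentrated groups a quarter-cycle apart are detected decisively
  set.seed(32)
  th2 <- c(rnorm(30, 0, 0.3), rnorm(30, pi / 2, 0.3))
  expect_lt(watson_williams(th2, rep(1:2, each = 30))$p, 1e-3)
  # identical angle vectors in every group: F ~ 0
  th3 <- rep(c(0.1, 0.2, 0.3), 2)
  expect_lt(watson_williams(th3, rep(1:2, each = 3))$F, 1e-6)
  expect_error(watson_williams(1:3, c(1, 1, 2)), "at least 2")
})

test_that("Watson-Williams p values are calibrated under the null", {
  set.seed(33)
  pv <- replicate(200, {
    th <- rnorm(60, 1, 0.5)  # one concentrated population
    watson_williams(th, rep(1:3, each = 20))$p
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("delayed FC sees through a quarter-cycle shift, instantaneous does not", {
  set.seed(13)
  tr <- 2
  t <- (0:419) * tr
  jit <- bandpass_bold(rnorm(420, 0, 0.02), tr)
  x <- sin(2 * pi * 0.05 * t) + jit
  expect_error(node_fc(x, rep(1, 420), 0.05), "constant")
  fc_same <- node_fc(x, x, 0.05)
  expect_equal(fc_same$instantaneous, 1, tolerance = 1e-9)
  expect_equal(fc_same$delayed, 1, tolerance = 1e-9)
  # quarter cycle of 0.05 Hz = 5 s
  y <- sin(2 * pi * 0.05 * (t - 5)) + bandpass_bold(rnorm(420, 0, 0.02), tr)
  fc <- node_fc(x, y, 0.05)
  expect_lt(fc$instantaneous, 0.15)
  expect_gt(fc$delayed, 0.8)
  # advancing the delayed series by the constructed lag restores
  # instantaneous FC to the delayed level
  adv <- c(y[-(1:round(5 / tr))], y[1:round(5 / tr)])
  # re-align tail wrap artefacts by trimming both
  fc_adv <- node_fc(x[1:400], adv[1:400], 0.05)
  expect_gt(fc_adv$instantaneous, 0.8 * fc_adv$delayed)
})
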