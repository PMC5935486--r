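test_that("analytic phase and amplitude follow the sinusoid ground truth", {
  tr <- 2
  t <- (0:419) * tr
  x <- 3 * cos(2 * pi * 0.05 * t)
  ap <- analytic_phase(x)
  mid <- 30:390
  dphi <- diff(ap$phase)[mid]
  dphi <- (dphi + pi) %% (2 * pi) - pi
  expect_lt(max(abs(dphi - 2 * pi * 0.05 * tr)), 0.01)
  expect_lt(max(abs(ap$amplitude[mid] - 3) / 3), 0.02)
  # sin lags cos by pi/2 everywhere
  ap2 <- analytic_phase(3 * sin(2 * pi * 0.05 * t))
  d <- circ_diff(ap$phase[mid], ap2$phase[mid] + pi / 2)
  expect_lt(max(d), 0.02)
  expect_error(analytic_phase(numeric(420)), "all-zero")
})

test_that("PLV matches its defining identities", {
  t <- (0:419) * 2
  p1 <- 2 * pi * 0.05 * t
  # equal-frequency sinusoids at any fixed offset lock perfectly
  expect_equal(plv(p1, p1 + 1.234), 1, tolerance = 1e-12)
  # antipodal phase differences cancel
  expect_equal(plv(c(0, pi), c(0, 0)), 0, tolerance = 1e-12)
  # {0, pi/2} -> |1 + i| / 2
  expect_equal(plv(c(0, pi / 2), c(0, 0)), sqrt(2) / 2, tolerance = 1e-12)
  # lag invariance
  set.seed(1)
  ph <- runif(420, -pi, pi)
  expect_equal(plv(ph, p1), plv(ph + 0.7, p1 + 0.7), tolerance = 1e-12)
  expect_error(plv(ph, ph[1:10]), "lengths differ")
})

test_that("PLV is invariant to amplitude scaling before phase extraction", {
  set.seed(42)
  tr <- 2
  x <- bandpass_bold(rnorm(450), tr = tr, band = c(0.03, 0.07))
  y <- bandpass_bold(rnorm(450), tr = tr, band = c(0.03, 0.07))
  p0 <- plv(analytic_phase(x), analytic_phase(y))
  p1 <- plv(analytic_phase(17.3 * x), analytic_phase(y / 251))
  expect_equal(p0, p1, tolerance = 1e-6)
})

test_that("surrogate offsets follow the half-open enumeration", {
  offs <- surrogate_offsets(420, 2, 60)
  expect_length(offs, 360)
  expect_true(all(pmin(offs, 420 - offs) >= 30))
  expect_identical(range(offs), c(30L, 389L))
  expect_length(surrogate_offsets(420, 2, 0), 419)
  expect_error(surrogate_offsets(50, 2, 60), "too short")
})

test_that("chance PLV with a single offset equals that surrogate's PLV", {
  set.seed(3)
  ph <- matrix(runif(3 * 100, -pi, pi), 3, 100)
  eg <- runif(100, -pi, pi)
  s <- 37L
  ch <- chance_plv_map(ph, eg, offsets = s)
  shifted <- eg[((seq_len(100) - 1 - s) %% 100) + 1]
  direct <- apply(ph, 1, function(v) plv(v, shifted))
  expect_equal(ch$chance, direct, tolerance = 1e-12)
})

test_that("uniform random phases give the Rayleigh-mean chance level", {
  # analytic expectation for T independent uniform phases:
  # E[PLV] = sqrt(pi) / (2 sqrt(T)) ~ 0.0432 at T = 420
  set.seed(7)
  Tn <- 420
  n_vox <- 300
  ph <- matrix(runif(n_vox * Tn, -pi, pi), n_vox, Tn)
  emp <- empirical_plv_map(ph, runif(Tn, -pi, pi))
  target <- sqrt(pi) / (2 * sqrt(Tn))
  se <- sqrt((4 - pi) / 4 / Tn) / sqrt(n_vox)  # SD of R is sqrt((4-pi)/(4T))
  expect_lt(abs(mean(emp) - target), 4 * se)
  # chance map over shifts of an independent uniform EGG behaves alike
  ch <- chance_plv_map(ph[1:50, ], runif(Tn, -pi, pi),
                       surrogate_offsets(Tn, 2, 60))
  expect_lt(abs(median(ch$chance) - target), 0.01)
})

test_that("a self-coupled voxel shows empirical PLV 1 and much lower chance", {
  gap <- replicate(10, {
    egg <- simulate_egg(egg_sim_params(base_freq = 0.047,
                                       seed = sample.int(1e6, 1)))
    pk <- egg_peak(egg)
    ep <- egg_phase_series(egg, pk)
    ch <- chance_plv_map(matrix(ep$phase, 1), ep$phase,
                         surrogate_offsets(length(ep$phase), 2, 60))
    c(plv(ep$phase, ep$phase), ch$chance)
  })
  expect_true(all(gap[1, ] == 1))
  expect_true(all(gap[2, ] < 1))
  expect_gt(median(gap[1, ] - gap[2, ]), 0.5)
})

test_that("coupling strength is the elementwise difference with valid bounds", {
  m <- coupling_strength_map(c(1, 0.5), c(0.04, 0.5))
  expect_equal(m$coupling_strength, c(0.96, 0))
  set.seed(1)
  e <- runif(100); c0 <- runif(100)
  m2 <- coupling_strength_map(e, c0)
  expect_true(all(m2$coupling_strength >= -1 & m2$coupling_strength <= 1))
  expect_error(coupling_strength_map(e, c0[1:10]), "voxel counts")
})

test_that("on coupling-free data the empirical PLV sits inside its own surrogate band", {
  egg <- simulate_egg(egg_sim_params(base_freq = 0.047, seed = 21))
  truth <- tiny_truth(grid = c(8, 8, 8), delays = 0, snr = 0,
                      mask = array(TRUE, c(8, 8, 8)))
  bold <- simulate_bold(truth, egg, tr = 2, n_volumes = 450, seed = 22)
  pk <- egg_peak(egg)
  ep <- egg_phase_series(egg, pk)
  bp <- bold_phase_series(bold, ep$center)
  emp <- empirical_plv_map(bp$phase, ep$phase)
  ch <- chance_plv_map(bp$phase, ep$phase,
                       surrogate_offsets(length(ep$phase), 2, 60),
                       quantiles = TRUE)
  inside <- emp >= ch$quantiles[, 1] & emp <= ch$quantiles[, 2]
  # ~95% coverage, wide binomial band since voxels are spatially smooth
  expect_gt(mean(inside), 0.85)
})
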