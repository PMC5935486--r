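test_that("paired t map behaves at the boundaries", {
  set.seed(1)
  n <- 10; V <- 50
  emp <- matrix(0.3 + rnorm(n * V, 0, 1e-3), n, V)
  cha <- matrix(0.2, n, V)
  tm <- paired_t_map(emp, cha)
  expect_true(all(tm > 10))
  # n = 2 with unequal differences: defined, df = 1
  t2 <- paired_t_map(matrix(c(0.3, 0.4), 2, 1), matrix(0.1, 2, 1))
  expect_true(is.finite(t2))
  expect_warning(tz <- paired_t_map(matrix(0.3, 5, 1), matrix(0.1, 5, 1)),
                 "zero difference variance")
  expect_equal(tz, 0)
})

test_that("null t maps rarely exceed the first-level threshold", {
  set.seed(2)
  n <- 12; V <- 2000
  tm <- paired_t_map(matrix(rnorm(n * V), n, V), matrix(0, n, V))
  thr <- qt(1 - 0.01 / 2, df = n - 1)
  expect_lt(mean(abs(tm) > thr), 0.01 + 3 * sqrt(0.01 * 0.99 / V))
})

test_that("cluster formation respects the connectivity contract", {
  dm <- c(8, 8, 8)
  mask <- array(TRUE, dm)
  tmap <- numeric(prod(dm))
  # single isolated voxel
  tmap[1] <- 5
  cl <- form_clusters(tmap, mask, threshold_t = 3)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$size, 1L)
  # corner-touching pair: one cluster at 26-connectivity, two at 6
  tmap <- numeric(prod(dm))
  i1 <- which(array(seq_len(prod(dm)), dm) == 0)  # placeholder
  arr <- array(0, dm); arr[2, 2, 2] <- 5; arr[3, 3, 3] <- 5
  tmap <- as.vector(arr)
  expect_length(form_clusters(tmap, mask, 3, connectivity = 26), 1L)
  expect_length(form_clusters(tmap, mask, 3, connectivity = 6), 2L)
  # planted 3x3x3 block of t = 5: one positive cluster, sum t = 135
  arr <- array(0, dm); arr[3:5, 3:5, 3:5] <- 5
  cl <- form_clusters(as.vector(arr), mask, 3)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$sum_t, 135)
  expect_equal(cl[[1]]$sign, 1)
  # negative clusters are separated from positive ones
  arr[7, 7, 7] <- -6
  cl2 <- form_clusters(as.vector(arr), mask, 3)
  signs <- vapply(cl2, `[[`, 0, "sign")
  expect_setequal(signs, c(1, -1))
})

test_that("clustering matches an independent flood-fill oracle", {
  set.seed(5)
  dm <- c(6, 6, 6)
  for (conn in c(6, 18, 26)) {
    lin <- sort(sample(prod(dm), 40))
    ours <- gastrosync:::label_components(lin, dm, conn)
    oracle <- oracle_label(lin, dm, conn)
    # same partition (labels may differ): compare co-membership
    expect_identical(outer(ours, ours, "=="), outer(oracle, oracle, "=="))
  }
})

test_that("degenerate and deterministic permutation nulls", {
  mask <- array(TRUE, c(4, 4, 4))
  D0 <- matrix(0, 6, 64)
  null0 <- suppressWarnings(
    permutation_null(D0, matrix(0, 6, 64), mask = mask, n_perm = 100,
                     seed = 1))
  expect_true(all(null0$max_pos == 0) && all(null0$min_neg == 0))
  set.seed(9)
  emp <- matrix(rnorm(6 * 64), 6, 64)
  n1 <- permutation_null(emp, matrix(0, 6, 64), mask = mask, n_perm = 150,
                         seed = 7)
  n2 <- permutation_null(emp, matrix(0, 6, 64), mask = mask, n_perm = 150,
                         seed = 7)
  expect_identical(n1$max_pos, n2$max_pos)
  expect_error(permutation_null(emp, matrix(0, 6, 64), mask = mask,
                                n_perm = 10, seed = 1), "at least 100")
})

test_that("Monte-Carlo p values hit the documented extremes", {
  null <- list(max_pos = seq(1, 100), min_neg = -seq(1, 100),
               threshold_t = 3, n_perm = 100, seed = 1)
  cand <- list(list(voxels = 1L, lin = 1L, sign = 1, sum_t = 1000,
                    size = 1L),
               list(voxels = 2L, lin = 2L, sign = 1, sum_t = 50.5,
                    size = 1L))
  res <- cluster_inference(cand, null, alpha = 0.05)
  expect_equal(res$clusters[[1]]$monte_carlo_p, 1 / 101)
  expect_true(res$clusters[[1]]$significant)
  expect_equal(res$clusters[[2]]$monte_carlo_p, 51 / 101, tolerance = 0.02)
  expect_false(res$clusters[[2]]$significant)
})

test_that("exhaustive sign-flip enumeration matches a direct oracle", {
  set.seed(11)
  dm <- c(4, 4, 4)
  mask <- array(TRUE, dm)
  n <- 5
  D <- matrix(rnorm(n * 64, mean = 0.3, sd = 1), n, 64)
  null <- permutation_null(D, matrix(0, n, 64), mask = mask,
                           voxel_p = 0.05, exhaustive = TRUE)
  expect_equal(null$n_perm, 32L)
  # oracle: per sign pattern, t via stats::t.test per voxel, clusters via
  # the independent flood-fill labeling
  thr <- qt(1 - 0.05 / 2, df = n - 1)
  patterns <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  oracle <- t(apply(patterns, 1, function(s) {
    Ds <- D * s
    tv <- apply(Ds, 2, function(col) unname(stats::t.test(col)$statistic))
    mx <- 0; mn <- 0
    for (sgn in c(1, -1)) {
      sel <- which(sgn * tv > thr)
      if (!length(sel)) next
      lab <- oracle_label(sel, dm, 26)
      sums <- vapply(seq_len(max(lab)),
                     function(k) sum(tv[sel[lab == k]]), 0)
      if (sgn > 0) mx <- max(sums) else mn <- min(sums)
    }
    c(mx, mn)
  }))
  expect_equal(sort(null$max_pos), sort(oracle[, 1]), tolerance = 1e-10)
  expect_equal(sort(null$min_neg), sort(oracle[, 2]), tolerance = 1e-10)
})

test_that("effect sizes match hand-computed references", {
  d <- c(0.9, 1.1, 1.0, 1.2, 0.8)  # toy paired differences
  expect_equal(effect_size_d(d), mean(d) / sd(d), tolerance = 1e-12)
  expect_equal(effect_size_d(d + 0.2, rep(0.2, 5)), mean(d) / sd(d))
  expect_warning(di <- effect_size_d(rep(1, 5)), "infinite")
  expect_identical(di, Inf)
  # null differences give small |d| nearly always
  set.seed(3)
  dn <- replicate(200, effect_size_d(rnorm(30)))
  expect_gt(mean(abs(dn) < 0.5), 0.95)
})
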