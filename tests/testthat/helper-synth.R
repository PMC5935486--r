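# Shared fixture builders: everything is generated in code at test time.

# Small, well-separated planted-coupling geometry for fast cohorts.
tiny_truth <- function(grid = c(10, 10, 10), delays = c(0, pi / 2),
                       snr = 3, mask = NULL, egg_params = egg_sim_params()) {
  centers <- rbind(c(3, 3, 5), c(8, 8, 5), c(5, 5, 8))
  synthetic_truth(grid_dim = grid, mask = mask,
                  cluster_centers = centers[seq_along(delays), , drop = FALSE],
                  cluster_half = 1, planted_delay = delays, snr = snr,
                  egg_params = egg_params)
}

# One simulated participant on a small grid, reused across files.
tiny_participant <- function(seed = 1, truth = tiny_truth(), snr = NULL) {
  egg <- simulate_egg(egg_sim_params(base_freq = 0.047, seed = seed))
  bold <- simulate_bold(truth, egg, tr = 2, n_volumes = 450,
                        seed = seed + 1000)
  list(egg = egg, bold = bold, truth = truth)
}

# Independent BFS flood-fill labeling used as a clustering oracle.
oracle_label <- function(lin_idx, grid_dim, connectivity = 26) {
  n <- length(lin_idx)
  if (n == 0) return(integer(0))
  co <- arrayInd(lin_idx, grid_dim)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  if (connectivity == 18) offs <- offs[rowSums(abs(offs)) <= 2, , drop = FALSE]
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  kset <- key(co)
  lab <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (lab[i] > 0L) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      nb <- sweep(offs, 2, as.numeric(co[j, ]), "+")
      hits <- match(key(nb), kset)
      hits <- hits[!is.na(hits)]
      new <- hits[lab[hits] == 0L]
      lab[new] <- cur
      queue <- c(queue, new)
    }
  }
  lab
}

default_mask_for_test <- function(grid) gastrosync:::default_mask(grid)

# Circular absolute difference.
circ_diff <- function(a, b) {
  d <- (a - b + pi) %% (2 * pi) - pi
  abs(d)
}
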