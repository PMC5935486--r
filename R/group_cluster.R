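# Group-level inference: voxelwise paired t between empirical and
# chance PLV, supra-threshold clustering, and a max-statistic
# permutation null from empirical/chance label exchanges.

#' @noRd
colSds <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1L))
}

#' Voxelwise paired t map
#'
#' Paired t statistic (df = n - 1) of empirical versus chance PLV
#' across participants, at each voxel.
#'
#' @param empirical participants x voxels matrix of empirical PLV, or a
#'   list of [coupling_strength_map()] outputs (in which case `chance`
#'   may be omitted).
#' @param chance participants x voxels matrix of chance PLV.
#' @return numeric t vector, one value per voxel; voxels with zero
#'   difference variance get t = 0 with a warning.
#' @export
paired_t_map <- function(empirical, chance = NULL) {
  if (is.list(empirical) && inherits(empirical[[1L]], "coupling_maps")) {
    D <- do.call(rbind, lapply(empirical, function(m) m$coupling_strength))
  } else {
    if (is.null(chance)) stop("chance maps required with matrix input")
    stopifnot(all(dim(empirical) == dim(chance)))
    D <- empirical - chance
  }
  n <- nrow(D)
  if (n < 2L) stop("paired t needs at least 2 participants")
  s <- colSds(D)
  mu <- colMeans(D)
  t_map <- numeric(ncol(D))
  ok <- s > 0
  t_map[ok] <- mu[ok] / (s[ok] / sqrt(n))
  if (any(!ok)) warning(sum(!ok), " voxel(s) with zero difference variance; ",
                        "t set to 0")
  t_map
}

#' @noRd
neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  keep <- switch(as.character(connectivity),
                 "6" = rowSums(abs(g)) == 1,
                 "18" = rowSums(abs(g)) <= 2,
                 "26" = rep(TRUE, nrow(g)),
                 stop("connectivity must be 6, 18 or 26"))
  g <- g[keep, , drop = FALSE]
  # keep one of each +/- pair: edges are undirected
  g[g[, 3] > 0 | (g[, 3] == 0 & (g[, 2] > 0 | (g[, 2] == 0 & g[, 1] > 0))), ,
    drop = FALSE]
}

#' @noRd
label_components <- function(lin_idx, grid_dim, connectivity = 26) {
  # connected-component labels for a set of 3D voxel linear indices
  n <- length(lin_idx)
  if (n == 0L) return(integer(0))
  if (n == 1L) return(1L)
  co <- arrayInd(lin_idx, grid_dim)
  offs <- neighbor_offsets(connectivity)
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    nb <- co + matrix(offs[r, ], n, 3, byrow = TRUE)
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_dim[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid_dim[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid_dim[3]
    nb_lin <- (nb[, 3] - 1L) * grid_dim[1] * grid_dim[2] +
      (nb[, 2] - 1L) * grid_dim[1] + nb[, 1]
    j <- match(nb_lin, lin_idx)
    hit <- ok & !is.na(j)
    from <- c(from, which(hit)); to <- c(to, j[hit])
  }
  if (length(from) == 0L) return(seq_len(n))
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  as.integer(igraph::components(g)$membership)
}

#' Form supra-threshold clusters from a t map
#'
#' Connected components of voxels with `|t|` above the first-level
#' threshold, positive and negative voxels clustered separately; each
#' cluster is scored by the sum of its member t values.
#'
#' @param t_map numeric t vector over in-mask voxels.
#' @param mask 3D logical array defining the grid and voxel order.
#' @param threshold_t first-level threshold on |t|.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list of clusters: each has `voxels` (indices into the
#'   in-mask vector), `lin` (3D linear indices), `sign` (+1/-1),
#'   `sum_t`, `size`.
#' @export
form_clusters <- function(t_map, mask, threshold_t, connectivity = 26) {
  stopifnot(length(t_map) == sum(mask))
  mask_lin <- which(mask)
  out <- list()
  for (sgn in c(1, -1)) {
    sel <- which(sgn * t_map > threshold_t)
    if (length(sel) == 0L) next
    memb <- label_components(mask_lin[sel], dim(mask), connectivity)
    for (cl in seq_len(max(memb))) {
      vox <- sel[memb == cl]
      out[[length(out) + 1L]] <- list(voxels = vox, lin = mask_lin[vox],
                                      sign = sgn,
                                      sum_t = sum(t_map[vox]),
                                      size = length(vox))
    }
  }
  out[order(-abs(vapply(out, `[[`, 0, "sum_t")))]
}

#' @noRd
extreme_cluster_stats <- function(t_map, mask_lin, grid_dim, threshold_t,
                                  connectivity) {
  # largest positive and smallest negative cluster sum(t), 0 when none
  mx <- 0; mn <- 0
  for (sgn in c(1, -1)) {
    sel <- which(sgn * t_map > threshold_t)
    if (length(sel) == 0L) next
    memb <- label_components(mask_lin[sel], grid_dim, connectivity)
    sums <- vapply(seq_len(max(memb)),
                   function(cl) sum(t_map[sel[memb == cl]]), 0)
    if (sgn > 0) mx <- max(sums) else mn <- min(sums)
  }
  c(mx, mn)
}

#' Permutation null distribution of extreme cluster statistics
#'
#' Within-participant exchange of the 'empirical' and 'chance' labels
#' is equivalent to randomly sign-flipping each participant's
#' difference map.  For every permutation the voxelwise paired t map is
#' recomputed, reclustered, and the largest positive and smallest
#' negative cluster sum(t) are recorded.
#'
#' @param empirical,chance participants x voxels matrices (or
#'   `empirical` a list of [coupling_strength_map()] objects).
#' @param mask 3D logical array.
#' @param n_perm number of permutations (default 10000).
#' @param voxel_p first-level two-sided voxel p threshold (0.01).
#' @param connectivity 6, 18 or 26.
#' @param seed integer RNG seed.
#' @param exhaustive enumerate all `2^n` sign patterns instead of
#'   sampling (only sensible for small cohorts).
#' @return list with `max_pos`, `min_neg` (numeric vectors, one entry
#'   per permutation), `threshold_t`, `n_perm`, `seed`.
#' @export
permutation_null <- function(empirical, chance = NULL, mask,
                             n_perm = 10000, voxel_p = 0.01,
                             connectivity = 26, seed = 1L,
                             exhaustive = FALSE) {
  if (is.list(empirical) && inherits(empirical[[1L]], "coupling_maps")) {
    D <- do.call(rbind, lapply(empirical, function(m) m$coupling_strength))
  } else {
    D <- empirical - chance
  }
  n <- nrow(D)
  if (!exhaustive && n_perm < 100L) stop("n_perm must be at least 100")
  threshold_t <- stats::qt(1 - voxel_p / 2, df = n - 1L)
  if (exhaustive) {
    if (n > 20L) stop("exhaustive enumeration only supported for n <= 20")
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    n_perm <- nrow(S)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
  }
  ssq <- colSums(D^2)
  mask_lin <- which(mask)
  grid_dim <- dim(mask)
  max_pos <- numeric(n_perm); min_neg <- numeric(n_perm)
  chunk <- 500L
  for (b in seq(1L, n_perm, by = chunk)) {
    rows <- b:min(b + chunk - 1L, n_perm)
    M <- (S[rows, , drop = FALSE] %*% D) / n   # perms x voxels means
    for (k in seq_along(rows)) {
      m <- M[k, ]
      v <- pmax(ssq - n * m^2, 0) / (n - 1L)
      tp <- numeric(length(m))
      ok <- v > 0
      tp[ok] <- m[ok] / sqrt(v[ok] / n)
      st <- extreme_cluster_stats(tp, mask_lin, grid_dim, threshold_t,
                                  connectivity)
      max_pos[rows[k]] <- st[1L]; min_neg[rows[k]] <- st[2L]
    }
  }
  list(max_pos = max_pos, min_neg = min_neg, threshold_t = threshold_t,
       n_perm = n_perm, seed = if (exhaustive) NA_integer_ else seed)
}

#' Monte-Carlo cluster inference
#'
#' Each positive candidate is referred to the null distribution of the
#' per-permutation maximum positive cluster statistic (negative
#' candidates to the minimum negative one).  The Monte-Carlo p is the
#' one-tailed exceedance probability with the +1 small-sample
#' correction; two-sided control at level `alpha` tests each sign
#' family at `alpha / 2`.
#'
#' @param candidates clusters from [form_clusters()].
#' @param null output of [permutation_null()].
#' @param alpha two-sided cluster threshold (default 0.05).
#' @return object of class `group_cluster_result`: `clusters` (each
#'   candidate augmented with `monte_carlo_p` and `significant`),
#'   `threshold_t`, `n_perm`, `alpha`, `seed`.
#' @export
cluster_inference <- function(candidates, null, alpha = 0.05) {
  np <- length(null$max_pos)
  if (np == 0L) stop("null distribution is empty")
  clusters <- lapply(candidates, function(cl) {
    p1 <- if (cl$sign > 0) {
      (1 + sum(null$max_pos >= cl$sum_t)) / (np + 1)
    } else {
      (1 + sum(null$min_neg <= cl$sum_t)) / (np + 1)
    }
    cl$monte_carlo_p <- p1
    cl$significant <- cl$monte_carlo_p < alpha / 2
    cl
  })
  structure(list(clusters = clusters, threshold_t = null$threshold_t,
                 n_perm = np, alpha = alpha, seed = null$seed),
            class = "group_cluster_result")
}

#' @export
print.group_cluster_result <- function(x, ...) {
  sig <- vapply(x$clusters, `[[`, TRUE, "significant")
  cat(sprintf("Cluster inference: %d candidate(s), %d significant at %g\n",
              length(x$clusters), sum(sig), x$alpha))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %d voxels, sum(t) = %.1f, p = %.4g%s\n",
                if (cl$sign > 0) "positive" else "negative",
                cl$size, cl$sum_t, cl$monte_carlo_p,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

#' One-call group cluster test
#'
#' Convenience wrapper: paired t map, candidate clusters at the
#' first-level threshold, permutation null, Monte-Carlo inference.
#'
#' @inheritParams permutation_null
#' @param alpha cluster-level two-sided threshold.
#' @return a [cluster_inference()] result with the `t_map` attached.
#' @export
group_cluster_test <- function(empirical, chance = NULL, mask,
                               n_perm = 10000, voxel_p = 0.01,
                               alpha = 0.05, connectivity = 26,
                               seed = 1L, exhaustive = FALSE) {
  t_map <- suppressWarnings(paired_t_map(empirical, chance))
  null <- permutation_null(empirical, chance, mask = mask, n_perm = n_perm,
                           voxel_p = voxel_p, connectivity = connectivity,
                           seed = seed, exhaustive = exhaustive)
  cand <- form_clusters(t_map, mask, null$threshold_t, connectivity)
  res <- cluster_inference(cand, null, alpha = alpha)
  res$t_map <- t_map
  res$null <- null
  res
}

#' Cohen's d for paired empirical vs chance PLV
#'
#' `mean(diff) / sd(diff)` on paired region-level values; an infinite
#' result (zero spread) is returned as +/-Inf with a warning.
#'
#' @param empirical,chance paired numeric vectors (one value per
#'   participant), or `empirical` a vector of differences with `chance`
#'   omitted.
#' @return scalar Cohen's d.
#' @export
effect_size_d <- function(empirical, chance = NULL) {
  d <- if (is.null(chance)) empirical else empirical - chance
  s <- stats::sd(d)
  if (s == 0) {
    warning("zero variance of differences; effect size is infinite")
    return(sign(mean(d)) * Inf)
  }
  mean(d) / s
}
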