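# Independent brute-force oracles used to pin expected values.

# Random small label map on a shared grid.
random_mask <- function(dims, p = 0.3, spacing = c(1, 1, 1.6), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_labelmap(array(rbinom(prod(dims), 1, p), dims), spacing = spacing)
}

# A compact random blob (so HD95 surfaces are non-trivial but small).
random_blob <- function(dims, seed, spacing = c(1, 1, 1.6)) {
  set.seed(seed)
  ctr <- dims / 2 + runif(3, -2, 2)
  r <- runif(1, 2, min(dims) / 2.5)
  idx <- as.matrix(expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3]))
  d2 <- ((idx[, 1] - ctr[1]) / r)^2 + ((idx[, 2] - ctr[2]) / r)^2 +
    ((idx[, 3] - ctr[3]) / (r * 0.8))^2
  as_labelmap(array(as.integer(d2 <= 1), dims), spacing = spacing)
}

# Surface voxels by direct 6-neighbour enumeration.
oracle_surface <- function(mask) {
  d <- dim(mask$data)
  out <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (mask$data[i, j, k] == 0) next
    nb <- c(
      if (i > 1) mask$data[i - 1, j, k] else 0,
      if (i < d[1]) mask$data[i + 1, j, k] else 0,
      if (j > 1) mask$data[i, j - 1, k] else 0,
      if (j < d[2]) mask$data[i, j + 1, k] else 0,
      if (k > 1) mask$data[i, j, k - 1] else 0,
      if (k < d[3]) mask$data[i, j, k + 1] else 0)
    if (length(nb) < 6 || any(nb == 0)) out[i, j, k] <- TRUE
  }
  out
}

# All-pairs pooled 95th-percentile surface distance.
oracle_hd95 <- function(a, m, percentile = 95) {
  pts <- function(mask) {
    idx <- which(oracle_surface(mask), arr.ind = TRUE)
    sweep(sweep(idx - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
  }
  A <- pts(a); M <- pts(m)
  dmat <- as.matrix(stats::dist(rbind(A, M)))[seq_len(nrow(A)),
                                              nrow(A) + seq_len(nrow(M)),
                                              drop = FALSE]
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(stats::quantile(pooled, percentile / 100, type = 7))
}

# Voxelwise fusion oracles by direct per-voxel enumeration over blocks.
oracle_fuse <- function(preds, starts, shape, depth_b, rule) {
  out <- array(0L, shape)
  for (i in 1:shape[1]) for (j in 1:shape[2]) for (k in 1:shape[3]) {
    votes <- 0L; cover <- 0L
    for (b in seq_along(preds)) {
      z <- k - starts[b] + 1L
      if (z >= 1L && z <= depth_b) {
        cover <- cover + 1L
        votes <- votes + preds[[b]][i, j, z]
      }
    }
    out[i, j, k] <- switch(rule,
                           union = as.integer(votes > 0L),
                           majority = as.integer(votes * 2L > cover))
  }
  out
}

# Plain-R flood fill (full diagonal connectivity) for component oracles.
oracle_components <- function(arr) {
  d <- dim(arr)
  if (length(d) == 2) { arr <- array(arr, c(d, 1)); d <- dim(arr) }
  lab <- array(0L, d); cur <- 0L
  for (s in which(arr == 1 & lab == 0)) {
    if (lab[s] != 0) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[v] != 0) next
      lab[v] <- cur
      k <- (v - 1) %/% (d[1] * d[2])
      r <- (v - 1) %% (d[1] * d[2])
      i <- r %% d[1]; j <- r %/% d[1]
      for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
        ii <- i + di; jj <- j + dj; kk <- k + dk
        if (ii < 0 || ii >= d[1] || jj < 0 || jj >= d[2] ||
            kk < 0 || kk >= d[3]) next
        u <- 1 + ii + d[1] * (jj + d[2] * kk)
        if (arr[u] == 1 && lab[u] == 0) queue <- c(queue, u)
      }
    }
  }
  lab
}
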