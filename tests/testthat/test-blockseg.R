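roi_vol <- function(D, seed = 1, nx = 12, ny = 10) {
  set.seed(seed)
  as_volume(array(rnorm(nx * ny * D), c(nx, ny, D)), spacing = c(1, 1, 1.6))
}

test_that("block counts follow the sliding-window formula", {
  for (case in list(c(40, 15, 1, 26), c(15, 15, 1, 1), c(20, 15, 2, 3),
                    c(34, 15, 1, 20), c(17, 5, 3, 5))) {
    bs <- extract_blocks(roi_vol(case[1]), depth_b = case[2], stride = case[3])
    expect_length(bs, case[4])
    expect_equal(diff(bs$si_starts), rep(case[3], case[4] - 1))
    expect_true(all(vapply(bs$blocks, function(b) dim(b)[3], 0) == case[2]))
  }
})

test_that("shallow ROIs are reflect-padded to a single block", {
  v <- roi_vol(12)
  bs <- extract_blocks(v, depth_b = 15)
  expect_length(bs, 1)
  expect_equal(dim(bs$blocks[[1]])[3], 15)
  expect_equal(bs$valid_z, c(rep(TRUE, 12), rep(FALSE, 3)))
  # reflection mirrors the last slices without repeating the edge
  expect_equal(bs$blocks[[1]][, , 13], v$data[, , 11])
  expect_equal(bs$blocks[[1]][, , 14], v$data[, , 10])
  # fused output drops the padded slices again
  preds <- list(array(1L, dim(bs$blocks[[1]])))
  fused <- fuse_union(bs, preds)
  expect_equal(dim(fused$data)[3], 12)
})

test_that("union and majority fusion equal their enumeration oracles", {
  set.seed(42)
  for (rep_i in 1:6) {
    D <- sample(16:22, 1)
    v <- roi_vol(D, seed = rep_i, nx = 6, ny = 5)
    bs <- extract_blocks(v, depth_b = 15, stride = 1)
    preds <- lapply(bs$blocks, function(b) array(rbinom(length(b), 1, 0.35), dim(b)))
    u <- fuse_union(bs, preds)
    m <- fuse_majority(bs, preds)
    expect_identical(u$data,
                     oracle_fuse(preds, bs$si_starts, dim(v$data), 15, "union"))
    expect_identical(m$data,
                     oracle_fuse(preds, bs$si_starts, dim(v$data), 15, "majority"))
    expect_true(all(m$data <= u$data))  # majority mask is contained in union
  }
})

test_that("fusion implements the at-least-once and strict-majority rules", {
  v <- roi_vol(29, nx = 4, ny = 4)
  bs <- extract_blocks(v, depth_b = 15)
  preds <- lapply(bs$blocks, function(b) array(0L, dim(b)))
  # central voxel z=15 is covered by all 15 blocks; flag it in exactly one
  preds[[3]][1, 1, 15 - bs$si_starts[3] + 1] <- 1L
  expect_equal(fuse_union(bs, preds)$data[1, 1, 15], 1L)
  expect_equal(fuse_majority(bs, preds)$data[1, 1, 15], 0L)
  # 8 of 15 covering blocks -> strict majority
  for (b in 1:8) preds[[b]][2, 2, 15 - bs$si_starts[b] + 1] <- 1L
  expect_equal(fuse_majority(bs, preds)$data[2, 2, 15], 1L)
  # edge voxel z=1 covered only by block 1: one positive of one -> majority
  preds[[1]][3, 3, 1] <- 1L
  expect_equal(fuse_majority(bs, preds)$data[3, 3, 1], 1L)
  # all-zero predictions -> all-zero mask
  zero <- lapply(bs$blocks, function(b) array(0L, dim(b)))
  expect_true(all(fuse_union(bs, zero)$data == 0L))
})

test_that("block predictions are per-block, ordered and deterministic", {
  m <- build_model(network_spec(dims = 3, depth = 2, base_filters = 2,
                                dropout = 0.5), seed = 6)
  v <- roi_vol(18, seed = 9, nx = 8, ny = 8)
  bs <- extract_blocks(v, depth_b = 15)
  p1 <- predict_blocks(m, bs)          # dropout off by default
  p2 <- predict_blocks(m, bs)
  expect_identical(p1, p2)
  expect_length(p1, length(bs))
  for (i in seq_along(p1)) {
    expect_equal(dim(p1[[i]])[1:3], dim(bs$blocks[[i]]))
    expect_true(all(p1[[i]] %in% c(0L, 1L)))
  }
})

test_that("ROI masks resample onto the native grid within their footprint", {
  native <- as_volume(array(0, c(24, 24, 16)), spacing = c(1, 1, 1.6))
  roi <- roi_spec(c(11, 11, 12), c(10, 10, 6), c(1, 1, 1.6))
  org <- c(11, 11, 12) - (c(10, 10, 6) - 1) / 2 * c(1, 1, 1.6)
  ones <- as_labelmap(array(1L, c(10, 10, 6)), c(1, 1, 1.6), org)
  nat <- to_native(ones, native)
  expect_true(all(nat$data %in% c(0L, 1L)))
  idx <- which(nat$data == 1L, arr.ind = TRUE)
  w <- sweep(sweep(idx - 1, 2, native$spacing, `*`), 2, native$origin, `+`)
  half <- c(10, 10, 6) / 2 * c(1, 1, 1.6) + native$spacing / 2
  expect_true(all(abs(sweep(w, 2, c(11, 11, 12))) <= rep(half, each = nrow(w))))
  # identical grids -> identity
  m <- random_mask(c(8, 8, 6), seed = 2)
  expect_identical(to_native(m, as_volume(array(0, c(8, 8, 6)),
                                          spacing = m$spacing))$data, m$data)
})
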