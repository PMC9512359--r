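test_that("centroid equals the enumeration oracle", {
  m <- as_labelmap(array(0L, c(10, 10, 8)), c(1, 1, 1.6), c(3, 4, 5))
  m$data[4, 7, 3] <- 1L
  expect_equal(centroid(m), c(3, 4, 5) + c(3, 6, 2) * c(1, 1, 1.6))
  box <- as_labelmap(array(0L, c(10, 10, 8)), c(1, 1, 1.6))
  box$data[3:6, 2:9, 2:5] <- 1L
  expect_equal(centroid(box), c(mean(2:5), mean(1:8), mean(1:4) * 1.6))
  for (s in 1:4) {
    r <- random_mask(c(9, 7, 6), seed = s)
    idx <- which(r$data == 1L, arr.ind = TRUE)
    manual <- colMeans(sweep(sweep(idx - 1, 2, r$spacing, `*`), 2, r$origin, `+`))
    expect_equal(centroid(r), unname(manual))
  }
  expect_error(centroid(as_labelmap(array(0L, c(3, 3, 3)))),
               class = "ctv_error_value")
})

test_that("CTV centre estimation shifts only the posterior coordinate", {
  expect_equal(estimate_ctv_center(c(10, 20, 30), 39), c(10, 59, 30))
  expect_equal(estimate_ctv_center(c(10, 20, 30), 0), c(10, 20, 30))
  expect_equal(estimate_ctv_center(c(-4, 7.5, 88), 40), c(-4, 47.5, 88))
  set.seed(6)
  for (i in 1:10) {
    p <- rnorm(3, 0, 50); off <- runif(1, 0, 60)
    est <- estimate_ctv_center(p, off)
    expect_equal(est - p, c(0, off, 0))
  }
})

test_that("morphological cleaning removes small components and is idempotent", {
  img <- matrix(0L, 30, 30)
  img[2:11, 2:11] <- 1L          # 100 px
  img[20:22, 20:23] <- 1L        # 12 px
  out <- clean_detection(img, 50)
  expect_equal(sum(out), 100)
  expect_equal(out[5, 5], 1L)
  expect_equal(out[21, 21], 0L)
  expect_identical(clean_detection(img, 0), img)
  expect_identical(clean_detection(out, 50), out)
  for (s in 1:5) {
    set.seed(s)
    r <- matrix(rbinom(400, 1, 0.35), 20, 20)
    lab <- oracle_components(r)
    keep <- which(tabulate(lab[lab > 0]) >= 6)
    manual <- matrix(as.integer(array(lab, dim(lab)) %in% keep), 20, 20)
    got <- clean_detection(r, 6)
    expect_identical(got, manual)
    expect_true(all(got <= r))
  }
})

test_that("largest-component filtering keeps exactly the biggest island", {
  m <- as_labelmap(array(0L, c(20, 20, 10)), c(1, 1, 1.6))
  m$data[2:6, 2:6, 2:5] <- 1L      # 100 voxels
  m$data[15, 15, 8] <- 1L          # 1 voxel
  m$data[10:11, 18, 2] <- 1L       # 2 voxels
  out <- largest_component(m)
  expect_equal(sum(out$data), 100)
  expect_equal(out$data[15, 15, 8], 0L)
})

test_that("span extraction follows the gap-tolerant longest-run rule", {
  ns <- asNamespace("ctvseg")
  expect_equal(ns$longest_run(c(10:20, 40)), c(10, 20))
  expect_equal(ns$longest_run(c(5, 8, 11)), c(5, 11))       # gaps of 2 bridged
  expect_equal(ns$longest_run(c(5, 9, 10, 11)), c(9, 11))   # gap of 3 splits
  expect_equal(ns$longest_run(7), c(7, 7))
  expect_equal(ns$longest_run(c(1, 2, 3, 30, 31, 32, 33)), c(30, 33))
})

test_that("ROI construction covers the span with clamped block depth", {
  vol <- as_volume(array(0, c(128, 128, 64)), spacing = c(1, 1, 1.6))
  roi <- build_roi(vol, c(64, 90, 40), c(11, 40))
  expect_equal(roi$size_vox[1:2], c(128L, 128L))
  expect_equal(roi$spacing_mm, c(1, 1, 1.6))
  expect_equal(roi$size_vox[3], 34L)            # 30 slices + 2*2 margin
  expect_equal(roi$center_mm[1:2], c(64, 90))
  roi2 <- build_roi(vol, c(64, 90, 40), c(20, 24))
  expect_equal(roi2$size_vox[3], 15L)           # clamped to block depth
  expect_error(build_roi(vol, c(0, 0, 0), c(9, 5)), class = "ctv_error_parameter")
})

test_that("oracle-mask localization always contains the true CTV in the ROI", {
  cfg <- phantom_config()
  misses <- 0L
  for (s in 1:25) {
    ph <- generate_phantom(cfg, seed = 5000 + s)
    ctr <- estimate_ctv_center(centroid(ph$bladder))
    pos <- which(apply(ph$ctv$data, 3, sum) > 0)
    roi <- build_roi(ph$image, ctr, c(min(pos), max(pos)))
    idx <- which(ph$ctv$data == 1L, arr.ind = TRUE)
    w <- sweep(sweep(idx - 1, 2, ph$ctv$spacing, `*`), 2, ph$ctv$origin, `+`)
    half <- roi$size_vox / 2 * roi$spacing_mm
    inside <- abs(sweep(w, 2, roi$center_mm)) <= rep(half, each = nrow(w))
    if (!all(inside)) misses <- misses + 1L
  }
  expect_equal(misses, 0L)
})
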