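test_that("NIfTI and MetaImage round trips preserve grid and voxels", {
  set.seed(1)
  v <- as_volume(array(rnorm(6 * 5 * 4), c(6, 5, 4)),
                 spacing = c(1, 1, 1.6), origin = c(5, -7, 2))
  for (ext in c(".nii", ".nii.gz", ".mha", ".mhd")) {
    f <- file.path(withr::local_tempdir(), paste0("vol", ext))
    write_volume(v, f)
    r <- read_volume(f)
    expect_equal(dim(r$data), dim(v$data))
    expect_equal(r$spacing, v$spacing, tolerance = 1e-5)
    expect_equal(r$origin, v$origin, tolerance = 1e-4)
    expect_equal(r$data, v$data, tolerance = 1e-6)
  }
})

test_that("label maps round-trip as exact 0/1 8-bit volumes", {
  m <- as_labelmap(array(rbinom(60, 1, 0.4), c(5, 4, 3)), spacing = c(1, 1, 1.6))
  for (ext in c(".nii.gz", ".mha")) {
    f <- file.path(withr::local_tempdir(), paste0("mask", ext))
    write_volume(m, f)
    r <- read_labelmap(f)
    expect_identical(as.integer(r$data), as.integer(m$data))
    expect_true(all(r$data %in% c(0L, 1L)))
  }
})

test_that("read errors are informative", {
  expect_error(read_volume("does_not_exist.nii"), class = "ctv_error_format")
  td <- withr::local_tempdir()
  f <- file.path(td, "img2d.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(rnorm(16), 4)), f)
  expect_error(read_volume(f), class = "ctv_error_format")
  expect_error(write_volume(as_volume(array(0, c(2, 2, 2))),
                            file.path(td, "missing", "x.nii")),
               class = "ctv_error_io")
  expect_error(write_volume(as_volume(array(0, c(2, 2, 2))),
                            file.path(td, "x.tiff")),
               class = "ctv_error_format")
})

test_that("resampling onto the source grid is the identity", {
  set.seed(2)
  v <- as_volume(array(rnorm(600), c(10, 10, 6)), spacing = c(1, 1, 1.6),
                 origin = c(2, 3, 4))
  r <- resample(v, roi_of_volume(v))
  expect_equal(r$data, v$data, tolerance = 1e-12)
  expect_equal(r$origin, v$origin)
  m <- as_labelmap(array(rbinom(600, 1, 0.5), c(10, 10, 6)),
                   spacing = c(1, 1, 1.6), origin = c(2, 3, 4))
  rm_ <- resample(m, roi_of_volume(m), "nearest")
  expect_identical(rm_$data, m$data)
})

test_that("resampling interpolates, zero-fills and preserves label sets", {
  v <- as_volume(array(7, c(8, 8, 8)))
  inner <- roi_spec(c(3.5, 3.5, 3.5), c(4, 4, 4), c(0.9, 0.9, 0.9))
  expect_true(all(abs(resample(v, inner)$data - 7) < 1e-12))
  outside <- roi_spec(c(100, 100, 100), c(3, 3, 3), c(1, 1, 1))
  expect_true(all(resample(v, outside)$data == 0))
  m <- random_mask(c(9, 9, 5), seed = 3)
  out <- resample(m, roi_spec(c(4, 4, 3), c(12, 12, 8), c(0.7, 0.7, 0.9)),
                  "nearest")
  expect_true(all(out$data %in% c(0L, 1L)))
  expect_error(resample(m, roi_of_volume(m), "linear"),
               class = "ctv_error_parameter")
})

test_that("histogram equalization is monotone with a closed-form two-level map", {
  two <- as_volume(array(rep(c(10, 200), each = 32), c(4, 4, 4)))
  eq <- histogram_equalize(two)
  expect_equal(sort(unique(as.vector(eq$data))), c(0.5, 1.0))
  expect_true(all(eq$data[two$data == 10] == 0.5))
  set.seed(4)
  v <- as_volume(array(rnorm(512), c(8, 8, 8)))
  e <- histogram_equalize(v)
  ord <- order(v$data)
  expect_true(all(diff(e$data[ord]) >= 0))
  expect_true(all(e$data >= 0 & e$data <= 1))
  const <- histogram_equalize(as_volume(array(3, c(4, 4, 4))))
  expect_equal(length(unique(as.vector(const$data))), 1L)
})

test_that("intensity normalization is affine-invariant with stated degenerate rule", {
  set.seed(5)
  v <- as_volume(array(runif(256, 5, 10), c(8, 8, 4)))
  n <- normalize_intensity(v)
  expect_equal(range(n$data), c(0, 1))
  shifted <- as_volume(3.7 * v$data + 11, v$spacing, v$origin)
  expect_equal(normalize_intensity(shifted)$data, n$data, tolerance = 1e-12)
  expect_true(all(normalize_intensity(as_volume(array(4, c(3, 3, 3))))$data == 0))
})
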