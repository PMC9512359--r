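tiny3 <- function(...) network_spec(dims = 3, depth = 2, base_filters = 2,
                                    dropout = 0, ...)

test_that("encoder channels double per level and invalid specs error", {
  sp <- network_spec(dims = 3, depth = 4, base_filters = 16, dropout = 0)
  expect_equal(spec_channels(sp), c(16L, 32L, 64L, 128L))
  expect_equal(spec_channels(network_spec(depth = 5, base_filters = 4)),
               c(4L, 8L, 16L, 32L, 64L))
  expect_error(network_spec(dims = 4), class = "ctv_error_parameter")
  expect_error(network_spec(depth = 1), class = "ctv_error_parameter")
  expect_error(network_spec(dropout = 1), class = "ctv_error_parameter")
})

test_that("probability maps preserve shape and stay in [0, 1]", {
  m <- build_model(tiny3(), seed = 1)
  v <- as_volume(array(rnorm(16 * 12 * 6), c(16, 12, 6)), spacing = c(1, 1, 1.6))
  p <- predict_map(m, v)
  expect_s3_class(p, "ctv_probmap")
  expect_equal(dim(p$data), dim(v$data))
  expect_true(all(p$data >= 0 & p$data <= 1))
  m2 <- build_model(network_spec(dims = 2, depth = 3, base_filters = 2,
                                 attention = TRUE, dropout = 0), seed = 2)
  img <- matrix(rnorm(32 * 24), 32, 24)
  p2 <- predict_map(m2, img)
  expect_equal(dim(p2), dim(img))
  expect_true(all(p2 >= 0 & p2 <= 1))
})

test_that("odd SI sizes skip pooling while bad in-plane sizes error", {
  m <- build_model(tiny3(), seed = 1)
  # depth 15 is odd: no SI pooling, still works
  v <- as_volume(array(rnorm(8 * 8 * 15), c(8, 8, 15)))
  expect_equal(dim(predict_map(m, v)$data), c(8, 8, 15))
  bad <- as_volume(array(rnorm(9 * 8 * 4), c(9, 8, 4)))
  err <- tryCatch(predict_map(m, bad), error = identity)
  expect_s3_class(err, "ctv_error_shape")
  expect_match(conditionMessage(err), "x size 9")
  deep <- build_model(network_spec(dims = 3, depth = 4, base_filters = 2,
                                   dropout = 0), seed = 1)
  expect_equal(dim(predict_map(deep, as_volume(array(0, c(16, 16, 15))))$data),
               c(16, 16, 15))
  expect_error(predict_map(deep, as_volume(array(0, c(12, 16, 15)))),
               class = "ctv_error_shape")
})

test_that("dropout controls determinism of prediction", {
  dm <- build_model(network_spec(dims = 3, depth = 2, base_filters = 2,
                                 dropout = 0.5), seed = 3)
  v <- as_volume(array(rnorm(8 * 8 * 6), c(8, 8, 6)))
  a <- predict_map(dm, v); b <- predict_map(dm, v)
  expect_identical(a$data, b$data)             # dropout off: deterministic
  set.seed(10)
  c1 <- predict_map(dm, v, dropout_active = TRUE)
  c2 <- predict_map(dm, v, dropout_active = TRUE)
  expect_false(identical(c1$data, c2$data))    # active dropout: stochastic
  zm <- build_model(tiny3(), seed = 3)
  d1 <- predict_map(zm, v, dropout_active = TRUE)
  expect_identical(d1$data, predict_map(zm, v)$data)  # rate 0: degenerate
})

test_that("thresholding is strict and satisfies the complement identity", {
  pm <- structure(list(data = array(0.9, c(4, 4, 2)), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)),
                  class = c("ctv_probmap", "ctv_volume"))
  expect_true(all(threshold_map(pm)$data == 1L))
  pm$data[] <- 0.5
  expect_true(all(threshold_map(pm, 0.5)$data == 0L))  # ties go background
  expect_error(threshold_map(pm, 0), class = "ctv_error_parameter")
  expect_error(threshold_map(pm, 1), class = "ctv_error_parameter")
  set.seed(8)
  p <- array(runif(200), c(10, 10, 2))
  t <- 0.37
  lhs <- 1L - threshold_map(p, t)                   # complement of p > t
  rhs <- threshold_map(1 - p, 1 - t)                # (1-p) > (1-t) <=> p < t
  ties <- abs(p - t) < 1e-12
  expect_identical(lhs[!ties], (rhs + 0L)[!ties])
})

test_that("checkpoints round-trip through save and load", {
  m <- build_model(tiny3(), seed = 5)
  f <- file.path(withr::local_tempdir(), "model.ckpt")
  save_model(m, f)
  r <- load_model(f)
  expect_equal(r$params, m$params)
  v <- as_volume(array(rnorm(8 * 8 * 4), c(8, 8, 4)))
  expect_identical(predict_map(r, v)$data, predict_map(m, v)$data)
  expect_error(load_model(file.path(tempdir(), "nope.ckpt")), class = "ctv_error_io")
})

test_that("attention gating stays within [0, 1] and reweights skips", {
  ns <- asNamespace("ctvseg")
  m <- build_model(network_spec(dims = 2, depth = 2, base_filters = 2,
                                attention = TRUE, dropout = 0), seed = 4)
  x <- array(rnorm(16 * 16), c(16, 16, 1, 1))
  fw <- ns$model_forward(m, x, FALSE, TRUE)
  alpha <- fw$cache$dec[[1]]$att$alpha
  expect_true(all(alpha > 0 & alpha < 1))
})
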