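test_that("soft-Dice loss matches its formula on random tensors", {
  t_ <- array(rbinom(64, 1, 0.4), c(4, 4, 4))
  expect_lt(dice_loss(array(as.numeric(t_), dim(t_)), t_), 0.01)
  expect_gt(dice_loss(array(0, dim(t_)), t_), 0.9)
  set.seed(3)
  for (i in 1:5) {
    p <- array(runif(64), c(4, 4, 4))
    manual <- 1 - (2 * sum(p * t_) + 1) / (sum(p) + sum(t_) + 1)
    expect_equal(dice_loss(p, t_), manual)
  }
  expect_true(dice_loss(array(runif(64), c(4, 4, 4)), t_) >= 0)
})

test_that("backpropagation matches central finite differences", {
  withr::local_options(ctvseg.double_precision = TRUE)
  ns <- asNamespace("ctvseg")
  for (spec in list(network_spec(3, 2, 2, FALSE, 0),
                    network_spec(2, 3, 2, TRUE, 0))) {
    m <- build_model(spec, seed = 7)
    set.seed(1)
    dims <- if (spec$dims == 3) c(8, 8, 6, 1) else c(8, 8, 1, 1)
    x <- array(rnorm(prod(dims)), dims)
    t_ <- array(rbinom(prod(dims), 1, 0.3), dims)
    loss <- function(model) {
      p <- ns$model_forward(model, x)$p
      dice_loss(as.vector(p), as.vector(t_))
    }
    fw <- ns$model_forward(m, x, FALSE, TRUE)
    g <- ns$model_backward(m, fw$cache, ns$dice_loss_grad(fw$p, t_))
    pv <- unlist(m$params); gv <- unlist(g)
    set.seed(2)
    idx <- sample(which(abs(gv) > 1e-7), 25)
    eps <- 1e-5
    for (i in idx) {
      mp <- m
      up <- pv; up[i] <- pv[i] + eps
      mp$params <- utils::relist(up, m$params); lp <- loss(mp)
      dn <- pv; dn[i] <- pv[i] - eps
      mp$params <- utils::relist(dn, m$params); lm <- loss(mp)
      num <- (lp - lm) / (2 * eps)
      expect_lt(abs(num - gv[i]) / max(1e-8, abs(num) + abs(gv[i])), 1e-4)
    }
  }
})

test_that("validation split counts are exact", {
  expect_equal(validation_count(10, 0.10), 1L)
  expect_equal(validation_count(40, 0.10), 4L)
  expect_equal(validation_count(25, 0.10), 2L)  # round(2.5) -> banker's 2
  expect_equal(validation_count(3, 0.10), 1L)   # floor of 1 sample
})

test_that("augmentation transforms image and mask identically", {
  set.seed(5)
  s <- list(x = matrix(rnorm(400), 20, 20),
            y = matrix(rbinom(400, 1, 0.3), 20, 20))
  expect_identical(augment(s, "none"), s)
  a <- augment(s, "shift_2d", shift_max_px = 3, seed = 9)
  b <- augment(s, "shift_2d", shift_max_px = 3, seed = 9)
  expect_identical(a, b)
  # interior mask voxel count preserved under pure integer translation
  inner <- list(x = matrix(0, 20, 20), y = matrix(0L, 20, 20))
  inner$y[8:12, 8:12] <- 1L
  sh <- augment(inner, "shift_2d", shift_max_px = 3, seed = 2)
  expect_equal(sum(sh$y), sum(inner$y))
  # 3-D: mask follows the image through the same rotation + translation
  vol <- list(x = array(0, c(24, 24, 8)), y = array(0L, c(24, 24, 8)))
  vol$y[10:15, 10:15, 3:6] <- 1L
  vol$x <- vol$y * 1.0
  tr <- augment(vol, "translate_rotate_3d", translate_max_vox = 3,
                rotate_max_deg = 10, seed = 4)
  expect_true(all(tr$y %in% c(0L, 1L)))
  agree <- sum(tr$y == 1 & tr$x > 0.5) /
    max(1, sum(tr$y == 1 | tr$x > 0.5))
  expect_gt(agree, 0.95)
  z <- augment(vol, "translate_rotate_3d", translate_max_vox = 0,
               rotate_max_deg = 0)
  expect_equal(z$x, vol$x, tolerance = 1e-12)
})

test_that("stage sample extraction follows the stated geometry", {
  phs <- lapply(1:2, function(i) generate_phantom(phantom_config(), seed = 40 + i))
  bl <- make_training_samples(phs, "bladder", seed = 1)
  expect_length(bl, 2)
  s <- get_sample(bl, 1)
  expect_equal(dim(s$x), c(94L, 94L, 50L))
  expect_true(all(s$y %in% c(0L, 1L)))
  blk <- make_training_samples(phs, "block", seed = 1)
  expected <- sum(vapply(phs, function(ph) {
    pos <- which(apply(ph$ctv$data, 3, sum) > 0)
    roi <- build_roi(ph$image, estimate_ctv_center(centroid(ph$bladder)),
                     c(min(pos), max(pos)))
    roi$size_vox[3] - 14L
  }, 0L))
  expect_length(blk, expected)             # D - 14 blocks per phantom
  b1 <- get_sample(blk, 1)
  expect_equal(dim(b1$x), c(128L, 128L, 15L))
  sp <- make_training_samples(phs, "span", seed = 1)
  s2 <- get_sample(sp, 1)
  expect_equal(dim(s2$x), c(128L, 128L))
  # positive slices are oversampled towards class balance
  npos <- sum(vapply(seq_len(length(sp)), function(i) any(get_sample(sp, i)$y > 0), TRUE))
  nneg <- length(sp) - npos
  expect_gte(npos, 0.5 * nneg)
  sp_a <- make_training_samples(phs, "span", seed = 1)
  expect_equal(get_sample(sp_a, 5)$x, get_sample(sp, 5)$x)  # seeded extraction
  expect_error(make_training_samples(list(), "bladder"),
               class = "ctv_error_parameter")
})

test_that("training is reproducible and the selection rule picks max validation DSC", {
  phs <- lapply(1:3, function(i) generate_phantom(phantom_config(), seed = 60 + i))
  samp <- make_training_samples(phs, "span", pos_per_phantom = 4,
                                neg_per_phantom = 2, seed = 2)
  spec <- network_spec(dims = 2, depth = 2, base_filters = 2, dropout = 0)
  cfg <- train_config(epochs = 2, seed = 11, batch_size = 4)
  f1 <- train_model(build_model(spec, seed = 3), samp, cfg)
  f2 <- train_model(build_model(spec, seed = 3), samp, cfg)
  expect_equal(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params)
  expect_equal(nrow(f1$history), 2)
  # the selected model's validation DSC is the history maximum
  best <- max(f1$history$val_dsc)
  sel_dsc <- if (f1$selected == "final")
    f1$history$val_dsc[nrow(f1$history)] else f1$history$val_dsc[f1$best_epoch]
  expect_gte(sel_dsc, best - 1e-12)
})
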