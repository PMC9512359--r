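test_that("DSC matches direct counts and identities", {
  a <- random_mask(c(8, 8, 6), seed = 1)
  expect_equal(dsc(a, a), 1.0)
  inv <- as_labelmap(1L - a$data, a$spacing, a$origin)
  expect_equal(dsc(a, inv), 0.0)
  half <- array(0L, c(4, 2, 2)); half[1:2, , ] <- 1L
  other <- array(0L, c(4, 2, 2)); other[2:3, , ] <- 1L
  expect_equal(dsc(as_labelmap(half), as_labelmap(other)), 0.5)
  for (s in 1:5) {
    x <- random_mask(c(7, 6, 5), seed = s)
    y <- random_mask(c(7, 6, 5), seed = s + 100)
    manual <- 2 * sum(x$data == 1 & y$data == 1) / (sum(x$data) + sum(y$data))
    expect_equal(dsc(x, y), manual)
    expect_equal(dsc(x, y), dsc(y, x))
  }
  expect_error(dsc(a, random_mask(c(5, 5, 5))), class = "ctv_error_shape")
  z <- as_labelmap(array(0L, c(3, 3, 3)))
  expect_error(dsc(z, z), class = "ctv_error_value")
})

test_that("AVD is the absolute volume difference in cm3", {
  g <- c(10, 10, 10)
  a <- array(0L, g); a[1:10, 1:10, 1:10][seq_len(1000)] <- 1L
  m <- array(0L, g); m[seq_len(500)] <- 1L
  am <- as_labelmap(a, spacing = c(1, 1, 1.6))
  mm <- as_labelmap(m, spacing = c(1, 1, 1.6))
  expect_equal(avd(am, mm), 0.8)
  expect_equal(avd(mm, am), 0.8)
  expect_equal(avd(am, am), 0)
})

test_that("HD95 equals the brute-force pooled-percentile oracle", {
  a <- as_labelmap(array(0L, c(12, 4, 4)), spacing = c(1, 1, 1.6))
  a$data[3, 2, 2] <- 1L
  expect_equal(hd95(a, a), 0)
  a2 <- as_labelmap(array(0L, c(4, 4, 12)), spacing = c(1, 1, 1.6))
  b2 <- a2
  a2$data[2, 2, 3] <- 1L
  b2$data[2, 2, 8] <- 1L
  expect_equal(hd95(a2, b2), 5 * 1.6)
  for (s in 1:6) {
    x <- random_blob(c(14, 12, 10), seed = s)
    y <- random_blob(c(14, 12, 10), seed = s + 50)
    expect_equal(hd95(x, y), oracle_hd95(x, y), tolerance = 1e-10)
    expect_equal(hd95(x, y), hd95(y, x))
    expect_lte(hd95(x, y), hd95(x, y, percentile = 100))
  }
  empty <- as_labelmap(array(0L, c(4, 4, 4)))
  expect_error(hd95(empty, random_mask(c(4, 4, 4), seed = 1, spacing = c(1, 1, 1))),
               class = "ctv_error_value")
})

test_that("identical masks give the degenerate score triple", {
  x <- random_blob(c(12, 12, 8), seed = 3)
  r <- evaluate_case(x, x)
  expect_equal(unlist(r), c(dsc = 1, avd_cm3 = 0, hd95_mm = 0))
})

test_that("Pearson correlation matches the textbook formula", {
  expect_equal(volume_score_correlation(1:5, 2 * (1:5) + 3), 1.0)
  expect_equal(volume_score_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  set.seed(9)
  v <- rnorm(20); s <- rnorm(20)
  manual <- sum((v - mean(v)) * (s - mean(s))) /
    sqrt(sum((v - mean(v))^2) * sum((s - mean(s))^2))
  expect_equal(volume_score_correlation(v, s), manual)
  expect_error(volume_score_correlation(rep(1, 5), rnorm(5)),
               class = "ctv_error_value")
  expect_error(volume_score_correlation(1:2, 1:2), class = "ctv_error_value")
})

test_that("paired t-test has the stated degenerate and symmetry behaviour", {
  a <- c(0.8, 0.82, 0.85, 0.9)
  r0 <- paired_test(a, a)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  set.seed(11)
  x <- rnorm(30); y <- x - 0.5 + rnorm(30, 0, 0.05)
  r <- paired_test(x, y)
  expect_lt(r$p, 0.05)
  expect_true(r$significant)
  r2 <- paired_test(y, x)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  expect_error(paired_test(c(1, 2, 3), c(0, 1, 2)), class = "ctv_error_value")
})

test_that("cohort evaluation tabulates cases and summarizes mean/SD", {
  x <- random_blob(c(12, 12, 8), seed = 5)
  pairs <- list(c1 = list(auto = x, manual = x),
                c2 = list(auto = x, manual = x))
  td <- withr::local_tempdir()
  r <- evaluate_cohort(pairs, csv_path = file.path(td, "scores.csv"))
  expect_equal(nrow(r$table), 2)
  expect_equal(r$summary$mean, c(1, 0, 0))
  expect_equal(r$summary$sd, c(0, 0, 0))
  expect_true(file.exists(file.path(td, "scores.csv")))
  expect_true(file.exists(file.path(td, "scores_summary.csv")))
  y <- random_blob(c(12, 12, 8), seed = 6)
  r2 <- evaluate_cohort(list(list(auto = x, manual = y)))
  expect_equal(r2$table$dsc, dsc(x, y))
  expect_equal(r2$summary$mean[1], mean(r2$table$dsc))
})
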