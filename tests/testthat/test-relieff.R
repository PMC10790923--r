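test_that("the square-root k rule returns odd k", {
  expect_identical(choose_k(6), 3L)   # HR feature count
  expect_identical(choose_k(9), 3L)
  expect_identical(choose_k(16), 5L)
  expect_identical(choose_k(1), 1L)
  expect_identical(choose_k(96), 11L) # round(9.8) = 10, even -> 11
  expect_error(choose_k(0), "at least 1")
})

test_that("ReliefF weights match a brute-force oracle", {
  set.seed(31)
  # small toy case, k = 1
  x <- matrix(rnorm(12), 6, 2)
  y <- rep(c("a", "b"), each = 3)
  expect_equal(unname(relieff_weights(x, y, k = 1)),
               brute_force_relieff(x, y, k = 1), tolerance = 1e-12)
  # random instances up to 30 samples x 5 features
  for (i in 1:10) {
    n <- sample(8:30, 1)
    p <- sample(2:5, 1)
    k <- sample(1:3, 1)
    x <- matrix(rnorm(n * p), n)
    y <- c(rep("a", k + 1), rep("b", k + 1),
           sample(c("a", "b"), n - 2 * k - 2, replace = TRUE))
    expect_equal(unname(relieff_weights(x, y, k = k)),
                 brute_force_relieff(x, y, k = k), tolerance = 1e-12)
  }
})

test_that("ReliefF ranks discriminative features above noise", {
  set.seed(32)
  n <- 40
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(signal = ifelse(y == "a", 0, 1) + rnorm(n, 0, 0.05),
             noise = rnorm(n))
  w <- relieff_weights(x, y, k = 3)
  expect_gt(w["signal"], w["noise"])
  expect_equal(names(which.max(w)), "signal")

  const <- cbind(x, flat = rep(2, n))
  expect_equal(unname(relieff_weights(const, y, k = 3)["flat"]), 0)

  expect_error(relieff_weights(x[1:4, ], c("a", "a", "b", "b"), k = 3),
               "more than k")
  expect_error(relieff_weights(x, rep("a", n), k = 3), "binary")
})

test_that("duplicating a feature leaves unrelated weights unchanged on separated data", {
  set.seed(33)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  # f1 is constant within class, so duplicating it shifts every cross-class
  # distance equally and leaves all neighbour sets unchanged
  x <- cbind(f1 = ifelse(y == "a", 0, 10),
             f2 = rnorm(n, 0, 0.1),
             f3 = ifelse(y == "a", 5, -5) + rnorm(n, 0, 0.1))
  w0 <- relieff_weights(x, y, k = 2)
  w1 <- relieff_weights(cbind(x, f1_dup = x[, "f1"]), y, k = 2)
  expect_lt(max(abs(w1[c("f2", "f3")] - w0[c("f2", "f3")])), 1e-9)
})

test_that("label permutation drives weights toward zero", {
  set.seed(34)
  n <- 24
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(ifelse(y == "a", 0, 1) + rnorm(n, 0, 0.1),
             ifelse(y == "a", 1, 0) + rnorm(n, 0, 0.1))
  observed <- mean(abs(relieff_weights(x, y, k = 2)))
  permuted <- replicate(100, {
    mean(abs(relieff_weights(x, sample(y), k = 2)))
  })
  expect_lt(mean(permuted), observed)
})

test_that("the elbow cut-off keeps the features above the weight cliff", {
  expect_equal(elbow_cutoff(c(1.0, 0.9, 0.1, 0.09, 0.08)), 2L)
  expect_equal(elbow_cutoff(c(1, 0, 0, 0)), 1L)
  lin <- seq(1, 0.1, length.out = 10)
  expect_equal(elbow_cutoff(lin), 10L)  # collinear: all positive kept
  lin2 <- seq(0.5, -0.5, length.out = 11)
  expect_equal(elbow_cutoff(lin2), sum(lin2 > 0))
  expect_equal(elbow_cutoff(c(2, 1)), 2L)
  expect_error(elbow_cutoff(c(0.1, 0.5, 0.2)), "descending")
})

test_that("select_features combines the k rule, weights and cut-off", {
  set.seed(36)
  n <- 30
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("f", 1:6)))
  x[, 1] <- x[, 1] + ifelse(y == "a", 0, 3)
  rf <- select_features(x, y)
  expect_s3_class(rf, "ranked_feature_set")
  expect_identical(rf$k, 3L)  # 6 features -> k = 3
  expect_equal(rf$features[1], "f1")
  expect_true(all(diff(rf$weights) <= 1e-12))
  expect_gte(rf$cutoff, 1L)

  n2 <- 40
  y2 <- rep(c("a", "b"), each = n2 / 2)
  x2 <- matrix(rnorm(n2 * 16), n2)
  rf15 <- select_features(x2, y2, k_override = 15, manual_cutoff = 10)
  expect_identical(rf15$k, 15L)
  expect_identical(rf15$method, "manual")
  expect_equal(length(rf15$selected), 10L)
})
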