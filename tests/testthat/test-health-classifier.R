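# Boosted stumps, relevance selection, voting and morphology.

test_that("boosted stumps separate separable data immediately", {
  X <- cbind(f = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9))
  y <- c(0, 0, 0, 1, 1, 1)
  m <- train_adaboost(X, y, n_rounds = 100)
  expect_equal(nrow(m$stumps), 1L)   # one stump suffices; early stop
  expect_identical(predict(m, X), as.integer(y))
  # deterministic retraining
  m2 <- train_adaboost(X, y, n_rounds = 100)
  expect_identical(m$stumps, m2$stumps)
  expect_error(train_adaboost(X, rep(1, 6)), "both classes")
})

test_that("boosting improves overlapping-class fit without diverging", {
  set.seed(21)
  n <- 300
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- as.integer(X[, 1] + 0.8 * rnorm(n) > 0)
  m <- train_adaboost(X, y, n_rounds = 50)
  acc <- mean(predict(m, X) == y)
  expect_gt(acc, 0.8)
  # labels independent of features -> held-out accuracy near chance
  yperm <- sample(y)
  m0 <- train_adaboost(X[1:200, ], yperm[1:200], n_rounds = 50)
  acc0 <- mean(predict(m0, X[201:300, ]) == yperm[201:300])
  expect_lt(abs(acc0 - 0.5), 0.2)
})

test_that("relevance selection confirms informative and rejects noise features", {
  set.seed(31)
  n <- 400
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(informative = y + rnorm(n, 0, 0.3),
             weak = 0.5 * y + rnorm(n),
             noise1 = rnorm(n),
             noise2 = runif(n),
             label_copy = as.numeric(y))
  sel <- boruta_select(X, y, n_repeats = 5, subset_size = 120,
                       num_trees = 60, seed = 7)
  expect_equal(unname(sel$scores["label_copy"]), 5)
  expect_true("informative" %in% sel$relevant)
  expect_false("noise1" %in% sel$relevant)
  expect_false("noise2" %in% sel$relevant)
  expect_error(boruta_select(X, rep(1L, n)), "both classes")
})

test_that("adjacent-frame voting follows the majority and end-tie rules", {
  # model: healthy iff feature f > 0.5
  m <- train_adaboost(cbind(f = c(0.1, 0.9)), c(0L, 1L))
  lo <- cbind(f = rep(0.2, 4))   # predicts diseased
  hi <- cbind(f = rep(0.8, 4))   # predicts healthy
  # unanimity
  expect_identical(predict_columns(m, hi, hi, hi), rep(1L, 4))
  # two neighbours overrule the current frame
  expect_identical(predict_columns(m, lo, hi, hi), rep(1L, 4))
  expect_identical(predict_columns(m, hi, lo, lo), rep(0L, 4))
  # pullback end with disagreeing single neighbour: own label wins
  expect_identical(predict_columns(m, hi, NULL, lo), rep(1L, 4))
  expect_identical(predict_columns(m, lo, NULL, hi), rep(0L, 4))
  # masked columns become NA
  out <- predict_columns(m, hi, hi, hi, mask = c(TRUE, FALSE, FALSE, FALSE))
  expect_identical(out, c(NA_integer_, 1L, 1L, 1L))
})

test_that("circular morphology removes short runs and keeps long ones", {
  n <- 60
  x <- rep(0L, n)
  x[10:12] <- 1L                       # length 3 < K_E = 4
  expect_identical(morphological_cleanup(x), rep(0L, n))

  y <- rep(0L, n)
  y[10:39] <- 1L                       # length 30 survives
  z <- morphological_cleanup(y)
  expect_true(all(z[15:35] == 1L))
  expect_true(all(z[c(1:4, 48:60)] == 0L))
  # boundary movement bounded by the kernel-size difference
  expect_lte(abs(sum(z) - sum(y)), 9 - 4 + 2)

  # full circle unchanged
  expect_identical(morphological_cleanup(rep(1L, n)), rep(1L, n))
  # wrap-around run is treated circularly
  w <- rep(0L, n)
  w[c(56:60, 1:5)] <- 1L
  zw <- morphological_cleanup(w)
  expect_true(all(zw[c(58:60, 1:3)] == 1L))

  # masked columns are transparent and restored
  v <- rep(1L, n)
  v[20:23] <- NA_integer_
  zv <- morphological_cleanup(v)
  expect_true(all(is.na(zv[20:23])))
  expect_true(all(zv[-(20:23)] == 1L))
})

test_that("repeating the cleanup changes at most kernel-difference columns", {
  for (s in 1:10) {
    set.seed(40 + s)
    n <- 100
    a <- sample.int(n, 1) - 1L
    len <- sample(20:70, 1)
    x <- rep(0L, n)
    x[((a + seq_len(len) - 1L) %% n) + 1L] <- 1L
    once <- morphological_cleanup(x)
    twice <- morphological_cleanup(once)
    expect_lte(sum(once != twice), 9 - 4)
  }
})

test_that("voting shields the middle frame from a corrupted neighbourhood", {
  m <- mini_model()
  pb <- generate_cohort(1, n_frames = 3, seed = 555)[[1]]
  config <- pipeline_config()
  seg <- segment_pullback(pb$frames, config)
  fe <- features_for_pullback(seg, config)
  clean <- classify_pullback(m, fe$features, fe$masks)
  # corrupt frame 1 (a neighbour of frame 2) with heavy feature noise
  fe_bad <- fe
  set.seed(1)
  fe_bad$features[[1]] <- fe$features[[1]] +
    matrix(rnorm(length(fe$features[[1]]), 0, 5), nrow(fe$features[[1]]))
  corrupted <- classify_pullback(m, fe_bad$features, fe_bad$masks)
  expect_identical(corrupted[, 2], clean[, 2])
})

test_that("classification is deterministic for fixed inputs", {
  m <- mini_model()
  pb <- generate_cohort(1, n_frames = 3, seed = 556)[[1]]
  config <- pipeline_config()
  seg <- segment_pullback(pb$frames, config)
  fe <- features_for_pullback(seg, config)
  l1 <- classify_pullback(m, fe$features, fe$masks)
  l2 <- classify_pullback(m, fe$features, fe$masks)
  expect_identical(l1, l2)
})
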