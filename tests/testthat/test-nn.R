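toy_hist_set <- function(n = 10, seed = 61) {
  set.seed(seed)
  x <- array(abs(rnorm(32 * 32 * n, sd = 0.1)), c(32, 32, 1, n))
  y <- rep(0:1, length.out = n)
  for (i in which(y == 1)) x[, 1:8, 1, i] <- x[, 1:8, 1, i] + 2
  list(x = x, y = y)
}

test_that("branches honour their shape contracts", {
  hb <- hist_branch(1); ib <- img_branch(1); fh <- fusion_head(1)
  xh <- array(runif(32 * 32 * 2), c(32, 32, 1, 2))
  xi <- array(runif(32 * 32 * 3 * 2), c(32, 32, 3, 2))
  for (pair in list(list(hb, xh), list(ib, xi))) {
    p <- nn_predict(pair[[1]], pair[[2]])
    expect_true(all(p >= 0 & p <= 1))
    f <- extract_features(pair[[1]], pair[[2]])
    expect_identical(dim(f), c(8L, 8L, 64L, 2L))
  }
  fused <- fuse_features(extract_features(hb, xh), extract_features(hb, xh),
                         extract_features(ib, xi))
  expect_identical(dim(fused), c(8L, 8L, 192L, 2L))
  pf <- nn_predict(fh, fused)
  expect_true(all(pf >= 0 & pf <= 1))
  # mismatched input shapes are rejected
  expect_error(nn_predict(hb, xi), "expects input")
  expect_error(nn_predict(fh, extract_features(hb, xh)), "expects input")
  # probabilities bounded for extreme inputs
  expect_true(all(nn_predict(ib, xi * 0) >= 0))
  expect_true(all(nn_predict(ib, xi * 0 + 100) <= 1))
})

test_that("evaluation-mode forward passes are deterministic", {
  hb <- hist_branch(2)
  x <- array(runif(32 * 32 * 3), c(32, 32, 1, 3))
  expect_identical(nn_predict(hb, x), nn_predict(hb, x))
  expect_identical(extract_features(hb, x), extract_features(hb, x))
})

test_that("training overfits a separable toy set and is seed-reproducible", {
  toy <- toy_hist_set()
  phases <- list(list(epochs = 30, lr = 1e-3, optimizer = "adam",
                      cosine = TRUE))
  hb <- nn_train(hist_branch(3), toy$x, toy$y, phases, batch_size = 4,
                 seed = 11)
  acc <- mean((nn_predict(hb, toy$x) > 0.5) == (toy$y == 1))
  expect_equal(acc, 1)
  expect_lt(tail(hb$loss, 1), head(hb$loss, 1))
  hb2 <- nn_train(hist_branch(3), toy$x, toy$y, phases, batch_size = 4,
                  seed = 11)
  expect_identical(hb$loss, hb2$loss)
  expect_error(nn_train(hist_branch(3), toy$x, rep(1, 10), phases),
               "both classes")
})

test_that("cosine annealing follows the half-cosine decay", {
  toy <- toy_hist_set(6)
  hb <- nn_train(hist_branch(4), toy$x, toy$y,
                 list(list(epochs = 8, lr = 1e-4, optimizer = "adam",
                           cosine = TRUE)), batch_size = 4, seed = 1)
  expect_equal(hb$lr, 1e-4 * 0.5 * (1 + cos(pi * (0:7) / 8)),
               tolerance = 1e-12)
  # the US fine-tuning schedule: 5 epochs at 1e-3 then 5 at 1e-4, constant
  usb <- us_branch(5)
  feats <- array(rnorm(7 * 7 * 512 * 6, sd = 0.1), c(7, 7, 512, 6))
  trained <- train_us_head(usb, feats, rep(0:1, 3), seed = 2)
  expect_equal(trained$loss, trained$loss)  # attached history
  expect_equal(us_head_view(trained)$tap, 4)
})

test_that("the US branch pins the printed feature shapes", {
  usb <- us_branch(6)
  x <- array(rnorm(224 * 224 * 3), c(224, 224, 3, 1))
  bb <- us_backbone_features(usb, x)
  expect_identical(dim(bb), c(7L, 7L, 512L, 1L))
  f <- extract_features(usb, x)
  expect_identical(dim(f), c(8L, 8L, 64L, 1L))
  p <- nn_predict(usb, x)
  expect_true(p >= 0 && p <= 1)
  # head-on-cached-features equals the full forward pass
  expect_equal(us_head_predict(usb, bb), p, tolerance = 1e-5)
  expect_equal(us_head_features(usb, bb), f, tolerance = 1e-4)
})

test_that("the frozen prefix of the US branch never moves", {
  usb <- us_branch(7)
  frozen_before <- branch_parameters(usb, 1:9)
  trainable_before <- branch_parameters(usb, 12:21)
  set.seed(71)
  x <- array(rnorm(224 * 224 * 3 * 4, sd = 0.5), c(224, 224, 3, 4))
  y <- c(0, 1, 0, 1)
  trained <- nn_train(usb, x, y,
                      list(list(epochs = 1, lr = 1e-3, optimizer = "sgd",
                                momentum = 0.9)), batch_size = 2, seed = 3)
  expect_identical(branch_parameters(trained, 1:9), frozen_before)
  expect_false(identical(branch_parameters(trained, 12:21),
                         trainable_before))
})

test_that("fusion training leaves branches untouched and handles one class", {
  set.seed(72)
  feats <- array(rnorm(8 * 8 * 192 * 10, sd = 0.2), c(8, 8, 192, 10))
  y <- rep(0:1, 5)
  for (i in which(y == 1)) feats[, , 1:8, i] <- feats[, , 1:8, i] + 1.5
  fh <- train_fusion(fusion_head(8), feats, y, seed = 4)
  acc <- mean((nn_predict(fh, feats) > 0.5) == (y == 1))
  expect_equal(acc, 1)
  expect_warning(bad <- train_fusion(fusion_head(8), feats, rep(1, 10)),
                 "single-class")
  expect_true(bad$fallback)
})
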