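test_that("conv_forward matches hand-enumerated sliding windows", {
  # annihilation and identity kernels
  x <- matrix(c(4, 7, 1, 2, 9, 3, 8, 5, 6), 3, 3)
  expect_equal(conv_forward(x, matrix(0, 2, 2)), matrix(0, 2, 2))
  expect_equal(conv_forward(x, matrix(1, 1, 1)), x)

  # 3x3 input, 2x2 kernel, stride 1, valid: exhaustive window enumeration
  k <- matrix(c(1, -1, 0.5, 2), 2, 2)
  expect_equal(conv_forward(x, k), oracle_conv(x, k))

  set.seed(15)
  x2 <- matrix(rnorm(36), 6, 6)
  k2 <- matrix(rnorm(9), 3, 3)
  expect_equal(conv_forward(x2, k2), oracle_conv(x2, k2))

  # zero padding adds a border of zeros
  expect_equal(conv_forward(x, k, padding = 1),
               oracle_conv(rbind(0, cbind(0, x, 0), 0), k))
  expect_error(conv_forward(x, matrix(1, 5, 5)), "fit")
})

test_that("forward pass equals a layer-by-layer manual computation", {
  m <- cnn_init(input_side = 4, n_filters = 1, kernel = 2, pool = 2, seed = 1)
  m$Wc <- matrix(c(1, -1, 0.5, 2), 4, 1)  # taps (1,1),(2,1),(1,2),(2,2)
  m$bc <- 0.1
  m$wf <- 0.3
  m$bf <- -0.2
  img <- matrix(c(10, 3, 7, 1, 5, 8, 2, 6, 4, 9, 11, 0, 12, 13, 14, 15), 4, 4)

  # manual: scale, conv (cross-correlation), bias, ReLU, single 2x2 pool
  x <- img / 255
  K <- matrix(c(1, 0.5, -1, 2), 2, 2, byrow = TRUE)  # K[m, n]
  S <- matrix(0, 3, 3)
  for (r in 1:3) for (c in 1:3) {
    s <- 0
    for (mm in 1:2) for (nn in 1:2) s <- s + K[mm, nn] * x[r + mm - 1, c + nn - 1]
    S[r, c] <- s + 0.1
  }
  R <- pmax(S, 0)
  flat <- max(R[1:2, 1:2])  # pool_out = 1: only the top-left 2x2 block
  p_manual <- 1 / (1 + exp(-(0.3 * flat - 0.2)))
  expect_equal(cnn_forward(m, img), p_manual)

  # all-zero weights force sigmoid(0) = 0.5
  m0 <- m; m0$Wc[] <- 0; m0$bc[] <- 0; m0$wf[] <- 0; m0$bf <- 0
  expect_equal(cnn_forward(m0, img), 0.5)

  # negative pre-activations rectify to an all-zero plane
  mneg <- m; mneg$Wc[] <- 0; mneg$bc[] <- -1
  cc <- cnn_forward(mneg, img, cache = TRUE)
  expect_true(all(cc$flat == 0))
  expect_false(any(cc$relu_mask))

  expect_error(cnn_forward(m, matrix(0, 5, 5)), "wrong input size")
})

test_that("backprop gradients match central finite differences", {
  set.seed(31)
  m <- tiny_model()
  imgs <- replicate(3, random_gray_image(8, 8), simplify = FALSE)
  labels <- c(0, 1, 1)
  a <- analytic_grads(m, imgs, labels)
  n <- numeric_grads(m, imgs, labels)
  rel <- abs(a - n) / pmax(abs(a), abs(n), 1e-6)
  expect_lt(max(rel), 1e-4)
})

test_that("gradient descent behaves as expected in degenerate and convex cases", {
  set.seed(8)
  imgs <- replicate(8, random_gray_image(8, 8), simplify = FALSE)
  labels <- rep(c(0, 1), 4)
  m <- tiny_model()

  # zero learning rate leaves every weight untouched
  fit0 <- train_gd(m, imgs, labels, learning_rate = 0, epochs = 3, seed = 1)
  expect_identical(hhocnn:::pack_weights(fit0$model, "all"),
                   hhocnn:::pack_weights(m, "all"))

  # full-batch descent with a small rate decreases the loss monotonically
  easy <- c(replicate(4, matrix(30, 8, 8), simplify = FALSE),
            replicate(4, matrix(220, 8, 8), simplify = FALSE))
  ylab <- rep(c(0, 1), each = 4)
  fit <- train_gd(m, easy, ylab, learning_rate = 0.2, epochs = 20,
                  batch_size = 8, seed = 2)
  expect_true(all(diff(fit$loss_history) <= 1e-10))

  expect_error(train_gd(m, imgs, rep(1, 8)), "both classes")
})

test_that("metaheuristic refinement never hurts and is deterministic", {
  set.seed(12)
  imgs <- c(replicate(4, round(matrix(pmax(0, 30 + rnorm(64, 0, 10)), 8, 8)),
                      simplify = FALSE),
            replicate(4, round(matrix(pmin(255, 220 + rnorm(64, 0, 10)), 8, 8)),
                      simplify = FALSE))
  labels <- rep(c(0, 1), each = 4)
  m <- tiny_model(seed = 3)
  # fixed averaging conv bank so the pooled features are informative and
  # the refinement problem reduces to the output layer
  m$Wc <- matrix(1 / 9, nrow(m$Wc), ncol(m$Wc))
  m$bc[] <- 0

  # zero budget: unchanged model
  r0 <- refine_hho(m, imgs, labels, pop_size = 0, iterations = 0)
  expect_identical(hhocnn:::pack_weights(r0$model, "all"),
                   hhocnn:::pack_weights(m, "all"))

  # refinement from random init improves on the recorded initial loss
  r <- refine_hho(m, imgs, labels, pop_size = 20, iterations = 200, seed = 4)
  expect_lte(r$loss_after, r$loss_before)
  expect_lt(r$loss_after, r$loss_before)

  # acceptance rule across seeds: loss never increases
  for (s in 1:3) {
    ri <- refine_hho(m, imgs, labels, pop_size = 8, iterations = 10, seed = s)
    expect_lte(ri$loss_after, ri$loss_before)
  }

  r2 <- refine_hho(m, imgs, labels, pop_size = 20, iterations = 200, seed = 4)
  expect_identical(hhocnn:::pack_weights(r$model, "all"),
                   hhocnn:::pack_weights(r2$model, "all"))
})

test_that("prediction preserves order, handles empty input and ties to 1", {
  m <- tiny_model()
  expect_equal(nrow(cnn_predict(m, list())), 0L)
  m0 <- m; m0$Wc[] <- 0; m0$bc[] <- 0; m0$wf[] <- 0; m0$bf <- 0
  pred <- cnn_predict(m0, list(matrix(0, 8, 8)))
  expect_equal(pred$prob, 0.5)
  expect_equal(pred$label, 1L)  # tie rule: 0.5 -> tumor
})

test_that("model serialization round-trips every weight exactly", {
  set.seed(2)
  m <- tiny_model(seed = 7)
  m$wf <- rnorm(m$D)  # arbitrary trained-looking weights
  path <- file.path(tempdir(), "model_rt")
  save_cnn(m, path)
  back <- load_cnn(path)
  expect_identical(hhocnn:::pack_weights(back, "all"),
                   hhocnn:::pack_weights(m, "all"))
  expect_equal(back$input_side, m$input_side)
  unlink(paste0(path, c(".json", ".weights")))
})

test_that("bilinear resize preserves constants and the gray range", {
  expect_equal(resize_image(matrix(77, 10, 10), 6), matrix(77, 6, 6))
  set.seed(3)
  img <- random_gray_image(20, 20)
  out <- resize_image(img, 9)
  expect_equal(dim(out), c(9L, 9L))
  expect_true(all(out >= 0 & out <= 255))
  expect_identical(resize_image(img, 20), img)
})
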