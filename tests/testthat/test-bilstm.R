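test_that("lstm_step algebra at zero weights", {
  h <- 3L
  Wg <- matrix(0, 4 * h, h + 1)
  bg <- numeric(4 * h)
  x <- matrix(0.7, 1, 2)
  y0 <- matrix(0, h, 2)
  s0 <- matrix(0, h, 2)
  st <- lstm_step(Wg, bg, x, y0, s0)
  expect_equal(st$cache$i, matrix(0.5, h, 2))
  expect_equal(st$cache$f, matrix(0.5, h, 2))
  expect_equal(st$cache$o, matrix(0.5, h, 2))
  expect_equal(st$cache$g, matrix(0, h, 2))
  expect_equal(st$s, matrix(0, h, 2))
  expect_equal(st$y, matrix(0, h, 2))
  # nonzero previous cell state: s = c/2, y = 0.5*tanh(c/2)
  cc <- matrix(1.2, h, 2)
  st2 <- lstm_step(Wg, bg, x, y0, cc)
  expect_equal(st2$s, 0.5 * cc)
  expect_equal(st2$y, 0.5 * tanh(0.5 * cc))
  expect_error(lstm_step(Wg[, 1:2], bg, x, y0, s0), "shapes")
})

test_that("lstm_step matches a straight-line re-evaluation", {
  set.seed(31)
  h <- 4L
  Wg <- matrix(rnorm(4 * h * (h + 1)), 4 * h)
  bg <- rnorm(4 * h)
  x <- matrix(rnorm(2), 1, 2)
  y0 <- matrix(rnorm(h * 2), h)
  s0 <- matrix(rnorm(h * 2), h)
  st <- lstm_step(Wg, bg, x, y0, s0)
  sig <- function(v) 1 / (1 + exp(-v))
  for (b in 1:2) {
    z <- c(y0[, b], x[, b])
    i <- sig(Wg[1:h, ] %*% z + bg[1:h])
    f <- sig(Wg[(h + 1):(2 * h), ] %*% z + bg[(h + 1):(2 * h)])
    o <- sig(Wg[(2 * h + 1):(3 * h), ] %*% z + bg[(2 * h + 1):(3 * h)])
    g <- tanh(Wg[(3 * h + 1):(4 * h), ] %*% z + bg[(3 * h + 1):(4 * h)])
    s <- f * s0[, b] + i * g
    expect_equal(st$s[, b], as.numeric(s))
    expect_equal(st$y[, b], as.numeric(o * tanh(s)))
  }
})

test_that("forward pass: softmax normalization and symmetry", {
  set.seed(32)
  m <- new_bilstm(1L, 5L, 5L, "onehot")
  m$W_head[] <- 0
  m$b_head[] <- 0
  fw <- bilstm_forward(m, matrix(rnorm(10), 10, 1))
  expect_equal(fw$outputs[, 1], rep(0.2, 5))
  # softmax columns always sum to 1
  for (i in 1:20) {
    m2 <- new_bilstm(1L, 3L, 5L, "onehot")
    fw2 <- bilstm_forward(m2, matrix(rnorm(8 * 3), 8, 3))
    expect_equal(colSums(fw2$outputs), rep(1, 3))
  }
  # palindromic input with tied directions: final states identical
  m3 <- new_bilstm(1L, 4L, 5L, "onehot")
  m3$Wg_b <- m3$Wg_f
  m3$bg_b <- m3$bg_f
  x <- c(1, -2, 0.5, -2, 1)
  fw3 <- bilstm_forward(m3, matrix(x, 5, 1))
  expect_equal(fw3$kf[1:4, ], fw3$kf[5:8, ])
  expect_error(bilstm_forward(m3, matrix(numeric(0), 0, 1)), "empty")
})

test_that("loss values and L2 additivity", {
  m <- new_bilstm(1L, 3L, 5L, "onehot")
  u <- matrix(0.2, 5, 1)
  y <- matrix(c(1, 0, 0, 0, 0), 5, 1)
  expect_equal(bilstm_loss(u, y, m, 0, 1), log(5))
  expect_lt(bilstm_loss(y, y, m, 0, 1), 1e-10)
  l2 <- bilstm_loss(u, y, m, 0.7, 13) - bilstm_loss(u, y, m, 0, 13)
  expect_equal(l2, 0.7 / (2 * 13) * sum(m$W_head^2))
  # walsh mode: perfect prediction also ~0
  mw <- new_bilstm(1L, 3L, 8L, "walsh")
  cw <- matrix(walsh_encode(2, walsh_codebook(5, 8)), 8, 1)
  expect_lt(bilstm_loss(cw, cw, mw, 0, 1), 1e-9)
})

test_that("BPTT gradients pass finite differences in both head modes", {
  set.seed(41)
  for (mode in c("onehot", "walsh")) {
    for (i in 1:10) {
      cs <- random_bilstm_case(mode)
      expect_true(fd_grad_ok(cs$model, cs$X, cs$Y, cs$lambda, cs$n_train))
    }
  }
})

test_that("gradient of the L2 term alone is (lambda/N) * W_head", {
  set.seed(42)
  cs <- random_bilstm_case("onehot")
  fw <- bilstm_forward(cs$model, cs$X)
  g0 <- bilstm_backward(cs$model, fw, cs$Y, 0, 10)
  g1 <- bilstm_backward(cs$model, fw, cs$Y, 2, 10)
  expect_equal(g1$W_head - g0$W_head, (2 / 10) * cs$model$W_head)
  expect_equal(g1$Wg_f, g0$Wg_f)
})

test_that("training separates two separable classes and is reproducible", {
  set.seed(43)
  X <- rbind(matrix(rnorm(30 * 10, -1, 0.3), 30),
             matrix(rnorm(30 * 10, 1, 0.3), 30))
  y <- rep(0:1, each = 30)
  cfg <- train_config(hidden = 8L, epochs = 50L, learning_rate = 5e-3,
                      feature_noise_sd = 0, seed = 9L)
  r1 <- train_bilstm(X, y, cfg)
  expect_equal(tail(r1$history$accuracy, 1), 1)
  expect_lt(tail(r1$history$loss, 1), r1$history$loss[1])
  expect_equal(nrow(r1$history), 50L)
  r2 <- train_bilstm(X, y, cfg)
  expect_identical(r1$model$Wg_f, r2$model$Wg_f)
  expect_identical(r1$history, r2$history)
  expect_equal(predict_bilstm(r1$model, X), y)
  expect_error(train_bilstm(X, rep(0L, 60), cfg), "two classes")
})

test_that("larger L2 shrinks trained head-weight norms", {
  set.seed(44)
  X <- rbind(matrix(rnorm(20 * 10, -1, 0.5), 20),
             matrix(rnorm(20 * 10, 1, 0.5), 20))
  y <- rep(0:1, each = 20)
  norms <- sapply(c(0, 0.1, 1, 10), function(lam) {
    cfg <- train_config(hidden = 6L, epochs = 30L, learning_rate = 5e-3,
                        l2_lambda = lam, feature_noise_sd = 0, seed = 5L)
    sum(train_bilstm(X, y, cfg)$model$W_head^2)
  })
  expect_true(all(diff(norms) < 0))
})

test_that("prediction ties and ordering contracts", {
  m <- new_bilstm(1L, 3L, 5L, "onehot")
  m$W_head[] <- 0
  m$b_head[] <- 0
  # uniform softmax for every sample: argmax tie -> lowest index (0)
  expect_equal(predict_bilstm(m, matrix(rnorm(40), 4, 10)), rep(0L, 4))
  # predictions do not depend on batch composition or order
  set.seed(45)
  m2 <- new_bilstm(1L, 4L, 5L, "onehot")
  X <- matrix(rnorm(12 * 10), 12)
  p_all <- predict_bilstm(m2, X)
  perm <- sample(12)
  expect_equal(predict_bilstm(m2, X[perm, ]), p_all[perm])
  p_one <- vapply(1:12, function(i) predict_bilstm(m2, X[i, , drop = FALSE]),
                  integer(1))
  expect_equal(p_one, p_all)
})

test_that("walsh-mode training attaches the codebook and decodes", {
  set.seed(46)
  X <- rbind(matrix(rnorm(15 * 10, -1, 0.3), 15),
             matrix(rnorm(15 * 10, 1, 0.3), 15))
  y <- rep(0:1, each = 15)
  cb <- walsh_codebook(5, 8)
  cfg <- train_config(hidden = 8L, epochs = 40L, learning_rate = 5e-3,
                      feature_noise_sd = 0, seed = 2L)
  r <- train_bilstm(X, y, cfg, codebook = cb)
  expect_equal(r$model$head_mode, "walsh")
  expect_equal(r$model$out_dim, 8L)
  pred <- predict_bilstm(r$model, X)
  expect_gt(mean(pred == y), 0.9)
})
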