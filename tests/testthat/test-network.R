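test_that("parameter count matches the closed-form LSTM + dense formula", {
  expect_equal(lstm_param_count(211, 512, 812),
               4 * (512 * (211 + 512) + 512) + (512 * 812 + 812))
  W <- duallex:::init_lstm_weights(211, 8, 12, seed = 1)
  got <- sum(vapply(W, length, 1L))
  expect_equal(got, lstm_param_count(211, 8, 12))
})

test_that("talker holdout splits are disjoint and sized one token per word", {
  tokens <- expand.grid(word = paste0("w", 1:30),
                        talker = paste0("t", 1:10),
                        stringsAsFactors = FALSE)
  sp <- split_train_val(tokens, seed = 1)
  expect_length(sp$val, 30)                     # one held-out token per word
  expect_length(intersect(sp$train, sp$val), 0)
  expect_equal(length(sp$train) / length(sp$val), 9)
  expect_true(all(tokens$talker[sp$val] == sp$holdout_talker))
  # 4 talkers: 3:1 split
  t4 <- expand.grid(word = paste0("w", 1:8), talker = paste0("t", 1:4),
                    stringsAsFactors = FALSE)
  s4 <- split_train_val(t4, seed = 2)
  expect_equal(length(s4$train) / length(s4$val), 3)
  pw <- split_train_val(t4, holdout = "per_word", seed = 3)
  expect_length(pw$val, 8)
  expect_error(split_train_val(data.frame(word = "w", talker = "t")),
               "two talkers")
})

test_that("analytic gradients match central finite differences", {
  set.seed(10)
  N <- 4; T <- 5; F <- 6; H <- 3; O <- 4
  x <- array(runif(N * T * F), c(N, T, F))
  y <- matrix(runif(N * O), N, O)
  nv <- c(5L, 3L, 4L, 5L)
  W <- duallex:::init_lstm_weights(F, H, O, seed = 3)
  cube <- aperm(x, c(3, 1, 2))
  g <- duallex:::cpp_lstm_grad(W, cube, nv, t(y))
  eps <- 1e-2
  for (nm in c("Wx", "Wh", "Wd")) {
    idx <- cbind(c(1, 2), c(1, 2))
    for (r in 1:2) {
      Wp <- W; Wm <- W
      Wp[[nm]][idx[r, 1], idx[r, 2]] <- Wp[[nm]][idx[r, 1], idx[r, 2]] + eps
      Wm[[nm]][idx[r, 1], idx[r, 2]] <- Wm[[nm]][idx[r, 1], idx[r, 2]] - eps
      num <- (duallex:::cpp_lstm_loss(Wp, cube, nv, t(y)) -
              duallex:::cpp_lstm_loss(Wm, cube, nv, t(y))) / (2 * eps)
      expect_equal(g[[nm]][idx[r, 1], idx[r, 2]], num, tolerance = 5e-2)
    }
  }
})

test_that("trailing padding never changes predictions or hidden states", {
  toy <- fix_toy_net()
  x <- toy$x
  T <- dim(x)[2]
  xpad <- array(0, c(dim(x)[1], T + 50, dim(x)[3]))
  xpad[, 1:T, ] <- x
  nv <- rep(T, dim(x)[1])
  cube1 <- aperm(x, c(3, 1, 2))
  cube2 <- aperm(xpad, c(3, 1, 2))
  W <- toy$net$weights
  o1 <- duallex:::cpp_lstm_forward(W, cube1, nv, TRUE)
  o2 <- duallex:::cpp_lstm_forward(W, cube2, nv, TRUE)
  expect_identical(o1$prediction, o2$prediction)
  expect_identical(o1$final_hidden, o2$final_hidden)
  # clamped frames repeat the final valid state exactly
  for (tt in (T + 1):(T + 50))
    expect_identical(o2$hidden[, , tt], o2$hidden[, , T])
})

test_that("sigmoid outputs and tanh hidden states stay in range", {
  toy <- fix_toy_net()
  p <- predict(toy$net, toy$x)
  expect_true(all(p > 0 & p < 1))
  h <- predict(toy$net, toy$x, type = "hidden")
  expect_true(all(h > -1 & h < 1))
})

test_that("final prediction equals the dense readout of the last valid state", {
  toy <- fix_toy_net()
  p <- predict(toy$net, toy$x)
  h <- predict(toy$net, toy$x, type = "hidden")
  W <- toy$net$weights
  T <- dim(h)[2]
  manual <- t(apply(h[, T, ], 1, function(hv)
    1 / (1 + exp(-(W$Wd %*% hv + W$bd)))))
  expect_equal(unname(p), unname(manual), tolerance = 1e-6)
})

test_that("training improves the loss and records the full history", {
  toy <- fix_toy_net()
  h <- toy$net$history
  expect_equal(nrow(h), toy$net$config$epochs /
                 toy$net$config$checkpoint_interval)
  expect_true(all(diff(h$epoch) > 0))
  expect_lt(tail(h$loss, 1), head(h$loss, 1))
  expect_gt(tail(h$train_cosine, 1), 0.8)
  expect_true(all(h$train_cosine >= 0 & h$train_cosine <= 1))
})

test_that("an untrained model predicts near the 0.5-constant cosine baseline", {
  set.seed(6)
  O <- 60
  y <- matrix(0, 10, O)
  for (i in 1:10) y[i, sample(O, 12)] <- 1
  x <- array(runif(10 * 8 * 5, 0, 0.5), c(10, 8, 5))
  W0 <- duallex:::init_lstm_weights(5, 4, O, seed = 1)
  p <- duallex:::cpp_lstm_forward(W0, aperm(x, c(3, 1, 2)), rep(8L, 10),
                                  FALSE)$prediction
  got <- mean(vapply(1:10, function(i) cosine_sim(p[, i], y[i, ]), 1.0))
  baseline <- mean(vapply(1:10, function(i)
    cosine_sim(rep(0.5, O), y[i, ]), 1.0))
  expect_equal(got, baseline, tolerance = 0.05)
})

test_that("saved models reload with bit-identical predictions", {
  toy <- fix_toy_net()
  path <- tempfile(fileext = ".rds")
  save_stream_net(toy$net, path)
  back <- load_stream_net(path)
  expect_identical(predict(back, toy$x), predict(toy$net, toy$x))
  unlink(path)
})

test_that("configuration errors are caught", {
  x <- array(runif(4 * 5 * 3), c(4, 5, 3))
  y <- matrix(runif(8), 4, 2)
  expect_error(stream_net(x, y, hidden = 4, epochs = 10,
                          checkpoint_interval = 3),
               "divide")
  expect_error(stream_net(x, y[1:3, ], hidden = 4, epochs = 10,
                          checkpoint_interval = 5))
})

test_that("model methods print, summarize, and expose coefficients", {
  toy <- fix_toy_net()
  expect_output(print(toy$net), "Masked LSTM")
  expect_output(summary(toy$net), "Checkpoint history")
  expect_named(coef(toy$net), c("Wx", "Wh", "b", "Wd", "bd"))
  r <- residuals(toy$net)
  expect_equal(dim(r), dim(toy$y))
  expect_equal(unname(as.matrix(toy$y - fitted(toy$net))), unname(r))
})
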