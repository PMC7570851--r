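test_that("single neurons follow the affine-plus-activation rule", {
  p <- ann_init(c(1, 1), "linear", seed = 1)
  p$W[[1]][] <- 2; p$b[[1]] <- 1
  expect_equal(ann_forward(3, p), 7)

  r <- ann_init(c(1, 1), "relu", seed = 1)
  r$W[[1]][] <- 1; r$b[[1]] <- 0
  expect_equal(ann_forward(-1, r), 0)
  expect_equal(ann_forward(2, r), 2)

  t <- ann_init(c(3, 1), "tanh", seed = 1)
  t$b[[1]] <- 0
  expect_equal(ann_forward(c(0, 0, 0), t), 0)

  s <- ann_init(c(1, 1), "logsig", seed = 1)
  s$W[[1]][] <- 1; s$b[[1]] <- 0
  expect_equal(ann_forward(0, s), 0.5)

  expect_error(ann_forward(c(1, 2), p), "input width")
})

finite_diff_grads <- function(params, X, Y, eps = 1e-6) {
  num <- list(dW = params$W, db = params$b)
  for (l in seq_along(params$W)) {
    for (i in seq_along(params$W[[l]])) {
      up <- params; up$W[[l]][i] <- up$W[[l]][i] + eps
      dn <- params; dn$W[[l]][i] <- dn$W[[l]][i] - eps
      num$dW[[l]][i] <- (ann_mse_grad(up, X, Y)$loss -
                           ann_mse_grad(dn, X, Y)$loss) / (2 * eps)
    }
    for (i in seq_along(params$b[[l]])) {
      up <- params; up$b[[l]][i] <- up$b[[l]][i] + eps
      dn <- params; dn$b[[l]][i] <- dn$b[[l]][i] - eps
      num$db[[l]][i] <- (ann_mse_grad(up, X, Y)$loss -
                           ann_mse_grad(dn, X, Y)$loss) / (2 * eps)
    }
  }
  num
}

test_that("backpropagated gradients match central finite differences", {
  set.seed(5)
  X <- matrix(rnorm(24), 6, 4)
  Y <- matrix(rnorm(12), 6, 2)
  for (acts in list(c("tanh", "linear"), c("logsig", "tanh"),
                    c("relu", "linear"))) {
    p <- ann_init(c(4, 5, 2), acts, seed = 8)
    # keep ReLU pre-activations away from the kink
    if (acts[1] == "relu") p$b[[1]] <- p$b[[1]] + 0.5
    g <- ann_mse_grad(p, X, Y)
    num <- finite_diff_grads(p, X, Y)
    for (l in 1:2) {
      denom <- pmax(abs(num$dW[[l]]), 1e-4)
      expect_lt(max(abs(g$dW[[l]] - num$dW[[l]]) / denom), 1e-5)
      denomb <- pmax(abs(num$db[[l]]), 1e-4)
      expect_lt(max(abs(g$db[[l]] - num$db[[l]]) / denomb), 1e-5)
    }
  }
})

test_that("training reduces the loss and is seed-reproducible", {
  set.seed(3)
  X <- matrix(rnorm(80), 40, 2)
  Y <- cbind(X %*% c(1, -2) + 0.5)
  cfg <- train_config(learning_rate = 0.02, epochs = 50, seed = 9,
                      validation_fraction = 0)
  fit <- train_ann(X, Y, hidden = 4, cfg = cfg)
  h <- attr(fit, "history")
  expect_lt(h[50], h[1])

  fit2 <- train_ann(X, Y, hidden = 4, cfg = cfg)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$b, fit2$b)

  sgd <- train_ann(X, Y, hidden = 4,
                   cfg = train_config(learning_rate = 0.05, epochs = 30,
                                      optimizer = "sgd", seed = 9,
                                      validation_fraction = 0))
  hs <- attr(sgd, "history")
  expect_lt(hs[30], hs[1])
})

test_that("dropout only acts in training mode", {
  p <- ann_init(c(3, 16, 2), c("tanh", "linear"), keep_prob = 0.6, seed = 2)
  x <- c(0.3, -0.2, 0.9)
  out1 <- ann_forward(x, p)
  out2 <- ann_forward(x, p)
  expect_identical(out1, out2)  # prediction mode ignores the RNG

  set.seed(1); tr1 <- ann_forward(x, p, train_mode = TRUE)
  set.seed(2); tr2 <- ann_forward(x, p, train_mode = TRUE)
  expect_false(isTRUE(all.equal(tr1, tr2)))

  expect_error(ann_init(c(3, 4, 2), c("tanh", "linear"), keep_prob = 0),
               "keep probabilities")
})

test_that("divergent training reports epoch and learning rate", {
  set.seed(4)
  X <- matrix(rnorm(40), 20, 2)
  Y <- matrix(rnorm(20) * 1e3, 20, 1)
  # unbounded linear layers with an oversized SGD step blow up quadratically
  expect_error(
    train_ann(X, Y, hidden = 4, activations = c("linear", "linear"),
              cfg = train_config(learning_rate = 5, epochs = 1000,
                                 optimizer = "sgd", seed = 1,
                                 validation_fraction = 0)),
    "diverged")
})
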