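test_that("an identity feature map reduces DKL to the plain GP", {
  set.seed(21)
  X <- matrix(rnorm(40), 10, 4)
  Y <- cbind(a = rnorm(10), b = rnorm(10))
  # square linear layer wired to the identity
  net <- ann_init(c(4, 4), "linear", seed = 1)
  net$W[[1]] <- diag(4); net$b[[1]] <- rep(0, 4)
  spec <- kernel_spec("rbf", length_scale = 1.1, noise_var = 0.05)
  st <- dkl_state(net, X, Y, spec)
  Xs <- matrix(rnorm(12), 3, 4)
  got <- dkl_predict(st, Xs)
  for (j in 1:2) {
    ref <- gp_predict(gp_fit(X, Y[, j], spec, optimize = FALSE), Xs)
    expect_close(got$mean[, j], ref$mean, tol = 1e-10)
    expect_close(got$variance[, j], ref$variance, tol = 1e-10)
  }
})

test_that("joint objective gradients match finite differences", {
  set.seed(22)
  X <- matrix(rnorm(36), 9, 4)
  Y <- matrix(rnorm(18), 9, 2)
  net <- ann_init(c(4, 3, 2), c("tanh", "linear"), seed = 5)
  log_l <- c(0.1, -0.2); log_s2 <- c(log(0.3), log(0.2))
  objective <- function(net) {
    Z <- ann_forward(X, net)
    ionsense:::dkl_heads_grad(Z, Y, "rbf", log_l, log_s2)$value
  }
  pass <- ionsense:::ann_forward_pass(net, X)
  Z <- pass$a[[3]]
  hg <- ionsense:::dkl_heads_grad(Z, Y, "rbf", log_l, log_s2)
  ng <- ionsense:::ann_backprop(net, pass, hg$dZ)
  eps <- 1e-6
  for (l in 1:2) {
    idx <- seq_len(min(6, length(net$W[[l]])))
    for (i in idx) {
      up <- net; up$W[[l]][i] <- up$W[[l]][i] + eps
      dn <- net; dn$W[[l]][i] <- dn$W[[l]][i] - eps
      num <- (objective(up) - objective(dn)) / (2 * eps)
      expect_close(ng$dW[[l]][i], num, tol = 1e-5 * max(1, abs(num)))
    }
  }
  # kernel-parameter gradients
  for (j in 1:2) {
    up <- log_l; up[j] <- up[j] + eps
    dn <- log_l; dn[j] <- dn[j] - eps
    num <- (ionsense:::dkl_heads_grad(Z, Y, "rbf", up, log_s2)$value -
              ionsense:::dkl_heads_grad(Z, Y, "rbf", dn, log_s2)$value) /
      (2 * eps)
    expect_close(hg$g_logl[j], num, tol = 1e-5 * max(1, abs(num)))
    up2 <- log_s2; up2[j] <- up2[j] + eps
    dn2 <- log_s2; dn2[j] <- dn2[j] - eps
    num2 <- (ionsense:::dkl_heads_grad(Z, Y, "rbf", log_l, up2)$value -
               ionsense:::dkl_heads_grad(Z, Y, "rbf", log_l, dn2)$value) /
      (2 * eps)
    expect_close(hg$g_logs2[j], num2, tol = 1e-5 * max(1, abs(num2)))
  }
})

test_that("joint training raises the marginal likelihood and is reproducible", {
  set.seed(23)
  X <- matrix(runif(60, -1, 1), 30, 2)
  Y <- cbind(sin(2 * X[, 1]) + 0.1 * rnorm(30),
             X[, 2]^2 + 0.1 * rnorm(30))
  cfg <- train_config(learning_rate = 0.01, epochs = 40, seed = 7,
                      validation_fraction = 0)
  st <- dkl_fit(X, Y, hidden = 8, feature_dim = 2, cfg = cfg)
  obj <- attr(st, "objective")
  expect_gt(obj[40], obj[1])

  st2 <- dkl_fit(X, Y, hidden = 8, feature_dim = 2, cfg = cfg)
  Xs <- matrix(runif(10, -1, 1), 5, 2)
  expect_identical(dkl_predict(st, Xs)$mean, dkl_predict(st2, Xs)$mean)
})

test_that("the PCA start places early features in the leading subspace", {
  set.seed(24)
  Xraw <- matrix(rnorm(200), 50, 4) %*% diag(c(3, 2, 0.3, 0.1))
  X <- apply_scaler(fit_scaler(Xraw), Xraw)  # the map expects scaled inputs
  Y <- matrix(rnorm(100), 50, 2)
  cfg <- train_config(epochs = 1, seed = 3, validation_fraction = 0)
  st <- dkl_fit(X, Y, hidden = 8, feature_dim = 2, cfg = cfg, init = "pca")
  Z <- ann_forward(X, st$network)
  V <- eigen(cov(X), symmetric = TRUE)$vectors[, 1:2]
  # features after one epoch still correlate almost perfectly with the PCs
  expect_gt(abs(cor(Z[, 1], X %*% V[, 1])), 0.98)
  expect_gt(abs(cor(Z[, 2], X %*% V[, 2])), 0.98)
})
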