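test_that("kernel evaluations match closed forms", {
  rbf <- kernel_spec("rbf", length_scale = 0.7)
  x <- c(1, 2)
  expect_equal(kernel_eval(rbf, x, x), 1)
  # separation of l * sqrt(2) gives exp(-1)
  xp <- x + c(0.7 * sqrt(2), 0)
  expect_close(kernel_eval(rbf, x, xp), exp(-1), tol = 1e-12)

  dot <- kernel_spec("dot")
  expect_equal(kernel_eval(dot, c(1, 2), c(3, -1)), 1)

  # spectral mixture: zero frequency drops the cosine; k(x,x) = sum of weights
  sm1 <- kernel_spec("sm", components = list(list(a = 2, sigma = 1.5, mu = 0)))
  expect_equal(kernel_eval(sm1, x, x), 2)
  tau <- c(0.4, -0.3)
  expect_close(kernel_eval(sm1, x, x + tau),
               2 * exp(-sum((1.5 * tau)^2) / 2), tol = 1e-12)
  sm2 <- kernel_spec("sm")
  expect_equal(kernel_eval(sm2, x, x),
               sum(vapply(sm2$components, `[[`, numeric(1), "a")))

  K <- kernel_matrix(rbf, matrix(rnorm(10), 5, 2))
  expect_equal(K, t(K))
  expect_error(kernel_eval(rbf, c(1, 2), c(1, 2, 3)), "dimension")
  expect_error(kernel_matrix(kernel_spec("rbf", length_scale = -1),
                             matrix(0, 1, 1)),
               "length_scale")
})

test_that("log marginal likelihood matches scalar cases and is symmetric", {
  noiseless <- kernel_spec("rbf", length_scale = 1, noise_var = 0)
  expect_equal(gp_log_marginal(matrix(0, 1, 1), 0, noiseless), 0)
  expect_equal(gp_log_marginal(matrix(0, 1, 1), 2, noiseless), -4)

  set.seed(6)
  X <- matrix(rnorm(12), 6, 2); y <- rnorm(6)
  spec <- kernel_spec("rbf", length_scale = 0.8, noise_var = 0.05)
  o <- sample(6)
  expect_close(gp_log_marginal(X[o, ], y[o], spec),
               gp_log_marginal(X, y, spec), tol = 1e-9)
})

test_that("posterior mean and variance match a direct inversion oracle", {
  set.seed(8)
  for (n in c(2, 3, 5)) {
    X <- matrix(rnorm(2 * n), n, 2)
    y <- rnorm(n)
    spec <- kernel_spec("rbf", length_scale = 1.2, noise_var = 0.1)
    st <- gp_fit(X, y, spec, optimize = FALSE)
    Xs <- matrix(rnorm(6), 3, 2)
    pr <- gp_predict(st, Xs)
    K <- kernel_matrix(spec, X)
    A <- K + diag(0.1, n)
    Ks <- kernel_matrix(spec, Xs, X)
    mo <- drop(Ks %*% solve(A, y))
    vo <- 1 - diag(Ks %*% solve(A, t(Ks)))
    expect_close(pr$mean, mo, tol = 1e-10)
    expect_close(pr$variance, vo, tol = 1e-10)
  }
})

test_that("a noiseless GP interpolates and reverts to the prior far away", {
  X <- matrix(c(0, 1, 2.5), 3, 1)
  y <- c(1, -1, 0.5)
  st <- gp_fit(X, y, kernel_spec("rbf", length_scale = 0.8, noise_var = 0),
               optimize = FALSE)
  at_train <- gp_predict(st, X)
  expect_close(at_train$mean, y, tol = 1e-6)
  expect_close(at_train$variance, rep(0, 3), tol = 1e-6)

  far <- gp_predict(st, matrix(100, 1, 1))
  expect_close(far$mean, 0, tol = 1e-8)
  expect_close(far$variance, 1, tol = 1e-8)
})

test_that("posterior mean is linear in the targets and variance shrinks", {
  set.seed(12)
  X <- matrix(rnorm(8), 4, 2)
  y1 <- rnorm(4); y2 <- rnorm(4)
  spec <- kernel_spec("rbf", length_scale = 1, noise_var = 0.2)
  Xs <- matrix(rnorm(10), 5, 2)
  p1 <- gp_predict(gp_fit(X, y1, spec, optimize = FALSE), Xs)
  p2 <- gp_predict(gp_fit(X, y2, spec, optimize = FALSE), Xs)
  p12 <- gp_predict(gp_fit(X, y1 + y2, spec, optimize = FALSE), Xs)
  expect_close(p12$mean, p1$mean + p2$mean, tol = 1e-10)
  # information never increases the posterior variance above the prior
  expect_true(all(p1$variance <= 1 + 1e-12))
})

test_that("marginal-likelihood fitting recovers generative kernel parameters", {
  true_l <- 0.8; true_s2 <- 0.05
  ratios <- vapply(1:5, function(s) {
    set.seed(100 + s)
    X <- matrix(runif(40, -2, 2), 40, 1)
    K <- kernel_matrix(kernel_spec("rbf", length_scale = true_l), X)
    y <- drop(t(chol(K + diag(1e-10, 40))) %*% rnorm(40)) +
      rnorm(40, 0, sqrt(true_s2))
    fit <- gp_fit(X, y, kernel_spec("rbf", length_scale = 0.3,
                                    noise_var = 0.5))
    fit$spec$length_scale / true_l
  }, numeric(1))
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)
})

test_that("analytic likelihood gradients agree with finite differences", {
  set.seed(15)
  X <- matrix(rnorm(14), 7, 2); y <- rnorm(7)
  p <- c(log(0.9), log(0.07))
  g <- ionsense:::rbf_lml_grad(X, y, p[1], p[2])
  for (i in 1:2) {
    eps <- 1e-6
    up <- p; up[i] <- up[i] + eps
    dn <- p; dn[i] <- dn[i] - eps
    num <- (ionsense:::rbf_lml_grad(X, y, up[1], up[2])$value -
              ionsense:::rbf_lml_grad(X, y, dn[1], dn[2])$value) / (2 * eps)
    expect_close(g$grad[i], num, tol = 1e-5 * max(1, abs(num)))
  }
})
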