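#' Specify a covariance kernel
#'
#' Three kernels are supported: the squared-exponential / RBF kernel
#' `k(x, x') = exp(-|x - x'|^2 / (2 l^2))`, the dot-product kernel
#' `k(x, x') = <x, x'>`, and a spectral-mixture kernel
#' `k(tau) = sum_q a_q exp(-1/2 |sigma_q tau|^2) cos(2 pi <mu_q, tau>)`
#' with `tau = x - x'`, whose weights parameterize the variance directly so
#' that `k(x, x) = sum_q a_q`.
#'
#' @param kind `"rbf"`, `"dot"` or `"sm"`.
#' @param length_scale RBF length scale `l` (> 0).
#' @param noise_var observation noise variance added to the kernel diagonal
#'   during fitting (>= 0).
#' @param components for `"sm"`: list of `Q` lists with fields `a` (weight,
#'   >= 0), `sigma` (per-dimension inverse length scales) and `mu`
#'   (per-dimension frequencies).
#' @return an object of class `kernel_spec`.
#' @export
kernel_spec <- function(kind = c("rbf", "dot", "sm"), length_scale = 1,
                        noise_var = 0.01, components = NULL) {
  kind <- match.arg(kind)
  if (kind == "rbf" && !is.null(length_scale) && length_scale <= 0)
    stop_input("length_scale must be > 0")
  if (noise_var < 0) stop_input("noise_var must be >= 0")
  if (kind == "sm") {
    if (is.null(components))
      components <- list(list(a = 1, sigma = 1, mu = 0),
                         list(a = 1, sigma = 2, mu = 0.5))
    for (cm in components)
      if (cm$a < 0) stop_input("spectral-mixture weights must be >= 0")
  }
  structure(list(kind = kind, length_scale = length_scale,
                 noise_var = noise_var, components = components),
            class = "kernel_spec")
}

# pairwise squared Euclidean distances between rows
sqdist <- function(X, Xp) {
  d2 <- outer(rowSums(X^2), rowSums(Xp^2), "+") - 2 * tcrossprod(X, Xp)
  pmax(d2, 0)
}

#' Evaluate the kernel matrix between two sets of points
#'
#' @param spec a [kernel_spec()].
#' @param X,Xp numeric matrices (rows = points); `Xp = NULL` means `X`.
#' @return covariance matrix `nrow(X) x nrow(Xp)`.
#' @export
kernel_matrix <- function(spec, X, Xp = NULL) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1) else as.matrix(X)
  Xp <- if (is.null(Xp)) X else
    if (is.null(dim(Xp))) matrix(Xp, ncol = 1) else as.matrix(Xp)
  if (ncol(X) != ncol(Xp)) stop_input("dimension mismatch")
  switch(spec$kind,
    rbf = {
      if (spec$length_scale <= 0) stop_input("length_scale must be > 0")
      exp(-sqdist(X, Xp) / (2 * spec$length_scale^2))
    },
    dot = tcrossprod(X, Xp),
    sm = {
      K <- matrix(0, nrow(X), nrow(Xp))
      for (cm in spec$components) {
        sig <- rep(cm$sigma, length.out = ncol(X))
        mu <- rep(cm$mu, length.out = ncol(X))
        A <- sqdist(sweep(X, 2, sig, "*"), sweep(Xp, 2, sig, "*"))
        B <- outer(drop(X %*% mu), drop(Xp %*% mu), "-")
        K <- K + cm$a * exp(-A / 2) * cos(2 * pi * B)
      }
      K
    })
}

#' Evaluate the kernel for a single pair of points
#' @inheritParams kernel_matrix
#' @param x,xp numeric vectors of equal length.
#' @return scalar covariance.
#' @export
kernel_eval <- function(spec, x, xp) {
  if (length(x) != length(xp)) stop_input("dimension mismatch")
  drop(kernel_matrix(spec, matrix(x, 1), matrix(xp, 1)))
}

# Cholesky with an escalating jitter ladder (1e-8 ... 1e-4 of the average
# diagonal) before giving up
chol_jitter <- function(A) {
  scale <- mean(diag(A))
  for (j in c(0, 10^(-8:-4)) * max(scale, 1)) {
    U <- tryCatch(chol(A + diag(j, nrow(A))), error = function(e) NULL)
    if (!is.null(U)) return(U)
  }
  stop_input("covariance factorization failed after maximum jitter")
}

#' Log marginal likelihood of GP targets
#'
#' Up to an additive constant and factor 1/2:
#' `-y' (K + sigma^2 I)^-1 y - log det(K + sigma^2 I)`.
#'
#' @param X training inputs (matrix, rows = points).
#' @param y training targets.
#' @param spec a [kernel_spec()] (its `noise_var` supplies `sigma^2`).
#' @return finite scalar.
#' @export
gp_log_marginal <- function(X, y, spec) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1) else as.matrix(X)
  K <- kernel_matrix(spec, X)
  A <- K + diag(spec$noise_var, nrow(K))
  U <- chol_jitter(A)
  alpha <- backsolve(U, forwardsolve(t(U), y))
  -sum(y * alpha) - 2 * sum(log(diag(U)))
}

# marginal likelihood and gradient wrt (log l, log sigma^2) for RBF
rbf_lml_grad <- function(X, y, log_l, log_s2) {
  l <- exp(log_l); s2 <- exp(log_s2)
  D2 <- sqdist(X, X)
  K <- exp(-D2 / (2 * l^2))
  A <- K + diag(s2, nrow(K))
  U <- chol_jitter(A)
  alpha <- backsolve(U, forwardsolve(t(U), y))
  Ainv <- chol2inv(U)
  M <- tcrossprod(alpha) - Ainv          # dL/dA
  value <- -sum(y * alpha) - 2 * sum(log(diag(U)))
  # dK/dl = K * D2 / l^3 ; chain to log l multiplies by l
  g_logl <- sum(M * (K * D2)) / l^2
  g_logs2 <- sum(diag(M)) * s2
  list(value = value, grad = c(g_logl, g_logs2))
}

#' Fit a Gaussian-process regressor
#'
#' Zero prior mean. Kernel parameters (RBF length scale and noise variance;
#' all spectral-mixture parameters) are estimated by maximizing the log
#' marginal likelihood — analytically differentiated L-BFGS for the RBF
#' kernel, numerical gradients otherwise. The fit is deterministic.
#'
#' @param X training inputs (matrix, rows = points).
#' @param y training targets.
#' @param spec initial [kernel_spec()]; `length_scale = NULL` requests the
#'   median-pairwise-distance initialization.
#' @param optimize set `FALSE` to condition on the supplied parameters
#'   without fitting them.
#' @return an object of class `gp_state` holding the fitted `kernel_spec`,
#'   the training data, and the cached Cholesky factorization.
#' @export
gp_fit <- function(X, y, spec = kernel_spec("rbf", length_scale = NULL),
                   optimize = TRUE) {
  X <- if (is.null(dim(X))) matrix(X, ncol = 1) else as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop_input("X and y sizes differ")
  if (spec$kind == "rbf" && is.null(spec$length_scale)) {
    d <- sqrt(sqdist(X, X)); d <- d[upper.tri(d)]
    spec$length_scale <- max(median(d), 1e-3)
  }
  if (optimize) {
    if (spec$kind == "rbf") {
      obj <- function(p) -rbf_lml_grad(X, y, p[1], p[2])$value
      grd <- function(p) -rbf_lml_grad(X, y, p[1], p[2])$grad
      p0 <- c(log(spec$length_scale), log(max(spec$noise_var, 1e-6)))
      opt <- optim(p0, obj, grd, method = "L-BFGS-B",
                   lower = c(log(1e-3), log(1e-8)),
                   upper = c(log(1e4), log(1e4)))
      spec$length_scale <- exp(opt$par[1])
      spec$noise_var <- exp(opt$par[2])
    } else if (spec$kind == "dot") {
      obj <- function(p) {
        s <- spec; s$noise_var <- exp(p)
        -gp_log_marginal(X, y, s)
      }
      opt <- optim(log(max(spec$noise_var, 1e-6)), obj, method = "Brent",
                   lower = log(1e-8), upper = log(1e4))
      spec$noise_var <- exp(opt$par)
    } else {
      pack <- function(s) unlist(lapply(s$components, function(cm)
        c(log(max(cm$a, 1e-8)), log(pmax(cm$sigma, 1e-8)), cm$mu)))
      unpack <- function(p) {
        s <- spec; i <- 1
        d <- length(s$components[[1]]$sigma)
        for (q in seq_along(s$components)) {
          s$components[[q]]$a <- exp(p[i]); i <- i + 1
          s$components[[q]]$sigma <- exp(p[i:(i + d - 1)]); i <- i + d
          s$components[[q]]$mu <- p[i:(i + d - 1)]; i <- i + d
        }
        s$noise_var <- exp(p[length(p)])
        s
      }
      obj <- function(p) -gp_log_marginal(X, y, unpack(p))
      p0 <- c(pack(spec), log(max(spec$noise_var, 1e-6)))
      opt <- optim(p0, obj, method = "BFGS",
                   control = list(maxit = 200))
      spec <- unpack(opt$par)
    }
  }
  K <- kernel_matrix(spec, X)
  U <- chol_jitter(K + diag(spec$noise_var, nrow(K)))
  structure(list(spec = spec, X = X, y = y, chol = U,
                 alpha = backsolve(U, forwardsolve(t(U), y))),
            class = "gp_state")
}

#' @export
print.gp_state <- function(x, ...) {
  cat(sprintf("<gp_state> %s kernel, n = %d", x$spec$kind, nrow(x$X)))
  if (x$spec$kind == "rbf")
    cat(sprintf(", l = %.4g", x$spec$length_scale))
  cat(sprintf(", noise_var = %.4g\n", x$spec$noise_var))
  invisible(x)
}

#' Posterior mean and variance of a fitted GP
#'
#' Closed-form conditioning under the zero-mean prior:
#' mean `K(X*, X) A^-1 y`, variance
#' `K(X*, X*) - K(X*, X) A^-1 K(X, X*)` with `A = K(X, X) + sigma^2 I`
#' (latent-function variance, without the observation noise).
#'
#' @param state a `gp_state`.
#' @param Xs query inputs (matrix or vector).
#' @return list with numeric vectors `mean` and `variance`.
#' @export
gp_predict <- function(state, Xs) {
  if (!inherits(state, "gp_state")) stop_input("state must be a gp_state")
  Xs <- if (is.null(dim(Xs))) matrix(Xs, ncol = ncol(state$X)) else as.matrix(Xs)
  Ks <- kernel_matrix(state$spec, Xs, state$X)
  mu <- drop(Ks %*% state$alpha)
  v <- forwardsolve(t(state$chol), t(Ks))
  kss <- switch(state$spec$kind,
    rbf = rep(1, nrow(Xs)),
    dot = rowSums(Xs^2),
    sm = rep(sum(vapply(state$spec$components, `[[`, numeric(1), "a")),
             nrow(Xs)))
  list(mean = mu, variance = pmax(kss - colSums(v^2), 0))
}
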