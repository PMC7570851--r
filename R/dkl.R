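#' Assemble a deep-kernel-learning state from fixed parts
#'
#' Conditions one GP head per target column on the network-mapped features
#' without touching any parameter. Used internally by [dkl_fit()] and
#' directly when the network and kernels are already decided (e.g. an
#' identity feature map reduces DKL to a plain GP).
#'
#' @param network an `ann_params` feature map.
#' @param X training feature matrix (network input width).
#' @param Y target matrix, one column per ion.
#' @param kernels a single [kernel_spec()] (recycled) or a list of one spec
#'   per target column.
#' @return an object of class `dkl_state`.
#' @export
dkl_state <- function(network, X, Y, kernels) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  Z <- ann_forward(X, network)
  if (inherits(kernels, "kernel_spec"))
    kernels <- rep(list(kernels), ncol(Y))
  heads <- lapply(seq_len(ncol(Y)), function(m)
    gp_fit(Z, Y[, m], kernels[[m]], optimize = FALSE))
  structure(list(network = network, heads = heads,
                 targets = colnames(Y) %||% paste0("y", seq_len(ncol(Y)))),
            class = "dkl_state")
}

#' @export
print.dkl_state <- function(x, ...) {
  cat(sprintf("<dkl_state> %s -> %d features -> %d GP heads (%s kernel)\n",
              paste(x$network$sizes, collapse = "-"),
              x$network$sizes[length(x$network$sizes)],
              length(x$heads), x$heads[[1]]$spec$kind))
  invisible(x)
}

# start the feature map near the leading principal-component projection of
# the training features: a scaled identity through the (near-linear) small-
# argument range of the first tanh layer, identity relays through middle
# layers, and the leading loadings in the final weight layer
pca_init <- function(net, X, feature_dim) {
  d <- net$sizes[1]
  n_layers <- length(net$W)
  V <- eigen(cov(X), symmetric = TRUE)$vectors[, seq_len(min(feature_dim, d)),
                                               drop = FALSE]
  s <- 0.4  # keeps first-layer pre-activations well inside tanh linearity
  embed <- function(n_in, n_out, M) {
    W <- matrix(0, n_in, n_out)
    k <- min(n_in, ncol(M)); W[seq_len(nrow(M)), seq_len(ncol(M))] <- M
    W
  }
  if (n_layers == 1L) {
    net$W[[1]] <- V * if (net$activations[1] == "tanh") s else 1
    net$b[[1]] <- rep(0, ncol(V))
    return(net)
  }
  if (net$sizes[2] >= d) {
    net$W[[1]] <- embed(d, net$sizes[2], diag(s, d))
    carry <- d   # width of the live identity block
  } else {
    net$W[[1]] <- s * V[, seq_len(min(ncol(V), net$sizes[2])), drop = FALSE]
    carry <- ncol(net$W[[1]])
  }
  net$b[[1]] <- rep(0, net$sizes[2])
  for (l in seq(2, n_layers)) {
    width <- net$sizes[l + 1L]
    if (l == n_layers) {
      M <- if (carry == d) V / s else diag(1 / s, carry)
      net$W[[l]] <- embed(net$sizes[l], width, M[, seq_len(min(ncol(M), width)),
                                                 drop = FALSE])
    } else {
      # unit relay keeps the carried block at gain ~ s through tanh layers
      net$W[[l]] <- embed(net$sizes[l], width, diag(1, min(carry, width)))
      carry <- min(carry, width)
    }
    net$b[[l]] <- rep(0, width)
  }
  net
}

# held-out mean squared error of the GP posterior means at the current
# joint parameters (network in prediction mode, no dropout)
dkl_holdout_error <- function(net, kind, log_l, log_s2, Xtr, Ytr, Xv, Yv) {
  Ztr <- ann_forward(Xtr, net)
  Zv <- ann_forward(Xv, net)
  if (is.null(dim(Zv))) Zv <- matrix(Zv, nrow = 1)
  err <- 0
  for (j in seq_len(ncol(Ytr))) {
    spec <- kernel_spec(kind,
                        length_scale = if (kind == "rbf") exp(log_l[j]) else 1,
                        noise_var = exp(log_s2[j]))
    K <- kernel_matrix(spec, Ztr)
    U <- chol_jitter(K + diag(spec$noise_var, nrow(K)))
    alpha <- backsolve(U, forwardsolve(t(U), Ytr[, j]))
    mu <- drop(kernel_matrix(spec, Zv, Ztr) %*% alpha)
    err <- err + mean((mu - Yv[, j])^2)
  }
  err
}

# summed per-head log marginal likelihood, its gradient wrt the shared
# feature matrix Z, and per-head kernel-parameter gradients
dkl_heads_grad <- function(Z, Y, kind, log_l, log_s2) {
  n <- nrow(Z); m <- ncol(Y)
  D2 <- if (kind == "rbf") sqdist(Z, Z) else NULL
  dZ <- matrix(0, n, ncol(Z))
  value <- 0
  g_logl <- numeric(m); g_logs2 <- numeric(m)
  for (j in seq_len(m)) {
    y <- Y[, j]
    if (kind == "rbf") {
      l <- exp(log_l[j])
      K <- exp(-D2 / (2 * l^2))
    } else K <- tcrossprod(Z)
    s2 <- exp(log_s2[j])
    U <- chol_jitter(K + diag(s2, n))
    alpha <- backsolve(U, forwardsolve(t(U), y))
    M <- tcrossprod(alpha) - chol2inv(U)
    value <- value - sum(y * alpha) - 2 * sum(log(diag(U)))
    g_logs2[j] <- sum(diag(M)) * s2
    if (kind == "rbf") {
      g_logl[j] <- sum(M * (K * D2)) / l^2
      G <- M * K
      dZ <- dZ + (2 / l^2) * (G %*% Z - rowSums(G) * Z)
    } else {
      dZ <- dZ + 2 * (M %*% Z)
    }
  }
  list(value = value, dZ = dZ, g_logl = g_logl, g_logs2 = g_logs2)
}

#' Fit a deep-kernel-learning model
#'
#' One shared feed-forward network maps the scaled 17-dimensional input to a
#' low-dimensional feature space; one GP head per target ion places a kernel
#' over those features. Network weights and kernel parameters are trained
#' *jointly* by full-batch gradient ascent (Adam) on the summed per-head log
#' marginal likelihood. Deterministic given the seed.
#'
#' @param X scaled feature matrix.
#' @param Y target matrix (one column per ion).
#' @param hidden hidden-layer widths of the feature map.
#' @param feature_dim width of the network output handed to the GP heads;
#'   typically the [select_pc_count()] result (default 8).
#' @param kernel `"rbf"` (default) or `"dot"`; the base kernel of every head.
#' @param activations per-layer activations (default tanh hidden layers and
#'   a ReLU feature layer).
#' @param cfg a [train_config()].
#' @param keep_prob dropout keep-probability for hidden layers during
#'   training.
#' @param pretrain_epochs supervised warm-start: the feature network plus a
#'   temporary linear readout is first trained on the targets by mean
#'   squared error for this many epochs, then the readout is dropped and
#'   the joint marginal-likelihood ascent starts from the learned features
#'   (0 disables the warm start).
#' @param init `"pca"` (default) starts the feature map near the principal-
#'   component projection of the training features — the first (tanh) layer
#'   embeds a scaled identity inside its linear range and the last layer
#'   holds the leading loadings, so training begins from the same subspace
#'   the explained-variance sizing rule reasons about; `"glorot"` uses plain
#'   random initialization.
#' @return a `dkl_state` with an `objective` attribute (per-epoch summed log
#'   marginal likelihood).
#' @export
dkl_fit <- function(X, Y, hidden = c(64, 32), feature_dim = 8,
                    kernel = c("rbf", "dot"), activations = NULL,
                    cfg = train_config(learning_rate = 0.01),
                    keep_prob = 1, pretrain_epochs = 0,
                    init = c("pca", "glorot")) {
  kernel <- match.arg(kernel)
  init <- match.arg(init)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_input("X and Y row counts differ")
  sizes <- c(ncol(X), hidden, feature_dim)
  if (is.null(activations))
    activations <- c(rep("tanh", length(hidden)), "linear")
  net <- ann_init(sizes, activations, keep_prob = keep_prob, seed = cfg$seed)
  if (init == "pca") net <- pca_init(net, X, feature_dim)
  if (pretrain_epochs > 0) {
    pre_cfg <- train_config(learning_rate = cfg$learning_rate,
                            epochs = pretrain_epochs,
                            optimizer = cfg$optimizer, seed = cfg$seed,
                            validation_fraction = 0)
    pre <- train_ann(X, Y, hidden = c(hidden, feature_dim),
                     activations = c(activations, "linear"),
                     cfg = pre_cfg, keep_prob = keep_prob)
    net$W <- pre$W[seq_along(net$W)]
    net$b <- pre$b[seq_along(net$b)]
  }
  m <- ncol(Y)
  Z0 <- ann_forward(X, net)
  d0 <- sqrt(sqdist(Z0, Z0)); d0 <- median(d0[upper.tri(d0)])
  log_l <- rep(log(max(d0, 0.1)), m)
  log_s2 <- rep(log(0.05), m)
  n_w <- length(net$W)
  n <- nrow(X)
  # epoch selection on a held-out split: likelihood gradients come from the
  # training rows; the epoch with the best held-out prediction error wins
  val_idx <- integer(0)
  if (cfg$validation_fraction > 0 && n >= 20) {
    n_val <- max(2L, floor(cfg$validation_fraction * n))
    val_idx <- with_seed(cfg$seed + 1L, sample.int(n, n_val))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate,
                        c(lapply(flatten_params(net), function(p)
                            dim(p) %||% length(p)),
                          list(m, m)))
  objective <- numeric(cfg$epochs)
  best <- list(err = Inf, net = net, log_l = log_l, log_s2 = log_s2)
  with_seed(cfg$seed + 2L, {
    for (epoch in seq_len(cfg$epochs)) {
      masks <- draw_dropout_masks(net, nrow(Xtr))
      pass <- ann_forward_pass(net, Xtr, masks)
      Z <- pass$a[[n_w + 1L]]
      hg <- dkl_heads_grad(Z, Ytr, kernel, log_l, log_s2)
      if (!is.finite(hg$value))
        stop_input("DKL training diverged at epoch ", epoch,
                   " with learning rate ", cfg$learning_rate)
      objective[epoch] <- hg$value
      ng <- ann_backprop(net, pass, hg$dZ)
      # Adam minimizes, so feed the negated ascent direction
      flat <- c(flatten_params(net), list(log_l, log_s2))
      grad <- c(lapply(c(ng$dW, ng$db), `-`),
                list(-hg$g_logl, -hg$g_logs2))
      flat <- opt$step(flat, grad, epoch)
      net <- unflatten_params(net, flat[seq_len(2L * n_w)])
      # clamp kernel parameters to a sane numerical range
      log_l <- pmin(pmax(flat[[2L * n_w + 1L]], log(1e-2)), log(1e3))
      log_s2 <- pmin(pmax(flat[[2L * n_w + 2L]], log(1e-4)), log(1e4))
      if (length(val_idx)) {
        err <- dkl_holdout_error(net, kernel, log_l, log_s2, Xtr, Ytr,
                                 X[val_idx, , drop = FALSE],
                                 Y[val_idx, , drop = FALSE])
        if (err < best$err)
          best <- list(err = err, net = net, log_l = log_l, log_s2 = log_s2)
      }
    }
  })
  if (length(val_idx) && is.finite(best$err)) {
    net <- best$net; log_l <- best$log_l; log_s2 <- best$log_s2
  }
  kernels <- lapply(seq_len(m), function(j)
    kernel_spec(kernel, length_scale = if (kernel == "rbf") exp(log_l[j]) else 1,
                noise_var = exp(log_s2[j])))
  # final heads condition on all rows at the selected parameters
  state <- dkl_state(net, X, Y, kernels)
  attr(state, "objective") <- objective
  state
}

#' Predict with a deep-kernel-learning model
#'
#' Maps the queries through the network (dropout disabled) and conditions
#' each GP head on its training factorization.
#'
#' @param state a `dkl_state`.
#' @param X query feature matrix (same scaling as training).
#' @return list with matrices `mean` and `variance`
#'   (`n x n_targets`, columns named by target).
#' @export
dkl_predict <- function(state, X) {
  if (!inherits(state, "dkl_state")) stop_input("state must be a dkl_state")
  Z <- ann_forward(as.matrix(X), state$network)
  if (is.null(dim(Z))) Z <- matrix(Z, nrow = 1)
  preds <- lapply(state$heads, gp_predict, Xs = Z)
  list(mean = vapply(preds, `[[`, numeric(nrow(Z)), "mean") |>
         matrix(nrow(Z), dimnames = list(NULL, state$targets)),
       variance = vapply(preds, `[[`, numeric(nrow(Z)), "variance") |>
         matrix(nrow(Z), dimnames = list(NULL, state$targets)))
}
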