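#' @keywords internal
activation_fun <- function(z, tag) {
  switch(tag,
    tanh   = tanh(z),
    logsig = 1 / (1 + exp(-z)),
    linear = z,
    relu   = pmax(z, 0),
    stop_input("unknown activation: ", tag))
}

# derivative of the activation wrt its argument, expressed through the
# already-computed activation value where cheap
activation_grad <- function(z, a, tag) {
  switch(tag,
    tanh   = 1 - a^2,
    logsig = a * (1 - a),
    linear = array(1, dim = dim(z) %||% length(z)),
    relu   = (z > 0) * 1,
    stop_input("unknown activation: ", tag))
}

#' Initialize feed-forward network parameters
#'
#' Glorot-uniform weight initialization, zero biases, seeded.
#'
#' @param sizes integer vector of layer widths including input and output,
#'   e.g. `c(17, 64, 32, 8)`.
#' @param activations character vector of per-layer activation tags
#'   (`"tanh"`, `"logsig"`, `"linear"`, `"relu"`), one per weight layer.
#' @param keep_prob dropout keep-probability in (0, 1], scalar or one value
#'   per hidden layer (the output layer is never dropped). 1 disables
#'   dropout.
#' @param seed integer seed.
#' @return an object of class `ann_params` with weight matrices `W`
#'   (`d_in x d_out`), bias vectors `b`, `activations` and `keep_prob`.
#' @export
ann_init <- function(sizes, activations, keep_prob = 1, seed = 1) {
  n_layers <- length(sizes) - 1L
  if (length(activations) != n_layers)
    stop_input("need one activation per weight layer")
  keep <- rep(keep_prob, length.out = max(n_layers - 1L, 0L))
  if (any(keep <= 0) || any(keep > 1))
    stop_input("keep probabilities must lie in (0, 1]")
  W <- vector("list", n_layers); b <- vector("list", n_layers)
  with_seed(seed, {
    for (l in seq_len(n_layers)) {
      lim <- sqrt(6 / (sizes[l] + sizes[l + 1]))
      W[[l]] <- matrix(runif(sizes[l] * sizes[l + 1], -lim, lim),
                       sizes[l], sizes[l + 1])
      b[[l]] <- rep(0, sizes[l + 1])
    }
  })
  structure(list(W = W, b = b, activations = activations, keep_prob = keep,
                 sizes = as.integer(sizes)),
            class = "ann_params")
}

# full forward pass keeping intermediates for backprop; masks is a list of
# inverted-dropout masks per hidden layer (NULL = no dropout)
ann_forward_pass <- function(params, X, masks = NULL) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != params$sizes[1])
    stop_input("input width ", ncol(X), " does not match first layer ",
               params$sizes[1])
  n_layers <- length(params$W)
  a <- vector("list", n_layers + 1L); z <- vector("list", n_layers)
  araw <- vector("list", n_layers)  # pre-dropout activations (for backprop)
  a[[1]] <- X
  for (l in seq_len(n_layers)) {
    z[[l]] <- sweep(a[[l]] %*% params$W[[l]], 2, params$b[[l]], "+")
    h <- activation_fun(z[[l]], params$activations[l])
    araw[[l]] <- h
    if (!is.null(masks) && l < n_layers) h <- h * masks[[l]]
    a[[l + 1L]] <- h
  }
  list(a = a, z = z, araw = araw, masks = masks)
}

draw_dropout_masks <- function(params, n) {
  n_layers <- length(params$W)
  if (n_layers < 2L || all(params$keep_prob == 1)) return(NULL)
  lapply(seq_len(n_layers - 1L), function(l) {
    p <- params$keep_prob[l]
    if (p == 1) matrix(1, n, params$sizes[l + 1L])
    else matrix((runif(n * params$sizes[l + 1L]) < p) / p,
                n, params$sizes[l + 1L])
  })
}

#' Run the network forward
#'
#' @param x input vector (one sample) or matrix (rows = samples) whose width
#'   matches the first layer.
#' @param params an [ann_init()] parameter set.
#' @param train_mode if `TRUE`, dropout masks are drawn from the current RNG
#'   stream and applied (inverted dropout); prediction mode is deterministic.
#' @return output matrix `n x d_out` (a plain vector for vector input).
#' @export
ann_forward <- function(x, params, train_mode = FALSE) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, nrow = 1) else as.matrix(x)
  masks <- if (train_mode) draw_dropout_masks(params, nrow(X)) else NULL
  out <- ann_forward_pass(params, X, masks)$a[[length(params$W) + 1L]]
  if (vec) drop(out) else out
}

# backpropagate an upstream gradient d_out (wrt the output activations)
# through a stored forward pass; returns per-layer weight/bias gradients and
# the gradient wrt the input rows
ann_backprop <- function(params, pass, d_out) {
  n_layers <- length(params$W)
  dW <- vector("list", n_layers); db <- vector("list", n_layers)
  delta <- d_out * activation_grad(pass$z[[n_layers]],
                                   pass$araw[[n_layers]],
                                   params$activations[n_layers])
  for (l in rev(seq_len(n_layers))) {
    dW[[l]] <- crossprod(pass$a[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      back <- delta %*% t(params$W[[l]])
      if (!is.null(pass$masks)) back <- back * pass$masks[[l - 1L]]
      delta <- back * activation_grad(pass$z[[l - 1L]], pass$araw[[l - 1L]],
                                      params$activations[l - 1L])
    } else {
      d_in <- delta %*% t(params$W[[1L]])
    }
  }
  list(dW = dW, db = db, d_input = d_in)
}

# mean-squared-error loss and its parameter gradient (one full batch)
ann_mse_grad <- function(params, X, Y, masks = NULL) {
  pass <- ann_forward_pass(params, X, masks)
  Yhat <- pass$a[[length(params$W) + 1L]]
  resid <- Yhat - Y
  loss <- mean(resid^2)
  g <- ann_backprop(params, pass, 2 * resid / length(resid))
  list(loss = loss, dW = g$dW, db = g$db)
}

#' Training configuration for the gradient-based fits
#'
#' @param learning_rate step size (default 0.005).
#' @param epochs number of full-batch iterations (max 1000).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed integer seed (initialization, dropout, validation split).
#' @param validation_fraction fraction of rows held out to pick the
#'   best-epoch parameters (0 disables; the final epoch is then returned).
#' @param goal early-stop training-loss goal.
#' @return list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.005, epochs = 250,
                         optimizer = c("adam", "sgd"), seed = 1,
                         validation_fraction = 0.1, goal = 1e-6) {
  optimizer <- match.arg(optimizer)
  if (learning_rate <= 0) stop_input("learning_rate must be > 0")
  if (epochs < 1 || epochs > 1000) stop_input("epochs must lie in [1, 1000]")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 optimizer = optimizer, seed = as.integer(seed),
                 validation_fraction = validation_fraction, goal = goal),
            class = "train_config")
}

# generic Adam/SGD update over a flat list of arrays
make_optimizer <- function(kind, lr, shapes) {
  if (kind == "sgd") {
    list(step = function(par, grad, t) {
      Map(function(p, g) p - lr * g, par, grad)
    })
  } else {
    m <- lapply(shapes, function(s) array(0, dim = s))
    v <- lapply(shapes, function(s) array(0, dim = s))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    env <- environment()
    list(step = function(par, grad, t) {
      env$m <- Map(function(mi, g) b1 * mi + (1 - b1) * g, env$m, grad)
      env$v <- Map(function(vi, g) b2 * vi + (1 - b2) * g^2, env$v, grad)
      Map(function(p, mi, vi) {
        mhat <- mi / (1 - b1^t); vhat <- vi / (1 - b2^t)
        p - lr * mhat / (sqrt(vhat) + eps)
      }, par, env$m, env$v)
    })
  }
}

flatten_params <- function(params) c(params$W, params$b)
unflatten_params <- function(params, flat) {
  k <- length(params$W)
  params$W <- flat[seq_len(k)]
  params$b <- flat[k + seq_len(k)]
  params
}

#' Train a feed-forward network by full-batch gradient descent
#'
#' Minimizes mean squared error with Adam or plain SGD; deterministic given
#' the seed. When a validation split is configured, the parameters at the
#' best validation loss are returned.
#'
#' @param X scaled feature matrix.
#' @param Y target matrix (same row count).
#' @param hidden integer vector of hidden-layer widths.
#' @param activations per-layer activation tags (hidden layers then output);
#'   defaults to tanh hidden layers with a linear output.
#' @param cfg a [train_config()].
#' @param keep_prob dropout keep-probability for hidden layers.
#' @return fitted `ann_params` (with a `history` attribute of per-epoch
#'   training loss).
#' @export
train_ann <- function(X, Y, hidden = c(64, 32),
                      activations = NULL, cfg = train_config(),
                      keep_prob = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop_input("X and Y row counts differ")
  if (any(!is.finite(Y))) stop_input("targets must be finite")
  sizes <- c(ncol(X), hidden, ncol(Y))
  if (is.null(activations))
    activations <- c(rep("tanh", length(hidden)), "linear")
  params <- ann_init(sizes, activations, keep_prob = keep_prob,
                     seed = cfg$seed)
  n <- nrow(X)
  val_idx <- integer(0)
  if (cfg$validation_fraction > 0 && n >= 20) {
    n_val <- max(2L, floor(cfg$validation_fraction * n))
    val_idx <- with_seed(cfg$seed + 1L, sample.int(n, n_val))
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  opt <- make_optimizer(cfg$optimizer, cfg$learning_rate,
                        lapply(flatten_params(params), function(p)
                          dim(p) %||% length(p)))
  best <- list(loss = Inf, flat = flatten_params(params))
  history <- numeric(cfg$epochs)
  with_seed(cfg$seed + 2L, {
    for (epoch in seq_len(cfg$epochs)) {
      masks <- draw_dropout_masks(params, nrow(Xtr))
      g <- ann_mse_grad(params, Xtr, Ytr, masks)
      if (!is.finite(g$loss))
        stop_input("training diverged (non-finite loss) at epoch ", epoch,
                   " with learning rate ", cfg$learning_rate)
      history[epoch] <- g$loss
      flat <- opt$step(flatten_params(params), c(g$dW, g$db), epoch)
      params <- unflatten_params(params, flat)
      monitor <- if (length(val_idx)) {
        pred <- ann_forward(X[val_idx, , drop = FALSE], params)
        mean((pred - Y[val_idx, , drop = FALSE])^2)
      } else g$loss
      if (monitor < best$loss)
        best <- list(loss = monitor, flat = flatten_params(params))
      if (g$loss <= cfg$goal) {
        history <- history[seq_len(epoch)]
        break
      }
    }
  })
  params <- unflatten_params(params, best$flat)
  attr(params, "history") <- history
  params
}
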