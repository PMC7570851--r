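#' Describe one of the three regression back ends
#'
#' A light container for model hyperparameters consumed by
#' [fit_ion_model()]. Targets are handled internally per back end: the GP
#' and DKL heads standardize each ion (zero mean matches the zero-mean GP
#' prior) while the network model min-max-scales targets to `[0, 1]` so its
#' ReLU output layer is feasible; predictions are always returned in mg/L.
#'
#' @param type `"ann"`, `"gp"` or `"dkl"`.
#' @param hidden hidden-layer widths (ann, dkl).
#' @param epochs,learning_rate training schedule (ann, dkl).
#' @param feature_dim DKL feature width; `NULL` defers to the explained-
#'   variance rule computed on the training fold.
#' @param kernel base kernel (gp: `"rbf"`, `"dot"`, `"sm"`; dkl: `"rbf"`,
#'   `"dot"`).
#' @param keep_prob dropout keep-probability (ann, dkl).
#' @param output_activation output activation of the network model.
#' @param target_transform `"identity"` (default) fits concentrations in
#'   mg/L directly, matching how the comparison report states slopes and
#'   intercepts; `"log"` fits every head on log-concentrations and
#'   back-transforms predictions, which suits strongly range-spanning
#'   single-electrode use.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(type = c("dkl", "gp", "ann"), hidden = NULL,
                       epochs = NULL, learning_rate = NULL,
                       feature_dim = NULL, kernel = "rbf", keep_prob = 1,
                       output_activation = "relu",
                       target_transform = c("identity", "log")) {
  type <- match.arg(type)
  target_transform <- match.arg(target_transform)
  hidden <- hidden %||% switch(type, ann = c(64, 32), dkl = 32, gp = NULL)
  epochs <- epochs %||% switch(type, ann = 400L, dkl = 400L, gp = NA_integer_)
  learning_rate <- learning_rate %||% switch(type, ann = 0.01, dkl = 0.005,
                                             gp = NA_real_)
  structure(list(type = type, hidden = hidden, epochs = epochs,
                 learning_rate = learning_rate, feature_dim = feature_dim,
                 kernel = kernel, keep_prob = keep_prob,
                 output_activation = output_activation,
                 target_transform = target_transform),
            class = "model_spec")
}

#' The default three-model comparison set
#' @return named list of [model_spec()] objects (`ANN`, `GP`, `DKL`).
#' @export
default_model_specs <- function() {
  list(ANN = model_spec("ann"), GP = model_spec("gp"), DKL = model_spec("dkl"))
}

#' Fit one multi-output ion regression model
#'
#' Shared fit contract of the three back ends: scaled features in, one
#' prediction column per ion out (via [predict_ions()]).
#'
#' @param X scaled feature matrix (rows = samples).
#' @param Y target concentration matrix in mg/L, columns named by ion.
#' @param spec a [model_spec()].
#' @param seed integer seed for the stochastic fits.
#' @param feature_dim DKL feature width decided by the caller (overrides the
#'   spec; typically the training-fold [select_pc_count()]).
#' @return object of class `ion_model`.
#' @export
fit_ion_model <- function(X, Y, spec = model_spec(), seed = 1,
                          feature_dim = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  ions <- colnames(Y) %||% paste0("y", seq_len(ncol(Y)))
  if (spec$target_transform == "log")
    Y <- log(pmax(Y, 0.5))  # concentrations live above the detection floor
  fit <- switch(spec$type,
    ann = {
      ymin <- apply(Y, 2, min); ymax <- apply(Y, 2, max)
      rng <- pmax(ymax - ymin, .Machine$double.eps)
      Y01 <- sweep(sweep(Y, 2, ymin), 2, rng, "/")
      cfg <- train_config(learning_rate = spec$learning_rate,
                          epochs = spec$epochs, seed = seed)
      net <- train_ann(X, Y01, hidden = spec$hidden,
                       activations = c(rep("tanh", length(spec$hidden)),
                                       spec$output_activation),
                       cfg = cfg, keep_prob = spec$keep_prob)
      list(net = net, ymin = ymin, yrange = rng)
    },
    gp = {
      ymu <- colMeans(Y); ysd <- pmax(apply(Y, 2, sd), .Machine$double.eps)
      Ys <- scale(Y, center = ymu, scale = ysd)
      heads <- lapply(seq_len(ncol(Y)), function(j)
        gp_fit(X, Ys[, j], kernel_spec(spec$kernel, length_scale = NULL)))
      list(heads = heads, ymu = ymu, ysd = ysd)
    },
    dkl = {
      ymu <- colMeans(Y); ysd <- pmax(apply(Y, 2, sd), .Machine$double.eps)
      Ys <- scale(Y, center = ymu, scale = ysd)
      cfg <- train_config(learning_rate = spec$learning_rate,
                          epochs = spec$epochs, seed = seed)
      st <- dkl_fit(X, Ys, hidden = spec$hidden,
                    feature_dim = feature_dim %||% spec$feature_dim %||% 8L,
                    kernel = spec$kernel, cfg = cfg,
                    keep_prob = spec$keep_prob)
      list(state = st, ymu = ymu, ysd = ysd)
    })
  structure(list(type = spec$type, spec = spec, fit = fit, ions = ions,
                 target_transform = spec$target_transform),
            class = "ion_model")
}

#' Predict ion concentrations with a fitted model
#'
#' @param model an `ion_model` from [fit_ion_model()].
#' @param X scaled feature matrix.
#' @return numeric matrix `n x n_ions` in mg/L, columns named by ion.
#' @export
predict_ions <- function(model, X) {
  X <- as.matrix(X)
  out <- switch(model$type,
    ann = {
      p <- ann_forward(X, model$fit$net)
      if (is.null(dim(p))) p <- matrix(p, nrow = 1)
      sweep(sweep(p, 2, model$fit$yrange, "*"), 2, model$fit$ymin, "+")
    },
    gp = {
      p <- vapply(model$fit$heads, function(h) gp_predict(h, X)$mean,
                  numeric(nrow(X)))
      p <- matrix(p, nrow(X))
      sweep(sweep(p, 2, model$fit$ysd, "*"), 2, model$fit$ymu, "+")
    },
    dkl = {
      p <- dkl_predict(model$fit$state, X)$mean
      sweep(sweep(p, 2, model$fit$ysd, "*"), 2, model$fit$ymu, "+")
    })
  if (identical(model$target_transform, "log")) out <- exp(out)
  colnames(out) <- model$ions
  out
}
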