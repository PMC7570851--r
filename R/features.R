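#' Names of the 17 enriched features, in fixed order
#'
#' Eight sample-phase raw channels (`ux_*`), eight enriched differences
#' (`fe_* = ux - u0`), then temperature. The difference block is invariant
#' to any session-constant channel offset, which is the mechanism by which
#' the standard-addition protocol cancels drift.
#'
#' @return character vector of length 17.
#' @export
feature_names <- function() {
  c(paste0("ux_", channel_names()), paste0("fe_", channel_names()), "temp_C")
}

#' Enrich one measurement record into the 17-dimensional feature vector
#'
#' @param record a `measurement_record`.
#' @return named numeric vector of length 17 in [feature_names()] order.
#' @examples
#' rec <- measure_msam(sample = solution_sample(c(NO3 = 100)),
#'                     array = default_array_config(), seed = 1)
#' length(enrich(rec))  # 17
#' @export
enrich <- function(record) {
  for (field in c("u0", "ux")) {
    missing <- setdiff(channel_names(), names(record[[field]]))
    if (length(missing))
      stop_input("record ", field, " is missing channel(s): ",
                 paste(missing, collapse = ", "))
  }
  u0 <- record$u0[channel_names()]
  ux <- record$ux[channel_names()]
  if (any(!is.finite(u0)) || any(!is.finite(ux)) || !is.finite(record$temperature))
    stop_input("record contains non-finite values")
  setNames(c(ux, ux - u0, record$temperature), feature_names())
}

#' Enrich a flat dataset into the feature matrix
#'
#' @param dataset data.frame in the [dataset_columns()] schema.
#' @return numeric matrix `n x 17` with columns [feature_names()].
#' @export
enrich_dataset <- function(dataset) {
  check_dataset(dataset)
  ux <- as.matrix(dataset[, paste0("ux_", channel_names())])
  u0 <- as.matrix(dataset[, paste0("u0_", channel_names())])
  X <- cbind(ux, ux - u0, dataset$temp_C)
  colnames(X) <- feature_names()
  X
}

#' Fit a min-max feature scaler
#'
#' Learns per-feature minima and maxima on training data; [apply_scaler()]
#' maps them affinely onto `[-1, 1]`. Constant features map to 0. Values
#' outside the training range map outside `[-1, 1]` (no clipping).
#'
#' @param X training feature matrix (>= 2 rows).
#' @return an object of class `scaler_state`.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_input("fit_scaler() needs at least 2 training rows")
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max)),
            class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state a fitted `scaler_state`.
#' @export
apply_scaler <- function(state, X) {
  if (!inherits(state, "scaler_state"))
    stop_input("apply_scaler() requires a fitted scaler_state")
  vec <- is.null(dim(X))
  X <- if (vec) matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  else as.matrix(X)
  rng <- state$max - state$min
  out <- matrix(0, nrow(X), ncol(X), dimnames = dimnames(X))
  ok <- rng > 0
  out[, ok] <- sweep(sweep(X[, ok, drop = FALSE], 2, state$min[ok]),
                     2, rng[ok], "/") * 2 - 1
  if (vec) drop(out) else out
}

#' Choose the feature-map width by explained variance
#'
#' Number of principal components of the scaled training features needed to
#' retain the requested fraction of total variance; used as the width of the
#' network's final layer (the dimension handed to the Gaussian-process head).
#'
#' @param X scaled feature matrix (>= 2 rows).
#' @param variance_threshold fraction of variance to retain, in (0, 1]
#'   (default 0.98).
#' @return integer number of components (never exceeding the matrix rank).
#' @export
select_pc_count <- function(X, variance_threshold = 0.98) {
  if (variance_threshold <= 0 || variance_threshold > 1)
    stop_input("variance_threshold must lie in (0, 1]")
  X <- as.matrix(X)
  if (nrow(X) < 2) stop_input("select_pc_count() needs at least 2 rows")
  ev <- eigen(cov(X), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  total <- sum(ev)
  if (total <= .Machine$double.eps * length(ev)) {
    warning("feature matrix is constant; returning 1 component")
    return(1L)
  }
  # discard numerically-zero directions so the count never exceeds rank
  rank <- sum(ev > max(ev) * 1e-12)
  k <- which(cumsum(ev) / total >= variance_threshold - 1e-12)[1]
  as.integer(min(k, rank))
}
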