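#' Root mean square error
#'
#' @param actual,predicted numeric vectors of equal length (>= 1).
#' @return RMSE in the units of the inputs (mg/L for concentrations).
#' @export
rmse <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_input("input lengths differ")
  if (!length(actual)) stop_input("empty input")
  sqrt(mean((actual - predicted)^2))
}

#' Coefficient of determination
#'
#' Standard definition: `1 - SS_res / SS_tot` with the total sum of squares
#' taken about the mean of the actual values.
#'
#' @param actual,predicted numeric vectors (>= 2 points; actual must vary).
#' @return dimensionless value, at most 1.
#' @export
r_squared <- function(actual, predicted) {
  if (length(actual) != length(predicted)) stop_input("input lengths differ")
  if (length(actual) < 2) stop_input("at least 2 points are required")
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0)
    stop_input("actual values have zero variance: R2 undefined")
  1 - sum((actual - predicted)^2) / ss_tot
}

#' Replicate coefficient of variation, percent
#'
#' Precision metric over repeated measurements: for each sample, the
#' standard deviation (denominator N-1) of its replicate predictions is
#' divided by the grand mean of all measurements and expressed in percent;
#' samples are aggregated as the mean per-sample CV.
#'
#' @param replicates numeric matrix, one row per sample, one column per
#'   replicate (>= 2 replicates).
#' @return mean CV in percent.
#' @examples
#' coeff_variation(matrix(c(9, 10, 11), 1))  # 10
#' @export
coeff_variation <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 2) stop_input("at least 2 replicates are required")
  grand <- mean(replicates)
  if (grand == 0) stop_input("zero grand mean: CV undefined")
  per_sample <- apply(replicates, 1, sd) / grand * 100
  mean(per_sample)
}
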