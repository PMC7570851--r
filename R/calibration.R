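#' Fit the log-linear single-electrode working curve
#'
#' Least-squares fit of `y = a * ln(x) + b` between concentrations and
#' electrode potentials — the classical Nikolsky-Eisenman working curve that
#' the learned models must beat. `log10` may be requested for users who
#' prefer decadic Nernstian slopes.
#'
#' @param concentrations mg/L, all > 0, at least 2 distinct values.
#' @param potentials mV, same length.
#' @param method label stored in the fit: `"MSAM"` or `"DCM"`.
#' @param electrode electrode identifier stored in the fit.
#' @param base `"ln"` (default) or `"log10"`.
#' @return object of class `calibration_fit` with `slope`, `intercept`,
#'   `r_squared`, `method`, `electrode`, `base`. A constant response yields
#'   slope 0 and `r_squared` 0 by convention.
#' @examples
#' fit_loglinear(c(1, exp(1)), c(10, 12))  # slope 2, intercept 10
#' @export
fit_loglinear <- function(concentrations, potentials, method = "MSAM",
                          electrode = NA_character_, base = c("ln", "log10")) {
  base <- match.arg(base)
  x <- as.numeric(concentrations); y <- as.numeric(potentials)
  if (length(x) != length(y)) stop_input("input lengths differ")
  if (length(x) < 2) stop_input("at least 2 points are required")
  if (any(x <= 0)) stop_input("concentrations must be > 0")
  lx <- if (base == "ln") log(x) else log10(x)
  if (length(unique(lx)) < 2)
    stop_input("all concentrations identical: singular design")
  fit <- lm(y ~ lx)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(fit$residuals^2) / ss_tot
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = r2, method = method, electrode = electrode,
                 base = base),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> %s %s: y = %.4g %s(x) %+.4g, R2 = %.4f\n",
              x$method, x$electrode %||% "?", x$slope,
              if (x$base == "ln") "ln" else "log10", x$intercept, x$r_squared))
  invisible(x)
}

#' Predict a potential from a calibration fit
#' @param fit a `calibration_fit`.
#' @param concentration mg/L (> 0).
#' @return potential in mV.
#' @export
predict_calibration <- function(fit, concentration) {
  if (any(concentration <= 0)) stop_input("concentration must be > 0")
  lx <- if (fit$base == "ln") log(concentration) else log10(concentration)
  fit$intercept + fit$slope * lx
}

#' Invert a calibration fit
#'
#' Solves the working curve for concentration: `exp((y - b) / a)` (base-10
#' analogue for decadic fits).
#'
#' @param fit a `calibration_fit` with non-zero slope.
#' @param potential mV.
#' @return concentration in mg/L.
#' @export
invert_calibration <- function(fit, potential) {
  if (fit$slope == 0) stop_input("cannot invert a zero-slope calibration")
  q <- (potential - fit$intercept) / fit$slope
  if (fit$base == "ln") exp(q) else 10^q
}

#' Calibrate every electrode of the array from a dataset
#'
#' Fits the log-linear working curve of each ISE against its primary-ion
#' concentration. For MSAM data the sample-phase potential `ux` is used; for
#' a DCM series the single-phase reading.
#'
#' @param dataset MSAM dataset (schema [dataset_columns()]) or, for
#'   `method = "DCM"`, a matrix from [measure_dcm_series()] together with
#'   `targets`.
#' @param method `"MSAM"` or `"DCM"`.
#' @param targets for DCM input: data.frame/matrix of per-sample true
#'   concentrations with columns named by ion.
#' @param base log base passed to [fit_loglinear()].
#' @return data.frame with columns `electrode`, `slope`, `intercept`,
#'   `r_squared`, `method`.
#' @export
calibrate_array <- function(dataset, method = c("MSAM", "DCM"),
                            targets = NULL, base = "ln") {
  method <- match.arg(method)
  rows <- lapply(ise_ions(), function(ion) {
    if (method == "MSAM") {
      check_dataset(dataset)
      x <- dataset[[paste0("c_", ion)]]
      y <- dataset[[paste0("ux_", ion)]]
    } else {
      if (is.null(targets)) stop_input("DCM calibration requires targets")
      x <- targets[, paste0("c_", ion)]
      y <- dataset[, ion]
    }
    f <- fit_loglinear(x, y, method = method, electrode = ion, base = base)
    data.frame(electrode = ion, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, method = method,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
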