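#' Construct a solution sample
#'
#' A solution sample holds the chemical ground truth: one concentration per
#' panel ion (mg/L) and a temperature (degrees C). Ions not named in
#' `concentrations` default to 0 mg/L.
#'
#' @param concentrations named numeric vector, ion -> mg/L. Names must be a
#'   subset of [ion_names()]; all values must be non-negative and finite.
#' @param temperature solution temperature in degrees C (default 25).
#' @return an object of class `solution_sample` with elements
#'   `concentrations` (full named vector over the panel) and `temperature`.
#' @examples
#' solution_sample(c(NO3 = 332, K = 150), temperature = 22)
#' @export
solution_sample <- function(concentrations = numeric(0), temperature = 25) {
  if (length(concentrations) && is.null(names(concentrations)))
    stop_input("concentrations must be a named vector (ion -> mg/L)")
  unknown <- setdiff(names(concentrations), ion_names())
  if (length(unknown))
    stop_input("unknown ion(s): ", paste(unknown, collapse = ", "))
  conc <- setNames(rep(0, length(ion_names())), ion_names())
  conc[names(concentrations)] <- as.numeric(concentrations)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop_input("concentrations must be finite and >= 0")
  if (!is.finite(temperature))
    stop_input("temperature must be finite")
  structure(list(concentrations = conc, temperature = temperature),
            class = "solution_sample")
}

#' @export
print.solution_sample <- function(x, ...) {
  cat("<solution_sample> ", x$temperature, " degC\n", sep = "")
  print(round(x$concentrations, 3))
  invisible(x)
}

#' The rinsed-water baseline solution
#'
#' The reference solution of the standard-addition protocol: every panel ion
#' diluted to roughly the lower limit of the electrodes' linear range.
#'
#' @param level concentration assigned to every ion (default 1 mg/L).
#' @param temperature degrees C.
#' @return a [solution_sample()].
#' @export
rinsed_water <- function(level = 1, temperature = 25) {
  solution_sample(setNames(rep(level, length(ion_names())), ion_names()),
                  temperature = temperature)
}

#' Mix solutions by volume
#'
#' Volume-weighted mass balance: each ion concentration (and the temperature)
#' of the mixture is the volume-weighted mean of the parts.
#'
#' @param parts a list whose elements are lists with fields `sample`
#'   (a [solution_sample()]) and `volume` (mL, >= 0).
#' @return the mixed [solution_sample()].
#' @examples
#' a <- solution_sample(c(NO3 = 1328))
#' b <- solution_sample(c(NO3 = 0))
#' mix_solutions(list(list(sample = a, volume = 10),
#'                    list(sample = b, volume = 30)))$concentrations[["NO3"]]
#' @export
mix_solutions <- function(parts) {
  if (!length(parts)) stop_input("at least one part is required")
  vols <- vapply(parts, function(p) as.numeric(p$volume), numeric(1))
  if (any(!is.finite(vols)) || any(vols < 0))
    stop_input("volumes must be finite and >= 0")
  total <- sum(vols)
  if (total <= 0) stop_input("total volume must be > 0")
  w <- vols / total
  conc <- Reduce(`+`, Map(function(p, wi) wi * p$sample$concentrations,
                          parts, as.list(w)))
  temp <- sum(w * vapply(parts, function(p) p$sample$temperature, numeric(1)))
  solution_sample(conc, temperature = temp)
}
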