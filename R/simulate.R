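#' Evaluate one electrode's potential for a solution
#'
#' Nikolsky-Eisenman forward model. The effective concentration seen by the
#' electrode is the primary-ion concentration plus selectivity-weighted
#' interferent terms `K_ji * c_i^(z_p/z_i)`; it is clamped at the detection
#' floor before entering the natural log. The slope is scaled by absolute
#' temperature when the electrode is temperature-coupled, and the returned
#' potential includes the supplied drift offset plus Gaussian measurement
#' noise drawn from the current RNG stream (when `noise_sd > 0`).
#'
#' A zero-concentration interferent contributes nothing, also when its
#' charge-ratio exponent is negative (which would otherwise be singular).
#'
#' @param sample a [solution_sample()].
#' @param spec an [electrode_spec()].
#' @param drift_offset additive session offset, mV (default 0).
#' @return potential in mV.
#' @examples
#' sp <- electrode_spec("NO3", -22.86, 208.47)
#' emf <- electrode_emf(solution_sample(c(NO3 = 100)), sp)  # 103.20 mV
#' @export
electrode_emf <- function(sample, spec, drift_offset = 0) {
  conc <- sample$concentrations
  zp <- ion_charge(spec$primary_ion)
  c_eff <- conc[[spec$primary_ion]]
  for (ion in names(spec$selectivity)) {
    ci <- conc[[ion]]
    if (ci > 0) {
      e <- zp / ion_charge(ion)
      c_eff <- c_eff + spec$selectivity[[ion]] * ci^e
    }
  }
  slope <- spec$slope
  if (isTRUE(spec$temperature_coupled))
    slope <- slope * (sample$temperature + 273.15) / 298.15
  emf <- spec$intercept + slope * log(max(c_eff, spec$detection_floor)) +
    drift_offset
  if (spec$noise_sd > 0) emf <- emf + rnorm(1, 0, spec$noise_sd)
  emf
}

#' Simulate the conductivity and pH transducer readings
#'
#' EC is a linear combination of molar concentrations weighted by the
#' configured equivalent conductances; pH falls logarithmically with
#' dihydrogen phosphate (acidification of the matrix). Noise is drawn from
#' the current RNG stream.
#'
#' @param sample a [solution_sample()].
#' @param array an `array_config`.
#' @param noise if `FALSE`, return the noise-free values.
#' @return named numeric `c(EC = ..., pH = ...)` (EC in uS).
#' @export
simulate_ec_ph <- function(sample, array, noise = TRUE) {
  conc <- sample$concentrations
  coefs <- array$ec$coefficients
  ec <- sum(coefs[ion_names()] * conc[ion_names()] / ion_molar_mass(ion_names()))
  ph <- array$ph$baseline -
    array$ph$sensitivity * log(1 + conc[["H2PO4"]] / array$ph$scale)
  if (noise) {
    if (array$ec$noise_sd > 0) ec <- ec + rnorm(1, 0, array$ec$noise_sd)
    if (array$ph$noise_sd > 0) ph <- ph + rnorm(1, 0, array$ph$noise_sd)
  }
  c(EC = ec, pH = ph)
}

# one pass over all 8 channels (no drift); draws noise from the current RNG
measure_channels <- function(sample, array) {
  ise <- vapply(ise_ions(), function(ion)
    electrode_emf(sample, array$electrodes[[ion]]), numeric(1))
  ecph <- simulate_ec_ph(sample, array)
  c(ise, pH = ecph[["pH"]], EC = ecph[["EC"]])[channel_names()]
}

draw_drift <- function(array) {
  off <- rnorm(length(channel_names()), 0, array$drift_sd)
  setNames(off * array$drift_scale[channel_names()], channel_names())
}

#' Measure one standard-addition (MSAM) cycle
#'
#' Executes the two-phase protocol: the rinsed-water baseline is measured
#' first (`u0`), then the sample (`ux`), within one session. One drift
#' offset per channel is drawn for the whole cycle and applied to both
#' phases, so it cancels exactly in `ux - u0`. Both phases are evaluated at
#' the sample temperature; measurement noise is drawn independently per
#' phase.
#'
#' @param baseline the reference [solution_sample()]; defaults to
#'   [rinsed_water()] at the sample temperature.
#' @param sample the measured [solution_sample()].
#' @param array an `array_config`.
#' @param seed integer seed for drift and noise. If omitted, a fixed default
#'   seed is used with a warning.
#' @param sample_id identifier stored in the record.
#' @return an object of class `measurement_record` with fields `sample_id`,
#'   `u0`, `ux` (named 8-vectors in [channel_names()] order), `temperature`,
#'   `targets` (named 8-vector of true concentrations, mg/L) and `seed`.
#' @export
measure_msam <- function(baseline = NULL, sample, array, seed = NULL,
                         sample_id = "s1") {
  if (is.null(seed)) {
    warning("no seed supplied to measure_msam(); using deterministic default 0")
    seed <- 0L
  }
  if (is.null(baseline)) baseline <- rinsed_water(temperature = sample$temperature)
  baseline <- solution_sample(baseline$concentrations,
                              temperature = sample$temperature)
  rec <- with_seed(seed, {
    drift <- draw_drift(array)
    u0 <- measure_channels(baseline, array) + drift
    ux <- measure_channels(sample, array) + drift
    list(u0 = u0, ux = ux)
  })
  structure(list(sample_id = sample_id, u0 = rec$u0, ux = rec$ux,
                 temperature = sample$temperature,
                 targets = sample$concentrations, seed = seed),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat("<measurement_record>", x$sample_id, "@", x$temperature, "degC\n")
  m <- rbind(u0 = x$u0, ux = x$ux, diff = x$ux - x$u0)
  print(round(m, 2))
  invisible(x)
}

#' Measure one direct-calibration (DCM) immersion
#'
#' Single-phase measurement: the array is immersed directly in the sample,
#' so the drawn session drift is *not* cancelled. Returns the 8 channel
#' values plus the temperature (9 raw values).
#'
#' @inheritParams measure_msam
#' @param drift_offset optional named per-channel drift vector (channel
#'   units); when `NULL` one is drawn from the seed. Supplying it lets a
#'   caller thread a drift random walk across a measurement series.
#' @return named numeric vector of length 9 (`channel_names()` plus
#'   `temp_C`).
#' @export
measure_dcm <- function(sample, array, seed = NULL, drift_offset = NULL) {
  if (is.null(seed)) {
    warning("no seed supplied to measure_dcm(); using deterministic default 0")
    seed <- 0L
  }
  vals <- with_seed(seed, {
    drift <- if (is.null(drift_offset)) draw_drift(array) else drift_offset
    measure_channels(sample, array) + drift
  })
  c(vals, temp_C = sample$temperature)
}

#' Measure a series of samples by direct calibration with drifting baseline
#'
#' Models a single long DCM session: the per-channel drift performs a
#' Gaussian random walk (step standard deviation `drift_sd`, scaled per
#' channel) between consecutive immersions, so that drift accumulates over
#' the series instead of being re-referenced the way each MSAM cycle is.
#'
#' @param samples list of [solution_sample()].
#' @param array an `array_config`.
#' @param seed integer seed.
#' @return matrix with one row per sample, columns `channel_names()` plus
#'   `temp_C`.
#' @export
measure_dcm_series <- function(samples, array, seed = 1) {
  seeds <- derive_seeds(seed, length(samples) + 1L)
  drift <- setNames(rep(0, length(channel_names())), channel_names())
  out <- matrix(NA_real_, length(samples), length(channel_names()) + 1L,
                dimnames = list(NULL, c(channel_names(), "temp_C")))
  for (i in seq_along(samples)) {
    drift <- drift + with_seed(seeds[i + 1L], draw_drift(array))
    out[i, ] <- measure_dcm(samples[[i]], array, seed = seeds[i],
                            drift_offset = drift)
  }
  out
}
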