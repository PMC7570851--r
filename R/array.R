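#' Construct an electrode specification
#'
#' Parameters of one ion-selective electrode following the Nikolsky-Eisenman
#' response model: a log-linear working curve in the primary-ion
#' concentration plus weighted contributions from interfering ions.
#'
#' @param primary_ion ion the electrode is selective for (must carry charge).
#' @param slope response slope in mV per ln(mg/L) at 25 degrees C; its sign
#'   must match the electrode convention (negative for anions, positive for
#'   cations).
#' @param intercept working-curve intercept in mV.
#' @param selectivity named numeric vector of dimensionless Nikolsky
#'   selectivity coefficients (interfering ion -> coefficient, all >= 0).
#' @param detection_floor lower limit of the linear range in mg/L; the log
#'   argument is clamped at this value (default 1).
#' @param noise_sd standard deviation of additive measurement noise, mV.
#' @param temperature_coupled if `TRUE` (default) the slope scales with
#'   absolute temperature as `(T + 273.15) / 298.15` (Nernstian behaviour).
#' @return an object of class `electrode_spec`.
#' @export
electrode_spec <- function(primary_ion, slope, intercept,
                           selectivity = numeric(0),
                           detection_floor = 1,
                           noise_sd = 0,
                           temperature_coupled = TRUE) {
  z <- ion_charge(primary_ion)
  if (z < 0 && slope > 0 || z > 0 && slope < 0)
    stop_input("slope sign must be negative for anion and positive for ",
               "cation electrodes (", primary_ion, ")")
  if (length(selectivity)) {
    if (is.null(names(selectivity)))
      stop_input("selectivity must be a named vector (ion -> coefficient)")
    ion_charge(names(selectivity))  # validates ion names
    if (any(selectivity < 0)) stop_input("selectivity coefficients must be >= 0")
  }
  if (detection_floor <= 0) stop_input("detection_floor must be > 0")
  if (noise_sd < 0) stop_input("noise_sd must be >= 0")
  structure(list(primary_ion = primary_ion, slope = slope,
                 intercept = intercept, selectivity = selectivity,
                 detection_floor = detection_floor, noise_sd = noise_sd,
                 temperature_coupled = temperature_coupled),
            class = "electrode_spec")
}

#' Default configuration of the simulated sensor array
#'
#' Six ISE specifications (working-curve coefficients follow published
#' commercial-electrode calibrations), a conductivity channel whose weights
#' are equivalent ionic conductances, a pH transducer that responds to
#' dihydrogen phosphate acidification, and a session-drift model.
#'
#' Selectivity defaults are small (order 1e-3 to 1e-2) same-sign cross terms
#' among the six electrode ions, with deliberate sensitivity of several
#' electrodes to phosphate and magnesium so that both electrode-less ions
#' remain inferable from the array (together with EC and pH): the calcium
#' electrode behaves like a divalent (water-hardness) sensor with a large
#' magnesium coefficient, the monovalent cation electrodes carry small
#' magnesium terms, and the anion electrodes respond weakly to phosphate.
#' Divalent-on-monovalent interference enters with the charge-ratio exponent
#' 1/2.
#'
#' @param drift_sd standard deviation of the per-channel session drift
#'   offset, mV (default 3).
#' @param noise_sd ISE measurement noise standard deviation, mV (default 0.3).
#' @return an object of class `array_config` with elements `electrodes`
#'   (named list of [electrode_spec()]), `ec` (coefficients + noise), `ph`
#'   (baseline, sensitivity, scale, noise), `drift_sd` and `drift_scale`
#'   (per-channel multiplier translating mV drift into the pH / EC units).
#' @export
default_array_config <- function(drift_sd = 3, noise_sd = 0.3) {
  el <- list(
    NO3 = electrode_spec("NO3", -22.86, 208.47,
                         selectivity = c(Cl = 0.01, H2PO4 = 0.05),
                         noise_sd = noise_sd),
    NH4 = electrode_spec("NH4", 22.92, -253.87,
                         selectivity = c(K = 0.01, Na = 0.005, Mg = 0.05),
                         noise_sd = noise_sd),
    K   = electrode_spec("K", 23.07, -237.03,
                         selectivity = c(NH4 = 0.01, Na = 0.005, Mg = 0.05),
                         noise_sd = noise_sd),
    Ca  = electrode_spec("Ca", 11.06, -76.90,
                         selectivity = c(Mg = 0.3),
                         noise_sd = noise_sd),
    Na  = electrode_spec("Na", 19.76, -186.22,
                         selectivity = c(K = 0.01, NH4 = 0.005, Mg = 0.05),
                         noise_sd = noise_sd),
    Cl  = electrode_spec("Cl", -23.02, 192.33,
                         selectivity = c(NO3 = 0.01, H2PO4 = 0.05),
                         noise_sd = noise_sd)
  )
  # equivalent conductances, S cm^2 / mol; EC (uS) = sum coef * c / M (mmol/L)
  ec_coef <- c(NO3 = 71.4, NH4 = 73.5, K = 73.5, Ca = 119.0,
               Na = 50.1, Cl = 76.3, H2PO4 = 36.0, Mg = 106.0)
  structure(list(
    electrodes = el,
    ec = list(coefficients = ec_coef, noise_sd = 20),
    ph = list(baseline = 6.5, sensitivity = 0.8, scale = 50, noise_sd = 0.02),
    drift_sd = drift_sd,
    # mV drift translated into channel units: 1 for ISEs, ~0.017 pH/mV
    # (59 mV per pH decade), 10 uS/mV for the conductivity meter
    drift_scale = c(setNames(rep(1, 6), ise_ions()), pH = 0.017, EC = 10)
  ), class = "array_config")
}

#' @export
print.array_config <- function(x, ...) {
  cat("<array_config> 6 ISEs + pH + EC; drift_sd =", x$drift_sd, "mV\n")
  for (nm in names(x$electrodes)) {
    e <- x$electrodes[[nm]]
    cat(sprintf("  %-4s slope %7.2f  intercept %8.2f  noise %4.2f mV  K: %s\n",
                nm, e$slope, e$intercept, e$noise_sd,
                if (length(e$selectivity))
                  paste(names(e$selectivity), signif(e$selectivity, 2),
                        sep = "=", collapse = " ")
                else "-"))
  }
  invisible(x)
}

#' Write / read an array configuration as YAML
#'
#' @param config an `array_config`.
#' @param path file path.
#' @return `read_array_config` returns an `array_config`;
#'   `write_array_config` returns `path` invisibly.
#' @export
write_array_config <- function(config, path) {
  to_plain <- function(x) {
    if (inherits(x, "electrode_spec") || inherits(x, "array_config"))
      x <- unclass(x)
    if (is.list(x)) lapply(x, to_plain)
    else if (!is.null(names(x))) as.list(x)  # keep names in the YAML map
    else x
  }
  yaml::write_yaml(to_plain(config), path)
  invisible(path)
}

#' @rdname write_array_config
#' @export
read_array_config <- function(path) {
  if (!file.exists(path)) stop_input("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  el <- lapply(raw$electrodes, function(e) {
    electrode_spec(e$primary_ion, e$slope, e$intercept,
                   selectivity = unlist(e$selectivity) %||% numeric(0),
                   detection_floor = e$detection_floor %||% 1,
                   noise_sd = e$noise_sd %||% 0,
                   temperature_coupled = e$temperature_coupled %||% TRUE)
  })
  structure(list(
    electrodes = el,
    ec = list(coefficients = unlist(raw$ec$coefficients),
              noise_sd = raw$ec$noise_sd %||% 0),
    ph = raw$ph,
    drift_sd = raw$drift_sd %||% 0,
    drift_scale = unlist(raw$drift_scale)
  ), class = "array_config")
}
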