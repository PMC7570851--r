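#' Default concentration level table for the six designed ions
#'
#' Ten strictly increasing concentration levels (mg/L) per designed ion,
#' spanning the working ranges of a hydroponic nutrient solution.
#'
#' @return named list of numeric vectors of length 10.
#' @export
default_levels <- function() {
  list(
    NO3 = c(44, 88, 177, 221, 332, 442, 553, 769, 1106, 1328),
    NH4 = c(6, 10, 15, 20, 25, 35, 45, 55, 75, 120),
    K   = c(15, 50, 75, 100, 150, 175, 200, 225, 350, 500),
    Ca  = c(10, 25, 50, 75, 100, 125, 175, 225, 250, 350),
    Na  = c(5, 12, 25, 35, 50, 100, 150, 175, 250, 300),
    Cl  = c(5, 15, 35, 50, 80, 125, 175, 200, 300, 350)
  )
}

check_levels <- function(levels) {
  if (!setequal(names(levels), ise_ions()))
    stop_input("levels must be named by the six designed ions")
  for (ion in names(levels)) {
    v <- levels[[ion]]
    if (length(v) != 10 || any(diff(v) <= 0))
      stop_input("levels for ", ion, " must be 10 strictly increasing values")
  }
  invisible(levels)
}

# modular (Graeco-Latin-style) coefficient pairs per supported level count;
# chosen so every pair determinant is a unit mod L where possible — complete
# mutually orthogonal sets do not exist for L = 6 or 10, so a few factor
# pairs are only near-uniform (see factorial_design details)
design_coefficients <- function(n_levels) {
  switch(as.character(n_levels),
    "6"  = list(c(1, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(5, 1)),
    "8"  = list(c(1, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(3, 5)),
    "10" = list(c(1, 0), c(0, 1), c(1, 1), c(1, 2), c(2, 1), c(3, 7)),
    stop_input("n_levels must be one of 3, 6, 8, 10"))
}

#' Specify a mixture design
#'
#' @param n_levels number of concentration levels per designed ion; one of
#'   3, 6, 8 or 10. The run counts are fixed at 27, 36, 64 and 100.
#' @param aux_ranges list with numeric ranges `H2PO4`, `Mg` (mg/L) and
#'   `temp_C` for the randomly assigned quantities.
#' @param log_uniform_aux draw the auxiliary ion concentrations log-uniformly
#'   instead of uniformly on the linear scale.
#' @param seed integer seed used when realizing samples.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_levels = 10,
                        aux_ranges = list(H2PO4 = c(6, 678), Mg = c(6, 125),
                                          temp_C = c(15, 35)),
                        log_uniform_aux = FALSE,
                        seed = 1) {
  if (!n_levels %in% c(3, 6, 8, 10))
    stop_input("n_levels must be one of 3, 6, 8, 10")
  n_runs <- c(`3` = 27L, `6` = 36L, `8` = 64L, `10` = 100L)[[as.character(n_levels)]]
  structure(list(n_levels = as.integer(n_levels), n_factors = 6L,
                 n_runs = n_runs, aux_ranges = aux_ranges,
                 log_uniform_aux = log_uniform_aux, seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a balanced fractional-factorial design
#'
#' Modular construction. For `L` in `{6, 8, 10}` the `L^2` runs are indexed
#' by `(i, k)` on the `L x L` grid and factor `f` receives level
#' `(alpha_f * i + beta_f * k) mod L` with fixed coefficient pairs whose
#' pairwise determinants are units mod `L` wherever the arithmetic of
#' orthogonal Latin squares allows (orders 6 and 10 admit no complete
#' orthogonal set, so a few factor pairs are near-uniform rather than
#' exactly uniform). For `L = 3` the 27 runs are indexed by
#' `(i, j, k)` in `{0,1,2}^3` and the six factors are
#' `i, j, k, i+j, i+k, j+k (mod 3)`, all pairwise uniform.
#'
#' Every factor column is exactly level-balanced: each level index occurs
#' `n_runs / n_levels` times.
#'
#' @param spec a [design_spec()].
#' @return integer matrix `n_runs x 6` of 0-based level indices, columns
#'   named by the designed ions.
#' @export
factorial_design <- function(spec) {
  L <- spec$n_levels
  if (L == 3) {
    g <- expand.grid(i = 0:2, j = 0:2, k = 0:2)
    m <- cbind(g$i, g$j, g$k,
               (g$i + g$j) %% 3, (g$i + g$k) %% 3, (g$j + g$k) %% 3)
  } else {
    co <- design_coefficients(L)
    g <- expand.grid(i = 0:(L - 1), k = 0:(L - 1))
    m <- vapply(co, function(ab) (ab[1] * g$i + ab[2] * g$k) %% L,
                numeric(nrow(g)))
  }
  m <- matrix(as.integer(m), nrow = spec$n_runs, ncol = spec$n_factors,
              dimnames = list(NULL, ise_ions()))
  m
}

# which of the 10 table levels are used when fewer levels are requested
level_subset <- function(n_levels) round(seq(1, 10, length.out = n_levels))

#' Realize design rows as solution samples
#'
#' Maps 0-based level indices to concentrations from the level table (an
#' evenly spread subset of the 10 table levels when `n_levels < 10`), and
#' draws dihydrogen phosphate, magnesium and temperature randomly within the
#' configured auxiliary ranges (seeded).
#'
#' @param design integer matrix from [factorial_design()].
#' @param levels level table, see [default_levels()].
#' @param spec the [design_spec()].
#' @return list of [solution_sample()] of length `nrow(design)`.
#' @export
realize_samples <- function(design, levels = default_levels(), spec) {
  check_levels(levels)
  if (any(design < 0) || any(design >= spec$n_levels))
    stop_input("design indices must lie in [0, n_levels)")
  sub <- level_subset(spec$n_levels)
  n <- nrow(design)
  aux <- with_seed(spec$seed, {
    draw <- function(rg) {
      if (spec$log_uniform_aux) exp(runif(n, log(rg[1]), log(rg[2])))
      else runif(n, rg[1], rg[2])
    }
    list(H2PO4 = draw(spec$aux_ranges$H2PO4),
         Mg = draw(spec$aux_ranges$Mg),
         temp = runif(n, spec$aux_ranges$temp_C[1], spec$aux_ranges$temp_C[2]))
  })
  lapply(seq_len(n), function(r) {
    conc <- vapply(ise_ions(), function(ion)
      levels[[ion]][sub[design[r, ion] + 1L]], numeric(1))
    solution_sample(c(conc, H2PO4 = aux$H2PO4[r], Mg = aux$Mg[r]),
                    temperature = aux$temp[r])
  })
}

#' Build a full synthetic training dataset
#'
#' Generates the factorial design, realizes the mixture samples, and runs one
#' MSAM measurement cycle per sample through the simulated array.
#'
#' @param spec a [design_spec()]; its seed drives sample realization.
#' @param levels level table (default [default_levels()]).
#' @param array an `array_config` (default [default_array_config()]).
#' @param seed measurement seed (drift + noise); defaults to the design seed.
#' @return data.frame in the [dataset_columns()] schema with
#'   `spec$n_runs` rows.
#' @examples
#' ds <- build_dataset(design_spec(n_levels = 3, seed = 7))
#' nrow(ds)  # 27
#' @export
build_dataset <- function(spec, levels = default_levels(),
                          array = default_array_config(), seed = NULL) {
  seed <- seed %||% spec$seed
  samples <- realize_samples(factorial_design(spec), levels, spec)
  measure_samples(samples, array, seed = seed)
}

#' Measure a list of solution samples as an MSAM dataset
#'
#' One MSAM cycle per sample with per-record seeds derived from `seed`.
#' Re-running with a different `seed` on the same samples yields a fresh
#' replicate measurement of identical targets.
#'
#' @param samples list of [solution_sample()].
#' @param array an `array_config`.
#' @param seed integer master measurement seed.
#' @return data.frame in the [dataset_columns()] schema.
#' @export
measure_samples <- function(samples, array = default_array_config(), seed = 1) {
  seeds <- derive_seeds(seed, length(samples))
  records <- lapply(seq_along(samples), function(i)
    measure_msam(sample = samples[[i]], array = array, seed = seeds[i],
                 sample_id = sprintf("s%03d", i)))
  records_to_dataset(records)
}
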