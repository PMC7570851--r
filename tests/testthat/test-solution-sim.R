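test_that("mixing is a volume-weighted mass balance", {
  a <- solution_sample(c(K = 100))
  b <- solution_sample(c(K = 0))
  mix <- mix_solutions(list(list(sample = a, volume = 10),
                            list(sample = b, volume = 10)))
  expect_equal(mix$concentrations[["K"]], 50)

  # 10 mL of 1328 mg/L nitrate into 30 mL blank -> level-5 concentration
  dil <- mix_solutions(list(
    list(sample = solution_sample(c(NO3 = 1328)), volume = 10),
    list(sample = solution_sample(c(NO3 = 0)), volume = 30)))
  expect_equal(dil$concentrations[["NO3"]], 332)

  single <- mix_solutions(list(list(sample = a, volume = 40)))
  expect_equal(single$concentrations, a$concentrations)
  expect_equal(single$temperature, a$temperature)

  expect_error(mix_solutions(list(list(sample = a, volume = 0))),
               "total volume")
})

test_that("electrode response follows the log-linear working curve", {
  sp <- nitrate_spec()
  s100 <- solution_sample(c(NO3 = 100))
  expect_equal(electrode_emf(s100, sp), 208.47 - 22.86 * log(100),
               tolerance = 1e-12)
  expect_equal(round(electrode_emf(s100, sp), 2), 103.20)

  # ln(1) = 0 forces the intercept exactly
  expect_equal(electrode_emf(solution_sample(c(NO3 = 1)), sp), 208.47)

  # additive drift offset
  expect_equal(electrode_emf(s100, sp, drift_offset = 5),
               electrode_emf(s100, sp) + 5)

  # detection floor clamps the log argument
  expect_equal(electrode_emf(solution_sample(c(NO3 = 0.01)), sp),
               electrode_emf(solution_sample(c(NO3 = 0)), sp))
})

test_that("slope scales with absolute temperature (Nernstian coupling)", {
  sp <- nitrate_spec()
  grid <- c(5, 20, 80, 300, 1000)
  emf_at <- function(tC) vapply(grid, function(cc)
    electrode_emf(solution_sample(c(NO3 = cc), temperature = tC), sp),
    numeric(1))
  sl25 <- coef(lm(emf_at(25) ~ log(grid)))[2]
  sl35 <- coef(lm(emf_at(35) ~ log(grid)))[2]
  expect_close(sl35, sl25 * 308.15 / 298.15, tol = 1e-9)
  expect_close(sl25, -22.86, tol = 1e-9)

  # decoupled electrode ignores temperature
  sp$temperature_coupled <- FALSE
  expect_equal(emf_at(15), emf_at(35))
})

test_that("interference is monotone and zero-selectivity series are log-linear", {
  sp <- electrode_spec("K", 23.07, -237.03,
                       selectivity = c(Na = 0.02, Mg = 0.05), noise_sd = 0)
  base <- electrode_emf(solution_sample(c(K = 50)), sp)
  higher <- electrode_emf(solution_sample(c(K = 50, Na = 100, Mg = 20)), sp)
  expect_gt(higher, base)
  # non-decreasing along an interferent grid
  emfs <- vapply(seq(0, 200, by = 25), function(na)
    electrode_emf(solution_sample(c(K = 50, Na = na)), sp), numeric(1))
  expect_true(all(diff(emfs) >= 0))

  # single-ion series above the floor: perfectly log-linear
  clean <- electrode_spec("K", 23.07, -237.03, noise_sd = 0)
  grid <- c(15, 50, 150, 500)
  y <- vapply(grid, function(cc)
    electrode_emf(solution_sample(c(K = cc)), clean), numeric(1))
  fit <- fit_loglinear(grid, y)
  expect_close(fit$r_squared, 1, tol = 1e-12)
})

test_that("EC is linear in composition and pH falls with phosphate", {
  arr <- quiet_array()
  zero <- simulate_ec_ph(solution_sample(), arr, noise = FALSE)
  expect_equal(zero[["EC"]], 0)
  expect_equal(zero[["pH"]], arr$ph$baseline)

  s <- solution_sample(c(NO3 = 100, K = 50, Mg = 20))
  s2 <- solution_sample(2 * s$concentrations)
  expect_equal(simulate_ec_ph(s2, arr, noise = FALSE)[["EC"]],
               2 * simulate_ec_ph(s, arr, noise = FALSE)[["EC"]])

  ph <- vapply(seq(0, 600, by = 50), function(p)
    simulate_ec_ph(solution_sample(c(H2PO4 = p)), arr, noise = FALSE)[["pH"]],
    numeric(1))
  expect_true(all(diff(ph) <= 0))
})

test_that("MSAM records are deterministic given a seed and cancel drift", {
  arr <- quiet_array()
  s <- solution_sample(c(NO3 = 100, K = 50))
  r1 <- measure_msam(sample = s, array = arr, seed = 4)
  r2 <- measure_msam(sample = s, array = arr, seed = 4)
  expect_identical(r1$u0, r2$u0)
  expect_identical(r1$ux, r2$ux)

  # sample equal to baseline: both phases identical (no noise)
  rb <- measure_msam(baseline = rinsed_water(), sample = rinsed_water(),
                     array = arr, seed = 4)
  expect_equal(rb$ux, rb$u0)

  # session-constant drift of any size cancels in ux - u0
  drifty <- quiet_array(drift_sd = 50)
  rd <- measure_msam(sample = s, array = drifty, seed = 4)
  r0 <- measure_msam(sample = s, array = quiet_array(), seed = 4)
  # exact up to floating-point rounding of the two shifted phases
  expect_close(rd$ux - rd$u0, r0$ux - r0$u0, tol = 1e-10)
  expect_false(isTRUE(all.equal(rd$ux, r0$ux)))

  expect_warning(measure_msam(sample = s, array = arr), "seed")
})

test_that("DCM immersion matches the sample phase and keeps drift", {
  arr <- quiet_array()
  s <- solution_sample(c(NO3 = 100, K = 50))
  v <- measure_dcm(s, arr, seed = 9)
  r <- measure_msam(sample = s, array = arr, seed = 9)
  expect_equal(v[channel_names()], r$ux)
  expect_equal(v[["temp_C"]], 25)

  expect_identical(measure_dcm(s, arr, seed = 9), measure_dcm(s, arr, seed = 9))

  drifty <- quiet_array(drift_sd = 10)
  vd <- measure_dcm(s, drifty, seed = 9)
  expect_false(isTRUE(all.equal(vd[channel_names()], v[channel_names()])))

  # a DCM series accumulates drift as a random walk
  series <- measure_dcm_series(rep(list(s), 5), drifty, seed = 2)
  expect_equal(dim(series), c(5, 9))
  expect_gt(sd(series[, "NO3"]), 0)
})

test_that("array config survives a YAML round trip", {
  arr <- quiet_array(drift_sd = 3)  # noise-free so responses compare exactly
  path <- withr::local_tempfile(fileext = ".yaml")
  write_array_config(arr, path)
  back <- read_array_config(path)
  expect_equal(back$electrodes$NO3$slope, arr$electrodes$NO3$slope)
  expect_equal(back$electrodes$Ca$selectivity, arr$electrodes$Ca$selectivity)
  expect_equal(back$drift_sd, arr$drift_sd)
  s <- solution_sample(c(NO3 = 200, Ca = 100, Mg = 30))
  expect_equal(electrode_emf(s, back$electrodes$Ca),
               electrode_emf(s, arr$electrodes$Ca))
})

test_that("invalid electrode and sample inputs are rejected", {
  expect_error(electrode_spec("NO3", 22.86, 208.47), "slope sign")
  expect_error(electrode_spec("K", -23, -237), "slope sign")
  expect_error(electrode_spec("K", 23, -237, selectivity = c(Na = -1)),
               "selectivity")
  expect_error(solution_sample(c(XX = 1)), "unknown ion")
  expect_error(solution_sample(c(K = -5)), "finite and >= 0")
})
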