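test_that("log-linear calibration recovers a generating retention law", {
  # markers placed exactly on r = 60 - 10 * log10(MW kDa)
  mw <- c(150, 500, 2500)
  mk <- marker_set(mw, 60 - 10 * log10(mw))
  cal <- fit_mw_calibration(mk)
  expect_equal(cal$slope, -0.1, tolerance = 1e-12)
  expect_equal(cal$intercept, 6, tolerance = 1e-12)
  expect_equal(cal$r_squared, 1, tolerance = 1e-12)
  # two markers: the line interpolates them exactly
  mk2 <- marker_set(c(100, 1000), c(40, 30))
  cal2 <- fit_mw_calibration(mk2)
  expect_equal(10^(cal2$intercept + cal2$slope * 40), 100,
               tolerance = 1e-10)
  expect_equal(10^(cal2$intercept + cal2$slope * 30), 1000,
               tolerance = 1e-10)
})

test_that("markers violating size-exclusion physics are rejected", {
  expect_error(marker_set(c(150, 500, 2500), c(38, 33, 40)), "elute")
  expect_error(marker_set(500, 30), "2 size markers")
  expect_error(marker_set(c(100, 100), c(30, 40)), "distinct")
})

test_that("peak fraction maps to molecular mass via the calibration", {
  cal <- fit_mw_calibration(
    marker_set(c(150, 500, 2500), 60 - 10 * log10(c(150, 500, 2500))))
  prof <- elution_profile(c(1, 5, 2), elution = c(30, 31, 32))
  expect_equal(as.numeric(peak_molecular_mass(prof, cal)),
               10^(6 - 0.1 * 31), tolerance = 1e-12)
  # ties resolve to the earlier-eluting (larger) fraction
  tie <- elution_profile(c(5, 5, 2), elution = c(30, 31, 32))
  expect_equal(as.numeric(peak_molecular_mass(tie, cal)),
               10^(6 - 0.1 * 30), tolerance = 1e-12)
  expect_error(peak_molecular_mass(
    elution_profile(c(0, 0), elution = c(30, 31)), cal), "zero")
})

test_that("simulator round-trip recovers the preset peak mass", {
  sim <- simulate_gpc(preset = gpc_preset("Ws"), seed = 7)
  cal <- fit_mw_calibration(sim$markers)
  # calibration recovered to machine precision from jitter-free markers
  expect_equal(cal$slope, sim$truth$cal_slope, tolerance = 1e-12)
  expect_equal(cal$intercept, sim$truth$cal_intercept, tolerance = 1e-12)
  mw <- peak_molecular_mass(sim$profile, cal)
  # within one fraction width of the preset, in MW terms
  i <- which.max(sim$profile$content)
  dt_min <- 0.5
  mw_lo <- 10^(cal$intercept + cal$slope * (sim$profile$elution_min[i] + dt_min))
  mw_hi <- 10^(cal$intercept + cal$slope * (sim$profile$elution_min[i] - dt_min))
  expect_lte(abs(as.numeric(mw) - 660), mw_hi - mw_lo)
})

test_that("mass distribution normalizes and decreases monotonically in MW", {
  cal <- fit_mw_calibration(
    marker_set(c(150, 500, 2500), 60 - 10 * log10(c(150, 500, 2500))))
  single <- mass_distribution(elution_profile(3, elution = 31), cal)
  expect_equal(single$content_fraction, 1)
  two <- mass_distribution(elution_profile(c(2, 2), elution = c(30, 31)), cal)
  expect_equal(two$content_fraction, c(0.5, 0.5))
  sim <- simulate_gpc(preset = gpc_preset("Ler"), seed = 8)
  dist <- mass_distribution(sim$profile, fit_mw_calibration(sim$markers))
  expect_equal(sum(dist$content_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(dist$mw_kda) < 0))
  # modal and centroid estimates both sit near the preset peak
  expect_equal(dist$mw_kda[which.max(dist$content)], 540, tolerance = 0.12)
  expect_equal(attr(dist, "centroid_mw_kda"), 540, tolerance = 0.12)
})

test_that("peaks outside the marker range are flagged as extrapolation", {
  expect_warning(sim <- simulate_gpc(peak_mw_kda = 50, seed = 9),
                 "outside the marker range")
  cal <- fit_mw_calibration(sim$markers)
  expect_warning(mw <- peak_molecular_mass(sim$profile, cal),
                 "outside the marker range")
  expect_true(attr(mw, "extrapolated"))
})
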