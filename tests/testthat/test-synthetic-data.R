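test_that("noiseless creep simulation equals the forward model exactly", {
  truth <- default_truth()
  curve <- simulate_creep(truth, seed = 1)
  expect_length(curve$times, 1201)
  expect_identical(curve$deformation,
                   burgers_strain(truth, 25, curve$times))
  expect_identical(attr(curve, "truth"), truth)
})

test_that("all generators are deterministic under a fixed seed", {
  truth <- default_truth()
  expect_identical(simulate_creep(truth, noise_sd = 0.01, seed = 3),
                   simulate_creep(truth, noise_sd = 0.01, seed = 3))
  expect_identical(simulate_gpc(preset = gpc_preset("Ws"), noise_sd = 0.5,
                                marker_jitter_sd = 0.05, seed = 4),
                   simulate_gpc(preset = gpc_preset("Ws"), noise_sd = 0.5,
                                marker_jitter_sd = 0.05, seed = 4))
  expect_identical(simulate_standards(2, 1, noise_sd = 0.1, seed = 5),
                   simulate_standards(2, 1, noise_sd = 0.1, seed = 5))
  expect_identical(simulate_morphometry(seed = 6),
                   simulate_morphometry(seed = 6))
  # different seeds produce different noise
  expect_false(identical(simulate_standards(2, 1, noise_sd = 0.1, seed = 5),
                         simulate_standards(2, 1, noise_sd = 0.1, seed = 6)))
})

test_that("zero-noise standards and markers reproduce their truth exactly", {
  st <- simulate_standards(0.05, 0.01, seed = 7)
  cal <- fit_linear_calibration(st)
  expect_equal(cal$slope, 0.05, tolerance = 1e-12)
  expect_equal(cal$intercept, 0.01, tolerance = 1e-12)
  sim <- simulate_gpc(preset = gpc_preset("trg1-2"), seed = 8)
  cal2 <- fit_mw_calibration(sim$markers)
  expect_equal(cal2$slope, sim$truth$cal_slope, tolerance = 1e-12)
  expect_equal(cal2$intercept, sim$truth$cal_intercept, tolerance = 1e-12)
})

test_that("morphometry draws concentrate on the preset group means", {
  presets <- morphometry_presets()
  presets$n <- 2000L
  tab <- simulate_morphometry(presets, seed = 9)
  for (i in seq_len(nrow(presets))) {
    p <- presets[i, ]
    v <- tab$value[tab$genotype == p$genotype & tab$trait == p$trait]
    expect_length(v, 2000L)
    expect_lt(abs(mean(v) - p$mean), 3 * p$sd / sqrt(2000))
  }
})

test_that("fit residual spread reflects the injected noise level", {
  truth <- default_truth()
  sigma <- 0.005 * burgers_strain(truth, 25, 600)
  curves <- simulate_creep(truth, noise_sd = sigma, n_replicates = 20,
                           seed = 10)
  res_sd <- vapply(curves, function(cv) {
    fit <- fit_burgers(cv, fit_config(n_restarts = 2, seed = 11))
    sd(fit$residuals)
  }, numeric(1))
  expect_lt(abs(mean(res_sd) - sigma) / sigma, 0.2)
})

test_that("invalid generator arguments are rejected", {
  truth <- default_truth()
  expect_error(simulate_creep(truth, noise_sd = -1, seed = 1),
               "non-negative")
  expect_error(simulate_creep(truth, n_replicates = 0, seed = 1),
               "at least 1")
  expect_error(simulate_creep(truth), "seed is mandatory")
  expect_error(simulate_gpc(peak_mw_kda = -5, seed = 1), "positive")
  pres <- morphometry_presets(); pres$n[1] <- 0L
  expect_error(simulate_morphometry(pres, seed = 1), "at least 1")
})

test_that("generator output survives the CSV dialects losslessly", {
  tmp <- tempfile(); dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE))
  truth <- default_truth()
  curve <- simulate_creep(truth, noise_sd = 0.01, seed = 12,
                          protocol = creep_protocol(diameter_mm = 1.2))
  p <- file.path(tmp, "creep.csv")
  write_creep_csv(curve, p)
  back <- read_creep_csv(p)
  expect_equal(back$deformation, curve$deformation, tolerance = 1e-12)
  expect_equal(back$protocol$diameter_mm, 1.2)
  expect_equal(back$label, curve$label)

  st <- simulate_standards(0.05, 0.01, noise_sd = 0.002, seed = 13)
  ps <- file.path(tmp, "standards.csv")
  write_standards_csv(st, ps)
  st2 <- read_standards_csv(ps)
  expect_equal(st2$response, st$response, tolerance = 1e-12)

  sim <- simulate_gpc(preset = gpc_preset("Ws"), noise_sd = 0.3, seed = 14)
  pp <- file.path(tmp, "profile.csv"); pm <- file.path(tmp, "markers.csv")
  write_profile_csv(sim$profile, pp)
  write_markers_csv(sim$markers, pm)
  expect_equal(read_profile_csv(pp)$content, sim$profile$content,
               tolerance = 1e-12)
  expect_equal(read_markers_csv(pm)$elution, sim$markers$elution,
               tolerance = 1e-12)

  tab <- simulate_morphometry(seed = 15)
  pt <- file.path(tmp, "morph.csv")
  write_morphometry_csv(tab, pt)
  expect_equal(read_morphometry_csv(pt)$value, tab$value,
               tolerance = 1e-12)
})
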