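test_that("noiseless simulated curves are recovered almost exactly", {
  truth <- default_truth()
  curve <- simulate_creep(truth, seed = 11)
  fit <- fit_burgers(curve, fit_config(n_restarts = 4, seed = 12))
  expect_true(all(rel_err(params_vec(fit$params), params_vec(truth)) < 1e-3))
  expect_gte(fit$r_squared, 0.999999)
  expect_true(fit$converged)
  # derived viscosities follow the fitted parameters exactly
  expect_identical(fit$plastic$eta1, fit$params$E1 * fit$params$tau1)
})

test_that("initial guess lands near the truth on clean simulator output", {
  truth <- default_truth()
  curve <- simulate_creep(truth, seed = 21)
  g <- initial_guess(curve)
  expect_lt(rel_err(g$E0, truth$E0), 0.05)
  # guessed retardation times are log-spaced inside the sampling window
  expect_equal(c(g$tau1, g$tau3), c(1, 600))
  expect_error(initial_guess(
    creep_curve(0:9, c(-1, rep(1, 9)), creep_protocol(dt = 1))), "positive")
})

test_that("a flat curve yields E0 = P0/c and an identifiability flag", {
  prot <- creep_protocol(dt = 1, T_total = 60)
  curve <- creep_curve(seq(0, 60), rep(0.5, 61), prot)
  g <- initial_guess(curve)
  expect_gt(g$E1, 1e4 * g$E0)  # retarded moduli parked very stiff
  fit <- fit_burgers(curve, fit_config(n_restarts = 2, seed = 1))
  expect_equal(fit$params$E0, prot$P0 / 0.5, tolerance = 1e-3)
  expect_true(any(grepl("unidentifiable", fit$warnings)))
})

test_that("fit is equivariant under rescaling of the deformation axis", {
  truth <- default_truth()
  curve <- simulate_creep(truth, seed = 31)
  k <- 7.3
  scaled <- creep_curve(curve$times, k * curve$deformation, curve$protocol)
  f1 <- fit_burgers(curve, fit_config(n_restarts = 2, seed = 32))
  f2 <- fit_burgers(scaled, fit_config(n_restarts = 2, seed = 32))
  for (nm in c("E0", "E1", "E2", "E3"))
    expect_equal(f2$params[[nm]], f1$params[[nm]] / k, tolerance = 1e-6)
  for (nm in c("tau1", "tau2", "tau3"))
    expect_equal(f2$params[[nm]], f1$params[[nm]], tolerance = 1e-6)
})

test_that("identical seed and config reproduce the fit bit for bit", {
  truth <- default_truth()
  epsT <- burgers_strain(truth, 25, 600)
  curve <- simulate_creep(truth, noise_sd = 0.005 * epsT, seed = 41)
  f1 <- fit_burgers(curve, fit_config(n_restarts = 6, seed = 42))
  f2 <- fit_burgers(curve, fit_config(n_restarts = 6, seed = 42))
  expect_identical(f1, f2)
  # and the caller's RNG stream is left untouched
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(fit_burgers(curve, fit_config(n_restarts = 2)))
  expect_identical(runif(1), before)
})

test_that("near-merged retardation times raise an identifiability warning", {
  truth <- burgers_params(10, 20, 25, 80, 40, 60, 500)
  curve <- simulate_creep(truth, seed = 51)
  fit <- fit_burgers(curve, fit_config(n_restarts = 4, seed = 52))
  expect_true(any(grepl("factor of 2", fit$warnings)))
})

test_that("uniform weights do not change the estimate", {
  truth <- default_truth()
  curve <- simulate_creep(truth, noise_sd = 0.01, seed = 61)
  f1 <- fit_burgers(curve, fit_config(n_restarts = 2, seed = 62))
  f2 <- fit_burgers(curve, fit_config(n_restarts = 2, seed = 62),
                    weights = rep(2, length(curve$times)))
  expect_equal(params_vec(f1$params), params_vec(f2$params),
               tolerance = 1e-8)
})

test_that("one-element reduction agrees with exhaustive grid search", {
  # pin the second and third elements very stiff so only (E0, E1, tau1)
  # matter, then compare the least-squares solution with a brute-force
  # lattice minimizer
  truth <- burgers_params(10, 20, 1e9, 1e9, 30, 100, 200)
  prot <- creep_protocol()
  curve <- simulate_creep(truth, prot, seed = 71)
  fit <- fit_burgers(curve, fit_config(n_restarts = 4, seed = 72),
                     fixed = c(E2 = 1e9, E3 = 1e9, tau2 = 100, tau3 = 200))
  grid <- grid_search_one_element(curve,
                                  E0_grid = seq(8, 12, by = 0.25),
                                  E1_grid = seq(16, 24, by = 0.5),
                                  tau1_grid = seq(20, 40, by = 1))
  expect_lte(abs(fit$params$E0 - grid$E0), 0.25)
  expect_lte(abs(fit$params$E1 - grid$E1), 0.5)
  expect_lte(abs(fit$params$tau1 - grid$tau1), 1)
})

test_that("degenerate inputs are rejected with clear errors", {
  truth <- default_truth()
  curve <- simulate_creep(truth, seed = 81)
  bad <- creep_curve(curve$times[1:9] ,
                     c(-1, curve$deformation[2:9]),
                     creep_protocol(dt = 0.5, T_total = 4))
  expect_error(fit_burgers(bad), "positive")
  expect_error(fit_burgers(curve, fit_config(), fixed = c(bogus = 1)),
               "named")
  expect_error(fit_burgers(curve, fit_config(),
                           fixed = c(E0 = 1, E1 = 1, E2 = 1, E3 = 1,
                                     tau1 = 1, tau2 = 2, tau3 = 3)),
               "free")
})
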