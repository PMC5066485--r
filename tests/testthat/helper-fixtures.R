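# shared ground truth for creep round-trips: well-separated retardation
# times under the default stem-segment protocol
default_truth <- function() burgers_params(10, 20, 40, 80, 5, 50, 500)

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

params_vec <- function(p) {
  unlist(p[c("E0", "E1", "E2", "E3", "tau1", "tau2", "tau3")])
}

# brute-force SSE grid search for the one-element reduction (E2, E3 pinned
# very stiff): independent of the least-squares path under test
grid_search_one_element <- function(curve, E0_grid, E1_grid, tau1_grid,
                                    E_pin = 1e9) {
  P0 <- curve$protocol$P0
  t <- curve$times
  eps <- curve$deformation
  best <- NULL
  for (E0 in E0_grid) for (E1 in E1_grid) for (tau1 in tau1_grid) {
    model <- P0 / E0 + (P0 / E1) * (1 - exp(-t / tau1)) +
      2 * (P0 / E_pin)  # asymptotic contribution of the two stiff elements
    sse <- sum((model - eps)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(E0 = E0, E1 = E1, tau1 = tau1, sse = sse)
  }
  best
}
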