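#' Configuration for the Burgers creep fit
#'
#' Controls the multi-start nonlinear least-squares estimation of the
#' seven Burgers parameters. Three-exponential creep fits are multi-modal,
#' so the fit is restarted from perturbed initial guesses and the lowest
#' sum of squared errors wins; ties are broken by the smaller parameter
#' norm in log space.
#'
#' @param n_restarts Number of local solves from perturbed starting
#'   points. The first restart always uses the unperturbed
#'   [initial_guess()].
#' @param max_iterations Iteration cap per local solve.
#' @param ftol Relative tolerance on the SSE decrease used to declare
#'   convergence.
#' @param seed Integer seed controlling the restart perturbations; fixing
#'   it makes the fit fully deterministic.
#' @param jitter_sd Log-scale standard deviation of the multiplicative
#'   perturbation applied to the initial guess on restarts 2..n.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 16L, max_iterations = 200L,
                       ftol = 1e-12, seed = 1L, jitter_sd = 0.5) {
  stopifnot(n_restarts >= 1L, max_iterations >= 1L, ftol > 0, jitter_sd >= 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iterations = as.integer(max_iterations),
                 ftol = ftol, seed = as.integer(seed),
                 jitter_sd = jitter_sd),
            class = "fit_config")
}

PARAM_NAMES <- c("E0", "E1", "E2", "E3", "tau1", "tau2", "tau3")

#' Heuristic starting values for the Burgers fit
#'
#' E0 is taken from the first sample (instantaneous compliance), the total
#' retarded compliance seen between the first and last sample is split
#' equally over the three Kelvin-Voigt elements, and the retardation times
#' are log-spaced across `[2 dt, T]` so the elements start well separated.
#'
#' @param curve A [creep_curve()].
#' @return A [burgers_params()] object.
#' @export
initial_guess <- function(curve) {
  stopifnot(inherits(curve, "creep_curve"))
  P0 <- curve$protocol$P0
  eps <- curve$deformation
  if (eps[1L] <= 0)
    stop("first deformation sample must be positive to estimate E0")
  E0 <- P0 / eps[1L]
  dt <- curve$times[2L] - curve$times[1L]
  T_end <- curve$times[length(curve$times)]
  c_retarded <- (eps[length(eps)] - eps[1L]) / P0
  if (c_retarded > .Machine$double.eps * abs(eps[1L] / P0)) {
    En <- rep(3 / c_retarded, 3L)
  } else {
    # flat curve: retarded compliance indistinguishable from zero; park the
    # Kelvin moduli at a very stiff value so the elements contribute nothing
    En <- rep(1e6 * E0, 3L)
  }
  taus <- 10^seq(log10(2 * dt), log10(T_end), length.out = 3L)
  burgers_params(E0, En[1L], En[2L], En[3L], taus[1L], taus[2L], taus[3L])
}

# Model deformation and its Jacobian with respect to the *log* parameters.
# Working in log space enforces positivity without penalty terms and makes
# the multiplicative restart jitter natural.
.burgers_model_logp <- function(logp, P0, t) {
  p <- exp(logp)
  E <- p[1:4]; tau <- p[5:7]
  eps <- P0 / E[1L]
  for (n in 1:3) eps <- eps + (P0 / E[n + 1L]) * (1 - exp(-t / tau[n]))
  eps
}

.burgers_jac_logp <- function(logp, P0, t) {
  p <- exp(logp)
  E <- p[1:4]; tau <- p[5:7]
  J <- matrix(0, nrow = length(t), ncol = 7L)
  J[, 1L] <- -P0 / E[1L]
  for (n in 1:3) {
    ex <- exp(-t / tau[n])
    J[, n + 1L] <- -(P0 / E[n + 1L]) * (1 - ex)
    J[, n + 4L] <- -(P0 / E[n + 1L]) * ex * t / tau[n]
  }
  J
}

#' Fit the Burgers model to a creep curve
#'
#' Estimates the four elastic moduli and three retardation times by
#' minimizing the sum of squared deviations between the observed
#' deformation and [burgers_strain()], using Levenberg-Marquardt in
#' log-parameter space with analytic derivatives, multiple restarts and a
#' positive box constraint (retardation times bounded to
#' `[dt/2, 10 T]`). Least squares is unweighted by default; per-point
#' weights may be supplied.
#'
#' Identifiability warnings are attached (and the result still returned)
#' when two fitted retardation times fall within a factor of two of each
#' other (elements nearly merged), when `tau3` exceeds the recording
#' duration (asymptote unobserved), or when the curve carries essentially
#' no retarded deformation (Kelvin terms unidentifiable).
#'
#' @param curve A [creep_curve()] with strictly positive deformation.
#' @param config A [fit_config()].
#' @param weights Optional non-negative per-point weights.
#' @param fixed Optional named numeric vector pinning a subset of
#'   `E0,E1,E2,E3,tau1,tau2,tau3` at given values (excluded from the
#'   optimization); used e.g. to reduce the model to fewer elements.
#' @return An object of class `burgers_fit` with elements `params`
#'   ([burgers_params()]), `plastic` ([plastic_params()]), `sse`,
#'   `r_squared`, `residuals`, `fitted`, `converged`, `best_restart`,
#'   `n_restarts`, and `warnings` (character vector of identifiability
#'   flags, possibly empty).
#' @export
fit_burgers <- function(curve, config = fit_config(), weights = NULL,
                        fixed = NULL) {
  stopifnot(inherits(curve, "creep_curve"), inherits(config, "fit_config"))
  t <- curve$times
  eps <- curve$deformation
  P0 <- curve$protocol$P0
  if (any(eps <= 0))
    stop("deformation must be strictly positive after load onset")
  if (length(t) <= 7L)
    stop("need more data points than the 7 model parameters")
  if (is.null(weights)) {
    sw <- NULL
  } else {
    stopifnot(length(weights) == length(t), all(weights >= 0))
    sw <- sqrt(weights)
  }
  if (!is.null(fixed)) {
    if (is.null(names(fixed)) || !all(names(fixed) %in% PARAM_NAMES))
      stop("fixed must be a named vector over ",
           paste(PARAM_NAMES, collapse = ", "))
    if (any(fixed <= 0)) stop("fixed parameter values must be positive")
  }
  free_idx <- which(!(PARAM_NAMES %in% names(fixed)))
  if (length(free_idx) == 0L) stop("at least one parameter must be free")

  dt <- t[2L] - t[1L]
  T_end <- t[length(t)]
  # positive box: generous modulus bounds scaled to the data, retardation
  # times confined to the observable window [dt/2, 10 T]
  lower <- c(rep(P0 / max(eps) * 1e-4, 4L), rep(dt / 2, 3L))
  upper <- c(rep(P0 / min(eps) * 1e8, 4L), rep(10 * T_end, 3L))
  names(lower) <- names(upper) <- PARAM_NAMES

  guess <- initial_guess(curve)
  g0 <- unlist(guess[PARAM_NAMES])
  g0 <- pmin(pmax(g0, lower), upper)

  full_logp <- log(g0)
  if (!is.null(fixed)) full_logp[names(fixed)] <- log(fixed)

  resid_fn <- function(lp_free) {
    lp <- full_logp; lp[free_idx] <- lp_free
    r <- .burgers_model_logp(lp, P0, t) - eps
    if (is.null(sw)) r else sw * r
  }
  jac_fn <- function(lp_free) {
    lp <- full_logp; lp[free_idx] <- lp_free
    J <- .burgers_jac_logp(lp, P0, t)[, free_idx, drop = FALSE]
    if (is.null(sw)) J else sw * J
  }

  # restart perturbations use a private RNG stream so the caller's RNG
  # state is left untouched
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  ctrl <- minpack.lm::nls.lm.control(maxiter = config$max_iterations,
                                     ftol = config$ftol, ptol = 1e-12)
  best <- NULL
  for (k in seq_len(config$n_restarts)) {
    start_logp <- log(g0)[free_idx]
    if (k > 1L)
      start_logp <- start_logp + stats::rnorm(length(free_idx),
                                              sd = config$jitter_sd)
    start_logp <- pmin(pmax(start_logp, log(lower[free_idx])),
                       log(upper[free_idx]))
    # iteration-cap warnings from individual restarts are expected on
    # ill-conditioned curves; convergence is reported via the result flag
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start_logp, fn = resid_fn, jac = jac_fn,
                           lower = log(lower[free_idx]),
                           upper = log(upper[free_idx]), control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    pnorm2 <- sum(fit$par^2)
    if (is.null(best) || sse < best$sse * (1 - 1e-12) ||
        (abs(sse - best$sse) <= 1e-12 * max(sse, best$sse) &&
         pnorm2 < best$pnorm2)) {
      best <- list(fit = fit, sse = sse, pnorm2 = pnorm2, restart = k)
    }
  }
  if (is.null(best))
    stop("Burgers fit failed to converge in any of the ", config$n_restarts,
         " restarts")

  lp <- full_logp
  lp[free_idx] <- best$fit$par
  p <- unname(exp(lp))
  params <- burgers_params(p[1L], p[2L], p[3L], p[4L], p[5L], p[6L], p[7L])
  fitted <- burgers_strain(params, P0, t)
  residuals <- eps - fitted
  sse <- sum(residuals^2)
  tss <- sum((eps - mean(eps))^2)
  r_squared <- if (tss > 0) 1 - sse / tss else NA_real_

  warn <- character(0)
  taus <- c(params$tau1, params$tau2, params$tau3)
  for (i in 1:2) for (j in (i + 1):3) {
    ratio <- taus[i] / taus[j]
    if (ratio >= 0.5 && ratio <= 2)
      warn <- c(warn, sprintf(
        "retardation times tau%d and tau%d within a factor of 2 (%.3g vs %.3g s): elements nearly merged",
        i, j, taus[i], taus[j]))
  }
  if (params$tau3 > T_end)
    warn <- c(warn, sprintf(
      "tau3 = %.3g s exceeds the recording duration %.3g s: asymptote unobserved",
      params$tau3, T_end))
  retarded <- 1 / params$E1 + 1 / params$E2 + 1 / params$E3
  if (retarded * P0 < 1e-6 * mean(eps))
    warn <- c(warn,
              "negligible retarded deformation: Kelvin elements unidentifiable")

  structure(list(params = params, plastic = plastic_params(params),
                 sse = sse, r_squared = r_squared,
                 residuals = residuals, fitted = fitted,
                 converged = best$fit$info %in% 1:4,
                 best_restart = best$restart,
                 n_restarts = config$n_restarts,
                 warnings = warn),
            class = "burgers_fit")
}

#' @export
print.burgers_fit <- function(x, ...) {
  cat("Burgers creep fit\n")
  print(x$params)
  cat(sprintf("  eta = (%.6g, %.6g, %.6g)\n",
              x$plastic$eta1, x$plastic$eta2, x$plastic$eta3))
  cat(sprintf("  SSE = %.6g, R^2 = %.8f, best restart %d/%d\n",
              x$sse, x$r_squared, x$best_restart, x$n_restarts))
  if (length(x$warnings))
    cat("  warnings:\n", paste0("   - ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}
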