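#' Creep loading protocol
#'
#' Describes how a constant-load creep experiment was run: the applied
#' stress, the sampling interval and the total recording time, plus
#' optional segment geometry. Defaults follow the standard stem-segment
#' protocol: a constant load of 25 gf mm^-2 recorded every 0.5 s for
#' 10 min.
#'
#' @param P0 Applied stress, gram-force per mm^2 of cross-section.
#' @param dt Sampling interval in seconds.
#' @param T_total Recording duration in seconds.
#' @param gauge_length_mm Optional free segment length between the clamps,
#'   mm. When present, deformation is interpreted as strain (extension
#'   divided by this length).
#' @param diameter_mm Optional segment diameter, mm, used to convert the
#'   per-area stress into an absolute load.
#' @return An object of class `creep_protocol`.
#' @export
creep_protocol <- function(P0 = 25, dt = 0.5, T_total = 600,
                           gauge_length_mm = NULL, diameter_mm = NULL) {
  stopifnot(is.numeric(P0), length(P0) == 1L, is.finite(P0),
            is.numeric(dt), length(dt) == 1L, is.finite(dt),
            is.numeric(T_total), length(T_total) == 1L, is.finite(T_total))
  if (P0 <= 0) stop("applied stress P0 must be positive")
  if (dt <= 0) stop("sampling interval dt must be positive")
  if (T_total < dt) stop("duration must be at least one sampling interval")
  if (!is.null(gauge_length_mm) && gauge_length_mm <= 0)
    stop("gauge length must be positive")
  if (!is.null(diameter_mm) && diameter_mm <= 0)
    stop("diameter must be positive; supply the segment geometry")
  structure(list(P0 = P0, dt = dt, T_total = T_total,
                 gauge_length_mm = gauge_length_mm,
                 diameter_mm = diameter_mm),
            class = "creep_protocol")
}

#' Sampled creep-extension curve
#'
#' A deformation trace recorded under constant load. Deformation is raw
#' extension unless the protocol carries a gauge length, in which case it
#' is dimensionless strain; the Burgers fit is invariant to this choice up
#' to a rescaling of the elastic moduli.
#'
#' @param times Sampling times in seconds, strictly increasing and
#'   uniformly spaced (within a small relative tolerance).
#' @param deformation Deformation values, same length as `times`, all
#'   finite.
#' @param protocol A [creep_protocol()].
#' @param label Optional sample label (genotype / segment).
#' @return An object of class `creep_curve`.
#' @export
creep_curve <- function(times, deformation, protocol = creep_protocol(),
                        label = NULL) {
  stopifnot(inherits(protocol, "creep_protocol"))
  times <- as.numeric(times)
  deformation <- as.numeric(deformation)
  if (length(times) != length(deformation))
    stop("times and deformation must have equal length")
  if (length(times) < 8L)
    stop("a creep curve needs at least 8 samples")
  if (times[1L] < 0) stop("times must start at or after load onset (t >= 0)")
  d <- diff(times)
  if (any(d <= 0)) stop("times must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * max(d))
    stop("times must be uniformly spaced")
  if (!all(is.finite(deformation)))
    stop("all deformation values must be finite")
  structure(list(times = times, deformation = deformation,
                 protocol = protocol, label = label),
            class = "creep_curve")
}

#' @export
print.creep_curve <- function(x, ...) {
  cat("Creep curve", if (!is.null(x$label)) paste0("[", x$label, "]"), "\n")
  cat(sprintf("  %d samples, t = %g..%g s, P0 = %g gf/mm^2\n",
              length(x$times), x$times[1L], x$times[length(x$times)],
              x$protocol$P0))
  invisible(x)
}

#' Burgers model parameters
#'
#' The four-element Kelvin-Voigt-Burgers model used for creep curves: an
#' instantaneous spring E0 in series with three Kelvin-Voigt elements
#' (En, tau_n). Retardation times are stored in canonical ascending order
#' (tau1 <= tau2 <= tau3) to break the permutation symmetry of the three
#' elements; the En are permuted alongside.
#'
#' @param E0,E1,E2,E3 Elastic moduli (stress per unit deformation), all
#'   positive.
#' @param tau1,tau2,tau3 Retardation (delay) times in seconds, all
#'   positive.
#' @return An object of class `burgers_params`.
#' @export
burgers_params <- function(E0, E1, E2, E3, tau1, tau2, tau3) {
  v <- c(E0 = E0, E1 = E1, E2 = E2, E3 = E3,
         tau1 = tau1, tau2 = tau2, tau3 = tau3)
  if (!all(is.finite(v))) stop("all Burgers parameters must be finite")
  if (any(v <= 0)) stop("all Burgers parameters must be positive")
  taus <- c(tau1, tau2, tau3)
  Es <- c(E1, E2, E3)
  o <- order(taus)
  structure(list(E0 = E0, E1 = Es[o[1L]], E2 = Es[o[2L]], E3 = Es[o[3L]],
                 tau1 = taus[o[1L]], tau2 = taus[o[2L]], tau3 = taus[o[3L]]),
            class = "burgers_params")
}

#' @export
print.burgers_params <- function(x, ...) {
  cat("Kelvin-Voigt-Burgers parameters\n")
  cat(sprintf("  E0 = %.6g\n", x$E0))
  for (n in 1:3)
    cat(sprintf("  E%d = %-12.6g tau%d = %.6g s\n",
                n, x[[paste0("E", n)]], n, x[[paste0("tau", n)]]))
  invisible(x)
}

#' Derived plastic (viscosity) parameters
#'
#' The viscosity of each Kelvin-Voigt dashpot, eta_n = E_n * tau_n.
#'
#' @param params A [burgers_params()] object.
#' @return An object of class `plastic_params` with fields `eta1`, `eta2`,
#'   `eta3` (stress x seconds per unit deformation).
#' @export
plastic_params <- function(params) {
  stopifnot(inherits(params, "burgers_params"))
  structure(list(eta1 = params$E1 * params$tau1,
                 eta2 = params$E2 * params$tau2,
                 eta3 = params$E3 * params$tau3),
            class = "plastic_params")
}

#' Forward Burgers creep deformation
#'
#' Evaluates the generalized Kelvin solid creep response under constant
#' stress `P0`:
#' \deqn{\varepsilon(t) = P_0/E_0 + \sum_{n=1}^{3} (P_0/E_n)\,
#'   (1 - e^{-t/\tau_n})}
#' The response is strictly increasing in t, starts at P0/E0 and
#' approaches P0 (1/E0 + 1/E1 + 1/E2 + 1/E3) as t grows.
#'
#' @param params A [burgers_params()] object.
#' @param P0 Constant applied stress (same stress unit as the moduli).
#' @param t Time(s) since load onset, seconds; vectorized, all `t >= 0`.
#' @return Deformation value(s), same length as `t`.
#' @export
burgers_strain <- function(params, P0, t) {
  stopifnot(inherits(params, "burgers_params"))
  if (!is.numeric(P0) || length(P0) != 1L || !is.finite(P0) || P0 <= 0)
    stop("P0 must be a single positive number")
  t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("t must be finite and non-negative (time since load onset)")
  P0 / params$E0 +
    (P0 / params$E1) * (1 - exp(-t / params$tau1)) +
    (P0 / params$E2) * (1 - exp(-t / params$tau2)) +
    (P0 / params$E3) * (1 - exp(-t / params$tau3))
}

#' Absolute load realizing a per-area stress
#'
#' Converts the per-area stress of a protocol into the absolute load in
#' gram-force applied to a segment of the given diameter:
#' `P0 * pi * d^2 / 4`.
#'
#' @param protocol A [creep_protocol()] whose `diameter_mm` is set.
#' @return Load in gram-force.
#' @export
total_load <- function(protocol) {
  stopifnot(inherits(protocol, "creep_protocol"))
  d <- protocol$diameter_mm
  if (is.null(d))
    stop("segment diameter is missing: supply diameter_mm in the protocol ",
         "to convert per-area stress to an absolute load")
  protocol$P0 * pi * d^2 / 4
}

# Conversion from gram-force per mm^2 to pascal, for callers who want SI
# units; the package itself reports stress in gf/mm^2 throughout.
#' Gram-force per square millimetre in pascal
#'
#' Conversion constant: 1 gf mm^-2 = 9806.65 Pa (standard gravity).
#' @export
GF_PER_MM2_IN_PA <- 9.80665e3
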