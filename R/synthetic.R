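#' Genotype presets for the synthetic generators
#'
#' Bundles the study conditions the generators emulate: the creep protocol
#' (25 gf/mm^2, 0.5 s sampling, 600 s), the dextran size markers
#' (150/500/2500 kDa) with a log-linear retention law, the 30 s fraction
#' interval, and the per-genotype xyloglucan peak molecular masses
#' (Ws 660, Ler 540, trg1-1 240, trg1-2 200 kDa).
#'
#' @param genotype One of `"Ws"`, `"Ler"`, `"trg1-1"`, `"trg1-2"`.
#' @return A list with `peak_mw_kda` plus the shared protocol constants.
#' @export
gpc_preset <- function(genotype = c("Ws", "Ler", "trg1-1", "trg1-2")) {
  genotype <- match.arg(genotype)
  peaks <- c("Ws" = 660, "Ler" = 540, "trg1-1" = 240, "trg1-2" = 200)
  list(genotype = genotype,
       peak_mw_kda = unname(peaks[genotype]),
       marker_mw_kda = c(150, 500, 2500),
       retention_intercept = 60,  # elution min at log10(MW kDa) = 0
       retention_slope = -10,     # min per log10(kDa); later = smaller
       fraction_interval_s = 30,
       log10_width = 0.15)
}

#' Table-style morphometry group presets
#'
#' Group means, SDs and replicate counts for wild-type and mutant fruit
#' morphometry, used as ground truth by [simulate_morphometry()].
#'
#' @return A data.frame with one row per genotype x trait.
#' @export
morphometry_presets <- function() {
  data.frame(
    genotype = rep(c("WT", "trg1-1"), each = 3L),
    trait = rep(c("fruit_length_mm", "circumference_um", "cell_count"), 2L),
    mean = c(12.2, 1569, 48.5, 8.3, 2163, 49.8),
    sd = c(0.6, 9, 2.6, 0.5, 118, 1.7),
    n = c(20L, 4L, 4L, 20L, 4L, 4L),
    stringsAsFactors = FALSE)
}

#' Simulate creep-extension curves with known ground truth
#'
#' Generates deformation traces from the forward Burgers model under the
#' given protocol, with additive homoscedastic Gaussian measurement noise.
#' The default protocol yields 1201 samples (0 to 600 s every 0.5 s). The
#' generating parameters are attached as attribute `truth` so recovery
#' studies can compare against them.
#'
#' @param truth A [burgers_params()] object (the generating parameters).
#' @param protocol A [creep_protocol()].
#' @param noise_sd Standard deviation of the additive Gaussian noise, in
#'   deformation units; 0 gives the exact forward model.
#' @param n_replicates Number of replicate curves.
#' @param seed Integer seed (mandatory; generation is fully deterministic
#'   given it).
#' @return A single [creep_curve()] when `n_replicates = 1`, otherwise a
#'   list of curves. Each carries attribute `truth`.
#' @export
simulate_creep <- function(truth, protocol = creep_protocol(),
                           noise_sd = 0, n_replicates = 1L, seed) {
  stopifnot(inherits(truth, "burgers_params"),
            inherits(protocol, "creep_protocol"))
  if (missing(seed)) stop("seed is mandatory for the synthetic generators")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_replicates < 1L) stop("n_replicates must be at least 1")
  times <- seq(0, protocol$T_total, by = protocol$dt)
  mu <- burgers_strain(truth, protocol$P0, times)
  curves <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(k) {
      eps <- mu + if (noise_sd > 0)
        stats::rnorm(length(times), sd = noise_sd) else 0
      cv <- creep_curve(times, eps, protocol,
                        label = sprintf("synthetic_rep%03d", k))
      attr(cv, "truth") <- truth
      cv
    })
  })
  if (n_replicates == 1L) curves[[1L]] else curves
}

#' Simulate a GPC run: size markers plus an elution profile
#'
#' Marker elution positions follow a ground-truth log-linear retention law
#' exactly (plus optional Gaussian jitter). The analyte content is
#' Gaussian in log10(MW), centred on `peak_mw_kda` with SD `log10_width`,
#' sampled at the fraction midpoints implied by the collection interval,
#' normalized to `total_content`, with optional additive content noise
#' (clipped at zero).
#'
#' @param peak_mw_kda True peak molecular mass, kDa, positive.
#' @param log10_width SD of the analyte distribution on the log10(kDa)
#'   scale.
#' @param preset Optional output of [gpc_preset()]; supplies
#'   `peak_mw_kda`, markers, retention law and fraction interval.
#' @param marker_mw_kda Marker masses, kDa.
#' @param retention_intercept,retention_slope Retention law
#'   `elution_min = intercept + slope * log10(MW kDa)`; slope < 0.
#' @param fraction_interval_s Fraction collection interval, s.
#' @param elution_range_min Time window (min) covered by the collected
#'   fractions.
#' @param total_content Total analyte content across fractions (e.g. ug
#'   xyloglucan loaded).
#' @param noise_sd SD of additive per-fraction content noise.
#' @param marker_jitter_sd SD of Gaussian jitter on marker elution
#'   positions (min).
#' @param seed Integer seed (mandatory).
#' @return A list with `markers` ([marker_set()]), `profile`
#'   ([elution_profile()]) and `truth` (the generating parameters).
#' @export
simulate_gpc <- function(peak_mw_kda = NULL, log10_width = NULL,
                         preset = NULL,
                         marker_mw_kda = c(150, 500, 2500),
                         retention_intercept = 60, retention_slope = -10,
                         fraction_interval_s = 30,
                         elution_range_min = c(20, 45),
                         total_content = 700, noise_sd = 0,
                         marker_jitter_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory for the synthetic generators")
  if (!is.null(preset)) {
    if (is.null(peak_mw_kda)) peak_mw_kda <- preset$peak_mw_kda
    if (is.null(log10_width)) log10_width <- preset$log10_width
    marker_mw_kda <- preset$marker_mw_kda
    retention_intercept <- preset$retention_intercept
    retention_slope <- preset$retention_slope
    fraction_interval_s <- preset$fraction_interval_s
  }
  if (is.null(log10_width)) log10_width <- 0.15
  if (is.null(peak_mw_kda) || peak_mw_kda <= 0)
    stop("peak molecular mass must be positive")
  if (retention_slope >= 0)
    stop("retention slope must be negative (larger molecules elute first)")
  if (noise_sd < 0 || marker_jitter_sd < 0)
    stop("noise SDs must be non-negative")
  if (peak_mw_kda < min(marker_mw_kda) || peak_mw_kda > max(marker_mw_kda))
    warning("peak molecular mass lies outside the marker range; ",
            "estimates will extrapolate the calibration")

  ret <- function(mw) retention_intercept + retention_slope * log10(mw)
  dt_min <- fraction_interval_s / 60
  first_frac <- floor(elution_range_min[1L] / dt_min) + 1L
  last_frac <- ceiling(elution_range_min[2L] / dt_min)
  fraction <- seq(first_frac, last_frac)
  mid <- (fraction - 0.5) * dt_min
  log10_mw <- (mid - retention_intercept) / retention_slope
  dens <- stats::dnorm(log10_mw, mean = log10(peak_mw_kda),
                       sd = log10_width)
  content <- total_content * dens / sum(dens)

  with_seed(seed, {
    if (noise_sd > 0)
      content <- pmax(content + stats::rnorm(length(content),
                                             sd = noise_sd), 0)
    marker_pos <- ret(marker_mw_kda)
    if (marker_jitter_sd > 0)
      marker_pos <- marker_pos + stats::rnorm(length(marker_pos),
                                              sd = marker_jitter_sd)
    list(markers = marker_set(marker_mw_kda, marker_pos),
         profile = elution_profile(content, elution = mid,
                                   fraction = fraction,
                                   interval_s = fraction_interval_s),
         truth = list(peak_mw_kda = peak_mw_kda,
                      log10_width = log10_width,
                      retention_intercept = retention_intercept,
                      retention_slope = retention_slope,
                      # calibration in the fitted direction:
                      # log10(MW) = a + b * elution
                      cal_slope = 1 / retention_slope,
                      cal_intercept = -retention_intercept / retention_slope))
  })
}

#' Simulate calibration standards with known line
#'
#' Linear responses `slope * amount + intercept` with additive Gaussian
#' response noise.
#'
#' @param slope,intercept Ground-truth line.
#' @param amounts Standard amounts (>= 2 distinct levels).
#' @param noise_sd SD of the response noise.
#' @param analyte Label passed through to [calibration_standards()].
#' @param seed Integer seed (mandatory).
#' @return A [calibration_standards()] with attribute `truth`.
#' @export
simulate_standards <- function(slope, intercept = 0,
                               amounts = c(0, 1, 2, 5, 10),
                               noise_sd = 0, analyte = "analyte", seed) {
  if (missing(seed)) stop("seed is mandatory for the synthetic generators")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  response <- with_seed(seed, {
    slope * amounts + intercept +
      if (noise_sd > 0) stats::rnorm(length(amounts), sd = noise_sd) else 0
  })
  st <- calibration_standards(amounts, response, analyte = analyte)
  attr(st, "truth") <- list(slope = slope, intercept = intercept)
  st
}

#' Simulate a morphometry replicate table
#'
#' Draws per-replicate trait values from Gaussian group distributions.
#'
#' @param presets A data.frame like [morphometry_presets()] with columns
#'   `genotype`, `trait`, `mean`, `sd`, `n`.
#' @param seed Integer seed (mandatory).
#' @return A long data.frame with columns `genotype`, `trait`,
#'   `replicate`, `value`; attribute `truth` holds the presets.
#' @export
simulate_morphometry <- function(presets = morphometry_presets(), seed) {
  if (missing(seed)) stop("seed is mandatory for the synthetic generators")
  stopifnot(all(c("genotype", "trait", "mean", "sd", "n") %in%
                  names(presets)))
  if (any(presets$n < 1L)) stop("replicate counts must be at least 1")
  if (any(presets$sd < 0)) stop("group SDs must be non-negative")
  out <- with_seed(seed, {
    rows <- lapply(seq_len(nrow(presets)), function(i) {
      p <- presets[i, ]
      data.frame(genotype = p$genotype, trait = p$trait,
                 replicate = seq_len(p$n),
                 value = stats::rnorm(p$n, p$mean, p$sd),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  attr(out, "truth") <- presets
  out
}
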