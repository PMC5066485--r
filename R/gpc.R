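#' Size-marker set for gel-permeation chromatography
#'
#' Molecular-mass standards (dextrans here) with their elution positions.
#' Size exclusion physics requires mass to decrease strictly with elution
#' position: larger molecules elute first.
#'
#' @param mw_kda Marker molecular masses in kDa, positive and distinct.
#' @param elution Elution positions (fraction midpoint time in minutes, or
#'   fraction index), distinct.
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(mw_kda, elution) {
  mw_kda <- as.numeric(mw_kda)
  elution <- as.numeric(elution)
  if (length(mw_kda) != length(elution))
    stop("mw_kda and elution must have equal length")
  if (length(mw_kda) < 2L) stop("at least 2 size markers are required")
  if (any(mw_kda <= 0)) stop("marker masses must be positive")
  if (anyDuplicated(mw_kda) || anyDuplicated(elution))
    stop("marker masses and elution positions must be distinct")
  o <- order(elution)
  mw_kda <- mw_kda[o]; elution <- elution[o]
  if (any(diff(mw_kda) >= 0))
    stop("marker mass must decrease with elution position: in size ",
         "exclusion larger molecules elute earlier")
  structure(list(mw_kda = mw_kda, elution = elution), class = "marker_set")
}

#' Fit a log-linear molecular-mass calibration
#'
#' Ordinary least squares of `log10(MW kDa)` on elution position, the
#' standard GPC calibration. With two markers, or collinear markers, the
#' line interpolates them exactly. The slope is necessarily negative.
#'
#' @param markers A [marker_set()].
#' @return An object of class `logmw_calibration` with `slope`,
#'   `intercept` (of log10(MW) vs elution position) and `r_squared`.
#' @export
fit_mw_calibration <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  y <- log10(markers$mw_kda)
  x <- markers$elution
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  res <- stats::residuals(fit)
  tss <- sum((y - mean(y))^2)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = if (tss > 0) 1 - sum(res^2) / tss else 1,
                 markers = markers),
            class = "logmw_calibration")
}

#' @export
print.logmw_calibration <- function(x, ...) {
  cat(sprintf(
    "GPC calibration: log10(MW kDa) = %.6g %+.6g * elution (R^2 = %.6f)\n",
    x$intercept, x$slope, x$r_squared))
  invisible(x)
}

# MW assigned to an elution position by a log-linear calibration
.mw_at <- function(cal, position) 10^(cal$intercept + cal$slope * position)

#' Per-fraction elution profile
#'
#' Analyte content of consecutive chromatography fractions. With the
#' standard 30 s collection interval at 1 ml/min, fraction `i` spans
#' `[(i-1), i] * 0.5` min and its elution position is the fraction
#' midpoint time.
#'
#' @param content Analyte content per fraction (e.g. xyloglucan by iodine
#'   staining), non-negative.
#' @param elution Optional elution positions (min), strictly increasing;
#'   derived from `fraction` and `interval_s` when omitted.
#' @param fraction Fraction indices (default `1:length(content)`).
#' @param interval_s Fraction collection interval in seconds (default 30).
#' @return An object of class `elution_profile` (also a data.frame with
#'   columns `fraction`, `elution_min`, `content`).
#' @export
elution_profile <- function(content, elution = NULL,
                            fraction = seq_along(content),
                            interval_s = 30) {
  content <- as.numeric(content)
  if (length(content) < 1L) stop("profile must be non-empty")
  if (any(!is.finite(content)) || any(content < 0))
    stop("fraction contents must be finite and non-negative")
  if (is.null(elution)) {
    elution <- (as.numeric(fraction) - 0.5) * interval_s / 60
  }
  elution <- as.numeric(elution)
  if (length(elution) != length(content))
    stop("elution and content must have equal length")
  if (any(diff(elution) <= 0))
    stop("fraction elution positions must be strictly increasing")
  structure(data.frame(fraction = as.numeric(fraction),
                       elution_min = elution, content = content),
            class = c("elution_profile", "data.frame"),
            interval_s = interval_s)
}

.check_profile <- function(profile) {
  stopifnot(inherits(profile, "elution_profile"))
  if (all(profile$content == 0))
    stop("all fraction contents are zero: no peak to locate")
}

# warn (via the result's attribute) when an assigned MW falls outside the
# marker range
.extrapolation_flag <- function(cal, mw) {
  rng <- range(cal$markers$mw_kda)
  mw < rng[1L] | mw > rng[2L]
}

#' Molecular mass at the profile's peak fraction
#'
#' Finds the fraction with maximal content (ties broken toward the
#' earlier-eluting, i.e. larger, fraction) and converts its elution
#' position to molecular mass via the log-linear calibration. This is the
#' peak-fraction estimator; see [mass_distribution()] for a
#' content-weighted centroid alternative.
#'
#' @param profile An [elution_profile()] with at least one positive
#'   content.
#' @param cal A fitted [fit_mw_calibration()].
#' @return Molecular mass in kDa (a single number) with attribute
#'   `extrapolated` set to TRUE when the peak lies outside the marker
#'   range.
#' @export
peak_molecular_mass <- function(profile, cal) {
  .check_profile(profile)
  stopifnot(inherits(cal, "logmw_calibration"))
  i <- which.max(profile$content)  # which.max returns the first maximum:
                                   # earliest-eluting fraction on ties
  mw <- .mw_at(cal, profile$elution_min[i])
  extrap <- .extrapolation_flag(cal, mw)
  if (extrap)
    warning("peak molecular mass lies outside the marker range (",
            paste(range(cal$markers$mw_kda), collapse = "-"), " kDa)")
  structure(mw, extrapolated = extrap)
}

#' Molecular-mass distribution of an elution profile
#'
#' Assigns each fraction a molecular mass through the calibration and
#' normalizes contents to fractions of the total. Also reports the
#' content-weighted centroid on the log10(MW) scale as attribute
#' `centroid_mw_kda` (an optional smoother alternative to the
#' peak-fraction estimate).
#'
#' @inheritParams peak_molecular_mass
#' @return A data.frame with columns `fraction`, `elution_min`, `mw_kda`,
#'   `content`, `content_fraction` (summing to 1) and `extrapolated`.
#' @export
mass_distribution <- function(profile, cal) {
  .check_profile(profile)
  stopifnot(inherits(cal, "logmw_calibration"))
  mw <- .mw_at(cal, profile$elution_min)
  total <- sum(profile$content)
  frac <- profile$content / total
  centroid <- 10^(sum(frac * log10(mw)))
  structure(data.frame(fraction = profile$fraction,
                       elution_min = profile$elution_min,
                       mw_kda = mw, content = profile$content,
                       content_fraction = frac,
                       extrapolated = .extrapolation_flag(cal, mw)),
            centroid_mw_kda = centroid)
}
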