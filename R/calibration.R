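#' Calibration standard series
#'
#' Known amounts of an analyte with the measured instrument response, as
#' used for colorimetric total-sugar (glucose standard), iodine-staining
#' xyloglucan (tamarind standard) and HPAEC-PAD oligosaccharide (XXXG
#' standard) quantification.
#'
#' @param amount Known amounts, non-negative, at least two distinct
#'   levels.
#' @param response Measured responses, same length.
#' @param analyte Label for the analyte (e.g. "glucose", "XXXG").
#' @param amount_unit,response_unit Axis unit labels.
#' @return An object of class `calibration_standards`.
#' @export
calibration_standards <- function(amount, response, analyte = "analyte",
                                  amount_unit = "ug",
                                  response_unit = "response") {
  amount <- as.numeric(amount)
  response <- as.numeric(response)
  if (length(amount) != length(response))
    stop("amount and response must have equal length")
  if (any(!is.finite(amount)) || any(!is.finite(response)))
    stop("standards must be finite")
  if (any(amount < 0)) stop("amounts must be non-negative")
  if (length(unique(amount)) < 2L)
    stop("at least 2 distinct amount levels are required")
  structure(list(amount = amount, response = response, analyte = analyte,
                 amount_unit = amount_unit, response_unit = response_unit),
            class = "calibration_standards")
}

#' Fit a linear standard curve
#'
#' Ordinary least squares of response on amount. The intercept is fitted
#' by default; `through_origin = TRUE` forces a zero-intercept curve.
#'
#' @param standards A [calibration_standards()].
#' @param through_origin Force the line through (0, 0)?
#' @return An object of class `calibration_curve` with `slope`,
#'   `intercept`, `r_squared`, `residual_sd` and the source `standards`.
#' @export
fit_linear_calibration <- function(standards, through_origin = FALSE) {
  stopifnot(inherits(standards, "calibration_standards"))
  a <- standards$amount
  r <- standards$response
  if (through_origin) {
    fit <- stats::lm(r ~ 0 + a)
    slope <- unname(stats::coef(fit)[1L])
    intercept <- 0
  } else {
    fit <- stats::lm(r ~ a)
    slope <- unname(stats::coef(fit)[2L])
    intercept <- unname(stats::coef(fit)[1L])
  }
  res <- stats::residuals(fit)
  tss <- sum((r - mean(r))^2)
  r_squared <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  residual_sd <- if (stats::df.residual(fit) > 0)
    sqrt(sum(res^2) / stats::df.residual(fit)) else NA_real_
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, residual_sd = residual_sd,
                 standards = standards),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve [%s]: response = %.6g * amount %+.6g",
              x$standards$analyte, x$slope, x$intercept),
      sprintf("(R^2 = %.6f)\n", x$r_squared))
  invisible(x)
}

#' Quantify a sample response against a standard curve
#'
#' Inverts the fitted line: `amount = (response - intercept) / slope`.
#' Negative recovered amounts are returned, not clipped, and flagged;
#' responses below the smallest standard's response (or below an optional
#' limit of detection) are flagged as extrapolation / below-LOD rather
#' than rejected, since trace-level samples are routinely reported.
#'
#' @param curve A [calibration_curve()] with non-zero slope.
#' @param response Measured response(s); vectorized.
#' @param lod Optional limit of detection on the amount scale; recovered
#'   amounts below it are flagged `below_lod`.
#' @return A data.frame with columns `response`, `amount`, `flag`
#'   (one of `"ok"`, `"negative"`, `"extrapolated_low"`,
#'   `"extrapolated_high"`, `"below_lod"`).
#' @export
quantify <- function(curve, response, lod = NULL) {
  stopifnot(inherits(curve, "calibration_curve"))
  # slope negligible relative to the response scale: flat curve, not
  # invertible (covers exact zeros and numerically-zero fits alike)
  resp_scale <- max(abs(curve$standards$response), 1)
  amt_span <- diff(range(curve$standards$amount))
  if (!is.finite(curve$slope) ||
      abs(curve$slope) * amt_span < 1e-12 * resp_scale)
    stop("calibration slope is zero: curve not invertible")
  response <- as.numeric(response)
  amount <- (response - curve$intercept) / curve$slope
  rng <- range(curve$standards$amount)
  flag <- rep("ok", length(amount))
  if (!is.null(lod)) flag[amount < lod] <- "below_lod"
  flag[amount < rng[1L]] <- "extrapolated_low"
  flag[amount > rng[2L]] <- "extrapolated_high"
  flag[amount < 0] <- "negative"
  data.frame(response = response, amount = amount, flag = flag,
             stringsAsFactors = FALSE)
}
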