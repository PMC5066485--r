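# CSV dialects used by all modules. Each writer emits exactly what the
# matching reader accepts, so generator -> file -> reader round-trips are
# lossless (up to numeric printing, which uses full precision).

#' Write / read a creep curve as CSV plus a metadata sidecar
#'
#' The CSV has the header `time_s,deformation`; the protocol (P0, dt,
#' duration, optional geometry) and sample label travel in a YAML sidecar
#' next to the CSV.
#'
#' @param curve A [creep_curve()].
#' @param path CSV output path.
#' @param sidecar Sidecar path (default: `path` with `.yaml` appended).
#' @return `path`, invisibly.
#' @export
write_creep_csv <- function(curve, path, sidecar = paste0(path, ".yaml")) {
  stopifnot(inherits(curve, "creep_curve"))
  df <- data.frame(time_s = curve$times, deformation = curve$deformation)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  pr <- curve$protocol
  meta <- list(P0 = pr$P0, dt = pr$dt, duration = pr$T_total)
  if (!is.null(pr$gauge_length_mm)) meta$gauge_length_mm <- pr$gauge_length_mm
  if (!is.null(pr$diameter_mm)) meta$diameter_mm <- pr$diameter_mm
  if (!is.null(curve$label)) meta$label <- curve$label
  yaml::write_yaml(meta, sidecar)
  invisible(path)
}

#' @rdname write_creep_csv
#' @param protocol Protocol to use when no sidecar is found.
#' @return For the reader: a [creep_curve()].
#' @export
read_creep_csv <- function(path, sidecar = paste0(path, ".yaml"),
                           protocol = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "deformation") %in% names(df)))
    stop("creep CSV must have columns time_s,deformation")
  label <- NULL
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    protocol <- creep_protocol(
      P0 = meta$P0, dt = meta$dt, T_total = meta$duration,
      gauge_length_mm = meta$gauge_length_mm,
      diameter_mm = meta$diameter_mm)
    label <- meta$label
  } else if (is.null(protocol)) {
    protocol <- creep_protocol()
  }
  creep_curve(df$time_s, df$deformation, protocol, label = label)
}

#' Write / read calibration standards as CSV (`amount,response`)
#' @param standards A [calibration_standards()].
#' @param path CSV path.
#' @return `path` (writer, invisibly) / a [calibration_standards()]
#'   (reader).
#' @export
write_standards_csv <- function(standards, path) {
  stopifnot(inherits(standards, "calibration_standards"))
  utils::write.csv(data.frame(amount = standards$amount,
                              response = standards$response),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_standards_csv
#' @param analyte Analyte label for the reader.
#' @export
read_standards_csv <- function(path, analyte = "analyte") {
  df <- utils::read.csv(path)
  if (!all(c("amount", "response") %in% names(df)))
    stop("standards CSV must have columns amount,response")
  calibration_standards(df$amount, df$response, analyte = analyte)
}

#' Write / read a GPC elution profile (`fraction,elution_min,content`)
#' @param profile An [elution_profile()].
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "elution_profile"))
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("fraction", "elution_min", "content") %in% names(df)))
    stop("profile CSV must have columns fraction,elution_min,content")
  elution_profile(df$content, elution = df$elution_min,
                  fraction = df$fraction)
}

#' Write / read a GPC marker set (`mw_kda,elution_min`)
#' @param markers A [marker_set()].
#' @param path CSV path.
#' @export
write_markers_csv <- function(markers, path) {
  stopifnot(inherits(markers, "marker_set"))
  utils::write.csv(data.frame(mw_kda = markers$mw_kda,
                              elution_min = markers$elution),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_markers_csv
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mw_kda", "elution_min") %in% names(df)))
    stop("markers CSV must have columns mw_kda,elution_min")
  marker_set(df$mw_kda, df$elution_min)
}

#' Write / read a morphometry replicate table
#'
#' Long format: `genotype,trait,replicate,value` (as produced by
#' [simulate_morphometry()]).
#' @param table The replicate data.frame.
#' @param path CSV path.
#' @export
write_morphometry_csv <- function(table, path) {
  stopifnot(all(c("genotype", "trait", "replicate", "value") %in%
                  names(table)))
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_morphometry_csv
#' @export
read_morphometry_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("genotype", "trait", "replicate", "value") %in% names(df)))
    stop("morphometry CSV must have columns genotype,trait,replicate,value")
  df
}

#' Pivot a long morphometry table to one column per trait
#' @param long A long table (`genotype,trait,replicate,value`).
#' @return A wide data.frame with `genotype`, `replicate` and one numeric
#'   column per trait, suitable for [compare_morphometry()].
#' @export
morphometry_wide <- function(long) {
  traits <- unique(long$trait)
  out <- NULL
  for (tr in traits) {
    sub <- long[long$trait == tr, c("genotype", "replicate", "value")]
    names(sub)[3L] <- tr
    out <- if (is.null(out)) sub else
      merge(out, sub, by = c("genotype", "replicate"), all = TRUE)
  }
  out
}
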