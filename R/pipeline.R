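# 64-bit-free FNV-1a hash of the deparsed configuration, recorded in every
# output for provenance. Stable across platforms; not cryptographic.
.config_hash <- function(config) {
  txt <- paste(deparse(config, control = c("keepNA", "keepInteger")),
               collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

.provenance <- function(config) {
  list(seed = config$seed,
       config_hash = .config_hash(config),
       package = "wallcreep",
       version = as.character(utils::packageVersion("wallcreep")))
}

#' Default end-to-end pipeline configuration
#'
#' A complete configuration exercising every stage on synthetic data:
#' creep simulation + Burgers fit, GPC simulation + molecular-mass
#' estimation for all genotype presets, a glucose-style standard curve
#' with sample quantification, and morphometry simulation + two-group
#' comparison.
#'
#' @param seed Integer seed propagated (with fixed offsets) to every
#'   stochastic stage.
#' @return A nested configuration list accepted by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("creep", "gpc", "standards", "morphometry"),
    creep = list(
      truth = list(E0 = 10, E1 = 20, E2 = 40, E3 = 80,
                   tau1 = 5, tau2 = 50, tau3 = 500),
      noise_sd = 0.02,
      fit = list(n_restarts = 8L)),
    gpc = list(genotypes = c("Ws", "Ler", "trg1-1", "trg1-2"),
               noise_sd = 0),
    standards = list(slope = 0.05, intercept = 0.01,
                     amounts = c(0, 1, 2, 5, 10, 20),
                     noise_sd = 0.002, analyte = "glucose",
                     sample_responses = c(0.12, 0.55, 0.9)),
    morphometry = list(variant = "pooled"))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the configured stages (simulate then analyse), writes every
#' simulated input in its CSV dialect plus a `results.json` bundle and a
#' human-readable `report.txt` under `out_dir`. All randomness derives
#' from `config$seed`, so a rerun with the same configuration produces
#' byte-identical outputs.
#'
#' @param config A configuration list (see [default_pipeline_config()]) or
#'   the path to a YAML file holding one.
#' @param out_dir Output directory, created if needed.
#' @return The results list, invisibly. Files written: per-stage input
#'   CSVs, `results.json`, `report.txt`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || length(config) == 0L || is.null(config$seed))
    stop("usage: run_pipeline(config, out_dir) where config is a ",
         "non-empty list (or YAML path) with at least a `seed` field; ",
         "see default_pipeline_config()")
  stages <- config$stages
  if (is.null(stages)) stages <- c("creep", "gpc", "standards", "morphometry")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  results <- list(provenance = .provenance(config))
  report <- c("wallcreep pipeline report",
              sprintf("seed: %d  config: %s", seed,
                      results$provenance$config_hash), "")

  if ("creep" %in% stages) {
    cc <- config$creep
    tr <- cc$truth
    truth <- burgers_params(tr$E0, tr$E1, tr$E2, tr$E3,
                            tr$tau1, tr$tau2, tr$tau3)
    curve <- simulate_creep(truth, noise_sd = cc$noise_sd %||% 0,
                            seed = seed + 101L)
    write_creep_csv(curve, file.path(out_dir, "creep.csv"))
    fcfg <- do.call(fit_config, c(cc$fit, list(seed = seed + 102L)))
    fit <- fit_burgers(curve, fcfg)
    results$creep <- list(
      truth = unclass(truth),
      params = unclass(fit$params), plastic = unclass(fit$plastic),
      sse = fit$sse, r_squared = fit$r_squared,
      converged = fit$converged, warnings = fit$warnings)
    report <- c(report, sprintf(
      "creep fit: E0=%.4g E1=%.4g E2=%.4g E3=%.4g tau=(%.4g, %.4g, %.4g) R^2=%.6f",
      fit$params$E0, fit$params$E1, fit$params$E2, fit$params$E3,
      fit$params$tau1, fit$params$tau2, fit$params$tau3, fit$r_squared))
  }

  if ("gpc" %in% stages) {
    gc_ <- config$gpc
    genos <- gc_$genotypes %||% "Ws"
    results$gpc <- list()
    for (g in genos) {
      sim <- simulate_gpc(preset = gpc_preset(g),
                          noise_sd = gc_$noise_sd %||% 0,
                          seed = seed + 200L + match(g, genos))
      write_profile_csv(sim$profile,
                        file.path(out_dir, sprintf("gpc_profile_%s.csv", g)))
      write_markers_csv(sim$markers,
                        file.path(out_dir, sprintf("gpc_markers_%s.csv", g)))
      cal <- fit_mw_calibration(sim$markers)
      mw <- peak_molecular_mass(sim$profile, cal)
      results$gpc[[g]] <- list(
        peak_mw_kda = as.numeric(mw),
        truth_peak_mw_kda = sim$truth$peak_mw_kda,
        cal_slope = cal$slope, cal_intercept = cal$intercept)
      report <- c(report, sprintf(
        "gpc %s: peak MW %.0f kDa (truth %.0f)", g, as.numeric(mw),
        sim$truth$peak_mw_kda))
    }
  }

  if ("standards" %in% stages) {
    sc <- config$standards
    st <- simulate_standards(sc$slope, sc$intercept %||% 0,
                             amounts = sc$amounts %||% c(0, 1, 2, 5, 10),
                             noise_sd = sc$noise_sd %||% 0,
                             analyte = sc$analyte %||% "analyte",
                             seed = seed + 301L)
    write_standards_csv(st, file.path(out_dir, "standards.csv"))
    curve <- fit_linear_calibration(st)
    results$standards <- list(
      slope = curve$slope, intercept = curve$intercept,
      r_squared = curve$r_squared)
    if (!is.null(sc$sample_responses)) {
      q <- quantify(curve, sc$sample_responses)
      results$standards$samples <- q
      report <- c(report, sprintf(
        "calibration [%s]: slope %.5g intercept %.5g R^2 %.6f; %d samples quantified",
        st$analyte, curve$slope, curve$intercept, curve$r_squared, nrow(q)))
    }
  }

  if ("morphometry" %in% stages) {
    mc <- config$morphometry
    long <- simulate_morphometry(seed = seed + 401L)
    write_morphometry_csv(long, file.path(out_dir, "morphometry.csv"))
    wide <- morphometry_wide(long)
    genos <- unique(wide$genotype)
    cmp <- compare_morphometry(
      wide[, setdiff(names(wide), "replicate")],
      genos[1L], genos[2L], variant = mc$variant %||% "pooled")
    results$morphometry <- cmp
    for (i in seq_len(nrow(cmp)))
      report <- c(report, sprintf(
        "morphometry %s: %s %.4g vs %s %.4g, t=%.3f, p=%.3g",
        cmp$trait[i], genos[1L], cmp$mean_a[i], genos[2L], cmp$mean_b[i],
        cmp$t[i], cmp$p_value[i]))
  }

  jsonlite::write_json(results, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(report, file.path(out_dir, "report.txt"))
  invisible(results)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
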