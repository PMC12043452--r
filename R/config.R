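.config_schema <- list(
  kinetics = c("Td", "Tc", "TG0", "TN", "TA", "RA", "RADiff", "RNDiff",
               "PG0toG1", "NLIMP", "Psym", "Psleep"),
  treatment = c("patient", "days", "drugs", "dt_post_treat"),
  simulator = c("mode", "capacity", "removal_threshold", "restructure_every",
                "dt", "seed"),
  ensemble = c("n_vps", "seed", "deviation", "tolerance", "width", "volumes",
               "calibrate"),
  stats = c("adjust"))

#' Load and validate a run configuration
#'
#' Reads a YAML configuration with sections `kinetics`, `treatment`,
#' `simulator`, `ensemble` and `stats`. Unknown sections or keys are
#' rejected with a descriptive error; missing keys take the package
#' defaults. An empty file yields the full default configuration.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return A list of class `nephrosim_config` with elements `kinetics`
#'   (a [kinetic_params()]), `simulator` (a [sim_config()]), `ensemble`
#'   (validated list), `treatment` (a [treatment_plan()] or `NULL`), and
#'   `stats`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("configuration must be a YAML mapping", call. = FALSE)
  bad <- setdiff(names(raw), names(.config_schema))
  if (length(bad))
    stop("unknown configuration section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(raw)) {
    unknown <- setdiff(names(raw[[sec]]), .config_schema[[sec]])
    if (length(unknown))
      stop("unknown key(s) in [", sec, "]: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  kin <- do.call(kinetic_params, raw$kinetics %||% list())
  simc <- do.call(sim_config, raw$simulator %||% list())
  ens_defaults <- list(n_vps = 50L, seed = 1L, deviation = 0.5, tolerance = 5,
                       width = 1 / 1024, volumes = "segmentation",
                       calibrate = TRUE)
  ens <- utils::modifyList(ens_defaults, raw$ensemble %||% list())
  if (ens$deviation <= 0 || ens$deviation > 1)
    stop("[ensemble] deviation must lie in (0, 1]", call. = FALSE)
  if (ens$tolerance <= 0)
    stop("[ensemble] tolerance must be > 0", call. = FALSE)
  if (!ens$volumes %in% c("segmentation", "database"))
    stop("[ensemble] volumes must be 'segmentation' or 'database'",
         call. = FALSE)
  trt <- NULL
  if (!is.null(raw$treatment)) {
    trt <- if (!is.null(raw$treatment$patient))
      patient_plan(raw$treatment$patient)
    else treatment_plan(raw$treatment$days, raw$treatment$drugs,
                        raw$treatment$dt_post_treat %||% 0)
  }
  structure(list(kinetics = kin, simulator = simc, ensemble = ens,
                 treatment = trt, stats = raw$stats %||% list()),
            class = "nephrosim_config")
}

#' Reproduce the full adaptation analysis for one patient
#'
#' Runs the virtual-patient ensemble for a preset patient, producing the
#' summary tables (median, IQR, min, max, n for `CKR_Total`/`ACT`/`VCR`
#' and adaptation errors under no filter, the adaptation criterion, and
#' both criteria) together with the per-iteration scatter data. Running
#' twice with the same seed yields identical results.
#'
#' @param patient_id `"P1"`, `"P2"` or `"P3"`.
#' @param n number of virtual patients.
#' @param seed master seed.
#' @param ... further arguments passed to [fit_ckr()].
#' @return A list with the `fit`, its `summary`, the per-VP `records` and
#'   the pooled `iterations` table.
#' @export
reproduce_patient <- function(patient_id, n = 50, seed = 42L, ...) {
  fit <- fit_ckr(patient_id, n = n, seed = seed, ...)
  list(fit = fit, summary = summary(fit), records = vp_records(fit),
       iterations = iterations(fit))
}

#' Write a run manifest
#'
#' Records everything needed to re-execute an aggregate-mode run
#' bit-identically: package version, master seed, the effective
#' configuration, input digests and timings.
#'
#' @param path output JSON path.
#' @param seed master seed of the run.
#' @param config the effective configuration (any list-like).
#' @param inputs named character vector of input files to digest (md5).
#' @param timings named numeric vector of per-stage timings, seconds.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(), inputs = character(),
                           timings = numeric()) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "nephrosim",
    version = as.character(utils::packageVersion("nephrosim")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config = config,
    input_md5 = digests,
    timings_sec = as.list(timings))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
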