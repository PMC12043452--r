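#' Post-surgical histology profile
#'
#' Fractions describing the resected tumor: the macroscopic
#' necrosis/regressive fraction, and the blastema/epithelium/stroma split
#' of the remaining vital tissue (which must sum to one).
#'
#' @param regressive fraction of the post-chemo tumor that is
#'   necrotic/regressive, in `[0, 1]`.
#' @param blastema,epithelium,stroma fractions of the vital tissue.
#' @return An object of class `histology_profile`.
#' @export
histology_profile <- function(regressive, blastema, epithelium, stroma) {
  v <- c(regressive = regressive, blastema = blastema,
         epithelium = epithelium, stroma = stroma)
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1))
    stop("all histology fractions must lie in [0, 1]", call. = FALSE)
  if (abs(blastema + epithelium + stroma - 1) > 1e-9)
    stop("vital-tissue fractions must sum to 1", call. = FALSE)
  structure(list(f_regressive = regressive, f_vital = 1 - regressive,
                 f_blastema = blastema, f_epithelium = epithelium,
                 f_stroma = stroma),
            class = "histology_profile")
}

#' Minimum initial fraction of proliferative cells (IFPC)
#'
#' Estimates a lower bound on the tumor's pre-treatment proliferative
#' fraction from the post-surgical histology: the necrosis/regressive
#' tissue is attributed to chemo-killed blastema and added to the
#' surviving vital blastema, relative to the pre-chemotherapy volume:
#' \deqn{IFPC = (V_{post} f_{regressive} + V_{post} f_{vital}
#'   f_{blastema}) / V_{pre}.}
#' This bound defines the histology criterion: an admissible virtual
#' patient must start with at least this proliferative fraction.
#'
#' @param histology a [histology_profile()].
#' @param v_pre,v_post pre/post-chemotherapy tumor volumes, cm^3.
#' @return The IFPC as a fraction in `[0, 1]`.
#' @examples
#' ifpc(histology_profile(0.98, 0, 1, 0), 126.25, 10.58)  # 0.082
#' @export
ifpc <- function(histology, v_pre, v_post) {
  stopifnot(inherits(histology, "histology_profile"))
  if (v_pre <= 0) stop("`v_pre` must be > 0", call. = FALSE)
  if (v_post < 0) stop("`v_post` must be >= 0", call. = FALSE)
  (v_post * histology$f_regressive +
     v_post * histology$f_vital * histology$f_blastema) / v_pre
}

# Clinical ground truth per patient: volumes by both methods, histology.
.patient_db <- list(
  P1 = list(risk = "low",
            db = c(pre = 143.99, post = 10.62),
            seg = c(pre = 126.25, post = 10.58),
            hist = c(regressive = 0.98, blastema = 0, epithelium = 1,
                     stroma = 0)),
  P2 = list(risk = "intermediate",
            db = c(pre = 536.73, post = 89.49),
            seg = c(pre = 526.99, post = 70.72),
            hist = c(regressive = 0.70, blastema = 0.20, epithelium = 0,
                     stroma = 0.80)),
  P3 = list(risk = "high",
            db = c(pre = 306.99, post = 126.29),
            seg = c(pre = 235.64, post = 108.22),
            hist = c(regressive = 0.05, blastema = 0.70, epithelium = 0.05,
                     stroma = 0.25)))

#' Clinical ground truth for the three reference patients
#'
#' Bundles, per patient, the observed pre/post-chemotherapy tumor volumes
#' (from manual segmentation by default, or the ellipsoid-formula database
#' values), the derived observed volume reduction, the histology profile
#' with its IFPC bound, and the recorded treatment schedule.
#'
#' @param patient_id `"P1"` (low risk), `"P2"` (intermediate) or `"P3"`
#'   (high risk).
#' @param volumes which volume determination to use as ground truth.
#' @return An object of class `patient_truth`.
#' @examples
#' patient_ground_truth("P3")
#' @export
patient_ground_truth <- function(patient_id,
                                 volumes = c("segmentation", "database")) {
  volumes <- match.arg(volumes)
  rec <- .patient_db[[patient_id]]
  if (is.null(rec)) stop("unknown patient preset: ", patient_id, call. = FALSE)
  v <- if (volumes == "segmentation") rec$seg else rec$db
  hist <- histology_profile(rec$hist[["regressive"]], rec$hist[["blastema"]],
                            rec$hist[["epithelium"]], rec$hist[["stroma"]])
  structure(list(id = patient_id, risk = rec$risk, volumes = volumes,
                 v_pre = v[["pre"]], v_post = v[["post"]],
                 observed_reduction = volume_reduction(v[["pre"]], v[["post"]]),
                 histology = hist,
                 ifpc = ifpc(hist, v[["pre"]], v[["post"]]),
                 plan = patient_plan(patient_id)),
            class = "patient_truth")
}

#' @export
print.patient_truth <- function(x, ...) {
  cat(sprintf("Patient %s (%s risk, %s volumes):\n", x$id, x$risk, x$volumes))
  cat(sprintf("  volume %.2f -> %.2f cm^3  (observed reduction %.1f%%)\n",
              x$v_pre, x$v_post, x$observed_reduction))
  cat(sprintf("  IFPC (histology criterion) = %.1f%%\n", 100 * x$ifpc))
  invisible(x)
}

#' Clinical adaptation error
#'
#' Relative deviation between predicted and observed tumor volume
#' reduction, in percent of the observed reduction.
#'
#' @param dv_pred,dv_obs predicted and observed reductions, percent;
#'   `dv_obs` must be positive.
#' @return `100 * |dv_pred - dv_obs| / dv_obs`.
#' @export
adaptation_error <- function(dv_pred, dv_obs) {
  if (any(dv_obs <= 0))
    stop("`dv_obs` must be > 0 (responding tumor)", call. = FALSE)
  100 * abs(dv_pred - dv_obs) / dv_obs
}

#' Sample one virtual patient's kinetic parameters
#'
#' Each real-valued kinetic parameter is drawn independently and uniformly
#' within `+/- deviation` (default 50\%) of its reference value;
#' probabilities are clipped to `[0, 1]` and the mitosis budget `NLIMP` is
#' drawn uniformly from the integers inside its interval. The draw is
#' deterministic given `(seed, vp_index)` via a counter-based substream,
#' so ensembles are reproducible independently of execution order.
#'
#' @param reference a [kinetic_params()] object of central values.
#' @param deviation maximal fractional deviation from the reference.
#' @param seed master seed of the ensemble.
#' @param vp_index index of the virtual patient (>= 1).
#' @return A [kinetic_params()] object.
#' @export
sample_vp <- function(reference, deviation = 0.5, seed = 1L, vp_index = 1L) {
  stopifnot(inherits(reference, "kinetic_params"))
  if (deviation <= 0 || deviation > 1)
    stop("`deviation` must lie in (0, 1]", call. = FALSE)
  local_seed(substream_seed(seed, vp_index))
  draw <- function(ref) stats::runif(1, (1 - deviation) * ref,
                                     (1 + deviation) * ref)
  prob <- function(ref) min(1, max(0, draw(ref)))
  nl_lo <- ceiling((1 - deviation) * reference$NLIMP - 1e-9)
  nl_hi <- floor((1 + deviation) * reference$NLIMP + 1e-9)
  nl_lo <- max(1L, nl_lo)
  kinetic_params(Td = draw(reference$Td), Tc = draw(reference$Tc),
                 TG0 = draw(reference$TG0), TN = draw(reference$TN),
                 TA = draw(reference$TA), RA = prob(reference$RA),
                 RADiff = prob(reference$RADiff),
                 RNDiff = prob(reference$RNDiff),
                 PG0toG1 = prob(reference$PG0toG1),
                 NLIMP = sample(seq.int(nl_lo, nl_hi), 1L),
                 Psym = prob(reference$Psym), Psleep = prob(reference$Psleep))
}

#' Binary-search adaptation of the total cell-kill ratio
#'
#' Calibrates `CKR_Total` for one virtual patient against the observed
#' tumor-volume reduction. The parameter starts at the median of the
#' bounds 0 and 1; after each simulation the predicted reduction is
#' compared with the observed one: within `tolerance` percent relative
#' error the search stops successfully, otherwise an over-prediction
#' lowers the upper bound and an under-prediction raises the lower bound.
#' If the bounds converge below `width` no suitable value exists for this
#' virtual patient. Signed reductions are compared, so a growing tumor
#' (negative predicted reduction) counts as an under-prediction.
#'
#' @param sim_dv function mapping a [split_ckr()] set to a predicted
#'   reduction in percent.
#' @param dv_obs observed reduction, percent (> 0).
#' @param tolerance adaptation criterion, percent relative error.
#' @param width bound-convergence width on the dyadic grid.
#' @return A list with `iterations` (data frame of `iter`, `ckr_total`,
#'   `dv`, `error`), `final_ckr` (`NA` if the bounds converged) and
#'   `met_adaptation`.
#' @export
binary_search_adapt <- function(sim_dv, dv_obs, tolerance = 5,
                                width = 1 / 1024) {
  lo <- 0; hi <- 1
  iters <- list()
  final <- NA_real_
  met <- FALSE
  i <- 0L
  repeat {
    i <- i + 1L
    x <- (lo + hi) / 2
    dv <- sim_dv(split_ckr(x))
    err <- adaptation_error(dv, dv_obs)
    iters[[i]] <- data.frame(iter = i, ckr_total = x, dv = dv, error = err)
    if (err <= tolerance) { final <- x; met <- TRUE; break }
    if (dv > dv_obs) hi <- x else lo <- x
    if (hi - lo < width) break
  }
  list(iterations = do.call(rbind, iters), final_ckr = final,
       met_adaptation = met)
}

#' Fit the cell-kill ratio distribution over a virtual-patient ensemble
#'
#' The central estimator of the package: for a real patient's observed
#' tumor-volume reduction, an ensemble of `n` virtual patients is drawn
#' around the reference kinetics, each virtual patient's clock is
#' calibrated to its sampled doubling time, and `CKR_Total` is adapted by
#' binary search ([binary_search_adapt()]) against the observed reduction
#' using the patient's recorded schedule. Virtual patients whose sampled
#' kinetics do not sustain free growth (or whose clock cannot be
#' calibrated) are replaced by fresh draws, as non-growing tumors are
#' excluded from the model.
#'
#' @param patient a patient id (`"P1"`, `"P2"`, `"P3"`) or a
#'   [patient_ground_truth()] object.
#' @param n number of virtual patients.
#' @param seed master seed; every random draw derives from it.
#' @param reference central kinetic values ([kinetic_reference()]).
#' @param deviation maximal fractional parameter deviation (default 0.5).
#' @param tolerance adaptation criterion, percent (default 5).
#' @param width binary-search convergence width (default 1/1024).
#' @param volumes ground-truth volume source, see [patient_ground_truth()].
#' @param calibrate calibrate each virtual patient's emergent doubling
#'   time to its sampled `Td` (default `TRUE`); with `FALSE` the raw
#'   sampled kinetics are used and `Td` is inert.
#' @param config a [sim_config()]; ensembles run in aggregate mode.
#' @param verbose print one line per virtual patient.
#' @return An object of class `ckr_fit` with methods [print()],
#'   [summary()], [coef()], [plot()] and accessors [vp_records()],
#'   [iterations()], [filter_vps()].
#' @examples
#' \donttest{
#' fit <- fit_ckr("P3", n = 5, seed = 1)
#' coef(fit)
#' }
#' @export
fit_ckr <- function(patient, n = 50, seed = 1L,
                    reference = kinetic_reference(), deviation = 0.5,
                    tolerance = 5, width = 1 / 1024,
                    volumes = c("segmentation", "database"),
                    calibrate = TRUE, config = sim_config(),
                    verbose = FALSE) {
  truth <- if (inherits(patient, "patient_truth")) patient
           else patient_ground_truth(patient, match.arg(volumes))
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (config$mode != "aggregate")
    stop("ensemble fitting runs in aggregate mode; use simulate_tumor() ",
         "directly for spatial runs", call. = FALSE)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- NULL
    for (attempt in 0:49) {
      draw_idx <- i + attempt * 1000000L
      vp <- sample_vp(reference, deviation, seed, draw_idx)
      if (calibrate) {
        cal <- tryCatch(calibrate_doubling_time(vp),
                        nephrosim_calibration_error = function(e) NULL)
        if (is.null(cal)) next
        run_params <- cal$params; s <- cal$s
      } else {
        if (!free_growth_check(vp)) next
        run_params <- vp; s <- 1
      }
      comp <- stable_composition(run_params)
      tm <- initialize_tumor(truth$v_pre, run_params, config, comp = comp)
      bs <- binary_search_adapt(
        function(ckr) simulate_tumor(tm, truth$plan, ckr)$dv,
        truth$observed_reduction, tolerance, width)
      prolif0 <- 100 * comp$fractions[["prolif"]]
      rec <- list(vp = i, params = vp, dilation = s,
                  lambda = comp$lambda, prolif_initial = prolif0,
                  iterations = cbind(vp = i, bs$iterations),
                  final_ckr = bs$final_ckr,
                  met_adaptation = bs$met_adaptation,
                  met_histology = prolif0 >= 100 * truth$ifpc,
                  redraws = attempt)
      break
    }
    if (is.null(rec))
      stop("could not draw an admissible virtual patient for index ", i,
           call. = FALSE)
    records[[i]] <- rec
    if (verbose)
      cat(sprintf("VP %3d: final CKR_Total = %s (%d iterations)\n", i,
                  format(rec$final_ckr, digits = 4),
                  nrow(rec$iterations)))
  }
  structure(list(records = records, patient = truth, n = n, seed = seed,
                 reference = reference, deviation = deviation,
                 tolerance = tolerance, width = width,
                 calibrate = calibrate, config = config,
                 call = match.call()),
            class = "ckr_fit")
}

#' Per-virtual-patient results of a fit
#'
#' @param fit a [fit_ckr()] object.
#' @return A data frame with one row per virtual patient: sampled
#'   parameters, clock dilation, initial proliferative fraction, final
#'   `ckr_total`/`ckr_act`/`ckr_vcr`, final adaptation `error`, iteration
#'   count and the two criteria flags.
#' @export
vp_records <- function(fit) {
  stopifnot(inherits(fit, "ckr_fit"))
  do.call(rbind, lapply(fit$records, function(r) {
    last <- r$iterations[nrow(r$iterations), ]
    data.frame(vp = r$vp, as.data.frame(unclass(r$params)),
               dilation = r$dilation, prolif_initial = r$prolif_initial,
               ckr_total = r$final_ckr,
               ckr_act = 3 / 5 * r$final_ckr, ckr_vcr = 2 / 5 * r$final_ckr,
               error = last$error, n_iter = nrow(r$iterations),
               met_adaptation = r$met_adaptation,
               met_histology = r$met_histology, redraws = r$redraws)
  }))
}

#' @rdname vp_records
#' @return [iterations()]: all binary-search iterations of all virtual
#'   patients (`vp`, `iter`, `ckr_total`, `dv`, `error`), the data behind
#'   iteration-scatter displays.
#' @export
iterations <- function(fit) {
  stopifnot(inherits(fit, "ckr_fit"))
  out <- do.call(rbind, lapply(fit$records, `[[`, "iterations"))
  rownames(out) <- NULL
  out
}

#' Filter virtual patients by criteria and summarize
#'
#' @param fit a [fit_ckr()] object.
#' @param criteria subset of `c("adaptation", "histology")`; the empty
#'   default keeps every virtual patient with a final value.
#' @return The filtered [vp_records()] subset (rows without a final value
#'   are always dropped).
#' @export
filter_vps <- function(fit, criteria = character()) {
  stopifnot(all(criteria %in% c("adaptation", "histology")))
  tab <- vp_records(fit)
  keep <- !is.na(tab$ckr_total)
  if ("adaptation" %in% criteria) keep <- keep & tab$met_adaptation
  if ("histology" %in% criteria) keep <- keep & tab$met_histology
  tab[keep, , drop = FALSE]
}

#' Median/IQR summary of a sample (quartiles by linear interpolation)
#'
#' @param x numeric values (NAs dropped).
#' @return A named vector `Mdn`, `Q1`, `Q3`, `Min`, `Max`, `n`; all `NA`
#'   with `n = 0` for an empty sample.
#' @export
summarize_values <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x))
    return(c(Mdn = NA_real_, Q1 = NA_real_, Q3 = NA_real_, Min = NA_real_,
             Max = NA_real_, n = 0))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(Mdn = q[2], Q1 = q[1], Q3 = q[3], Min = min(x), Max = max(x),
    n = length(x))
}

#' @export
print.ckr_fit <- function(x, ...) {
  tab <- vp_records(x)
  cat(sprintf("Cell-kill ratio fit: patient %s (%s risk), %d virtual patients\n",
              x$patient$id, x$patient$risk, x$n))
  cat(sprintf("  observed reduction %.1f%%, adaptation criterion %.1f%%\n",
              x$patient$observed_reduction, x$tolerance))
  cat(sprintf("  adapted: %d/%d met adaptation, %d also met histology\n",
              sum(tab$met_adaptation), x$n,
              sum(tab$met_adaptation & tab$met_histology)))
  s <- summarize_values(filter_vps(x, "adaptation")$ckr_total)
  cat(sprintf("  CKR_Total (adaptation criterion): Mdn %.3f, IQR [%.3f, %.3f], n %d\n",
              s[["Mdn"]], s[["Q1"]], s[["Q3"]], as.integer(s[["n"]])))
  invisible(x)
}

#' @export
coef.ckr_fit <- function(object, criteria = "adaptation", ...) {
  sub <- filter_vps(object, criteria)
  med <- stats::median(sub$ckr_total)
  c(CKR_Total = med, CKR_ACT = 3 / 5 * med, CKR_VCR = 2 / 5 * med)
}

#' @export
summary.ckr_fit <- function(object, ...) {
  filt <- list(none = character(), adaptation = "adaptation",
               both = c("adaptation", "histology"))
  out <- lapply(filt, function(cr) {
    sub <- filter_vps(object, cr)
    rbind(CKR_Total = summarize_values(sub$ckr_total),
          CKR_ACT = summarize_values(sub$ckr_act),
          CKR_VCR = summarize_values(sub$ckr_vcr),
          error_pct = summarize_values(sub$error))
  })
  structure(list(tables = out, patient = object$patient, n = object$n,
                 seed = object$seed),
            class = "summary.ckr_fit")
}

#' @export
print.summary.ckr_fit <- function(x, ...) {
  cat(sprintf("Adapted cell-kill ratios, patient %s (%s risk), N = %d VPs\n",
              x$patient$id, x$patient$risk, x$n))
  lab <- c(none = "final iterations, no criteria",
           adaptation = "adaptation criterion",
           both = "adaptation + histology criteria")
  for (nm in names(x$tables)) {
    cat("\n--", lab[[nm]], "--\n")
    print(round(x$tables[[nm]], 3))
  }
  invisible(x)
}

#' @export
plot.ckr_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  it <- iterations(x)
  sub <- filter_vps(x, "adaptation")
  graphics::hist(sub$ckr_total, breaks = seq(0, 1, by = 1 / 32),
                 col = "steelblue", border = "white",
                 main = sprintf("Adapted CKR_Total (%s)", x$patient$id),
                 xlab = "CKR_Total (final iterations)")
  graphics::abline(v = stats::median(sub$ckr_total), lwd = 2, col = "red3")
  graphics::plot(it$ckr_total, pmin(it$error, 100),
                 col = grDevices::adjustcolor(
                   ifelse(it$error <= x$tolerance, "royalblue", "firebrick"),
                   0.5), pch = 16, xlab = "CKR_Total tried",
                 ylab = "adaptation error [%] (capped at 100)",
                 main = "All binary-search iterations")
  graphics::abline(h = x$tolerance, lty = 2)
  invisible(x)
}
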