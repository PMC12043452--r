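#' Drug-specific cell-kill ratios from the total
#'
#' The overall effect of the four-week vincristine/actinomycin regimen is
#' summarized by a single total cell-kill ratio which splits into fixed
#' drug-specific shares: actinomycin carries 3/5 and vincristine 2/5 of the
#' total.
#'
#' @param total total cell-kill ratio in `[0, 1]`.
#' @return An object of class `ckr_set`: list with `total`, `act`, `vcr`.
#' @examples
#' split_ckr(0.875)
#' @export
split_ckr <- function(total) {
  if (!is.finite(total) || total < 0 || total > 1)
    stop("`total` must lie in [0, 1]", call. = FALSE)
  structure(list(total = total, act = 3 / 5 * total, vcr = 2 / 5 * total),
            class = "ckr_set")
}

#' @export
print.ckr_set <- function(x, ...) {
  cat(sprintf("CKR_Total = %.4g (ACT %.4g + VCR %.4g)\n", x$total, x$act,
              x$vcr))
  invisible(x)
}

#' Chemotherapy schedule as day offsets
#'
#' A treatment plan lists drug administrations as whole-day offsets from the
#' pre-chemotherapy MRI (simulation day 0) and the number of days between
#' the last administration and the end of simulation (the post-chemo MRI).
#'
#' @param days nonnegative, nondecreasing integer day offsets.
#' @param drugs character vector, one of `"VCR"` or `"ACT"` per entry.
#' @param dt_post_treat days from the last administration to the end of the
#'   simulation (>= 0).
#' @return An object of class `treatment_plan`: a data frame of
#'   administrations with attributes `dt_post_treat` and `horizon_days`.
#' @examples
#' patient_plan("P2")
#' @export
treatment_plan <- function(days, drugs, dt_post_treat) {
  days <- as.numeric(days)
  drugs <- toupper(as.character(drugs))
  if (length(days) != length(drugs))
    stop("`days` and `drugs` must have the same length", call. = FALSE)
  if (any(days < 0) || is.unsorted(days))
    stop("administration days must be nonnegative and nondecreasing",
         call. = FALSE)
  if (!all(drugs %in% c("VCR", "ACT")))
    stop("drugs must be 'VCR' or 'ACT'", call. = FALSE)
  if (dt_post_treat < 0) stop("`dt_post_treat` must be >= 0", call. = FALSE)
  plan <- data.frame(day = days, drug = drugs, stringsAsFactors = FALSE)
  attr(plan, "dt_post_treat") <- dt_post_treat
  attr(plan, "horizon_days") <- if (nrow(plan)) max(days) + dt_post_treat
                                else dt_post_treat
  class(plan) <- c("treatment_plan", "data.frame")
  plan
}

#' @export
print.treatment_plan <- function(x, ...) {
  cat("Treatment plan:", nrow(x), "administrations, simulation ends day",
      attr(x, "horizon_days"), "\n")
  print.data.frame(x)
  invisible(x)
}

# Clinically recorded schedules, as day offsets from the pre-chemo MRI.
.plan_presets <- list(
  P1 = list(vcr = c(4, 12, 19, 26), act = c(4, 19), post = 6),
  P2 = list(vcr = c(4, 11, 18, 25), act = c(4, 18), post = 1),
  P3 = list(vcr = c(4, 11, 20, 27), act = c(4, 20), post = 7))

#' @rdname treatment_plan
#' @param patient_id one of `"P1"`, `"P2"`, `"P3"` (low, intermediate and
#'   high risk respectively).
#' @export
patient_plan <- function(patient_id) {
  ps <- .plan_presets[[patient_id]]
  if (is.null(ps)) stop("unknown patient preset: ", patient_id, call. = FALSE)
  days <- c(ps$vcr, ps$act)
  drugs <- c(rep("VCR", length(ps$vcr)), rep("ACT", length(ps$act)))
  o <- order(days, drugs)
  treatment_plan(days[o], drugs[o], ps$post)
}

#' Read or write a treatment plan as CSV
#'
#' Plans serialize as a two-column `day,drug` table; `dt_post_treat` is
#' stored in a `# dt_post_treat:` comment line.
#'
#' @param path CSV file path.
#' @return [read_plan()] returns a [treatment_plan()]; [write_plan()]
#'   returns `path` invisibly.
#' @export
read_plan <- function(path) {
  lines <- readLines(path)
  post <- 0
  m <- grep("^#\\s*dt_post_treat\\s*:", lines, value = TRUE)
  if (length(m)) post <- as.numeric(sub("^#\\s*dt_post_treat\\s*:\\s*", "", m[1]))
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  treatment_plan(tab$day, tab$drug, post)
}

#' @rdname read_plan
#' @param plan a [treatment_plan()].
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "treatment_plan"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dt_post_treat: %g", attr(plan, "dt_post_treat")), con)
  utils::write.csv(as.data.frame(plan), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Apply one drug administration to a compartment state
#'
#' A fraction `ckr_drug` of every viable tumor cell (cycling and dormant
#' stem/LIMP cells and differentiated cells) is lethally hit and moves to
#' the start of the apoptosis clearance pathway. Cells already dead are
#' unaffected and the total cell count is conserved exactly.
#'
#' @param state numeric state vector (or matrix with one column per voxel)
#'   laid out as in [transition_operator()].
#' @param layout the operator `layout` describing slot indices.
#' @param ckr_drug drug-specific cell-kill ratio in `[0, 1]`.
#' @return The state after the instantaneous kill.
#' @export
apply_drug <- function(state, layout, ckr_drug) {
  if (!is.finite(ckr_drug) || ckr_drug < 0 || ckr_drug > 1)
    stop("`ckr_drug` must lie in [0, 1]", call. = FALSE)
  live <- layout$live
  a1 <- layout$apop[1]
  if (is.matrix(state)) {
    killed <- ckr_drug * colSums(state[live, , drop = FALSE])
    state[live, ] <- (1 - ckr_drug) * state[live, , drop = FALSE]
    state[a1, ] <- state[a1, ] + killed
  } else {
    killed <- ckr_drug * sum(state[live])
    state[live] <- (1 - ckr_drug) * state[live]
    state[a1] <- state[a1] + killed
  }
  state
}
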