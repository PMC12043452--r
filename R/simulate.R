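#' Simulation configuration
#'
#' @param mode `"aggregate"` pools all tumor cells into one compartment
#'   state (the default; tumor-volume reduction depends only on totals
#'   because every rule is proportional), `"spatial"` tracks one state per
#'   occupied voxel and applies morphological mesh restructuring.
#' @param capacity biological cells per geometrical cell (voxel); the
#'   default 1e6 corresponds to the standard ~1e6 cells/mm^3 tissue density
#'   at 1 mm spacing.
#' @param removal_threshold voxels whose load falls below this fraction of
#'   capacity donate their contents to a neighbour and become unoccupied.
#' @param restructure_every hours between mesh restructuring scans.
#' @param dt simulation step in whole hours.
#' @param seed seed for the (spatial-only) restructuring tie-breaks.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(mode = c("aggregate", "spatial"), capacity = 1e6,
                       removal_threshold = 0.1, restructure_every = 24,
                       dt = 1, seed = 1L) {
  mode <- match.arg(mode)
  if (capacity <= 0) stop("`capacity` must be > 0", call. = FALSE)
  if (removal_threshold <= 0 || removal_threshold >= 1)
    stop("`removal_threshold` must lie in (0, 1)", call. = FALSE)
  if (restructure_every < 1) stop("`restructure_every` must be >= 1 hour",
                                  call. = FALSE)
  structure(list(mode = mode, capacity = capacity,
                 removal_threshold = removal_threshold,
                 restructure_every = as.integer(restructure_every),
                 dt = as.integer(dt), seed = as.integer(seed)),
            class = "sim_config")
}

#' Initialize the tumor state from a mask or a volume
#'
#' Every tumor-occupied voxel is seeded with `capacity` cells distributed
#' over the age-resolved compartments according to the stable composition
#' of untreated growth, so a simulation started without treatment continues
#' smoothly along the free-growth trajectory.
#'
#' @param x a [voxel_mask()] (any spacing; occupied voxels define the mesh)
#'   or a single tumor volume in cm^3 (aggregate mode only; the mesh is
#'   implied at 1 mm spacing).
#' @param params a [kinetic_params()] object; must allow sustained growth.
#' @param config a [sim_config()].
#' @param comp optionally a precomputed [stable_composition()] for
#'   `params`.
#' @return An object of class `tumor_state` holding the transition
#'   operator, the state (vector, or matrix with one column per voxel in
#'   spatial mode), voxel bookkeeping and the configuration.
#' @export
initialize_tumor <- function(x, params, config = sim_config(), comp = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(comp)) comp <- stable_composition(params)
  op <- comp$op
  if (inherits(x, "voxel_mask")) {
    n_vox <- sum(x$occupancy)
    if (n_vox == 0L) stop("cannot initialize from an empty mask", call. = FALSE)
    vox_mm3 <- prod(x$spacing)
    dims <- dim(x$occupancy)
    coords <- which(x$occupancy > 0, arr.ind = TRUE)
    coords <- coords[order(coords[, 3], coords[, 2], coords[, 1]), , drop = FALSE]
  } else {
    vol <- as.numeric(x)
    if (!is.finite(vol) || vol <= 0)
      stop("`x` must be a voxel_mask or a positive volume in cm^3",
           call. = FALSE)
    n_vox <- vol * 1000
    vox_mm3 <- 1
    dims <- NULL
    coords <- NULL
    if (config$mode == "spatial")
      stop("spatial mode needs a voxel_mask, not a bare volume", call. = FALSE)
  }
  total <- n_vox * config$capacity
  state <- if (config$mode == "aggregate") comp$state * total
           else matrix(comp$state * config$capacity, nrow = op$layout$n,
                       ncol = n_vox)
  structure(list(op = op, params = params, config = config, state = state,
                 coords = coords, dims = dims, vox_mm3 = vox_mm3,
                 n_vox = n_vox, comp = comp),
            class = "tumor_state")
}

#' @export
print.tumor_state <- function(x, ...) {
  cat("Tumor state (", x$config$mode, " mode): ",
      format(sum(x$state), digits = 4), " cells, ",
      format(.state_volume(x), digits = 4), " cm^3\n", sep = "")
  invisible(x)
}

.state_total <- function(x) sum(x$state)

# imaging-visible volume: live plus uncleared dead cells occupy space
.state_volume <- function(x) .state_total(x) / x$config$capacity *
  x$vox_mm3 / 1000

.aggregate_fractions <- function(state, layout) {
  tot <- if (is.matrix(state)) rowSums(state) else state
  s <- sum(tot)
  if (s <= 0) return(c(prolif = 0, dormant = 0, diff = 0, dead = 100))
  100 * c(prolif = sum(tot[layout$prolif]), dormant = sum(tot[layout$dormant]),
          diff = sum(tot[layout$diff]),
          dead = sum(tot[layout$apop]) + sum(tot[layout$necr])) / s
}

#' Simulate the treated (or untreated) tumor time course
#'
#' Runs the hourly cytokinetic update from day 0 (the pre-chemotherapy MRI)
#' to the end of the plan's horizon (last administration plus
#' `dt_post_treat`). Drug administrations are instantaneous proportional
#' kills at the start of their day, vincristine and actinomycin applied
#' with their drug-specific cell-kill ratios. In spatial mode the
#' morphological restructuring scan runs every `restructure_every` hours.
#'
#' @param tumor a [initialize_tumor()] state.
#' @param plan a [treatment_plan()]; an empty plan simulates free growth.
#' @param ckr a [split_ckr()] set (or a bare total in `[0,1]`).
#' @param horizon_days optionally extend the simulation past the plan's
#'   horizon; it is an error to choose a horizon that truncates the plan.
#' @param keep_trajectory record the hourly volume/composition trajectory.
#' @return An object of class `sim_output`: the nine summary outputs
#'   (initial and final composition percentages and the tumor-volume
#'   reduction `dv` in percent), the final state, and optionally the
#'   trajectory data frame.
#' @examples
#' \donttest{
#' tm <- initialize_tumor(1, kinetic_params(), sim_config())
#' out <- simulate_tumor(tm, patient_plan("P2"), split_ckr(0.8))
#' out$dv
#' }
#' @export
simulate_tumor <- function(tumor, plan, ckr, horizon_days = NULL,
                           keep_trajectory = FALSE) {
  stopifnot(inherits(tumor, "tumor_state"), inherits(plan, "treatment_plan"))
  if (!inherits(ckr, "ckr_set")) ckr <- split_ckr(ckr)
  plan_horizon <- attr(plan, "horizon_days")
  horizon_days <- horizon_days %||% plan_horizon
  if (nrow(plan) && horizon_days < max(plan$day))
    stop("simulation horizon (", horizon_days, " d) truncates the plan",
         call. = FALSE)
  H <- as.integer(round(horizon_days * 24))
  op <- tumor$op
  lay <- op$layout
  A <- op$A
  cfg <- tumor$config
  state <- tumor$state
  spatial <- cfg$mode == "spatial"
  coords <- tumor$coords; dims <- tumor$dims

  events <- split(plan$drug, plan$day * 24L)  # hour -> drugs, VCR before ACT
  v0 <- sum(state) / cfg$capacity * tumor$vox_mm3 / 1000
  init_fr <- .aggregate_fractions(state, lay)
  traj <- if (keep_trajectory)
    matrix(NA_real_, nrow = H + 1L, ncol = 5,
           dimnames = list(NULL, c("hour", "volume", "prolif", "dormant",
                                   "dead"))) else NULL
  record <- function(h) {
    if (is.null(traj)) return()
    fr <- .aggregate_fractions(state, lay)
    traj[h + 1L, ] <<- c(h, sum(state) / cfg$capacity * tumor$vox_mm3 / 1000,
                         fr["prolif"], fr["dormant"], fr["dead"])
  }
  record(0L)
  n_scan <- 0L
  for (h in seq_len(H)) {
    ev <- events[[as.character(h - 1L)]]
    if (!is.null(ev)) {
      for (drug in sort(ev, decreasing = TRUE))  # VCR, then ACT
        state <- apply_drug(state, lay,
                            if (drug == "VCR") ckr$vcr else ckr$act)
    }
    state <- if (spatial) as.matrix(A %*% state) else as.numeric(A %*% state)
    if (spatial && h %% cfg$restructure_every == 0L) {
      n_scan <- n_scan + 1L
      rs <- .restructure(state, coords, dims, cfg,
                         substream_seed(cfg$seed, n_scan))
      state <- rs$state; coords <- rs$coords
    }
    record(h)
  }
  v1 <- sum(state) / cfg$capacity * tumor$vox_mm3 / 1000
  final_fr <- .aggregate_fractions(state, lay)
  out <- list(
    prolif_initial = init_fr[["prolif"]], dormant_initial = init_fr[["dormant"]],
    diff_initial = init_fr[["diff"]], dead_initial = init_fr[["dead"]],
    prolif_final = final_fr[["prolif"]], dormant_final = final_fr[["dormant"]],
    diff_final = final_fr[["diff"]], dead_final = final_fr[["dead"]],
    dv = volume_reduction(v0, v1),
    volume_initial = v0, volume_final = v1,
    ckr = ckr, horizon_days = horizon_days,
    state = state, coords = coords,
    trajectory = if (keep_trajectory) as.data.frame(traj) else NULL)
  class(out) <- "sim_output"
  out
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("Simulated tumor response over %g days:\n", x$horizon_days))
  cat(sprintf("  volume %.3f -> %.3f cm^3  (DV = %.1f%% reduction)\n",
              x$volume_initial, x$volume_final, x$dv))
  tab <- rbind(initial = c(x$prolif_initial, x$dormant_initial,
                           x$diff_initial, x$dead_initial),
               final = c(x$prolif_final, x$dormant_final, x$diff_final,
                         x$dead_final))
  colnames(tab) <- c("prolif", "dormant", "diff", "dead")
  print(round(tab, 2))
  invisible(x)
}

# ---- morphological mesh restructuring --------------------------------------

.neighbor_offsets <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                           c(0, 0, -1), c(0, 0, 1))

# One restructuring scan over the voxel mesh, raster order (x fastest).
# Underfull voxels donate their whole contents to their least-loaded
# occupied 6-neighbour and become unoccupied; overfull voxels spill their
# excess proportionally to their least-loaded unoccupied-or-underfull
# neighbour, occupying it if necessary. Ties are broken by a seeded draw.
# Total cell count is conserved exactly.
.restructure <- function(state, coords, dims, cfg, seed) {
  local_seed(seed)
  n <- ncol(state)
  voxmap <- array(0L, dims)
  voxmap[coords] <- seq_len(n)
  loads <- colSums(state)
  active <- rep(TRUE, n)
  thresh <- cfg$removal_threshold * cfg$capacity
  # room for newly occupied voxels
  grow <- list()
  neighbors <- function(xyz) {
    nb <- sweep(.neighbor_offsets, 2, xyz, `+`)
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] & nb[, 2] >= 1 &
      nb[, 2] <= dims[2] & nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb[ok, , drop = FALSE]
  }
  pick_min <- function(vals) {
    cand <- which(vals <= min(vals) + 1e-12 * max(1, min(vals)))
    if (length(cand) > 1L) cand <- cand[sample.int(length(cand), 1L)]
    cand
  }
  order_scan <- order(coords[, 3], coords[, 2], coords[, 1])
  for (j in order_scan) {
    if (!active[j]) next
    nb <- neighbors(coords[j, ])
    ids <- voxmap[nb]
    if (loads[j] < thresh) {
      occ <- ids[ids > 0L]
      occ <- occ[occ != j & active[occ]]
      if (!length(occ)) next
      tgt <- occ[pick_min(loads[occ])]
      state[, tgt] <- state[, tgt] + state[, j]
      loads[tgt] <- loads[tgt] + loads[j]
      state[, j] <- 0; loads[j] <- 0
      active[j] <- FALSE
      voxmap[coords[j, , drop = FALSE]] <- 0L
    } else if (loads[j] > cfg$capacity) {
      if (!nrow(nb)) next
      nb_loads <- ifelse(ids > 0L, loads[pmax(ids, 1L)], 0)
      under <- ids == 0L | nb_loads < cfg$capacity
      if (!any(under)) next
      pick <- which(under)[pick_min(nb_loads[under])]
      excess <- loads[j] - cfg$capacity
      moved <- state[, j] * (excess / loads[j])
      state[, j] <- state[, j] - moved
      loads[j] <- cfg$capacity
      if (ids[pick] > 0L) {
        tgt <- ids[pick]
        state[, tgt] <- state[, tgt] + moved
        loads[tgt] <- loads[tgt] + excess
      } else {
        new_xyz <- nb[pick, , drop = FALSE]
        state <- cbind(state, moved)
        coords <- rbind(coords, new_xyz)
        loads <- c(loads, excess)
        active <- c(active, TRUE)
        voxmap[new_xyz] <- ncol(state)
      }
    }
  }
  keep <- active
  list(state = state[, keep, drop = FALSE],
       coords = coords[keep, , drop = FALSE])
}

#' Morphological mesh restructuring scan
#'
#' Applies one restructuring pass to a spatial tumor state: voxels whose
#' total load has fallen below `removal_threshold * capacity` donate their
#' contents to their least-loaded occupied 6-neighbour and become
#' unoccupied (tumor shrinkage), while voxels above capacity spill their
#' excess to their least-loaded unoccupied-or-underfull 6-neighbour,
#' occupying new voxels as the tumor grows. The scan runs in raster order
#' with seeded random tie-breaks; cell counts are conserved exactly.
#'
#' @param tumor a spatial-mode [initialize_tumor()] state.
#' @param seed tie-break seed (defaults to the configuration seed).
#' @return The restructured `tumor_state`.
#' @export
restructure_mesh <- function(tumor, seed = NULL) {
  stopifnot(inherits(tumor, "tumor_state"))
  if (tumor$config$mode != "spatial")
    stop("restructuring applies to spatial mode only", call. = FALSE)
  rs <- .restructure(tumor$state, tumor$coords, tumor$dims, tumor$config,
                     seed %||% tumor$config$seed)
  tumor$state <- rs$state
  tumor$coords <- rs$coords
  tumor$n_vox <- ncol(rs$state)
  tumor
}

#' Export the occupied mesh as a label-map mask
#'
#' @param tumor a spatial-mode `tumor_state`.
#' @param spacing voxel spacing of the exported mask (mm).
#' @return A [voxel_mask()] with the currently occupied voxels set to 1.
#' @export
mesh_to_mask <- function(tumor, spacing = c(1, 1, 1)) {
  stopifnot(inherits(tumor, "tumor_state"))
  if (is.null(tumor$coords)) stop("aggregate states carry no mesh", call. = FALSE)
  occ <- array(0L, tumor$dims)
  occ[tumor$coords] <- 1L
  voxel_mask(occ, spacing = spacing)
}
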