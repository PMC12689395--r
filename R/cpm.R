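# Cellular Potts (Glazier-Graner-Hogeweg) growth of capillaries from seeded
# centerlines, with endocrine cells frozen as fixed obstacles.

.default_contact_energies <- function() {
  J <- matrix(0, 5, 5, dimnames = list(.all_types, .all_types))
  J["medium", c("alpha", "beta", "delta")] <- 80
  J[c("alpha", "beta", "delta"), "medium"] <- 80
  J["medium", "capillary"] <- 70
  J["capillary", "medium"] <- 70
  J["capillary", c("alpha", "beta", "delta")] <- 10
  J[c("alpha", "beta", "delta"), "capillary"] <- 10
  J["capillary", "capillary"] <- 1e3
  J
}

#' Cellular Potts configuration
#'
#' Contact energies, capillary volume constraint and Metropolis temperature
#' for the capillary growth stage. Defaults are the reference parameter set
#' (J capillary/medium 70, cell/medium 80, capillary/cell 10,
#' capillary/capillary 1e3; volume constraint strength 1e3; temperature 10).
#'
#' @param J Symmetric 5x5 contact-energy matrix over types
#'   `medium, alpha, beta, delta, capillary` (arbitrary energy units).
#'   Interfaces between two entities of the same frozen type carry J = 0;
#'   frozen-frozen interfaces never change, so their value only shifts the
#'   energy by a constant.
#' @param lambda_vol Capillary volume-constraint strength.
#' @param r_c Target capillary radius, µm.
#' @param temperature Metropolis temperature (> 0).
#' @param neighbor_order Neighborhood for the boundary-energy term: 1 (6
#'   face neighbors) or 2 (18 face+edge neighbors, the default); copy
#'   attempts always use the 6-neighborhood.
#' @param n_mcs Monte Carlo steps (one step = as many copy attempts as
#'   lattice sites).
#' @param volume_mode How the per-capillary target volume follows from `r_c`
#'   and the capillary length `L_c0`: `"cylinder"` (pi r^2 L, the default
#'   used by the pipeline) or `"as_printed"` (2 pi r^2 L, the reference
#'   table's literal formula). See the methods vignette for why the
#'   geometric cylinder volume is the default.
#' @param L_c0_mode Where each capillary's length `L_c0` comes from:
#'   `"axis_dim"` (the grid dimension along the path's axis -- the length
#'   "calculated from the islet size", the default) or `"path_length"`
#'   (the path's own centerline voxel count, which for 6-connected paths
#'   between random face endpoints is Manhattan-inflated well above the
#'   grid dimension).
#' @param checkpoint_every Recompute the total energy every this many MCS to
#'   audit the incremental bookkeeping.
#' @param convergence_window,convergence_tol The run is reported converged
#'   when the relative change of the energy over the last
#'   `convergence_window` MCS falls below `convergence_tol`.
#' @return An object of class `cpm_config`.
#' @export
cpm_config <- function(J = .default_contact_energies(), lambda_vol = 1e3,
                       r_c = 3.5, temperature = 10, neighbor_order = 2L,
                       n_mcs = 300L,
                       volume_mode = c("cylinder", "as_printed"),
                       L_c0_mode = c("axis_dim", "path_length"),
                       checkpoint_every = 50L, convergence_window = 50L,
                       convergence_tol = 1e-3) {
  volume_mode <- match.arg(volume_mode)
  L_c0_mode <- match.arg(L_c0_mode)
  stopifnot(temperature > 0, lambda_vol >= 0, r_c > 0,
            neighbor_order %in% 1:2, isTRUE(all.equal(J, t(J))))
  structure(list(J = J, lambda_vol = lambda_vol, r_c = r_c,
                 temperature = temperature,
                 neighbor_order = as.integer(neighbor_order),
                 n_mcs = as.integer(n_mcs), volume_mode = volume_mode,
                 L_c0_mode = L_c0_mode,
                 checkpoint_every = as.integer(checkpoint_every),
                 convergence_window = as.integer(convergence_window),
                 convergence_tol = convergence_tol),
            class = "cpm_config")
}

#' Capillary target volume
#'
#' The reference parameterization defines the capillary target volume from
#' the mean capillary radius and the initial centerline length as
#' `2 * pi * r_c^2 * L_c0` (mode `"as_printed"`); mode `"cylinder"` gives
#' the geometric cylinder volume `pi * r_c^2 * L_c0`.
#'
#' @param r_c Capillary radius, µm.
#' @param L_c0 Initial centerline length, µm.
#' @param mode `"as_printed"` (default) or `"cylinder"`.
#' @return Target volume in µm³.
#' @export
target_volume <- function(r_c, L_c0, mode = c("as_printed", "cylinder")) {
  mode <- match.arg(mode)
  stopifnot(r_c > 0, L_c0 >= 0)
  (if (mode == "as_printed") 2 else 1) * pi * r_c^2 * L_c0
}

#' Seed capillary paths into a Potts state
#'
#' Burns each selected path into the lattice as a one-voxel-wide capillary
#' entity and assigns its target volume from `cfg$r_c` and the capillary
#' length `L_c0` (by default the grid dimension along the path's axis; see
#' [cpm_config()]). Endocrine cells are frozen: they are excluded from copy
#' attempts and carry no volume constraint.
#'
#' @param grid A `voxel_grid` with rasterized cells.
#' @param paths A `capillary_paths` selection.
#' @param cfg A [cpm_config()].
#' @return A list of class `cpm_state`: `lattice`, `entity_type`,
#'   `target_vol`, `vol_lambda`, `frozen`, `volumes`, `cfg`.
#' @export
seed_capillaries <- function(grid, paths, cfg = cpm_config()) {
  stopifnot(inherits(paths, "capillary_paths") || is.list(paths))
  lattice <- array(as.integer(grid), dim = dim(grid))
  cell_types <- attr(grid, "entity_type")
  max_label <- if (length(paths))
    max(vapply(paths, `[[`, numeric(1), "label")) else length(cell_types)
  n_ent <- as.integer(max(max_label, length(cell_types)))
  entity_type <- rep("medium", n_ent)
  entity_type[seq_along(cell_types)] <- cell_types
  target_vol <- rep(-1, n_ent)
  vol_lambda <- rep(0, n_ent)
  frozen <- entity_type %in% .cell_types
  vol_mode <- if (cfg$volume_mode == "as_printed") "as_printed" else "cylinder"
  for (p in paths) {
    lab <- p$label
    entity_type[lab] <- "capillary"
    L_c0 <- if (identical(cfg$L_c0_mode, "path_length")) nrow(p$voxels)
            else dim(grid)[.axis_index(p$axis %||% "x")]
    target_vol[lab] <- target_volume(cfg$r_c, L_c0, vol_mode)
    vol_lambda[lab] <- cfg$lambda_vol
    vox <- p$voxels + 1L
    idx <- vox[, 1] + dim(grid)[1] * ((vox[, 2] - 1L) +
             dim(grid)[2] * (vox[, 3] - 1L))
    free <- lattice[idx] == 0L  # paths may cross; first path keeps the voxel
    lattice[idx[free]] <- lab
  }
  structure(list(lattice = lattice,
                 entity_type = entity_type,
                 type_code = .type_code(entity_type),
                 target_vol = target_vol,
                 vol_lambda = vol_lambda,
                 frozen = frozen,
                 volumes = cpm_entity_volumes_cpp(lattice, n_ent),
                 cfg = cfg),
            class = "cpm_state")
}

#' Total Potts energy
#'
#' Sum of contact energies over unordered neighboring site pairs of unlike
#' entities plus the volume penalty `lambda * (v - V)^2` of every
#' volume-constrained (capillary) entity. Frozen endocrine cells carry no
#' volume term; sites outside the lattice contribute no interface energy.
#'
#' @param state A `cpm_state`.
#' @param cfg A [cpm_config()]; defaults to the state's configuration.
#' @return Total energy (arbitrary energy units).
#' @export
total_energy <- function(state, cfg = state$cfg) {
  stopifnot(inherits(state, "cpm_state"))
  cpm_total_energy_cpp(state$lattice, dim(state$lattice),
                       state$type_code, state$target_vol, state$vol_lambda,
                       state$frozen, cfg$J, cfg$neighbor_order)
}

#' Attempt a single voxel-copy update
#'
#' Proposes copying the entity id at `neighbor` into `site`. Attempts
#' touching a frozen endocrine entity (as source or target) are rejected
#' without an energy evaluation; otherwise the change is accepted with
#' probability 1 when the energy change is non-positive and
#' `exp(-dH / T)` when positive (Metropolis; dH = 0 always accepted).
#'
#' @param state A `cpm_state`.
#' @param site,neighbor 0-based voxel index 3-vectors; must be lattice
#'   neighbors under the 6-connectivity.
#' @param cfg A [cpm_config()].
#' @return A list with `accepted`, `delta_H` (`NA` when rejected for a
#'   frozen entity), `frozen_rejected` and the updated `state`.
#' @export
attempt_copy <- function(state, site, neighbor, cfg = state$cfg) {
  stopifnot(inherits(state, "cpm_state"),
            sum(abs(site - neighbor)) == 1L)
  res <- cpm_attempt_copy_cpp(state$lattice, dim(state$lattice),
                              state$type_code, state$target_vol,
                              state$vol_lambda, state$frozen, cfg$J,
                              cfg$neighbor_order, cfg$temperature,
                              as.integer(site), as.integer(neighbor),
                              state$volumes)
  state$lattice <- array(res$lattice, dim = dim(state$lattice))
  state$volumes <- res$volumes
  list(accepted = res$accepted, delta_H = res$delta_H,
       frozen_rejected = res$frozen_rejected, state = state)
}

#' Evolve capillaries by Metropolis Monte Carlo
#'
#' Runs `cfg$n_mcs` Monte Carlo steps over the seeded lattice. Capillary
#' voxels rearrange to grow toward their target volume and adapt their shape
#' in the extracellular space; endocrine cell voxels never change. The
#' incremental energy bookkeeping is audited against a full recomputation at
#' checkpoints (must agree to 1e-6 relative).
#'
#' @param x A `cpm_state` from [seed_capillaries()], or a `voxel_grid`
#'   (then `paths` must be given).
#' @param cfg A [cpm_config()].
#' @param seed Optional integer seed (same seed, identical final lattice).
#' @param paths Capillary paths when `x` is a `voxel_grid`.
#' @return A `voxel_grid` with grown capillary labels; attribute
#'   `cpm_diagnostics` holds the energy trace, checkpoint audits, acceptance
#'   rate, final volumes and a convergence report.
#' @export
evolve_capillaries <- function(x, cfg = cpm_config(), seed = NULL,
                               paths = NULL) {
  if (inherits(x, "voxel_grid")) {
    if (is.null(paths)) stop("paths are required when passing a voxel_grid")
    state <- seed_capillaries(x, paths, cfg)
  } else state <- x
  stopifnot(inherits(state, "cpm_state"))
  if (!is.null(seed)) set.seed(seed)
  if (cfg$n_mcs == 0L) {
    res <- list(lattice = state$lattice, volumes = state$volumes,
                H_trace = numeric(0), H_incremental = numeric(0),
                H_recomputed = numeric(0), acceptance_rate = NA_real_)
  } else {
    res <- cpm_evolve_cpp(state$lattice, dim(state$lattice),
                          state$type_code, state$target_vol,
                          state$vol_lambda, state$frozen, cfg$J,
                          cfg$neighbor_order, cfg$temperature, cfg$n_mcs,
                          cfg$checkpoint_every)
  }
  if (length(res$H_recomputed)) {
    rel <- abs(res$H_incremental - res$H_recomputed) /
      pmax(abs(res$H_recomputed), 1)
    if (max(rel) > 1e-6)
      warning("incremental energy bookkeeping deviates from recomputation ",
              "(max relative ", format(max(rel)), ")")
  }
  H <- res$H_trace
  converged <- if (length(H) > cfg$convergence_window) {
    w <- cfg$convergence_window
    span <- abs(H[length(H)] - H[length(H) - w])
    span / max(abs(H[length(H)]), 1) < cfg$convergence_tol
  } else NA
  out <- array(res$lattice, dim = dim(state$lattice))
  structure(out, class = "voxel_grid",
            entity_type = state$entity_type,
            frozen = state$frozen,
            n_cells = sum(state$entity_type %in% .cell_types),
            cpm_diagnostics = list(
              H_trace = H,
              H_incremental = res$H_incremental,
              H_recomputed = res$H_recomputed,
              acceptance_rate = res$acceptance_rate,
              volumes = res$volumes,
              target_vol = state$target_vol,
              converged = converged))
}
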