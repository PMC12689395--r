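# Steady-state oxygen diffusion-consumption on the labeled voxel grid.
# Units: µm / ms / µM internally; PO2 in mmHg at the module boundary.

#' Oxygen transport parameters
#'
#' @param glucose `"G6"` (6 mM) or `"G20"` (20 mM); selects the default
#'   consumption-rate table.
#' @param D Oxygen diffusion coefficient in islet tissue, µm²/ms
#'   (2.1 µm²/ms = 2.1e-9 m²/s).
#' @param capillary_concentration Concentration clamped at capillary voxels,
#'   µM (7.02 µM = 30 mmHg at the default solubility).
#' @param solubility Oxygen solubility, mol/(mmHg·m³).
#' @param rates Named consumption rates `c(alpha=, beta=, delta=)` in µM/ms
#'   per voxel; defaults to the published table for `glucose`.
#' @param consumption_order `"zeroth"` (constant uptake while oxygen is
#'   present, the default: the printed rates are µM/ms) or `"first"`
#'   (uptake proportional to the local concentration, for sensitivity
#'   analysis; rates then act as 1/ms constants).
#' @param tol Convergence threshold on the discrete steady-state residual,
#'   µM/ms.
#' @param max_iter Maximum relaxation sweeps.
#' @param omega Over-relaxation factor; default near-optimal for the grid.
#' @return An object of class `oxygen_params`.
#' @export
oxygen_params <- function(glucose = c("G6", "G20"), D = 2.1,
                          capillary_concentration = 7.02,
                          solubility = 2.34e-4, rates = NULL,
                          consumption_order = c("zeroth", "first"),
                          tol = 1e-6, max_iter = 20000L, omega = NULL) {
  glucose <- match.arg(glucose)
  consumption_order <- match.arg(consumption_order)
  if (is.null(rates)) rates <- .oxygen_rates[[glucose]]
  stopifnot(all(rates >= 0), D > 0, capillary_concentration >= 0, tol > 0)
  structure(list(glucose = glucose, D = D,
                 capillary_concentration = capillary_concentration,
                 solubility = solubility, rates = rates,
                 consumption_order = consumption_order,
                 tol = tol, max_iter = as.integer(max_iter), omega = omega),
            class = "oxygen_params")
}

#' Convert oxygen partial pressure to concentration
#'
#' `concentration [µM] = p [mmHg] * solubility [mol/(mmHg·m³)] * 1e3`
#' (1 mmol/m³ = 1 µM); 30 mmHg gives 7.02 µM at the default solubility.
#'
#' @param p Partial pressure, mmHg (>= 0).
#' @param solubility Solubility, mol/(mmHg·m³).
#' @return Concentration, µM.
#' @export
po2_to_concentration <- function(p, solubility = 2.34e-4) {
  stopifnot(all(p >= 0))
  p * solubility * 1e3
}

#' Convert oxygen concentration to partial pressure
#'
#' @param c_um Concentration, µM (>= 0).
#' @param solubility Solubility, mol/(mmHg·m³).
#' @return Partial pressure, mmHg.
#' @export
concentration_to_po2 <- function(c_um, solubility = 2.34e-4) {
  stopifnot(all(c_um >= 0))
  c_um / (solubility * 1e3)
}

#' Look up an oxygen consumption rate
#'
#' @param cell_type `"alpha"`, `"beta"` or `"delta"`.
#' @param glucose `"G6"` or `"G20"`.
#' @return Consumption rate, µM/ms per voxel.
#' @export
consumption_lookup <- function(cell_type, glucose = c("G6", "G20")) {
  glucose <- match.arg(glucose)
  if (!all(cell_type %in% .cell_types))
    stop("unknown cell type: ", paste(setdiff(cell_type, .cell_types),
                                      collapse = ", "))
  unname(.oxygen_rates[[glucose]][cell_type])
}

# per-voxel consumption-rate field from the labeled grid
.lambda_field <- function(grid, params) {
  et <- attr(grid, "entity_type")
  rate_of_id <- rep(0, length(et))
  for (ct in .cell_types) {
    r <- params$rates[[ct]]
    if (!is.null(r)) rate_of_id[et == ct] <- r
  }
  lam <- array(0, dim = dim(grid))
  occ <- grid > 0L
  lam[occ] <- rate_of_id[grid[occ]]
  lam
}

#' Relax the oxygen field to steady state
#'
#' Solves the discrete steady-state diffusion-consumption balance
#' `D * Laplacian(C) = consumption` on the 1-µm lattice with capillary
#' voxels clamped at the capillary concentration (Dirichlet sources),
#' zero-flux domain boundaries and, by default, zeroth-order consumption in
#' cell voxels that never drives the concentration below zero. The solver is
#' a projected red-black successive over-relaxation; convergence is declared
#' when the largest discrete residual falls below `params$tol` (µM/ms).
#'
#' @param grid A `voxel_grid` whose entity table identifies capillary and
#'   cell labels.
#' @param params An [oxygen_params()].
#' @param init Optional concentration array to warm-start from.
#' @return An object of class `oxygen_field`: `concentration` (µM array),
#'   `converged`, `iterations`, `max_residual` and the `params` used.
#'   With no capillary voxel the zero field is returned with a warning.
#' @export
relax_to_steady_state <- function(grid, params = oxygen_params(),
                                  init = NULL) {
  et <- attr(grid, "entity_type")
  cap_ids <- which(et == "capillary")
  clamp <- array(grid %in% cap_ids, dim = dim(grid))
  if (!any(clamp)) {
    warning("grid contains no capillary voxel; returning the zero field")
    return(structure(list(concentration = array(0, dim = dim(grid)),
                          converged = TRUE, iterations = 0L,
                          max_residual = 0, params = params),
                     class = "oxygen_field"))
  }
  lam <- .lambda_field(grid, params)
  omega <- params$omega
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / (2 * max(dim(grid)))))
  res <- oxygen_sor_cpp(as.logical(clamp), as.numeric(lam),
                        as.integer(dim(grid)),
                        params$capillary_concentration, params$D,
                        params$tol, params$max_iter, omega,
                        params$consumption_order == "first",
                        if (is.null(init)) numeric(0) else as.numeric(init))
  if (!res$converged)
    warning("oxygen solver did not reach tol within ", params$max_iter,
            " sweeps (max residual ", format(res$max_residual), ")")
  structure(list(concentration = array(res$concentration, dim = dim(grid)),
                 converged = res$converged, iterations = res$iterations,
                 max_residual = res$max_residual, params = params),
            class = "oxygen_field")
}

#' @export
print.oxygen_field <- function(x, ...) {
  cat(sprintf("Oxygen field: %s after %d sweeps (max residual %.2e uM/ms)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$max_residual))
  cat(sprintf("  concentration range %.3f-%.3f uM (%.2f-%.2f mmHg)\n",
              min(x$concentration), max(x$concentration),
              concentration_to_po2(min(x$concentration), x$params$solubility),
              concentration_to_po2(max(x$concentration), x$params$solubility)))
  invisible(x)
}
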