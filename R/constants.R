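# Shared constants: cell-type codes, published reference tables.

# Integer type codes used on the lattice and in the compiled kernels.
.all_types <- c("medium", "alpha", "beta", "delta", "capillary")
.cell_types <- c("alpha", "beta", "delta")

.type_code <- function(type) {
  code <- match(type, .all_types) - 1L
  if (anyNA(code)) stop("unknown type token(s): ",
                        paste(unique(type[is.na(code)]), collapse = ", "))
  code
}

# Reference human islet environments: grid dimensions (um) and cell counts
# per type for the six reconstructed human islets. Used as the size reference
# for capillary-count scaling and as the fitted range of the bundled
# viability parameters.
.human_islet_envs <- data.frame(
  islet = 1:6,
  x = c(227L, 309L, 340L, 359L, 282L, 313L),
  y = c(208L, 364L, 388L, 389L, 263L, 307L),
  z = c(164L, 196L, 225L, 237L, 219L, 230L),
  n_cells = c(583L, 2252L, 3323L, 3516L, 2084L, 2841L),
  n_alpha = c(148L, 427L, 1082L, 961L, 642L, 830L),
  n_beta = c(316L, 1461L, 1523L, 2209L, 1168L, 1355L),
  n_delta = c(119L, 364L, 617L, 346L, 274L, 656L)
)

# Oxygen consumption rates per voxel (uM/ms) by cell type and glucose level.
.oxygen_rates <- list(
  G6 = c(alpha = 0.1313, beta = 0.1810, delta = 0.1170),
  G20 = c(alpha = 0.2040, beta = 0.4850, delta = 0.2450)
)

# Published sigmoidal viability parameters (human islets, whole-islet fits).
.published_viability <- list(
  human = list(
    G6 = list(v_min = 0.13, v_max = 1.00, c50 = 6.82, n50 = 669.16,
              n_c = 1.92, n_n = -1.70, r_squared = 0.96),
    G20 = list(v_min = 0.12, v_max = 1.00, c50 = 14.23, n50 = 1271.88,
               n_c = 1.77, n_n = -1.60, r_squared = 0.96)
  )
)

# Default endocrine composition (fractions alpha/beta/delta).
.default_composition <- list(
  human = c(alpha = 0.29, beta = 0.53, delta = 0.18),
  mouse = c(alpha = 0.25, beta = 0.75, delta = 0.00)
)

#' Reference table of human islet environments
#'
#' Grid dimensions (µm, including the 30-µm buffer) and endocrine cell counts
#' of the six reconstructed human islets used as the size reference throughout
#' the package (capillary-count scaling, extrapolation ranges).
#'
#' @return A data frame with columns `islet`, `x`, `y`, `z`, `n_cells`,
#'   `n_alpha`, `n_beta`, `n_delta`.
#' @export
human_islet_reference <- function() .human_islet_envs
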