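# Islet architectures: typed spheres in micrometre space, overlap-minimizing
# packing, and rasterization onto the 1-um voxel lattice.

#' Radii distribution for endocrine cells
#'
#' Describes how cell radii are drawn when they are not supplied with the
#' cell table. The default is a truncated normal (mean 5.5 µm, sd 0.8 µm,
#' bounds 3.5–8 µm), a stand-in calibrated so that typical cell counts fit
#' their printed environments; an `empirical` family resamples a supplied
#' vector of radii.
#'
#' @param family `"truncated_normal"` or `"empirical"`.
#' @param mean,sd Mean and standard deviation in µm (truncated normal).
#' @param lower,upper Truncation bounds in µm; sampling always returns radii
#'   in `[lower, upper]`.
#' @param values Numeric vector of radii to resample (empirical family).
#' @return An object of class `radii_distribution`.
#' @export
radii_distribution <- function(family = c("truncated_normal", "empirical"),
                               mean = 5.5, sd = 0.8, lower = 3.5, upper = 8,
                               values = NULL) {
  family <- match.arg(family)
  if (family == "empirical") {
    if (is.null(values) || !length(values) || any(values <= 0))
      stop("empirical radii distribution needs a vector of positive radii")
    lower <- min(values); upper <- max(values)
  }
  if (lower <= 0) stop("lower radius bound must be positive")
  if (upper < lower) stop("upper bound must be >= lower bound")
  structure(list(family = family, mean = mean, sd = sd,
                 lower = lower, upper = upper, values = values),
            class = "radii_distribution")
}

#' Sample cell radii
#'
#' @param n Number of radii to draw.
#' @param dist A [radii_distribution()].
#' @return Numeric vector of `n` radii (µm), all within the distribution
#'   bounds.
#' @export
sample_radii <- function(n, dist = radii_distribution()) {
  stopifnot(inherits(dist, "radii_distribution"), n >= 0)
  if (n == 0) return(numeric(0))
  if (dist$family == "empirical")
    return(sample(dist$values, n, replace = TRUE))
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * (n - length(out)) + 8L, dist$mean, dist$sd)
    out <- c(out, x[x >= dist$lower & x <= dist$upper])
  }
  out[seq_len(n)]
}

#' Construct an islet architecture
#'
#' Normalizes coordinates so every cell sphere lies inside the environment
#' box with a `buffer`-wide clear margin on each side, and computes the
#' environment dimensions (bounding box of the spheres plus twice the buffer,
#' rounded up to integer µm).
#'
#' @param cells Data frame with columns `x`, `y`, `z`, `type`
#'   (`alpha`/`beta`/`delta`) and `radius` (µm); an optional `cell_id`
#'   column is preserved.
#' @param species `"human"` or `"mouse"`. Mouse architectures must not
#'   contain delta cells.
#' @param buffer Clear margin between the islet and the grid faces, µm.
#' @return An object of class `islet_architecture`: a list with `cells`
#'   (data frame `cell_id`, `type`, `x`, `y`, `z`, `radius`), `env_dims`
#'   (integer 3-vector, µm), `buffer` and `species`.
#' @export
islet_architecture <- function(cells, species = c("human", "mouse"),
                               buffer = 30) {
  species <- match.arg(species)
  stopifnot(is.data.frame(cells))
  if (!nrow(cells)) stop("architecture must contain at least one cell")
  need <- c("x", "y", "z", "type", "radius")
  if (!all(need %in% names(cells)))
    stop("cell table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!cells$type %in% .cell_types)
  if (length(bad))
    stop("unknown cell type token(s) in row(s) ",
         paste(head(bad, 5L), collapse = ", "), ": ",
         paste(unique(cells$type[bad]), collapse = ", "))
  if (species == "mouse" && any(cells$type == "delta"))
    stop("mouse architectures must not contain delta cells")
  if (any(!is.finite(as.matrix(cells[, c("x", "y", "z")]))))
    stop("cell coordinates must be finite")
  if (any(!is.finite(cells$radius)) || any(cells$radius <= 0))
    stop("cell radii must be positive")
  if (is.null(cells$cell_id)) cells$cell_id <- seq_len(nrow(cells))
  if (anyDuplicated(cells$cell_id)) stop("cell_id values must be unique")
  cells <- cells[, c("cell_id", "type", "x", "y", "z", "radius")]
  for (ax in c("x", "y", "z"))
    cells[[ax]] <- cells[[ax]] - min(cells[[ax]] - cells$radius) + buffer
  env_dims <- vapply(c("x", "y", "z"), function(ax)
    as.integer(ceiling(max(cells[[ax]] + cells$radius) + buffer)),
    integer(1), USE.NAMES = FALSE)
  structure(list(cells = cells, env_dims = env_dims, buffer = buffer,
                 species = species),
            class = "islet_architecture")
}

#' @export
print.islet_architecture <- function(x, ...) {
  cnt <- table(factor(x$cells$type, levels = .cell_types))
  cat(sprintf("Islet architecture (%s): %d cells (alpha %d, beta %d, delta %d)\n",
              x$species, nrow(x$cells), cnt["alpha"], cnt["beta"], cnt["delta"]))
  cat(sprintf("Environment: %d x %d x %d um (buffer %g um), overlaps: %d\n",
              x$env_dims[1], x$env_dims[2], x$env_dims[3], x$buffer,
              count_overlaps(x)))
  invisible(x)
}

#' Load an islet cell table
#'
#' Reads a delimited text table (comma or tab separated, header required)
#' with columns `x`, `y`, `z`, `type` and optionally `radius` (all µm).
#' Missing radii are drawn from `radii`.
#'
#' @param path Path to the cell table.
#' @param species `"human"` or `"mouse"`.
#' @param radii A [radii_distribution()] used for missing radii.
#' @param buffer Environment margin, µm.
#' @param seed Optional integer seed for radius sampling.
#' @return An [islet_architecture()].
#' @export
load_cells <- function(path, species = c("human", "mouse"),
                       radii = radii_distribution(), buffer = 30,
                       seed = NULL) {
  species <- match.arg(species)
  header <- readLines(path, n = 1L)
  if (!length(header)) stop("empty cell table: ", path)
  tab <- if (grepl(",", header)) read.csv(path, stringsAsFactors = FALSE)
         else read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(tab)) stop("empty cell table: ", path)
  if (is.null(tab$radius) || all(is.na(tab$radius))) tab$radius <- NA_real_
  miss <- is.na(tab$radius)
  if (any(miss)) {
    if (!is.null(seed)) set.seed(seed)
    tab$radius[miss] <- sample_radii(sum(miss), radii)
  }
  islet_architecture(tab, species = species, buffer = buffer)
}

#' Write an islet cell table
#'
#' @param arch An [islet_architecture()].
#' @param path Output path (CSV with header `x,y,z,type,radius`).
#' @return `path`, invisibly.
#' @export
write_cells <- function(arch, path) {
  stopifnot(inherits(arch, "islet_architecture"))
  out <- arch$cells[, c("x", "y", "z", "type", "radius")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Count overlapping cell pairs
#'
#' Number of unordered pairs whose center distance is strictly smaller than
#' the sum of their radii; tangent spheres do not overlap.
#'
#' @param arch An [islet_architecture()].
#' @return Integer overlap count.
#' @export
count_overlaps <- function(arch) {
  stopifnot(inherits(arch, "islet_architecture"))
  n <- nrow(arch$cells)
  if (n < 2L) return(0L)
  d <- as.matrix(stats::dist(as.matrix(arch$cells[, c("x", "y", "z")])))
  rsum <- outer(arch$cells$radius, arch$cells$radius, `+`)
  as.integer(sum(d < rsum & upper.tri(d)))
}

# Indices of cells overlapping cell i, given centers/radii matrices.
.cell_overlap_set <- function(centers, radius, i) {
  d2 <- colSums((t(centers) - centers[i, ])^2)
  d2[i] <- Inf
  which(d2 < (radius + radius[i])^2)
}

#' Overlap-minimizing packing
#'
#' Iteratively perturbs randomly chosen cells (new center within ±r of the
#' old one, radius optionally re-drawn) to reduce the number of overlapping
#' pairs. Moves that reduce the overlap count are always accepted; other
#' moves are accepted with a geometrically decaying probability
#' `p_k = p0 * gamma^k` to escape local minima. The best configuration seen
#' is returned, so the result never has more overlaps than the input.
#'
#' @param arch An [islet_architecture()].
#' @param radii Optional [radii_distribution()]; when supplied, perturbed
#'   cells get a re-drawn radius.
#' @param max_iter Maximum number of single-cell perturbations.
#' @param seed Optional integer seed.
#' @param p0 Initial uphill acceptance probability.
#' @param gamma Decay factor per iteration; the default reaches 1e-3 at
#'   `max_iter / 2`.
#' @param bound Optional confinement: a list with `center` (3-vector) and
#'   `radius`; proposals placing a sphere outside the ball are rejected.
#'   Used by [synthesize_islet()] to keep the islet at its target diameter.
#' @return An [islet_architecture()] with attributes `trajectory` (best
#'   overlap count per iteration), `iterations` and `converged` (`TRUE` if
#'   zero overlaps were reached).
#' @export
optimize_packing <- function(arch, radii = NULL, max_iter = 10000L,
                             seed = NULL, p0 = 0.5, gamma = NULL,
                             bound = NULL) {
  stopifnot(inherits(arch, "islet_architecture"), max_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gamma)) gamma <- (1e-3 / p0)^(2 / max_iter)
  centers <- as.matrix(arch$cells[, c("x", "y", "z")])
  radius <- arch$cells$radius
  n <- nrow(centers)
  per_cell <- integer(n)
  for (i in seq_len(n))
    per_cell[i] <- length(.cell_overlap_set(centers, radius, i))
  total <- sum(per_cell) / 2
  best <- total
  best_centers <- centers
  best_radius <- radius
  traj <- numeric(max_iter)
  iter <- 0L
  p_accept <- p0
  while (iter < max_iter && best > 0) {
    iter <- iter + 1L
    # random cell, biased toward cells currently involved in an overlap so
    # late-stage convergence does not stall on unlucky draws
    ov <- which(per_cell > 0L)
    i <- if (length(ov) && runif(1) < 0.9) ov[sample.int(length(ov), 1L)]
         else sample.int(n, 1L)
    old_c <- centers[i, ]; old_r <- radius[i]
    old_set <- .cell_overlap_set(centers, radius, i)
    centers[i, ] <- old_c + runif(3, -old_r, old_r)
    if (!is.null(radii)) radius[i] <- sample_radii(1L, radii)
    reject_hard <- !is.null(bound) &&
      sqrt(sum((centers[i, ] - bound$center)^2)) > bound$radius - radius[i]
    if (!reject_hard) {
      new_set <- .cell_overlap_set(centers, radius, i)
      new_total <- total + (length(new_set) - length(old_set))
      accept <- new_total < total || runif(1) < p_accept
    } else accept <- FALSE
    if (accept) {
      total <- new_total
      per_cell[old_set] <- per_cell[old_set] - 1L
      per_cell[new_set] <- per_cell[new_set] + 1L
      per_cell[i] <- length(new_set)
      if (total < best) {
        best <- total
        best_centers <- centers
        best_radius <- radius
      }
    } else {
      centers[i, ] <- old_c
      radius[i] <- old_r
    }
    p_accept <- p_accept * gamma
    traj[iter] <- best
  }
  cells <- arch$cells
  cells$x <- best_centers[, 1]; cells$y <- best_centers[, 2]
  cells$z <- best_centers[, 3]; cells$radius <- best_radius
  out <- islet_architecture(cells, species = arch$species,
                            buffer = arch$buffer)
  attr(out, "trajectory") <- traj[seq_len(iter)]
  attr(out, "iterations") <- iter
  attr(out, "converged") <- best == 0
  out
}

#' Synthesize an islet architecture
#'
#' Places `n_cells` spheres uniformly at random in a ball and relaxes them
#' with [optimize_packing()] until overlap-free. Cell types are drawn from
#' `composition` (defaults: human 0.29/0.53/0.18 alpha/beta/delta, mouse
#' 0.25/0.75/0).
#'
#' @param n_cells Number of cells (>= 1).
#' @param species `"human"` or `"mouse"`.
#' @param composition Named fractions (`alpha`, `beta`, `delta`) summing
#'   to 1.
#' @param radii A [radii_distribution()].
#' @param target_diameter Islet diameter, µm; default gives a sphere packing
#'   fraction of 0.40 at the expected cell radius.
#' @param seed Optional integer seed (same seed, same architecture).
#' @param buffer Environment margin, µm.
#' @param max_iter Packing iterations per relaxation round (default
#'   `400 * n_cells`, up to three rounds).
#' @return An overlap-free [islet_architecture()].
#' @export
synthesize_islet <- function(n_cells, species = c("human", "mouse"),
                             composition = NULL,
                             radii = radii_distribution(),
                             target_diameter = NULL, seed = NULL,
                             buffer = 30, max_iter = NULL) {
  species <- match.arg(species)
  stopifnot(n_cells >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(composition)) composition <- .default_composition[[species]]
  composition <- composition[composition > 0]
  if (abs(sum(composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  if (!all(names(composition) %in% .cell_types))
    stop("composition names must be among: ",
         paste(.cell_types, collapse = ", "))
  if (species == "mouse" && isTRUE(composition["delta"] > 0))
    stop("mouse islets have no delta cells")
  type <- sample(names(composition), n_cells, replace = TRUE,
                 prob = composition)
  radius <- sample_radii(n_cells, radii)
  if (is.null(target_diameter)) {
    # default cell volume fraction 0.55: islets are dense epithelial tissue
    # with narrow interstitial clefts, not loose sphere clouds
    exp_r3 <- if (radii$family == "empirical") mean(radii$values^3)
              else mean(sample_radii(4096L, radii)^3)
    target_diameter <- 2 * (n_cells * exp_r3 / 0.55)^(1 / 3)
  }
  R <- target_diameter / 2
  if (sum(4 / 3 * pi * radius^3) > 0.64 * 4 / 3 * pi * R^3)
    stop("infeasible density: total sphere volume exceeds 64% of the target ball")
  if (is.null(max_iter)) max_iter <- 1200L * n_cells
  # uniform placement inside the ball, spheres kept inside the islet
  # surface; an unlucky placement is re-drawn (RNG stream continues, so
  # the whole construction stays deterministic under the seed)
  for (attempt in 1:3) {
    u <- matrix(rnorm(3 * n_cells), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    rad_pos <- pmax(R - radius, 0) * runif(n_cells)^(1 / 3)
    centers <- u * rad_pos
    cells <- data.frame(x = centers[, 1], y = centers[, 2], z = centers[, 3],
                        type = type, radius = radius,
                        stringsAsFactors = FALSE)
    arch <- islet_architecture(cells, species = species, buffer = buffer)
    # confinement ball in the architecture's normalized coordinates
    bound <- list(center = colMeans(as.matrix(arch$cells[, c("x", "y", "z")])),
                  radius = R + 2)
    for (round in 1:3) {
      if (count_overlaps(arch) == 0) break
      arch <- optimize_packing(arch, radii = radii, max_iter = max_iter,
                               bound = bound)
      bound$center <- colMeans(as.matrix(arch$cells[, c("x", "y", "z")]))
    }
    if (count_overlaps(arch) == 0) return(arch)
  }
  stop("packing did not reach zero overlaps; lower the density or raise max_iter")
}

#' Rasterize an architecture onto the voxel lattice
#'
#' Builds the integer label grid of shape `env_dims` (1-µm cubic voxels).
#' A voxel belongs to a cell when its center `(i + 0.5, j + 0.5, k + 0.5)`
#' lies strictly inside the cell sphere; all other voxels are medium (0).
#' Endocrine cells are flagged immobile (fixed obstacles) for the downstream
#' capillary stages.
#'
#' @param arch An overlap-free [islet_architecture()].
#' @return A `voxel_grid`: integer 3-D array with attributes
#'   `entity_type` (type name per entity id), `frozen` (logical per id) and
#'   `n_cells`.
#' @export
rasterize <- function(arch) {
  stopifnot(inherits(arch, "islet_architecture"))
  if (count_overlaps(arch) > 0)
    stop("architecture must be overlap-free before rasterization")
  dims <- arch$env_dims
  grid <- array(0L, dim = dims)
  cells <- arch$cells
  for (row in seq_len(nrow(cells))) {
    cx <- cells$x[row]; cy <- cells$y[row]; cz <- cells$z[row]
    r <- cells$radius[row]
    ir <- max(1L, floor(cx - r) + 1L):min(dims[1], ceiling(cx + r))
    jr <- max(1L, floor(cy - r) + 1L):min(dims[2], ceiling(cy + r))
    kr <- max(1L, floor(cz - r) + 1L):min(dims[3], ceiling(cz + r))
    dx2 <- (ir - 0.5 - cx)^2
    dy2 <- (jr - 0.5 - cy)^2
    dz2 <- (kr - 0.5 - cz)^2
    inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) < r^2
    sub <- grid[ir, jr, kr, drop = FALSE]
    if (any(sub[inside] != 0L))
      stop("internal consistency error: voxel claimed by two cells")
    sub[inside] <- cells$cell_id[row]
    grid[ir, jr, kr] <- sub
  }
  n <- max(cells$cell_id)
  entity_type <- rep("medium", n)
  entity_type[cells$cell_id] <- cells$type
  structure(grid, class = "voxel_grid",
            entity_type = entity_type,
            frozen = entity_type %in% .cell_types,
            n_cells = nrow(cells),
            species = arch$species)
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  et <- attr(x, "entity_type")
  cat(sprintf("Voxel grid %d x %d x %d (1-um voxels)\n", d[1], d[2], d[3]))
  cat(sprintf("  entities: %d cells, %d capillaries; occupied voxels: %.1f%%\n",
              sum(et %in% .cell_types), sum(et == "capillary"),
              100 * mean(x != 0L)))
  invisible(x)
}

#' Architecture summary
#'
#' @param arch An [islet_architecture()].
#' @return A list (suitable for JSON export) with per-type counts,
#'   environment dimensions, buffer and overlap count.
#' @export
architecture_summary <- function(arch) {
  stopifnot(inherits(arch, "islet_architecture"))
  cnt <- table(factor(arch$cells$type, levels = .cell_types))
  list(species = arch$species,
       n_cells = nrow(arch$cells),
       n_alpha = as.integer(cnt["alpha"]),
       n_beta = as.integer(cnt["beta"]),
       n_delta = as.integer(cnt["delta"]),
       env_dims = as.integer(arch$env_dims),
       buffer = arch$buffer,
       overlaps = count_overlaps(arch))
}
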