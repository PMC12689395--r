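# Initial capillary centerlines: greedy best-first search between random
# endpoints on opposite grid faces, avoiding endocrine-cell voxels.

.axis_index <- function(axis) match(axis, c("x", "y", "z"))

# logical mask of voxels impassable to capillary paths (endocrine cells)
.blocked_mask <- function(grid) {
  et <- attr(grid, "entity_type")
  blocked_ids <- which(et %in% .cell_types)
  array(grid %in% blocked_ids, dim = dim(grid))
}

#' Sample a start/goal endpoint pair on opposite grid faces
#'
#' The start is drawn uniformly over the medium voxels of the axis-minimum
#' face, the goal uniformly over the medium voxels of the axis-maximum face.
#' Voxel indices are 0-based; a voxel `(i, j, k)` spans `[i, i+1)` µm per
#' axis.
#'
#' @param grid A `voxel_grid`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return A list with integer 3-vectors `start` and `goal` (0-based).
#' @export
sample_endpoint_pair <- function(grid, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  ax <- .axis_index(axis)
  dims <- dim(grid)
  blocked <- .blocked_mask(grid)
  pick <- function(face_idx) {
    idx <- switch(ax,
                  which(!blocked[face_idx, , ], arr.ind = TRUE),
                  which(!blocked[, face_idx, ], arr.ind = TRUE),
                  which(!blocked[, , face_idx], arr.ind = TRUE))
    if (!nrow(idx)) stop("grid face has no medium voxel on axis ", axis)
    sel <- idx[sample.int(nrow(idx), 1L), ]
    out <- integer(3)
    out[ax] <- face_idx - 1L
    out[setdiff(1:3, ax)] <- as.integer(sel) - 1L
    out
  }
  list(start = pick(1L), goal = pick(dims[ax]))
}

#' Greedy best-first path between two voxels
#'
#' Expands the frontier voxel closest (Euclidean) to the goal, stepping over
#' the 6-connected lattice and skipping endocrine-cell voxels. Ties are
#' broken first-in-first-out with neighbors generated in the fixed order
#' +x, -x, +y, -y, +z, -z, so paths are reproducible.
#'
#' @param grid A `voxel_grid`.
#' @param start,goal Integer 3-vectors, 0-based voxel indices; must be
#'   medium voxels.
#' @param connectivity Lattice connectivity for path steps: 6 (face
#'   neighbors, the default) or 26 (diagonal moves allowed; paths then
#'   track the Euclidean rather than the Manhattan geometry).
#' @return A list of class `capillary_path` with `voxels` (n x 3 integer
#'   matrix, 0-based, start to goal), `start`, `goal` and `success`; on an
#'   exhausted frontier, `success` is `FALSE` and `voxels` is empty.
#' @export
best_first_path <- function(grid, start, goal, connectivity = 6L) {
  dims <- dim(grid)
  start <- as.integer(start); goal <- as.integer(goal)
  stopifnot(length(start) == 3L, length(goal) == 3L,
            all(start >= 0L), all(goal >= 0L),
            all(start < dims), all(goal < dims))
  blocked <- .blocked_mask(grid)
  if (blocked[matrix(start + 1L, 1L)] || blocked[matrix(goal + 1L, 1L)])
    stop("start and goal must be medium voxels, not cell voxels")
  stopifnot(connectivity %in% c(6L, 26L))
  res <- bfs_best_first_cpp(as.logical(blocked), as.integer(dims),
                            start, goal, as.integer(connectivity))
  structure(list(voxels = res$voxels, start = start, goal = goal,
                 success = isTRUE(res$success),
                 n_expanded = res$n_expanded,
                 connectivity = as.integer(connectivity)),
            class = "capillary_path")
}

#' Generate the initial capillary path pool
#'
#' Draws `n_per_axis` collision-free face-to-face paths per axis (3 *
#' `n_per_axis` in total), resampling endpoints on pathfinding failure up to
#' `retry_cap` times per path. Each path receives a unique capillary entity
#' label starting above the largest cell id.
#'
#' @param grid A `voxel_grid` with rasterized cells.
#' @param n_per_axis Paths per axis (default 100, i.e. 300 in total).
#' @param seed Optional integer seed.
#' @param retry_cap Endpoint resamples allowed per requested path.
#' @param connectivity Path-step connectivity, 6 or 26 (see
#'   [best_first_path()]).
#' @return A list of class `capillary_paths`; each element has `path_id`,
#'   `label` (lattice entity id), `axis`, `start`, `goal` and `voxels`.
#' @export
generate_initial_capillaries <- function(grid, n_per_axis = 100L,
                                         seed = NULL, retry_cap = 50L,
                                         connectivity = 6L) {
  stopifnot(n_per_axis >= 1)
  if (!is.null(seed)) set.seed(seed)
  base_label <- length(attr(grid, "entity_type"))
  paths <- vector("list", 3L * n_per_axis)
  pid <- 0L
  for (axis in c("x", "y", "z")) {
    for (p in seq_len(n_per_axis)) {
      path <- NULL
      for (try in seq_len(retry_cap)) {
        ends <- sample_endpoint_pair(grid, axis)
        cand <- best_first_path(grid, ends$start, ends$goal, connectivity)
        if (cand$success) { path <- cand; break }
      }
      if (is.null(path))
        stop("could not find a collision-free path on axis ", axis,
             " within ", retry_cap, " endpoint resamples")
      pid <- pid + 1L
      path$path_id <- pid
      path$label <- base_label + pid
      path$axis <- axis
      paths[[pid]] <- path
    }
  }
  structure(paths, class = "capillary_paths", grid_dims = dim(grid))
}

#' @export
print.capillary_paths <- function(x, ...) {
  ax <- vapply(x, `[[`, character(1), "axis")
  len <- vapply(x, function(p) nrow(p$voxels), integer(1))
  cat(sprintf("Capillary path pool: %d paths (x %d, y %d, z %d), mean length %.1f voxels\n",
              length(x), sum(ax == "x"), sum(ax == "y"), sum(ax == "z"),
              mean(len)))
  invisible(x)
}

#' Select a random capillary subset
#'
#' Uniform sample without replacement from a path pool; deterministic under
#' `seed`.
#'
#' @param paths A `capillary_paths` pool.
#' @param n Number of paths to keep (`0 <= n <= length(paths)`).
#' @param seed Optional integer seed.
#' @return A `capillary_paths` list of length `n` (original labels kept).
#' @export
select_capillary_subset <- function(paths, n, seed = NULL) {
  stopifnot(inherits(paths, "capillary_paths"))
  if (n < 0 || n > length(paths))
    stop("n must be between 0 and the number of available paths (",
         length(paths), ")")
  if (!is.null(seed)) set.seed(seed)
  keep <- if (n == 0) integer(0) else sort(sample.int(length(paths), n))
  structure(paths[keep], class = "capillary_paths",
            grid_dims = attr(paths, "grid_dims"))
}

#' Export capillary paths as JSON lines
#'
#' One record per line with `path_id`, `label`, `axis`, `start`, `goal` and
#' a run-length encoding of the voxel list.
#'
#' @param paths A `capillary_paths` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_paths_jsonl <- function(paths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in paths) {
    steps <- diff(p$voxels)
    step_code <- steps[, 1] * 9L + steps[, 2] * 3L + steps[, 3]
    rle_steps <- rle(as.integer(step_code))
    rec <- list(path_id = p$path_id, label = p$label, axis = p$axis,
                start = p$start, goal = p$goal,
                n_voxels = nrow(p$voxels),
                step_lengths = rle_steps$lengths,
                step_codes = rle_steps$values)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}
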