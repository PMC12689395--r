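# Per-cell viability classification from mean PO2, population summaries,
# and slice morphometrics (capillary diameters, vascular density).

#' Classify a cell state from its mean oxygen partial pressure
#'
#' Functional above 10 mmHg, hypoxic between 0.45 and 10 mmHg, non-viable
#' below 0.45 mmHg. Values exactly at a threshold are assigned to the lower
#' class (the strict published inequalities leave exact boundaries
#' undefined; they are measure-zero in practice).
#'
#' @param mean_po2 Mean PO2 per cell, mmHg (vectorized, >= 0).
#' @return Character vector: `"functional"`, `"hypoxic"` or `"nonviable"`.
#' @export
classify_cell <- function(mean_po2) {
  stopifnot(all(mean_po2 >= 0))
  ifelse(mean_po2 > 10, "functional",
         ifelse(mean_po2 > 0.45, "hypoxic", "nonviable"))
}

#' Per-cell oxygen summary
#'
#' Averages the steady concentration over exactly the voxels labeled with
#' each cell id, converts to PO2 and classifies the cell state.
#'
#' @param grid A `voxel_grid` (cells, optionally grown capillaries).
#' @param field An `oxygen_field` for the same grid.
#' @return Data frame: `cell_id`, `cell_type`, `n_voxels`, `mean_conc`
#'   (µM), `mean_po2` (mmHg), `state`.
#' @export
cell_oxygen_summary <- function(grid, field) {
  stopifnot(inherits(field, "oxygen_field"),
            all(dim(grid) == dim(field$concentration)))
  et <- attr(grid, "entity_type")
  cell_ids <- which(et %in% .cell_types)
  lab <- as.integer(grid)
  keep <- lab %in% cell_ids
  sums <- rowsum(as.numeric(field$concentration)[keep], lab[keep])
  counts <- rowsum(rep(1, sum(keep)), lab[keep])
  ids <- as.integer(rownames(sums))
  mean_conc <- as.numeric(sums) / as.numeric(counts)
  mean_po2 <- concentration_to_po2(mean_conc, field$params$solubility)
  data.frame(cell_id = ids,
             cell_type = et[ids],
             n_voxels = as.integer(counts),
             mean_conc = mean_conc,
             mean_po2 = mean_po2,
             state = classify_cell(mean_po2),
             stringsAsFactors = FALSE)
}

#' Summarize viability by population
#'
#' Aggregates per-cell states into whole-islet and per-type proportions of
#' functional, hypoxic and non-viable cells (viable = functional + hypoxic),
#' and reports the mean oxygen over medium voxels. Strata with no cells are
#' omitted rather than reported as zero.
#'
#' @param cells A per-cell summary from [cell_oxygen_summary()].
#' @param grid,field Optional; when both are given the mean medium oxygen is
#'   included.
#' @param metadata Optional list (e.g. capillary count, glucose, seed)
#'   echoed into the report.
#' @return An object of class `viability_report`: `cells`, `proportions`
#'   (one row per stratum with `functional`, `hypoxic`, `nonviable`,
#'   `viable`, `n`), `mean_medium_conc`, `mean_medium_po2`, `metadata`.
#' @export
summarize_viability <- function(cells, grid = NULL, field = NULL,
                                metadata = list()) {
  stopifnot(is.data.frame(cells), nrow(cells) >= 1)
  strata <- c(list(islet = cells),
              split(cells, factor(cells$cell_type,
                                  levels = .cell_types))[
                                    unique(cells$cell_type)])
  props <- do.call(rbind, lapply(names(strata), function(nm) {
    s <- strata[[nm]]
    n <- nrow(s)
    f <- sum(s$state == "functional") / n
    h <- sum(s$state == "hypoxic") / n
    nv <- sum(s$state == "nonviable") / n
    data.frame(stratum = nm, functional = f, hypoxic = h, nonviable = nv,
               viable = f + h, n = n, stringsAsFactors = FALSE)
  }))
  mean_medium_conc <- mean_medium_po2 <- NA_real_
  if (!is.null(grid) && !is.null(field)) {
    med <- as.integer(grid) == 0L
    mean_medium_conc <- mean(as.numeric(field$concentration)[med])
    mean_medium_po2 <- concentration_to_po2(mean_medium_conc,
                                            field$params$solubility)
  }
  structure(list(cells = cells, proportions = props,
                 mean_medium_conc = mean_medium_conc,
                 mean_medium_po2 = mean_medium_po2,
                 metadata = metadata),
            class = "viability_report")
}

#' @export
print.viability_report <- function(x, ...) {
  p <- x$proportions[x$proportions$stratum == "islet", ]
  cat(sprintf("Viability report (%d cells): %.1f%% functional, %.1f%% hypoxic, %.1f%% non-viable (viable %.1f%%)\n",
              p$n, 100 * p$functional, 100 * p$hypoxic, 100 * p$nonviable,
              100 * p$viable))
  if (is.finite(x$mean_medium_conc))
    cat(sprintf("  mean medium oxygen: %.3f uM (%.2f mmHg)\n",
                x$mean_medium_conc, x$mean_medium_po2))
  invisible(x)
}

#' Extract the middle z slice
#'
#' Returns the plane `z = floor(Nz / 2)` (0-based voxel coordinates) with
#' entity labels preserved.
#'
#' @param grid A `voxel_grid`.
#' @return An integer label matrix with the grid's `entity_type` attribute.
#' @export
extract_mid_slice <- function(grid) {
  stopifnot(length(dim(grid)) == 3L)
  z0 <- floor(dim(grid)[3] / 2)
  slice <- grid[, , z0 + 1L]
  structure(as.matrix(slice), entity_type = attr(grid, "entity_type"),
            z_index = z0)
}

.slice_masks <- function(slice) {
  et <- attr(slice, "entity_type")
  if (is.null(et)) stop("slice lacks an entity_type attribute")
  cap_ids <- which(et == "capillary")
  cell_ids <- which(et %in% .cell_types)
  list(cap = matrix(slice %in% cap_ids, nrow(slice)),
       cell = matrix(slice %in% cell_ids, nrow(slice)))
}

#' Vascular density of a slice
#'
#' Capillary area as a percentage of islet-section area:
#' `100 * capillary pixels inside the mask / mask pixels`.
#'
#' Two mask rules are available. `"environment"` (the default) normalizes by
#' the whole slice, matching islet sections that fill the imaging field;
#' `"closing"` restricts to the morphological closing (disc,
#' `closing_radius` µm) of the union of cell and capillary pixels, a
#' deterministic surrogate for a manually drawn tight islet outline. The
#' two differ substantially whenever capillaries concentrate inside the
#' islet; reports should state the rule used.
#'
#' @param slice A label matrix from [extract_mid_slice()].
#' @param mask_rule `"environment"` or `"closing"`.
#' @param closing_radius Structuring-disc radius, µm (closing rule).
#' @return Density in percent; attribute `mask_pixels` records the mask
#'   area and `mask_rule` the rule used.
#' @export
vascular_density <- function(slice, mask_rule = c("environment", "closing"),
                             closing_radius = 5) {
  mask_rule <- match.arg(mask_rule)
  m <- .slice_masks(slice)
  fg <- m$cap | m$cell
  if (!any(fg)) stop("slice contains no islet pixels; mask is empty")
  if (mask_rule == "environment") {
    mask <- matrix(TRUE, nrow(fg), ncol(fg))
  } else {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    # zero-pad so the dilated region never touches the image border (erosion
    # otherwise treats outside pixels as foreground and inflates the mask)
    pad <- closing_radius + 1L
    fgp <- matrix(0, nrow(fg) + 2L * pad, ncol(fg) + 2L * pad)
    fgp[pad + seq_len(nrow(fg)), pad + seq_len(ncol(fg))] <- fg * 1
    maskp <- EBImage::closing(fgp, brush) > 0
    mask <- maskp[pad + seq_len(nrow(fg)), pad + seq_len(ncol(fg))]
  }
  dens <- 100 * sum(m$cap & mask) / sum(mask)
  structure(dens, mask_pixels = sum(mask), mask_rule = mask_rule)
}

#' Measure capillary cross-section diameters on a slice
#'
#' For each sampled capillary cross-section (a connected component of one
#' capillary label), casts a profile line through the component centroid at
#' a random orientation and returns the chord length between the two wall
#' crossings, in µm -- the in-silico analogue of measuring the distance
#' between vessel-wall peaks on an intensity profile. Components touching
#' the slice border are skipped (their count is recorded in the
#' `skipped_border` attribute), as are fragments below `min_area` pixels --
#' a cross-section smaller than the narrowest physiological capillary lumen
#' (~4 µm across, ~13 µm²) is not an identifiable vessel on a micrograph.
#' Components are sampled with replacement with a fresh orientation per
#' draw.
#'
#' @param slice A label matrix from [extract_mid_slice()].
#' @param n_samples Number of diameter measurements to draw.
#' @param step Ray-marching step along the profile line, pixels.
#' @param min_area Minimum component area (pixels = µm²) for a
#'   cross-section to count as a measurable vessel.
#' @return Numeric vector of diameters (µm); empty when the slice has no
#'   interior capillary cross-section.
#' @export
measure_capillary_diameters <- function(slice, n_samples = 100L,
                                        step = 0.25, min_area = 13L) {
  et <- attr(slice, "entity_type")
  cap_ids <- which(et == "capillary")
  nr <- nrow(slice); nc <- ncol(slice)
  comps <- list()
  skipped <- 0L
  for (id in cap_ids) {
    m <- matrix(slice == id, nr)
    if (!any(m)) next
    labm <- EBImage::bwlabel(m)
    for (cc in seq_len(max(labm))) {
      px <- which(labm == cc, arr.ind = TRUE)
      if (any(px[, 1] == 1L | px[, 1] == nr | px[, 2] == 1L | px[, 2] == nc)) {
        skipped <- skipped + 1L
        next
      }
      if (nrow(px) < min_area) next
      comps[[length(comps) + 1L]] <- px
    }
  }
  if (!length(comps))
    return(structure(numeric(0), skipped_border = skipped))
  inside <- function(px_set, y, x) {
    # pixel p spans [p - 0.5, p + 0.5) in each direction
    yi <- floor(y + 0.5); xi <- floor(x + 0.5)
    if (yi < 1 || yi > nr || xi < 1 || xi > nc) return(FALSE)
    px_set[yi, xi]
  }
  out <- numeric(n_samples)
  for (s in seq_len(n_samples)) {
    px <- comps[[sample.int(length(comps), 1L)]]
    mask <- matrix(FALSE, nr, nc)
    mask[px] <- TRUE
    cy <- mean(px[, 1]); cx <- mean(px[, 2])
    if (!inside(mask, cy, cx)) { # centroid outside a concave component
      j <- sample.int(nrow(px), 1L)
      cy <- px[j, 1]; cx <- px[j, 2]
    }
    theta <- runif(1, 0, pi)
    dy <- sin(theta); dx <- cos(theta)
    tpos <- 0
    while (inside(mask, cy + (tpos + step) * dy, cx + (tpos + step) * dx))
      tpos <- tpos + step
    tneg <- 0
    while (inside(mask, cy - (tneg + step) * dy, cx - (tneg + step) * dx))
      tneg <- tneg + step
    out[s] <- tpos + tneg + step # wall-to-wall width at step resolution
  }
  structure(out, skipped_border = skipped, n_components = length(comps))
}
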