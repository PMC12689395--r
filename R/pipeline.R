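# End-to-end orchestration: geometry -> seeding -> Potts growth -> oxygen ->
# viability, plus capillary-count sweeps and result aggregation.

#' Mean cross-sectional face area of an environment
#'
#' @param env_dims Integer 3-vector of grid dimensions, µm.
#' @return Mean of the three axis face areas, µm².
#' @export
mean_face_area <- function(env_dims) {
  stopifnot(length(env_dims) == 3L)
  d <- as.numeric(env_dims)
  (d[1] * d[2] + d[1] * d[3] + d[2] * d[3]) / 3
}

#' Capillary count equivalent across islet scales
#'
#' Scales a capillary count so capillaries per unit cross-sectional area are
#' preserved between a reference full-size environment and a (typically
#' smaller) simulated environment. The default reference is the mean face
#' area of the six reference human islet environments.
#'
#' @param n_full Capillary count at the reference scale.
#' @param env_dims Environment dimensions of the simulated grid, µm.
#' @param reference_area Reference cross-section area, µm².
#' @return Integer equivalent count (rounded, vectorized over `n_full`).
#' @export
capillary_count_equivalent <- function(n_full, env_dims,
                                       reference_area = NULL) {
  if (is.null(reference_area)) {
    e <- .human_islet_envs
    reference_area <- mean(apply(cbind(e$x, e$y, e$z), 1L, mean_face_area))
  }
  as.integer(round(n_full * mean_face_area(env_dims) / reference_area))
}

#' Pipeline run configuration
#'
#' @param synthesis List of [synthesize_islet()] arguments (`n_cells`,
#'   `target_diameter`, `composition`, ...) used when no `cells_file` is
#'   given.
#' @param cells_file Optional path to a cell table for [load_cells()].
#' @param species `"human"` or `"mouse"`.
#' @param n_capillaries Capillary count for a single [run_pipeline()] run.
#' @param counts Capillary counts for [sweep_capillary_counts()]
#'   (reference-scale values; see `scale_counts`).
#' @param scale_counts When `TRUE`, `counts` are interpreted at the
#'   reference human scale and converted per islet with
#'   [capillary_count_equivalent()].
#' @param glucose Glucose conditions to simulate.
#' @param replicates Replicate seeds per condition.
#' @param n_per_axis Size of the capillary path pool per axis.
#' @param cpm A [cpm_config()].
#' @param oxygen_tol,oxygen_max_iter Solver settings forwarded to
#'   [oxygen_params()].
#' @param seed Master seed; all stage seeds are derived from it.
#' @param out_dir Optional output directory for artifacts.
#' @param write_volumes Also write the labeled volume (run-length-encoded
#'   JSON); off by default because volumes are large.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthesis = list(n_cells = 100),
                            cells_file = NULL,
                            species = c("human", "mouse"),
                            n_capillaries = 10L,
                            counts = c(5, 10, 25, 50, 100, 200, 300),
                            scale_counts = FALSE,
                            glucose = c("G6", "G20"),
                            replicates = 1L, n_per_axis = 100L,
                            cpm = cpm_config(),
                            oxygen_tol = 1e-6, oxygen_max_iter = 20000L,
                            seed = 1L, out_dir = NULL,
                            write_volumes = FALSE) {
  species <- match.arg(species)
  glucose <- match.arg(glucose, several.ok = TRUE)
  structure(list(synthesis = synthesis, cells_file = cells_file,
                 species = species, n_capillaries = as.integer(n_capillaries),
                 counts = counts, scale_counts = scale_counts,
                 glucose = glucose, replicates = as.integer(replicates),
                 n_per_axis = as.integer(n_per_axis), cpm = cpm,
                 oxygen_tol = oxygen_tol,
                 oxygen_max_iter = as.integer(oxygen_max_iter),
                 seed = as.integer(seed), out_dir = out_dir,
                 write_volumes = write_volumes),
            class = "pipeline_config")
}

# stage seeds derived deterministically from one master seed
.stage_seeds <- function(master, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

.log_stage <- function(fmt, ...) {
  message(sprintf("[isletvasc %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

.get_islet <- function(cfg, seed) {
  if (!is.null(cfg$cells_file))
    load_cells(cfg$cells_file, species = cfg$species, seed = seed)
  else
    do.call(synthesize_islet,
            c(cfg$synthesis, list(species = cfg$species, seed = seed)))
}

#' Run the full vascularized-islet pipeline
#'
#' Executes geometry, capillary seeding, Potts growth, oxygen relaxation and
#' viability analysis in order for a single islet and capillary count, with
#' stage logging. When `cfg$out_dir` is set, artifacts (cell table,
#' architecture summary, path pool, per-cell viability tables, JSON
#' summaries and a manifest with file hashes) are written there.
#'
#' @param cfg A [pipeline_config()].
#' @return A list of class `pipeline_result`: `architecture`, `grid`
#'   (grown), `paths`, `subset`, per-glucose `fields` and `reports`,
#'   `config` and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  seeds <- .stage_seeds(cfg$seed, 5L)
  t0 <- Sys.time()
  .log_stage("stage geometry: building islet architecture")
  arch <- .get_islet(cfg, seeds[1])
  grid <- rasterize(arch)
  .log_stage("stage seeding: %d paths per axis", cfg$n_per_axis)
  pool <- generate_initial_capillaries(grid, cfg$n_per_axis, seed = seeds[2])
  subset <- select_capillary_subset(pool, cfg$n_capillaries, seed = seeds[3])
  .log_stage("stage cpm: growing %d capillaries for %d MCS",
             length(subset), cfg$cpm$n_mcs)
  grown <- evolve_capillaries(grid, cfg$cpm, seed = seeds[4], paths = subset)
  fields <- list()
  reports <- list()
  init <- NULL
  for (g in cfg$glucose) {
    .log_stage("stage oxygen: relaxing %s field", g)
    par <- oxygen_params(g, tol = cfg$oxygen_tol,
                         max_iter = cfg$oxygen_max_iter)
    fields[[g]] <- relax_to_steady_state(grown, par, init = init)
    init <- fields[[g]]$concentration
    .log_stage("stage viability: classifying cells (%s)", g)
    cells <- cell_oxygen_summary(grown, fields[[g]])
    reports[[g]] <- summarize_viability(
      cells, grown, fields[[g]],
      metadata = list(n_capillaries = length(subset), glucose = g,
                      species = cfg$species, seed = cfg$seed))
  }
  .log_stage("pipeline finished in %.1f s",
             as.numeric(difftime(Sys.time(), t0, units = "secs")))
  result <- structure(list(architecture = arch, grid = grown, paths = pool,
                           subset = subset, fields = fields,
                           reports = reports, config = cfg,
                           manifest = NULL),
                      class = "pipeline_result")
  if (!is.null(cfg$out_dir)) result$manifest <- .write_bundle(result, cfg)
  result
}

.write_bundle <- function(result, cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  f <- function(...) file.path(cfg$out_dir, ...)
  write_cells(result$architecture, f("cells.csv"))
  jsonlite::write_json(architecture_summary(result$architecture),
                       f("architecture.json"), auto_unbox = TRUE, digits = NA)
  write_paths_jsonl(result$paths, f("capillary_paths.jsonl"))
  for (g in names(result$reports)) {
    rep <- result$reports[[g]]
    write.csv(rep$cells, f(sprintf("viability_cells_%s.csv", g)),
              row.names = FALSE)
    jsonlite::write_json(
      list(proportions = rep$proportions,
           mean_medium_conc_uM = rep$mean_medium_conc,
           mean_medium_po2_mmHg = rep$mean_medium_po2,
           metadata = rep$metadata),
      f(sprintf("viability_summary_%s.json", g)),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  if (isTRUE(cfg$write_volumes)) .write_volume_rle(result$grid, f("volume.json"))
  cfg_out <- cfg
  cfg_out$cpm <- unclass(cfg_out$cpm)
  cfg_out$cpm$J <- as.vector(cfg_out$cpm$J)
  jsonlite::write_json(unclass(cfg_out), f("config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- setdiff(files, f("manifest.json"))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, f("manifest.json"), dataframe = "rows")
  manifest
}

# labeled volume as run-length-encoded JSON (plain-text, reloadable)
.write_volume_rle <- function(grid, path) {
  r <- rle(as.integer(grid))
  jsonlite::write_json(list(dims = dim(grid),
                            entity_type = attr(grid, "entity_type"),
                            lengths = r$lengths, values = r$values),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a run-length-encoded labeled volume
#'
#' @param path Path written by the pipeline's volume export.
#' @return A `voxel_grid`.
#' @export
read_volume_rle <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- array(inverse.rle(list(lengths = v$lengths, values = v$values)),
                dim = v$dims)
  structure(grid, class = "voxel_grid", entity_type = v$entity_type,
            frozen = v$entity_type %in% .cell_types,
            n_cells = sum(v$entity_type %in% .cell_types))
}

#' Sweep capillary counts over one or more islets
#'
#' For each islet the 300-path pool is generated once and reused across
#' counts and glucose conditions, so comparisons share geometry (capillary
#' positions held constant); for each count a random subset is selected,
#' grown with the Potts model, and the steady oxygen field and viability
#' report computed per glucose condition.
#'
#' @param cfg A [pipeline_config()]; `cfg$synthesis` may be a list of
#'   synthesis specs (one per islet).
#' @return A data frame of sweep records (one row per islet x count x
#'   glucose x replicate) with columns `islet_id`, `species`, `glucose`,
#'   `n_capillaries`, `count_reference` (the pre-scaling count),
#'   `n_cells`, `viable_proportion`, `functional_proportion`,
#'   `nonviable_proportion`, `mean_medium_po2`, `seed`. The `aggregate`
#'   attribute holds mean and SEM of the viable proportion per
#'   count x glucose.
#' @export
sweep_capillary_counts <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  specs <- cfg$synthesis
  if (!is.null(specs$n_cells)) specs <- list(specs)  # single spec
  n_islets <- length(specs)
  seeds <- .stage_seeds(cfg$seed, 1000L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }
  records <- list()
  for (ii in seq_len(n_islets)) {
    arch <- do.call(synthesize_islet,
                    c(specs[[ii]], list(species = cfg$species,
                                        seed = next_seed())))
    grid <- rasterize(arch)
    n_cells <- nrow(arch$cells)
    counts <- if (cfg$scale_counts)
      capillary_count_equivalent(cfg$counts, dim(grid)) else cfg$counts
    .log_stage("islet %d: %d cells, env %s, counts %s", ii, n_cells,
               paste(dim(grid), collapse = "x"),
               paste(counts, collapse = ","))
    pool <- generate_initial_capillaries(grid, cfg$n_per_axis,
                                         seed = next_seed())
    for (rep_i in seq_len(cfg$replicates)) {
      init <- NULL  # oxygen warm start carried across counts and glucose
      for (ci in seq_along(counts)) {
        k <- counts[ci]
        rec_seed <- next_seed()
        if (k > 0) {
          subset <- select_capillary_subset(pool, min(k, length(pool)),
                                            seed = rec_seed)
          grown <- evolve_capillaries(grid, cfg$cpm, seed = rec_seed,
                                      paths = subset)
        } else grown <- grid
        for (g in cfg$glucose) {
          par <- oxygen_params(g, tol = cfg$oxygen_tol,
                               max_iter = cfg$oxygen_max_iter)
          field <- suppressWarnings(relax_to_steady_state(grown, par,
                                                          init = init))
          init <- field$concentration
          cells <- cell_oxygen_summary(grown, field)
          rep_ <- summarize_viability(cells, grown, field)
          p <- rep_$proportions[rep_$proportions$stratum == "islet", ]
          records[[length(records) + 1L]] <- data.frame(
            islet_id = ii, species = cfg$species, glucose = g,
            n_capillaries = if (k > 0) length(subset) else 0L,
            count_reference = cfg$counts[ci],
            n_cells = n_cells,
            viable_proportion = p$viable,
            functional_proportion = p$functional,
            nonviable_proportion = p$nonviable,
            mean_medium_po2 = rep_$mean_medium_po2,
            seed = rec_seed, stringsAsFactors = FALSE)
        }
      }
    }
  }
  records <- do.call(rbind, records)
  agg <- do.call(rbind, lapply(
    split(records, list(records$count_reference, records$glucose),
          drop = TRUE),
    function(s) data.frame(
      count_reference = s$count_reference[1], glucose = s$glucose[1],
      mean_viable = mean(s$viable_proportion),
      sem_viable = stats::sd(s$viable_proportion) / sqrt(nrow(s)),
      n = nrow(s), stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  structure(records, aggregate = agg)
}
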