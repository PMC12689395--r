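# Modified sigmoidal viability model: viable fraction as a function of
# capillary count and islet cell number; evaluation, nonlinear fitting and
# the prediction tool backed by the published parameter sets.

.new_viability_params <- function(v_min, v_max, c50, n50, n_c, n_n,
                                  species = NA_character_,
                                  glucose = NA_character_,
                                  r_squared = NA_real_, mse = NA_real_,
                                  source = "user") {
  stopifnot(v_min <= v_max, c50 > 0, n50 > 0)
  structure(list(v_min = v_min, v_max = v_max, c50 = c50, n50 = n50,
                 n_c = n_c, n_n = n_n, species = species, glucose = glucose,
                 r_squared = r_squared, mse = mse, source = source),
            class = "viability_params")
}

#' Published viability model parameters
#'
#' Bundled whole-islet parameter sets of the sigmoidal viability model for
#' human islets at 6 and 20 mM glucose. Mouse parameters were not published
#' as a table; mouse predictions require a user-supplied fit (see
#' [fit_viability_model()]).
#'
#' @param species `"human"` (`"mouse"` raises an informative error).
#' @param glucose `"G6"` or `"G20"`.
#' @return An object of class `viability_params` with fields `v_min`,
#'   `v_max`, `c50`, `n50`, `n_c`, `n_n`.
#' @export
viability_params <- function(species = c("human", "mouse"),
                             glucose = c("G6", "G20")) {
  species <- match.arg(species)
  glucose <- match.arg(glucose)
  if (species == "mouse")
    stop("no bundled mouse parameter set (only human fits were published); ",
         "fit your own sweep records with fit_viability_model()")
  p <- .published_viability[[species]][[glucose]]
  .new_viability_params(p$v_min, p$v_max, p$c50, p$n50, p$n_c, p$n_n,
                        species = species, glucose = glucose,
                        r_squared = p$r_squared, source = "published")
}

#' @export
print.viability_params <- function(x, ...) {
  cat(sprintf("Viability model parameters (%s, %s, %s):\n",
              x$species, x$glucose, x$source))
  cat(sprintf("  Vmin %.3f  Vmax %.3f  C50 %.2f  N50 %.2f  nC %.2f  nN %.2f\n",
              x$v_min, x$v_max, x$c50, x$n50, x$n_c, x$n_n))
  if (is.finite(x$r_squared))
    cat(sprintf("  R^2 %.3f%s\n", x$r_squared,
                if (is.finite(x$mse)) sprintf("  MSE %.4g", x$mse) else ""))
  invisible(x)
}

#' Evaluate the sigmoidal viability model
#'
#' `V = Vmin + (Vmax - Vmin) / (1 + (C50/Ncap)^nC * (N50/Ncells)^nN)`.
#' At `Ncap = C50`, `Ncells = N50` the model returns the midpoint
#' `(Vmin + Vmax) / 2`. With `nC > 0` viability increases with the
#' capillary count (cooperative effect); with `nN < 0` it decreases with
#' islet size (inhibitory effect).
#'
#' @param n_cap Number of capillaries (> 0, vectorized).
#' @param n_cells Number of islet cells (> 0, vectorized).
#' @param params A `viability_params` object (or list with the six fields).
#' @return Predicted viable proportion(s) in `[v_min, v_max]`.
#' @export
evaluate_viability <- function(n_cap, n_cells, params) {
  if (any(n_cap <= 0) || any(n_cells <= 0))
    stop("n_cap and n_cells must be positive")
  p <- params
  p$v_min + (p$v_max - p$v_min) /
    (1 + (p$c50 / n_cap)^p$n_c * (p$n50 / n_cells)^p$n_n)
}

.fit_bounds <- function() {
  list(lower = c(v_min = 0, v_max = 0.8, c50 = 1, n50 = 100,
                 n_c = 0.5, n_n = -4),
       upper = c(v_min = 0.5, v_max = 1, c50 = 100, n50 = 5000,
                 n_c = 4, n_n = -0.5))
}

# bounds in the identifiable parameterization (log_k = nC*log C50 + nN*log N50)
.fit_bounds_ident <- function(b = .fit_bounds()) {
  lo <- b$lower; up <- b$upper
  term_c <- range(outer(c(lo["n_c"], up["n_c"]),
                        log(c(lo["c50"], up["c50"]))))
  term_n <- range(outer(c(lo["n_n"], up["n_n"]),
                        log(c(lo["n50"], up["n50"]))))
  list(lower = c(v_min = unname(lo["v_min"]), v_max = unname(lo["v_max"]),
                 n_c = unname(lo["n_c"]), n_n = unname(lo["n_n"]),
                 log_k = term_c[1] + term_n[1]),
       upper = c(v_min = unname(up["v_min"]), v_max = unname(up["v_max"]),
                 n_c = unname(up["n_c"]), n_n = unname(up["n_n"]),
                 log_k = term_c[2] + term_n[2]))
}

#' Fit the sigmoidal viability model
#'
#' Nonlinear least squares of the viable proportion against capillary count
#' and islet cell number, with multi-start initialization (Latin hypercube
#' over the parameter bounds) to avoid poor local minima. Goodness of fit is
#' reported as `R^2 = 1 - SS_res / SS_tot` on the fitted data and
#' `MSE = SS_res / n`.
#'
#' The sigmoid depends on `C50` and `N50` only through the product
#' `K = C50^nC * N50^nN`, so the pair is identifiable only up to a ridge.
#' The fit is therefore performed over `(Vmin, Vmax, nC, nN, log K)` and the
#' reported `(C50, N50)` are the ridge point with `N50` fixed at the
#' geometric mean islet size of the records (`log K` is kept in the result
#' for ridge-independent comparisons).
#'
#' @param records Data frame with columns `n_capillaries`, `n_cells`,
#'   `viable_proportion` (at least 10 records spanning >= 3 distinct
#'   capillary counts and >= 2 islet sizes).
#' @param n_starts Number of Latin-hypercube starts.
#' @param bounds List with named `lower` and `upper` vectors over
#'   `v_min, v_max, c50, n50, n_c, n_n`.
#' @param seed Optional integer seed (fit is deterministic under it).
#' @return A list of class `viability_fit`: `params`
#'   (a `viability_params`), `r_squared`, `mse`, `ss_res`, `n`,
#'   `n_converged` (starts that converged), `fitted`, `residuals`.
#' @export
fit_viability_model <- function(records, n_starts = 16L,
                                bounds = .fit_bounds(), seed = NULL) {
  stopifnot(is.data.frame(records),
            all(c("n_capillaries", "n_cells", "viable_proportion") %in%
                  names(records)))
  records <- records[records$n_capillaries > 0 & records$n_cells > 0, ]
  if (nrow(records) < 10)
    stop("need at least 10 records with positive capillary counts")
  if (length(unique(records$n_capillaries)) < 3)
    stop("records must span at least 3 distinct capillary counts")
  if (length(unique(records$n_cells)) < 2)
    stop("records must span at least 2 islet sizes")
  v <- records$viable_proportion
  ss_tot <- sum((v - mean(v))^2)
  if (ss_tot == 0)
    stop("degenerate records: constant viable proportion (R^2 undefined)")
  if (!is.null(seed)) set.seed(seed)
  bi <- .fit_bounds_ident(bounds)
  lo <- bi$lower; up <- bi$upper
  starts <- lhs::randomLHS(n_starts, 5L)
  colnames(starts) <- names(lo)
  starts <- sweep(sweep(starts, 2L, up - lo, `*`), 2L, lo, `+`)
  clamp <- function(x) pmin(up, pmax(lo, x))
  # one data-informed start ahead of the Latin-hypercube draws
  informed <- clamp(c(
    v_min = min(v), v_max = max(v), n_c = 2, n_n = -1.5,
    log_k = unname(2 * log(median(records$n_capillaries)) -
                     1.5 * log(median(records$n_cells)))))
  starts <- rbind(informed, starts)
  best <- NULL
  n_conv <- 0L
  for (s in seq_len(nrow(starts))) {
    st <- as.list(starts[s, ])
    fit <- tryCatch(
      minpack.lm::nlsLM(
        viable_proportion ~ v_min + (v_max - v_min) /
          (1 + exp(log_k - n_c * log(n_capillaries) -
                     n_n * log(n_cells))),
        data = records, start = st, lower = lo, upper = up,
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    ssr <- sum(residuals(fit)^2)
    if (is.null(best) || ssr < best$ssr) best <- list(fit = fit, ssr = ssr)
  }
  if (is.null(best))
    stop("nonlinear least squares failed to converge from all ",
         nrow(starts), " starts")
  cf <- coef(best$fit)
  n <- nrow(records)
  # report the ridge point with N50 at the geometric mean islet size
  n50_ref <- exp(mean(log(records$n_cells)))
  c50_ref <- exp((cf["log_k"] - cf["n_n"] * log(n50_ref)) / cf["n_c"])
  params <- .new_viability_params(unname(cf["v_min"]), unname(cf["v_max"]),
                                  unname(c50_ref), n50_ref,
                                  unname(cf["n_c"]), unname(cf["n_n"]),
                                  r_squared = 1 - best$ssr / ss_tot,
                                  mse = best$ssr / n, source = "fitted")
  params$log_k <- unname(cf["log_k"])
  structure(list(params = params, r_squared = params$r_squared,
                 mse = params$mse, ss_res = best$ssr, n = n,
                 n_converged = n_conv, log_k = unname(cf["log_k"]),
                 fitted = as.numeric(fitted(best$fit)),
                 residuals = as.numeric(residuals(best$fit))),
            class = "viability_fit")
}

#' @export
print.viability_fit <- function(x, ...) {
  cat(sprintf("Sigmoidal viability fit: n = %d, R^2 = %.4f, MSE = %.5f (%d/%d starts converged)\n",
              x$n, x$r_squared, x$mse, x$n_converged, x$n_converged))
  print(x$params)
  invisible(x)
}

#' Predict islet cell viability
#'
#' Evaluates the viability model for a capillary count, islet size, glucose
#' level and species -- the prediction tool backing the package's
#' command-line interface. Inputs outside the fitted range (capillary count
#' 5-300, cell number within the reference human islet range) trigger an
#' extrapolation warning.
#'
#' @param n_cap Number of capillaries.
#' @param n_cells Number of islet cells.
#' @param glucose `"G6"` or `"G20"`.
#' @param species `"human"` or `"mouse"`.
#' @param params Optional `viability_params` (e.g. from a user fit);
#'   defaults to the bundled published set for `species`/`glucose`.
#' @return A list of class `viability_prediction` with `viability`,
#'   `params`, `extrapolation` (logical) and the inputs.
#' @export
predict_viability <- function(n_cap, n_cells, glucose = c("G6", "G20"),
                              species = c("human", "mouse"),
                              params = NULL) {
  glucose <- match.arg(glucose)
  species <- match.arg(species)
  if (is.null(params)) params <- viability_params(species, glucose)
  v <- evaluate_viability(n_cap, n_cells, params)
  rng_cells <- range(.human_islet_envs$n_cells)
  extrap <- n_cap < 5 | n_cap > 300 |
    n_cells < rng_cells[1] | n_cells > rng_cells[2]
  out <- structure(list(viability = v, n_cap = n_cap, n_cells = n_cells,
                        glucose = glucose, species = species,
                        params = params, extrapolation = extrap,
                        fitted_range = list(n_cap = c(5, 300),
                                            n_cells = rng_cells)),
                   class = "viability_prediction")
  out
}

#' @export
print.viability_prediction <- function(x, ...) {
  cat(sprintf("Predicted viable proportion: %s\n",
              paste(sprintf("%.3f", x$viability), collapse = ", ")))
  cat(sprintf("  inputs: %s capillaries, %s cells, %s, %s (parameters: %s)\n",
              paste(x$n_cap, collapse = "/"),
              paste(x$n_cells, collapse = "/"), x$glucose, x$species,
              x$params$source))
  if (any(x$extrapolation))
    cat(sprintf("  warning: input(s) outside the fitted range (capillaries %g-%g, cells %g-%g); extrapolated\n",
                x$fitted_range$n_cap[1], x$fitted_range$n_cap[2],
                x$fitted_range$n_cells[1], x$fitted_range$n_cells[2]))
  invisible(x)
}

#' Write / read viability parameter files
#'
#' JSON round trip for fitted or published parameter sets.
#'
#' @param params A `viability_params`.
#' @param path File path.
#' @return `path` (write) or a `viability_params` (read).
#' @export
write_viability_params <- function(params, path) {
  stopifnot(inherits(params, "viability_params"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_viability_params
#' @export
read_viability_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  .new_viability_params(p$v_min, p$v_max, p$c50, p$n50, p$n_c, p$n_n,
                        species = p$species %||% NA_character_,
                        glucose = p$glucose %||% NA_character_,
                        r_squared = p$r_squared %||% NA_real_,
                        mse = p$mse %||% NA_real_,
                        source = p$source %||% "file")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
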