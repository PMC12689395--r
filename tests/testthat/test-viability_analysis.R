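test_that("cell states follow the PO2 thresholds with lower-class boundaries", {
  expect_identical(classify_cell(30), "functional")
  expect_identical(classify_cell(5), "hypoxic")
  expect_identical(classify_cell(0.2), "nonviable")
  expect_identical(classify_cell(10), "hypoxic")     # boundary: lower class
  expect_identical(classify_cell(0.45), "nonviable") # boundary: lower class
  expect_identical(classify_cell(0), "nonviable")
  expect_error(classify_cell(-1))
  # monotone in PO2: increasing pressure never worsens the state
  rank <- c(nonviable = 1, functional = 3, hypoxic = 2)
  p <- sort(runif(50, 0, 40))
  expect_true(all(diff(rank[classify_cell(p)]) >= 0))
})

test_that("per-cell means are taken over exactly the cell's voxels", {
  lat <- array(0L, dim = c(4, 4, 4))
  lat[1:2, 1, 1] <- 1L  # beta cell, 2 voxels
  lat[4, 4, 4] <- 2L    # alpha cell, 1 voxel
  lat[1, 4, 4] <- 3L    # capillary
  g <- label_grid(lat, types = c("beta", "alpha", "capillary"))
  conc <- array(0, dim = dim(lat))
  conc[1, 1, 1] <- 1.5; conc[2, 1, 1] <- 0.9  # mean 1.2 uM = 5.13 mmHg
  conc[4, 4, 4] <- 7.02
  f <- structure(list(concentration = conc, converged = TRUE,
                      iterations = 1L, max_residual = 0,
                      params = oxygen_params("G6")),
                 class = "oxygen_field")
  cs <- cell_oxygen_summary(g, f)
  expect_equal(nrow(cs), 2L)
  b <- cs[cs$cell_id == 1, ]
  expect_equal(b$mean_conc, 1.2)
  expect_equal(b$mean_po2, concentration_to_po2(1.2))
  expect_identical(b$state, "hypoxic")
  a <- cs[cs$cell_id == 2, ]
  expect_equal(a$mean_po2, 30)
  expect_identical(a$state, "functional")
})

test_that("viability proportions partition, mix across types, and drop empty strata", {
  cells <- data.frame(
    cell_id = 1:10,
    cell_type = c(rep("alpha", 4), rep("beta", 6)),
    n_voxels = 10L,
    mean_conc = 1,
    mean_po2 = c(30, 30, 5, 0.1, 30, 5, 5, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
  cells$state <- classify_cell(cells$mean_po2)
  rep <- summarize_viability(cells)
  pr <- rep$proportions
  # three proportions sum to 1 in every stratum; viable = functional + hypoxic
  expect_true(all(abs(pr$functional + pr$hypoxic + pr$nonviable - 1) < 1e-12))
  expect_identical(pr$viable, pr$functional + pr$hypoxic)
  # no delta cells: stratum absent, not zero
  expect_false("delta" %in% pr$stratum)
  # whole-islet proportions equal the type mixture weighted by counts
  a <- pr[pr$stratum == "alpha", ]; b <- pr[pr$stratum == "beta", ]
  isl <- pr[pr$stratum == "islet", ]
  expect_equal(isl$functional, (a$functional * a$n + b$functional * b$n) / 10)
  # independent tally agrees exactly
  expect_equal(isl$nonviable, sum(cells$state == "nonviable") / 10)
})

test_that("all cells hugging capillaries are functional; no capillaries, none viable", {
  set.seed(12)
  arch <- synthesize_islet(12, "human", seed = 41)
  grid <- rasterize(arch)
  # no capillaries: zero field, everything non-viable
  f0 <- suppressWarnings(relax_to_steady_state(grid, oxygen_params("G6")))
  cs0 <- cell_oxygen_summary(grid, f0)
  rep0 <- summarize_viability(cs0)
  expect_equal(rep0$proportions$nonviable[
    rep0$proportions$stratum == "islet"], 1.0)
  # dense vascularization: all cells functional
  pool <- generate_initial_capillaries(grid, n_per_axis = 12, seed = 42)
  grown <- evolve_capillaries(grid, cpm_config(n_mcs = 30), seed = 43,
                              paths = pool)
  f1 <- relax_to_steady_state(grown, oxygen_params("G6"))
  rep1 <- summarize_viability(cell_oxygen_summary(grown, f1), grown, f1)
  expect_equal(rep1$proportions$functional[
    rep1$proportions$stratum == "islet"], 1.0)
  expect_gt(rep1$mean_medium_po2, 10)
})

test_that("the mid slice is the floor(Nz/2) plane with labels preserved", {
  g <- empty_grid(c(70, 70, 70))
  sl <- extract_mid_slice(g)
  expect_identical(attr(sl, "z_index"), 35)
  arch <- islet_architecture(data.frame(x = 0, y = 0, z = 0, type = "beta",
                                        radius = 6), buffer = 10)
  grid <- rasterize(arch)
  sl2 <- extract_mid_slice(grid)
  # slice of a mid-grid sphere: a disc of about the sphere radius
  a <- sum(sl2 == 1L)
  expect_lt(abs(sqrt(a / pi) - 6), 0.7)
  expect_true(all(unique(as.integer(sl2)) %in% unique(as.integer(grid))))
})

test_that("vascular density is the capillary share of the islet mask", {
  # constructed slice: 20x20 cell block (400 px) with 24 capillary pixels
  lat <- array(0L, dim = c(30, 30, 3))
  lat[6:25, 6:25, 2] <- 1L
  lat[11:14, 11:16, 2] <- 2L  # 24 capillary pixels inside
  g <- label_grid(lat, types = c("beta", "capillary"))
  sl <- extract_mid_slice(g)
  d <- vascular_density(sl, mask_rule = "closing")
  expect_equal(as.numeric(d), 100 * 24 / 400)
  expect_identical(attr(d, "mask_pixels"), 400L)
  # full-slice normalization
  denv <- vascular_density(sl, mask_rule = "environment")
  expect_equal(as.numeric(denv), 100 * 24 / 900)
  # rotation by 90 degrees leaves the density unchanged
  sl_rot <- structure(t(sl[nrow(sl):1, ]), entity_type = attr(sl, "entity_type"))
  expect_equal(as.numeric(vascular_density(sl_rot, mask_rule = "closing")),
               as.numeric(d))
  # no capillaries: exactly zero
  lat0 <- lat; lat0[lat0 == 2L] <- 1L
  sl0 <- extract_mid_slice(label_grid(lat0, types = c("beta", "capillary")))
  expect_identical(as.numeric(vascular_density(sl0)), 0)
  # empty slice errors
  expect_error(vascular_density(extract_mid_slice(empty_grid(c(10, 10, 3)))),
               "no islet pixels")
})

test_that("profile-line diameters recover disc and ribbon geometry", {
  # rasterized disc of radius 3 -> estimates in [5, 7], mean about 6
  lat <- array(0L, dim = c(21, 21, 3))
  for (i in 1:21) for (j in 1:21)
    if ((i - 11)^2 + (j - 11)^2 < 3^2) lat[i, j, 2] <- 1L
  g <- label_grid(lat, types = "capillary")
  sl <- extract_mid_slice(g)
  set.seed(3)
  d <- measure_capillary_diameters(sl, n_samples = 100)
  expect_length(d, 100L)
  expect_true(all(d >= 4.5 & d <= 7.5))
  expect_equal(mean(d), 6, tolerance = 0.15)

  # elongated 3 x 10 component: estimates range from about 3 to about 10
  lat2 <- array(0L, dim = c(24, 24, 3))
  lat2[8:10, 6:15, 2] <- 1L
  sl2 <- extract_mid_slice(label_grid(lat2, types = "capillary"))
  set.seed(4)
  d2 <- measure_capillary_diameters(sl2, n_samples = 300)
  expect_gte(min(d2), 2.5)
  expect_lte(max(d2), 10.7)
  expect_gt(max(d2) - min(d2), 3)

  # no capillary cross-sections: empty result
  lat3 <- array(0L, dim = c(10, 10, 3)); lat3[4, 4, 2] <- 1L
  sl3 <- extract_mid_slice(label_grid(lat3, types = "beta"))
  expect_length(measure_capillary_diameters(sl3, 10), 0L)
  # components touching the border are skipped and counted
  lat4 <- array(0L, dim = c(10, 10, 3)); lat4[1:3, 4:6, 2] <- 1L
  sl4 <- extract_mid_slice(label_grid(lat4, types = "capillary"))
  d4 <- measure_capillary_diameters(sl4, 10)
  expect_length(d4, 0L)
  expect_identical(attr(d4, "skipped_border"), 1L)
})
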