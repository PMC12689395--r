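test_that("target volume follows the parameterized formula and is linear in length", {
  expect_equal(target_volume(3.5, 100), 2 * pi * 3.5^2 * 100)
  expect_equal(target_volume(3.5, 100), 7696.9, tolerance = 1e-4)
  expect_equal(target_volume(3.5, 0), 0)
  expect_equal(target_volume(3.5, 200), 2 * target_volume(3.5, 100))
  expect_equal(target_volume(3.5, 100, mode = "cylinder"),
               pi * 3.5^2 * 100)
})

test_that("total energy matches hand enumeration and an independent oracle", {
  # all-medium lattice: no interfaces, no entities
  st0 <- make_state(array(0L, dim = c(4, 4, 4)), types = character(0))
  expect_equal(total_energy(st0), 0)

  # one capillary voxel (v = 1, V = 10, lambda = 1e3) centered in a 3^3
  # medium lattice, 6-neighbor boundary: 6 * 70 + 1e3 * 81 = 81420
  lat <- array(0L, dim = c(3, 3, 3)); lat[2, 2, 2] <- 1L
  st1 <- make_state(lat, types = "capillary", target_vol = 10,
                    vol_lambda = 1e3, frozen = FALSE,
                    cfg = cpm_config(neighbor_order = 1))
  expect_equal(total_energy(st1), 6 * 70 + 1e3 * (1 - 10)^2)

  # oracle equivalence on random small lattices, both neighbor orders
  set.seed(61)
  for (order in 1:2) {
    for (rep in 1:3) {
      dims <- c(6, 5, 7)
      types <- c("alpha", "beta", "capillary", "capillary", "delta")
      lat <- array(sample(0:5, prod(dims), TRUE,
                          prob = c(0.5, rep(0.1, 5))), dim = dims)
      lat[lat == 5L] <- 0L
      tv <- c(-1, -1, 40, 25, -1)
      vl <- c(0, 0, 1e3, 1e3, 0)
      frz <- c(TRUE, TRUE, FALSE, FALSE, TRUE)
      cfg <- cpm_config(neighbor_order = order)
      st <- make_state(lat, types, tv, vl, frz, cfg)
      expect_equal(total_energy(st),
                   r_total_energy(lat, types, cfg$J, order, tv, vl, frz),
                   tolerance = 1e-12)
    }
  }
})

test_that("frozen cell voxels reject copies in both directions, state unchanged", {
  lat <- array(0L, dim = c(3, 3, 3))
  lat[2, 2, 2] <- 1L  # alpha cell at center (0-based site (1,1,1))
  st <- make_state(lat, types = "alpha")
  # medium copied INTO the cell voxel (site = cell, neighbor = medium)
  res_in <- attempt_copy(st, site = c(1, 1, 1), neighbor = c(0, 1, 1))
  expect_true(res_in$frozen_rejected)
  expect_false(res_in$accepted)
  expect_identical(res_in$state$lattice, st$lattice)
  # cell id copied OUT into a medium voxel (source frozen)
  res_out <- attempt_copy(st, site = c(0, 1, 1), neighbor = c(1, 1, 1))
  expect_true(res_out$frozen_rejected)
  expect_false(res_out$accepted)
  expect_identical(res_out$state$lattice, st$lattice)
})

test_that("dH = 0 attempts are always accepted", {
  lat <- array(0L, dim = c(4, 3, 3))
  lat[2, 2, 2] <- 1L
  J0 <- matrix(0, 5, 5, dimnames = list(
    c("medium", "alpha", "beta", "delta", "capillary"),
    c("medium", "alpha", "beta", "delta", "capillary")))
  cfg <- cpm_config(J = J0, neighbor_order = 1)
  st <- make_state(lat, types = "capillary", target_vol = -1,
                   vol_lambda = 0, frozen = FALSE, cfg = cfg)
  for (i in 1:10) {
    res <- attempt_copy(st, site = c(2, 1, 1), neighbor = c(1, 1, 1))
    expect_equal(res$delta_H, 0)
    expect_true(res$accepted)
  }
})

test_that("Metropolis acceptance frequency at dH = T is about exp(-1)", {
  # expanding an isolated capillary voxel with J_cm = 2.5 and no volume
  # term costs dH = (5 - 1) * 2.5 = 10 = T exactly (order-1 boundary)
  lat <- array(0L, dim = c(5, 5, 5))
  lat[3, 3, 3] <- 1L
  J <- matrix(0, 5, 5, dimnames = list(
    c("medium", "alpha", "beta", "delta", "capillary"),
    c("medium", "alpha", "beta", "delta", "capillary")))
  J["medium", "capillary"] <- J["capillary", "medium"] <- 2.5
  cfg <- cpm_config(J = J, neighbor_order = 1, temperature = 10)
  st <- make_state(lat, types = "capillary", target_vol = -1,
                   vol_lambda = 0, frozen = FALSE, cfg = cfg)
  probe <- attempt_copy(st, site = c(1, 2, 2), neighbor = c(2, 2, 2))
  expect_equal(probe$delta_H, 10)
  set.seed(71)
  n <- 1e5
  acc <- 0L
  for (i in seq_len(n)) {
    if (attempt_copy(st, site = c(1, 2, 2),
                     neighbor = c(2, 2, 2))$accepted) acc <- acc + 1L
  }
  p <- exp(-1)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(acc / n - p), 3 * se)
})

test_that("acceptance approaches 1 at very high temperature", {
  lat <- array(0L, dim = c(5, 5, 5))
  lat[3, 3, 3] <- 1L
  cfg <- cpm_config(temperature = 1e12, neighbor_order = 1)
  # at target volume already: expanding is strictly uphill (dH > 0)
  st <- make_state(lat, types = "capillary", target_vol = 1,
                   vol_lambda = 1e3, frozen = FALSE, cfg = cfg)
  set.seed(5)
  ok <- vapply(1:200, function(i)
    attempt_copy(st, site = c(1, 2, 2), neighbor = c(2, 2, 2))$accepted,
    logical(1))
  expect_true(all(ok))
})

test_that("evolution grows a straight capillary toward its target volume", {
  g <- empty_grid(c(60, 60, 60))
  paths <- make_paths(list(straight_path_x(60, 30, 30)))
  cfg <- cpm_config(n_mcs = 200, volume_mode = "as_printed")
  # 0 MCS: seeded grid unchanged
  st <- seed_capillaries(g, paths, cfg)
  same <- evolve_capillaries(st, cpm_config(n_mcs = 0), seed = 1)
  expect_identical(as.integer(same), as.integer(st$lattice))

  grown <- evolve_capillaries(g, cfg, seed = 2, paths = paths)
  diag <- attr(grown, "cpm_diagnostics")
  Vc <- target_volume(3.5, 60, mode = "as_printed")
  vol <- sum(grown == 1L)
  expect_lt(abs(vol - Vc) / Vc, 0.10)
  # cross-section equivalent diameter in [5, 10] um (mean over the span;
  # single planes fluctuate with the interface roughness at T = 10)
  lat <- array(as.integer(grown), dim = dim(grown))
  per_x <- vapply(1:60, function(i) sum(lat[i, , ] == 1L), numeric(1))
  d_eq <- 2 * sqrt(mean(per_x[per_x > 0]) / pi)
  expect_gte(d_eq, 5); expect_lte(d_eq, 10)
  # volume bookkeeping equals exact recount
  expect_equal(diag$volumes[1], vol)
  # incremental energy audit matches recomputation
  expect_lt(max(abs(diag$H_incremental - diag$H_recomputed) /
                  pmax(abs(diag$H_recomputed), 1)), 1e-6)
  # determinism: same seed, identical lattice
  grown2 <- evolve_capillaries(g, cfg, seed = 2, paths = paths)
  expect_identical(as.integer(grown), as.integer(grown2))
})

test_that("prohibitive capillary-capillary contact energy prevents merging", {
  g <- empty_grid(c(40, 40, 40))
  paths <- make_paths(list(straight_path_x(40, 18, 20),
                           straight_path_x(40, 22, 20)))
  grown <- evolve_capillaries(g, cpm_config(n_mcs = 100), seed = 3,
                              paths = paths)
  lat <- array(as.integer(grown), dim = dim(grown))
  touching <- 0L
  for (o in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    a <- lat[1:(40 - o[1]), 1:(40 - o[2]), 1:(40 - o[3])]
    b <- lat[(1 + o[1]):40, (1 + o[2]):40, (1 + o[3]):40]
    touching <- touching + sum(a > 0L & b > 0L & a != b)
  }
  expect_identical(touching, 0L)
})

test_that("frozen cells are immutable through evolution and energy decreases", {
  set.seed(9)
  arch <- synthesize_islet(20, "human", seed = 31)
  grid <- rasterize(arch)
  pool <- generate_initial_capillaries(grid, n_per_axis = 2, seed = 32)
  cfg <- cpm_config(n_mcs = 40)
  grown <- evolve_capillaries(grid, cfg, seed = 33, paths = pool)
  cell_ids <- arch$cells$cell_id
  before <- array(as.integer(grid), dim = dim(grid))
  after <- array(as.integer(grown), dim = dim(grown))
  for (id in cell_ids)
    expect_identical(which(after == id), which(before == id))
  # smoothed energy trajectory is non-increasing during growth
  H <- attr(grown, "cpm_diagnostics")$H_trace
  sm <- stats::filter(H, rep(1 / 5, 5), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(sm[length(sm)], sm[1])
  expect_lt(sum(diff(sm) > 0) / length(sm), 0.2)
})
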