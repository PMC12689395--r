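test_that("load_cells reads tables, reports type counts and applies the buffer rule", {
  set.seed(101)
  # composition of reconstructed human islet 1: 148 alpha, 316 beta, 119 delta
  path <- write_cell_table(148, 316, 119, spread = 120)
  arch <- load_cells(path, species = "human")
  cnt <- table(arch$cells$type)
  expect_equal(nrow(arch$cells), 583L)
  expect_equal(as.integer(cnt[c("alpha", "beta", "delta")]),
               c(148L, 316L, 119L))
  # tab-separated variant reads identically
  path2 <- write_cell_table(3, 4, 2, sep = "\t")
  expect_equal(nrow(load_cells(path2, "human")$cells), 9L)

  # single cell at origin, radius 5, buffer 30 -> 70^3 environment
  one <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,type,radius", "0,0,0,beta,5"), one)
  expect_equal(load_cells(one, "human")$env_dims, c(70L, 70L, 70L))

  # unknown type token rejected with the offending row named
  bad <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,type,radius", "0,0,0,beta,5", "9,9,9,pp,5"), bad)
  expect_error(load_cells(bad, "human"), "row.*2.*pp|pp")
  # empty table rejected
  emptyf <- tempfile(fileext = ".csv")
  writeLines("x,y,z,type,radius", emptyf)
  expect_error(load_cells(emptyf, "human"), "empty")
  # missing radii are drawn within the distribution bounds
  nor <- tempfile(fileext = ".csv")
  writeLines(c("x,y,z,type", "0,0,0,beta", "30,0,0,alpha"), nor)
  a <- load_cells(nor, "human", seed = 5)
  expect_true(all(a$cells$radius >= 3.5 & a$cells$radius <= 8))
})

test_that("mouse architectures reject delta cells", {
  tab <- data.frame(x = c(0, 20), y = 0, z = 0,
                    type = c("beta", "delta"), radius = 5)
  expect_error(islet_architecture(tab, species = "mouse"), "delta")
  expect_s3_class(islet_architecture(tab, species = "human"),
                  "islet_architecture")
})

test_that("count_overlaps uses strict tangency and matches a brute-force oracle", {
  one <- islet_architecture(data.frame(x = 0, y = 0, z = 0, type = "beta",
                                       radius = 5))
  expect_identical(count_overlaps(one), 0L)
  two <- function(d) islet_architecture(
    data.frame(x = c(0, d), y = 0, z = 0, type = "beta", radius = 5))
  expect_identical(count_overlaps(two(8)), 1L)
  expect_identical(count_overlaps(two(10)), 0L)  # tangency: no overlap

  set.seed(42)
  n <- 50
  cells <- data.frame(x = runif(n, 0, 40), y = runif(n, 0, 40),
                      z = runif(n, 0, 40),
                      type = sample(c("alpha", "beta", "delta"), n, TRUE),
                      radius = runif(n, 2, 6))
  arch <- islet_architecture(cells)
  brute <- 0L
  cc <- arch$cells
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((cc[i, c("x", "y", "z")] - cc[j, c("x", "y", "z")])^2))
    if (d < cc$radius[i] + cc$radius[j]) brute <- brute + 1L
  }
  expect_identical(count_overlaps(arch), brute)

  # invariance under reordering and translation
  perm <- cells[sample(n), ]
  perm$x <- perm$x + 100
  expect_identical(count_overlaps(islet_architecture(perm)), brute)
})

test_that("optimize_packing resolves overlaps, never worsens, and is seed-reproducible", {
  clean <- islet_architecture(data.frame(x = c(0, 20), y = 0, z = 0,
                                         type = "beta", radius = 5))
  out <- optimize_packing(clean, max_iter = 10)
  expect_identical(count_overlaps(out), 0L)
  expect_equal(out$cells[, c("x", "y", "z", "radius")],
               clean$cells[, c("x", "y", "z", "radius")])

  overl <- islet_architecture(data.frame(x = c(0, 4), y = 0, z = 0,
                                         type = "beta", radius = 5))
  fixed <- optimize_packing(overl, max_iter = 10000, seed = 1)
  expect_identical(count_overlaps(fixed), 0L)
  expect_true(attr(fixed, "converged"))
  # best-so-far trajectory is non-increasing
  expect_true(all(diff(attr(fixed, "trajectory")) <= 0))

  a <- optimize_packing(overl, max_iter = 500, seed = 7)
  b <- optimize_packing(overl, max_iter = 500, seed = 7)
  expect_identical(a$cells, b$cells)
})

test_that("synthesize_islet honors composition, density limits and seeds", {
  arch <- synthesize_islet(583, "human", seed = 3)
  expect_identical(count_overlaps(arch), 0L)
  cnt <- table(factor(arch$cells$type, levels = c("alpha", "beta", "delta")))
  chi <- suppressWarnings(
    stats::chisq.test(as.integer(cnt), p = c(0.29, 0.53, 0.18)))
  expect_gt(chi$p.value, 1e-4)  # counts within multinomial noise

  small <- synthesize_islet(10, "mouse", composition = c(beta = 1),
                            seed = 2)
  expect_true(all(small$cells$type == "beta"))

  expect_error(synthesize_islet(100, "human", target_diameter = 40,
                                seed = 1),
               "infeasible density")

  a <- synthesize_islet(40, "human", seed = 9)
  b <- synthesize_islet(40, "human", seed = 9)
  expect_identical(a$cells, b$cells)  # bit-reproducible under the seed
})

test_that("rasterize labels voxel centers inside spheres and partitions the grid", {
  # digital volume depends on sub-voxel alignment; averaged over random
  # alignments it matches the analytic sphere volume within 3%
  set.seed(77)
  vols <- vapply(1:20, function(i) {
    arch <- islet_architecture(data.frame(x = 0, y = 0, z = 0,
                                          type = "beta", radius = 5),
                               buffer = 10 + runif(1))
    sum(rasterize(arch) == 1L)
  }, numeric(1))
  expect_lt(abs(mean(vols) - 4 / 3 * pi * 125) / (4 / 3 * pi * 125), 0.03)
  expect_true(all(abs(vols - 4 / 3 * pi * 125) / (4 / 3 * pi * 125) < 0.10))

  # empty architecture is not constructible; an all-medium grid comes from
  # the helper and rasterized grids partition into {medium, cell ids}
  set.seed(8)
  multi <- synthesize_islet(25, "human", seed = 8)
  g <- rasterize(multi)
  expect_equal(dim(g), multi$env_dims)
  ids <- sort(unique(as.integer(g)))
  expect_true(all(ids %in% c(0L, multi$cells$cell_id)))
  # per-cell voxel count positive and at most the bounding cube
  for (id in multi$cells$cell_id) {
    nv <- sum(g == id)
    r <- multi$cells$radius[multi$cells$cell_id == id]
    expect_gt(nv, 0)
    expect_lte(nv, (2 * ceiling(r))^3)
  }
  # overlapping architectures are rejected
  overl <- islet_architecture(data.frame(x = c(0, 4), y = 0, z = 0,
                                         type = "beta", radius = 5))
  expect_error(rasterize(overl), "overlap")
})
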