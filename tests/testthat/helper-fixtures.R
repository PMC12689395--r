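# Shared fixture builders (everything generated in code at test time).

# grid with no entities: all-medium lattice of the given dimensions
empty_grid <- function(dims) {
  structure(array(0L, dim = dims), class = "voxel_grid",
            entity_type = character(0), frozen = logical(0), n_cells = 0L)
}

# grid with given integer labels and a type per entity id
label_grid <- function(lattice, types) {
  structure(array(as.integer(lattice), dim = dim(lattice)),
            class = "voxel_grid", entity_type = types,
            frozen = types %in% c("alpha", "beta", "delta"),
            n_cells = sum(types %in% c("alpha", "beta", "delta")))
}

# hand-built Potts state from a labeled lattice
make_state <- function(lattice, types, target_vol = NULL, vol_lambda = NULL,
                       frozen = NULL, cfg = cpm_config()) {
  n <- length(types)
  if (is.null(target_vol)) target_vol <- rep(-1, n)
  if (is.null(vol_lambda)) vol_lambda <- rep(0, n)
  if (is.null(frozen)) frozen <- types %in% c("alpha", "beta", "delta")
  structure(list(lattice = array(as.integer(lattice), dim = dim(lattice)),
                 entity_type = types,
                 type_code = match(types,
                                   c("medium", "alpha", "beta", "delta",
                                     "capillary")) - 1L,
                 target_vol = target_vol, vol_lambda = vol_lambda,
                 frozen = frozen,
                 volumes = as.numeric(tabulate(lattice[lattice > 0L], n)),
                 cfg = cfg),
            class = "cpm_state")
}

# capillary path list from explicit voxel matrices (0-based coordinates)
make_paths <- function(voxel_list, first_label = 1L, axis = "x") {
  paths <- lapply(seq_along(voxel_list), function(i) {
    v <- voxel_list[[i]]
    list(path_id = i, label = first_label + i - 1L, axis = axis,
         start = v[1, ], goal = v[nrow(v), ], voxels = v, success = TRUE)
  })
  structure(paths, class = "capillary_paths")
}

# straight path along the x axis at fixed (y, z), spanning the grid
straight_path_x <- function(nx, y, z) {
  cbind(0:(nx - 1L), y, z)
}

# random cell table (counts per type) written to a temp CSV; returns the path
write_cell_table <- function(n_alpha, n_beta, n_delta, spread = 60,
                             radius = 5, sep = ",") {
  n <- n_alpha + n_beta + n_delta
  tab <- data.frame(
    x = runif(n, 0, spread), y = runif(n, 0, spread), z = runif(n, 0, spread),
    type = rep(c("alpha", "beta", "delta"), c(n_alpha, n_beta, n_delta)),
    radius = radius)
  path <- tempfile(fileext = ".csv")
  write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  path
}

# independent R re-implementation of the Potts Hamiltonian (oracle):
# brute-force double loop over sites and neighbor offsets
r_total_energy <- function(lattice, types, J, neighbor_order, target_vol,
                           vol_lambda, frozen) {
  dims <- dim(lattice)
  offs <- list()
  for (dk in -1:1) for (dj in -1:1) for (di in -1:1) {
    m <- abs(di) + abs(dj) + abs(dk)
    if (m == 0 || m > neighbor_order) next
    offs[[length(offs) + 1L]] <- c(di, dj, dk)
  }
  type_of <- function(id) if (id == 0L) "medium" else types[id]
  H <- 0
  for (k in seq_len(dims[3])) for (j in seq_len(dims[2]))
    for (i in seq_len(dims[1])) {
      id1 <- lattice[i, j, k]
      for (o in offs) {
        i2 <- i + o[1]; j2 <- j + o[2]; k2 <- k + o[3]
        if (i2 < 1 || i2 > dims[1] || j2 < 1 || j2 > dims[2] ||
            k2 < 1 || k2 > dims[3]) next
        id2 <- lattice[i2, j2, k2]
        if (id2 != id1) H <- H + J[type_of(id1), type_of(id2)] / 2
      }
    }
  vols <- tabulate(lattice[lattice > 0L], length(types))
  for (e in seq_along(types)) {
    if (frozen[e] || target_vol[e] < 0) next
    H <- H + vol_lambda[e] * (vols[e] - target_vol[e])^2
  }
  H
}

# breadth-first-search reachability oracle on a blocked lattice (6-conn)
bfs_reachable <- function(blocked, start, goal) {
  dims <- dim(blocked)
  idx <- function(p) p[1] + dims[1] * ((p[2] - 1) + dims[2] * (p[3] - 1))
  visited <- array(FALSE, dims)
  queue <- matrix(start + 1L, ncol = 3)
  visited[queue] <- TRUE
  goal1 <- goal + 1L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    if (all(cur == goal1)) return(TRUE)
    for (r in 1:6) {
      nb <- cur + offs[r, ]
      if (any(nb < 1) || any(nb > dims)) next
      if (blocked[nb] || visited[nb]) next
      visited[nb] <- TRUE
      queue <- rbind(queue, nb)
    }
  }
  FALSE
}

# exact closed form of the 1-D slab steady state with zeroth-order
# consumption and Dirichlet C0 at x = 0 and x = L (dead core handled)
slab_closed_form <- function(x, L, C0, lam, D) {
  xd <- sqrt(2 * D * C0 / lam)
  if (xd >= L / 2) {
    C0 - lam / (2 * D) * x * (L - x)
  } else {
    ifelse(x <= xd, C0 - lam / D * (xd * x - x^2 / 2),
           ifelse(x >= L - xd,
                  C0 - lam / D * (xd * (L - x) - (L - x)^2 / 2), 0))
  }
}
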