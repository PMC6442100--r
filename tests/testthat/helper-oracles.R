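# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force pair enumeration instead of cell
# lists, explicit bookkeeping instead of closed forms, plain BFS instead of
# the compiled percolation kernel.

# All-pairs DPD forces (conservative + optional dissipative + bonds), no
# neighbor list, minimum image by nearest-integer shift.
oracle_forces <- function(system, params, arep, dissipative = TRUE) {
  pos <- system$positions
  vel <- system$velocities
  n <- nrow(pos)
  F <- matrix(0, n, 3)
  W <- numeric(3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - system$box * round(d / system$box)
      r <- sqrt(sum(d^2))
      if (r < 1 && r > 1e-10) {
        w <- 1 - r
        e <- d / r
        a <- arep[system$types[i], system$types[j]]
        fc <- a * w
        fm <- fc
        if (dissipative)
          fm <- fm - params$gamma * w^2 * sum(e * (vel[i, ] - vel[j, ]))
        F[i, ] <- F[i, ] + fm * e
        F[j, ] <- F[j, ] - fm * e
        W <- W + fc * e * d
      }
    }
  }
  if (nrow(system$bonds)) {
    for (b in seq_len(nrow(system$bonds))) {
      i <- system$bonds[b, 1]; j <- system$bonds[b, 2]
      d <- pos[i, ] - pos[j, ]
      d <- d - system$box * round(d / system$box)
      r <- sqrt(sum(d^2))
      fm <- -params$bond_k * (r - params$bond_r0)
      e <- d / r
      F[i, ] <- F[i, ] + fm * e
      F[j, ] <- F[j, ] - fm * e
      W <- W + fm * e * d
    }
  }
  list(forces = F, virial = W)
}

# Mass-balance bookkeeping for the Franz cell: track the drug removed with
# each withdrawn aliquot explicitly.
oracle_cumulative <- function(C, V, V0, A) {
  removed <- 0
  Q <- numeric(length(C))
  for (n in seq_along(C)) {
    Q[n] <- (C[n] * V + removed) / A
    removed <- removed + C[n] * V0
  }
  Q
}

# Plain-R spanning check: BFS over occupied voxels, periodic wrap in the
# transverse axes, open boundaries along `axis`.
oracle_percolates <- function(grid, axis) {
  dims <- dim(grid)
  idx_all <- which(grid, arr.ind = TRUE)
  if (!nrow(idx_all)) return(FALSE)
  key <- function(c3) paste(c3, collapse = ",")
  occ <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx_all))) assign(key(idx_all[r, ]), TRUE, occ)
  start <- idx_all[idx_all[, axis] == 1, , drop = FALSE]
  seen <- new.env(hash = TRUE)
  queue <- lapply(seq_len(nrow(start)), function(r) start[r, ])
  for (c3 in queue) assign(key(c3), TRUE, seen)
  while (length(queue)) {
    c3 <- queue[[1]]; queue <- queue[-1]
    if (c3[axis] == dims[axis]) return(TRUE)
    for (d in 1:3) for (s in c(-1, 1)) {
      nb <- c3
      nb[d] <- nb[d] + s
      if (d == axis) {
        if (nb[d] < 1 || nb[d] > dims[d]) next
      } else {
        nb[d] <- ((nb[d] - 1) %% dims[d]) + 1
      }
      k <- key(nb)
      if (!is.null(occ[[k]]) && is.null(seen[[k]])) {
        assign(k, TRUE, seen)
        queue[[length(queue) + 1]] <- nb
      }
    }
  }
  FALSE
}

# Trajectory of independent Gaussian random walkers with per-axis step
# variance 2 D dt (ground truth for the diffusivity estimator).
random_walk_traj <- function(D, n_frames, n_walkers, dt = 1, seed = 1) {
  set.seed(seed)
  frames <- vector("list", n_frames)
  pos <- matrix(0, n_walkers, 3)
  frames[[1]] <- pos
  sdstep <- sqrt(2 * D * dt)
  for (k in 2:n_frames) {
    pos <- pos + matrix(rnorm(n_walkers * 3, 0, sdstep), n_walkers, 3)
    frames[[k]] <- pos
  }
  traj <- structure(list(times = (seq_len(n_frames) - 1) * dt,
                         positions = frames, positions_wrapped = frames,
                         velocities = NULL,
                         types = rep("WATER", n_walkers),
                         box = rep(Inf, 3), kinetic_T = NULL,
                         pressure = NULL, momentum = NULL, params = NULL),
                    class = "dpd_trajectory")
  attr(traj, "unwrapped") <- TRUE
  traj
}

# Small water box used by several engine tests.
small_water_system <- function(n = 375, params = dpd_params(), seed = 1) {
  init_system(c(WATER = n), default_box(n, params$rho), params, seed = seed)
}
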