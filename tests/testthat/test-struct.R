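test_that("density field conserves the water bead count and averages correctly", {
  p <- dpd_params(n_steps = 200, equil_steps = 100, sample_every = 100)
  sys <- small_water_system(648, p, seed = 2)
  traj <- dpd_run(sys, p, seed = 2)
  fld <- water_density_field(traj, 12)
  voxel <- prod(traj$box) / prod(dim(fld$grid))
  expect_equal(sum(fld$grid) * voxel, 648, tolerance = 0.01)
  expect_true(all(fld$grid >= 0))
  # uniform box: voxel counts are ~Poisson, CV ~ 1/sqrt(mean count)
  mean_count <- 648 * length(traj$positions) / prod(dim(fld$grid))
  cv <- sd(fld$grid) / mean(fld$grid)
  expect_lt(abs(cv - 1 / sqrt(mean_count)) / (1 / sqrt(mean_count)), 0.25)
  # averaging a frozen system is idempotent: duplicate the frames
  traj2 <- traj
  traj2$positions_wrapped <- c(traj$positions_wrapped,
                               traj$positions_wrapped)
  traj2$positions <- c(traj$positions, traj$positions)
  traj2$times <- c(traj$times, traj$times + max(traj$times))
  fld2 <- water_density_field(traj2, 12)
  expect_equal(fld2$grid, fld$grid, tolerance = 1e-12)
  # beads confined to one octant leave the rest empty
  traj3 <- traj
  traj3$positions_wrapped <- lapply(traj$positions_wrapped,
                                    function(x) x / 2)
  fld3 <- water_density_field(traj3, 12)
  expect_true(all(fld3$grid[, , 7:12] == 0))
  expect_error(water_density_field(traj, 4), "at least 8")
})

test_that("compiled percolation agrees with a plain BFS oracle and the D nodal surface percolates triply", {
  set.seed(42)
  for (i in 1:8) {
    g <- array(runif(8^3) < runif(1, 0.2, 0.6), dim = c(8, 8, 8))
    for (ax in 1:3)
      expect_identical(
        cubiphase:::percolates_cpp(as.vector(g), dim(g), ax),
        oracle_percolates(g, ax),
        info = sprintf("grid %d axis %d", i, ax))
  }
  # both level sets of the Schwarz D nodal field span all three axes
  fld <- gen_density_field("bicontinuous_cubic", grid_n = 32, noise = 0)
  rich <- fld$grid > mean(fld$grid)
  for (ax in 1:3) {
    expect_true(oracle_percolates(rich, ax))
    expect_true(oracle_percolates(!rich, ax))
  }
})

test_that("the classifier labels constructed fields by their designed structure", {
  # single-wavevector stack -> lamellar
  lam <- gen_density_field("lamellar", grid_n = 32, noise = 0)
  expect_identical(classify_phase(lam)$label, "lamellar")
  # Schwarz D nodal field -> bicontinuous cubic
  cub <- gen_density_field("bicontinuous_cubic", grid_n = 32, noise = 0)
  call <- classify_phase(cub)
  expect_identical(call$label, "bicontinuous_cubic")
  expect_lt(call$diagnostics$direction_share, 0.6)
  expect_true(all(call$diagnostics$percolation))
  # constant + white noise -> disordered
  dis <- gen_density_field("disordered", grid_n = 32, seed = 3)
  expect_identical(classify_phase(dis)$label, "disordered")
  # degenerate constant field -> disordered with a warning
  flat <- density_field(array(2, dim = c(8, 8, 8)), 10)
  expect_warning(res <- classify_phase(flat), "constant")
  expect_identical(res$label, "disordered")
})

test_that("the phase label is invariant under axis relabeling", {
  for (phase in c("lamellar", "bicontinuous_cubic")) {
    fld <- gen_density_field(phase, grid_n = 24, noise = 0.05, seed = 5)
    base <- classify_phase(fld)$label
    for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
      rot <- density_field(aperm(fld$grid, perm), fld$box[perm])
      expect_identical(classify_phase(rot)$label, base,
                       info = paste(phase, paste(perm, collapse = "")))
    }
  }
})

test_that("diffusivity estimator recovers the step variance of constructed random walks", {
  for (D in c(0.05, 0.25, 1.0)) {
    traj <- random_walk_traj(D, n_frames = 400, n_walkers = 4000,
                             seed = round(100 * D))
    res <- water_diffusivity(traj)
    expect_lt(abs(res$D_water - D) / D, 0.05)
    # MSD curve starts at zero and grows
    expect_equal(res$msd_curve$msd[1], 0)
    sm <- stats::filter(res$msd_curve$msd, rep(1 / 51, 51), sides = 2)
    expect_true(all(diff(sm[!is.na(sm)]) > -1e-9 * max(res$msd_curve$msd)))
  }
  # frozen beads have zero diffusivity
  frozen <- random_walk_traj(0, n_frames = 50, n_walkers = 20)
  expect_equal(water_diffusivity(frozen)$D_water, 0)
  # wrapped-only trajectories are rejected
  t2 <- random_walk_traj(0.1, 50, 10)
  attr(t2, "unwrapped") <- FALSE
  expect_error(water_diffusivity(t2), "unwrapped")
})

test_that("tension estimator matches a frame-wise virial recomputation and is near zero for a homogeneous fluid", {
  p <- dpd_params(n_steps = 300, equil_steps = 100, sample_every = 100)
  sys <- small_water_system(100, p, seed = 8)
  traj <- dpd_run(sys, p, seed = 8)
  ten <- surface_tension(traj, axis = 3)
  # recompute each frame's gamma from stored positions/velocities
  arep <- matrix(p$a_ii, 1, 1, dimnames = list("WATER", "WATER"))
  for (k in seq_along(traj$times)) {
    frame_sys <- structure(list(box = traj$box,
                                positions = traj$positions_wrapped[[k]],
                                velocities = traj$velocities[[k]],
                                types = traj$types,
                                bonds = matrix(0L, 0, 2)),
                           class = "bead_system")
    W <- oracle_forces(frame_sys, p, arep)$virial
    kin <- colSums(traj$velocities[[k]]^2)
    P <- (kin + W) / prod(traj$box)
    gamma_k <- (traj$box[3] / 2) * (P[3] - (P[1] + P[2]) / 2)
    expect_equal(ten$per_frame[k], gamma_k, tolerance = 1e-10)
  }
  # isotropy: x- and y-normal estimates agree within statistical error
  p2 <- dpd_params(n_steps = 4000, equil_steps = 1000, sample_every = 100)
  sys2 <- small_water_system(1029, p2, seed = 9)
  traj2 <- dpd_run(sys2, p2, seed = 9)
  gx <- surface_tension(traj2, axis = 1)$gamma_mean
  gy <- surface_tension(traj2, axis = 2)$gamma_mean
  pooled_sd <- sd(surface_tension(traj2, axis = 1)$per_frame)
  expect_lt(abs(gx - gy), 4 * pooled_sd / sqrt(length(traj2$times)) + 0.05)
  expect_error(surface_tension(structure(list(pressure = NULL),
                                         class = "dpd_trajectory")),
               "pressure")
})
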