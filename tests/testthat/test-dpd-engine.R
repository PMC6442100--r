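test_that("params constructor enforces fluctuation-dissipation and sane ranges", {
  p <- dpd_params()
  expect_equal(p$sigma^2, 2 * p$gamma * p$kT)
  expect_error(dpd_params(sigma = 2, gamma = 4.5), "fluctuation-dissipation")
  expect_error(dpd_params(dt = 0), "dt")
  expect_error(dpd_params(lambda = 1.5), "lambda")
})

test_that("initialized systems have zero momentum, equipartition energy, and are seed-deterministic", {
  p <- dpd_params()
  sys <- init_system(c(A = 200, B = 200, WATER = 800), default_box(1200),
                     p, seed = 7)
  expect_lt(max(abs(colSums(sys$velocities))), 1e-10)
  ke <- mean(rowSums(sys$velocities^2)) / 2
  expect_lt(abs(ke - 1.5) / 1.5, 0.05)
  # bonded partners sit at the rest length
  d <- sys$positions[sys$bonds[, 1], ] - sys$positions[sys$bonds[, 2], ]
  d <- d - sweep(round(sweep(d, 2, sys$box, "/")), 2, sys$box, "*")
  expect_equal(unname(sqrt(rowSums(d^2))), rep(p$bond_r0, 200),
               tolerance = 1e-9)
  sys2 <- init_system(c(A = 200, B = 200, WATER = 800), default_box(1200),
                      p, seed = 7)
  expect_identical(sys$positions, sys2$positions)
  expect_identical(sys$velocities, sys2$velocities)
  # box/density inconsistency is rejected
  expect_error(init_system(c(WATER = 1200), c(5, 5, 5), p), "inconsistent")
  # A/B count mismatch is rejected
  expect_error(init_system(c(A = 10, B = 9, WATER = 281),
                           default_box(300), p), "equal")
})

test_that("pair forces match hand arithmetic, vanish beyond cutoff, and obey Newton's third law", {
  p <- dpd_params()
  # two like beads at r = 0.5: |F| = 25 * (1 - 0.5) = 12.5
  sys <- structure(list(box = c(6, 6, 6),
                        positions = rbind(c(1, 1, 1), c(1.5, 1, 1)),
                        velocities = matrix(0, 2, 3),
                        types = c("WATER", "WATER"),
                        bonds = matrix(0L, 0, 2)),
                   class = "bead_system")
  f <- dpd_forces(sys, p)
  expect_equal(f$forces[1, ], c(-12.5, 0, 0))
  expect_equal(f$forces[2, ], c(12.5, 0, 0))
  # beyond the cutoff all terms vanish (unbonded)
  sys$positions[2, 1] <- 2.1
  f2 <- dpd_forces(sys, p, include_random = TRUE, seed = 3)
  expect_equal(f2$forces, matrix(0, 2, 3))
  # random kicks on: total force still zero (pairwise symmetric noise)
  sys3 <- small_water_system(300, p, seed = 2)
  f3 <- dpd_forces(sys3, p, include_random = TRUE, seed = 11)
  expect_lt(max(abs(colSums(f3$forces))), 1e-9)
})

test_that("cell-list forces equal the brute-force pair enumeration oracle", {
  p <- dpd_params()
  arep <- chi_to_repulsion(default_chi_matrix())
  # mixed bonded system, box large enough for cell lists
  sys <- init_system(c(A = 30, B = 30, WATER = 120, ETHANOL = 15, MET = 5),
                     default_box(200), p, seed = 5)
  got <- dpd_forces(sys, p, arep, include_dissipative = TRUE)
  want <- oracle_forces(sys, p, arep, dissipative = TRUE)
  expect_equal(got$forces, want$forces, tolerance = 1e-12)
  expect_equal(got$virial, want$virial, tolerance = 1e-12)
  # tiny box exercises the all-pairs fallback; 3 beads as the minimal case
  sys2 <- structure(list(box = c(2.5, 2.5, 2.5),
                         positions = rbind(c(0.2, 0.3, 0.4),
                                           c(0.8, 0.5, 0.6),
                                           c(2.3, 2.4, 0.1)),
                         velocities = matrix(rnorm(9, sd = 0.5), 3, 3),
                         types = c("A", "B", "WATER"),
                         bonds = matrix(c(1L, 2L), 1, 2)),
                    class = "bead_system")
  got2 <- dpd_forces(sys2, p, arep)
  want2 <- oracle_forces(sys2, p, arep)
  expect_equal(got2$forces, want2$forces, tolerance = 1e-12)
})

test_that("a bonded dimer in a quiet box oscillates harmonically about the rest length", {
  p <- dpd_params(gamma = 0, a_ii = 0, n_steps = 200, equil_steps = 0,
                  sample_every = 1, bond_k = 100, bond_r0 = 0.7)
  delta <- 0.05
  sys <- structure(list(box = c(5, 5, 5),
                        positions = rbind(c(2, 2, 2), c(2 + p$bond_r0 + delta, 2, 2)),
                        velocities = matrix(0, 2, 3),
                        types = c("A", "B"),
                        bonds = matrix(c(1L, 2L), 1, 2)),
                   class = "bead_system")
  arep <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  traj <- dpd_run(sys, p, arep)
  sep <- vapply(traj$positions, function(x) abs(x[2, 1] - x[1, 1]), 1)
  # bounded oscillation about r0 with the initial amplitude
  expect_lt(max(sep), p$bond_r0 + delta + 1e-3)
  expect_gt(min(sep), p$bond_r0 - delta - 1e-3)
  expect_equal(mean(sep), p$bond_r0, tolerance = 0.01)
  # angular frequency sqrt(2k) for the relative coordinate (reduced mass 1/2)
  zero_cross <- which(diff(sign(sep - p$bond_r0)) != 0)
  period_est <- 2 * mean(diff(traj$times[zero_cross]))
  expect_equal(period_est, 2 * pi / sqrt(2 * p$bond_k), tolerance = 0.05)
})

test_that("thermostat holds kT = 1 and conserves momentum on a pure-water box", {
  p <- dpd_params(n_steps = 1500, equil_steps = 500, sample_every = 50)
  sys <- small_water_system(1029, p, seed = 3)
  traj <- dpd_run(sys, p, seed = 3)
  expect_lt(abs(mean(traj$kinetic_T) - 1), 0.03)
  expect_lt(max(abs(traj$momentum)), 1e-8)
})

test_that("identical parameters and seed give bit-identical trajectories", {
  p <- dpd_params(n_steps = 300, equil_steps = 100, sample_every = 50)
  sys <- small_water_system(375, p, seed = 4)
  t1 <- dpd_run(sys, p, seed = 9)
  t2 <- dpd_run(sys, p, seed = 9)
  expect_identical(t1$positions, t2$positions)
  expect_identical(t1$pressure, t2$pressure)
  t3 <- dpd_run(sys, p, seed = 10)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("with zero conservative repulsion the pressure approaches the ideal-gas value", {
  p <- dpd_params(a_ii = 0, n_steps = 2000, equil_steps = 500,
                  sample_every = 50)
  sys <- small_water_system(1029, p, seed = 6)
  traj <- dpd_run(sys, p, seed = 6)
  expect_lt(abs(mean(traj$pressure) - p$rho * p$kT) / (p$rho * p$kT), 0.02)
})
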