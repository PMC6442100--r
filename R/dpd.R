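#' Simulation constants for the DPD engine
#'
#' Defaults follow the standard Groot-Warren parameterization: bead density
#' rho = 3 r_c^-3, like-bead repulsion a_ii = 25 kT/r_c, dissipative
#' coefficient gamma = 4.5, timestep 0.04 tau, velocity-Verlet prediction
#' factor lambda = 0.65, with r_c = kT = 1 defining the units. The noise
#' amplitude is tied to gamma by the fluctuation-dissipation relation
#' sigma^2 = 2 gamma kT, enforced at construction. GMO head and tail beads
#' are joined by a harmonic spring (`bond_k`, `bond_r0`).
#'
#' @param rho Bead number density (r_c^-3).
#' @param a_ii Like-bead repulsion (kT/r_c).
#' @param gamma Dissipative coefficient.
#' @param sigma Noise amplitude; if supplied it must satisfy
#'   `sigma^2 == 2 * gamma * kT`.
#' @param dt Timestep (DPD time units).
#' @param lambda Velocity-Verlet prediction factor, in (0, 1].
#' @param kT Thermostat target (1 in reduced units).
#' @param bond_k,bond_r0 Harmonic A-B bond constants (kT/r_c^2, r_c).
#' @param seed RNG seed for the pairwise thermostat noise.
#' @param n_steps Production steps.
#' @param equil_steps Equilibration steps (not sampled).
#' @param sample_every Sampling interval in steps.
#' @return An object of class `dpd_params`.
#' @examples
#' dpd_params()
#' @export
dpd_params <- function(rho = 3, a_ii = 25, gamma = 4.5, sigma = NULL,
                       dt = 0.04, lambda = 0.65, kT = 1,
                       bond_k = 100, bond_r0 = 0.7, seed = 1,
                       n_steps = 12000, equil_steps = 6000,
                       sample_every = 100) {
  if (rho <= 0) stop("rho must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (lambda <= 0 || lambda > 1) stop("lambda must be in (0, 1]")
  if (gamma < 0) stop("gamma must be non-negative")
  sigma_fd <- sqrt(2 * gamma * kT)
  if (is.null(sigma)) {
    sigma <- sigma_fd
  } else if (abs(sigma^2 - 2 * gamma * kT) > 1e-9) {
    stop("fluctuation-dissipation violated: need sigma^2 = 2 * gamma * kT (",
         signif(sigma_fd, 6), ")")
  }
  structure(list(rho = rho, a_ii = a_ii, gamma = gamma, sigma = sigma,
                 dt = dt, lambda = lambda, r_c = 1, kT = kT,
                 bond_k = bond_k, bond_r0 = bond_r0, seed = seed,
                 n_steps = as.integer(n_steps),
                 equil_steps = as.integer(equil_steps),
                 sample_every = as.integer(sample_every)),
            class = "dpd_params")
}

#' Map a formulation's mass composition to bead counts
#'
#' Bead numbers are proportional to mole numbers `mass_parts_i / M_i`, with
#' one water bead lumping `molecules_per_bead` water molecules and each GMO
#' mole contributing exactly one A and one B bead. Counts are rounded so
#' that the A and B counts are identical; the total lands within 5% of
#' `n_target`.
#'
#' @param f A [formulation()].
#' @param species Species table, see [species_table()].
#' @param n_target Approximate total bead count (>= 100).
#' @return List with `counts` (named integer vector over A, B, WATER,
#'   ETHANOL, MET) and `mass_fractions` (realized mass fractions).
#' @examples
#' f4 <- formulation("F4", 64, 6, 30, 5)
#' map_composition(f4, n_target = 3000)$counts
#' @export
map_composition <- function(f, species = species_table(), n_target = 3000) {
  stopifnot(inherits(f, "formulation"))
  if (n_target < 100) stop("n_target must be at least 100")
  mp <- f$mass_parts
  if (sum(mp) <= 0) stop("all-zero composition")
  M <- setNames(species$molar_mass, species$id)
  mpb <- setNames(species$molecules_per_bead, species$id)
  gmo_M <- M[["A"]] + M[["B"]]
  gmo_mol <- mp[["gmo"]] / gmo_M
  beads <- c(
    A = gmo_mol,
    B = gmo_mol,
    WATER = mp[["water"]] / (M[["WATER"]] * mpb[["WATER"]]),
    ETHANOL = mp[["ethanol"]] / (M[["ETHANOL"]] * mpb[["ETHANOL"]]),
    MET = mp[["met"]] / (M[["MET"]] * mpb[["MET"]])
  )
  counts <- round(beads * n_target / sum(beads))
  counts[["B"]] <- counts[["A"]]   # dimer pairing is exact by construction
  counts <- as.integer(counts)
  names(counts) <- names(beads)
  if (sum(counts) == 0) stop("composition maps to zero beads")
  mass <- counts * M[names(beads)] * mpb[names(beads)]
  list(counts = counts, mass_fractions = mass / sum(mass))
}

#' Cubic box edge matching a bead count at a given density
#'
#' @param n_total Total bead count.
#' @param rho Bead number density.
#' @return Length-3 vector of box edges (r_c).
#' @export
default_box <- function(n_total, rho = 3) {
  rep((n_total / rho)^(1 / 3), 3)
}

#' Initialize a bead system from species counts
#'
#' Positions are uniform in the periodic box; each A bead's bonded B partner
#' is placed at the bond rest length in a random direction. Velocities are
#' Maxwell-Boltzmann at kT with the center-of-mass motion removed, so the
#' total momentum is exactly zero.
#'
#' @param counts Named integer vector of bead counts (A, B, WATER, ETHANOL,
#'   MET; missing species are taken as 0). A and B counts must be equal.
#' @param box Box edge lengths (scalar or length 3), r_c units.
#' @param params A [dpd_params()]; its `rho` must be consistent with
#'   `sum(counts) / prod(box)` within 1%.
#' @param seed RNG seed (uses R's RNG through a local stream).
#' @return An object of class `bead_system` with elements `box`, `positions`,
#'   `velocities`, `types`, `bonds`.
#' @export
init_system <- function(counts, box, params = dpd_params(), seed = 1) {
  if (length(box) == 1) box <- rep(box, 3)
  stopifnot(length(box) == 3, all(box > 0))
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 1) stop("no beads")
  nA <- if ("A" %in% names(counts)) counts[["A"]] else 0L
  nB <- if ("B" %in% names(counts)) counts[["B"]] else 0L
  if (!isTRUE(all.equal(nA, nB)))
    stop("A and B bead counts must be equal (bonded dimers)")
  rho_actual <- n / prod(box)
  if (abs(rho_actual - params$rho) / params$rho > 0.01)
    stop(sprintf("box/density inconsistent: %d beads in volume %.2f gives rho %.3f, params say %.3f",
                 n, prod(box), rho_actual, params$rho))
  with_seed(seed, {
    types <- character(0)
    pos <- matrix(0, 0, 3)
    bonds <- matrix(0L, 0, 2)
    if (nA > 0) {
      pa <- cbind(runif(nA, 0, box[1]), runif(nA, 0, box[2]),
                  runif(nA, 0, box[3]))
      u <- matrix(rnorm(3 * nA), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pb <- pa + params$bond_r0 * u
      pos <- rbind(pa, pb)
      types <- c(rep("A", nA), rep("B", nB))
      bonds <- cbind(seq_len(nA), nA + seq_len(nA))
    }
    for (sp in setdiff(names(counts), c("A", "B"))) {
      k <- counts[[sp]]
      pos <- rbind(pos, cbind(runif(k, 0, box[1]), runif(k, 0, box[2]),
                              runif(k, 0, box[3])))
      types <- c(types, rep(sp, k))
    }
    pos <- sweep(pos, 2, box, function(x, L) x - L * floor(x / L))
    vel <- matrix(rnorm(nrow(pos) * 3, sd = sqrt(params$kT)), ncol = 3)
    vel <- sweep(vel, 2, colMeans(vel))
    structure(list(box = box, positions = pos, velocities = vel,
                   types = types, bonds = bonds),
              class = "bead_system")
  })
}

#' @export
print.bead_system <- function(x, ...) {
  cat(sprintf("<bead_system> %d beads in %.2f x %.2f x %.2f box; %d bonds\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3], nrow(x$bonds)))
  print(table(x$types))
  invisible(x)
}

# Map character bead types to 0-based codes matching the repulsion matrix.
.type_codes <- function(types, arep) {
  ids <- rownames(arep)
  code <- match(types, ids) - 1L
  if (anyNA(code))
    stop("bead types not in repulsion matrix: ",
         paste(unique(types[is.na(code)]), collapse = ", "))
  code
}

#' Evaluate DPD pair forces on a bead system
#'
#' Conservative soft repulsion \eqn{F_C = a_{ij}(1 - r/r_c)\hat r} for
#' r < r_c, pairwise dissipative drag
#' \eqn{F_D = -\gamma w(r)^2 (\hat r \cdot v_{ij}) \hat r} and symmetric
#' random kicks \eqn{F_R = \sigma w(r) \theta_{ij} \hat r / \sqrt{dt}}, plus
#' harmonic A-B bond forces. Newton's third law holds pairwise, so the
#' force sum is zero to round-off. The returned virial is the conservative
#' (including bond) contribution to the diagonal pressure-tensor components.
#'
#' @param system A [init_system()] bead system.
#' @param params A [dpd_params()].
#' @param arep Repulsion matrix from [chi_to_repulsion()]; defaults to the
#'   like-bead value for all pairs present.
#' @param include_dissipative,include_random Switch the thermostat terms on
#'   or off (deterministic force checks use `include_random = FALSE`).
#' @param seed Seed for the pairwise noise stream.
#' @return List with `forces` (n x 3) and `virial` (length-3 diagonal).
#' @export
dpd_forces <- function(system, params = dpd_params(), arep = NULL,
                       include_dissipative = TRUE, include_random = FALSE,
                       seed = params$seed) {
  stopifnot(inherits(system, "bead_system"))
  if (is.null(arep)) {
    ids <- sort(unique(system$types))
    arep <- matrix(params$a_ii, length(ids), length(ids),
                   dimnames = list(ids, ids))
  }
  code <- .type_codes(system$types, arep)
  bonds0 <- if (nrow(system$bonds)) system$bonds - 1L else
    matrix(0L, 0, 2)
  dpd_forces_cpp(system$positions, system$velocities, code,
                 bonds0, system$box, arep,
                 params$gamma, params$sigma, params$dt,
                 params$bond_k, params$bond_r0,
                 include_dissipative, include_random, seed)
}

#' Run a DPD simulation
#'
#' Integrates the system with the modified velocity-Verlet scheme
#' (prediction factor lambda), records frames every `sample_every` steps
#' after `equil_steps` equilibration steps, and stores per-frame kinetic
#' temperature, diagonal pressure-tensor components (ideal + conservative
#' virial) and total momentum. With a fixed seed the trajectory is
#' bit-reproducible (single-threaded).
#'
#' @param system A [init_system()] bead system.
#' @param params A [dpd_params()].
#' @param arep Repulsion matrix (see [chi_to_repulsion()]); defaults to
#'   `a_ii` everywhere.
#' @param seed Thermostat noise seed; defaults to `params$seed`.
#' @param store_velocities Keep per-frame velocities (needed to re-derive
#'   pressures; default TRUE).
#' @return An object of class `dpd_trajectory`: `times`, `positions`
#'   (unwrapped, for displacement statistics), `positions_wrapped`,
#'   `velocities`, `types`, `box`, `kinetic_T`, `pressure` (frames x 3),
#'   `momentum` (frames x 3), `params`.
#' @export
dpd_run <- function(system, params = dpd_params(), arep = NULL,
                    seed = params$seed, store_velocities = TRUE) {
  stopifnot(inherits(system, "bead_system"))
  if (is.null(arep)) {
    ids <- sort(unique(system$types))
    arep <- matrix(params$a_ii, length(ids), length(ids),
                   dimnames = list(ids, ids))
  }
  code <- .type_codes(system$types, arep)
  bonds0 <- if (nrow(system$bonds)) system$bonds - 1L else matrix(0L, 0, 2)
  out <- dpd_run_cpp(system$positions, system$velocities, code, bonds0,
                     system$box, arep, params$gamma, params$sigma,
                     params$dt, params$lambda,
                     params$bond_k, params$bond_r0,
                     params$n_steps, params$equil_steps,
                     params$sample_every, seed, store_velocities)
  traj <- structure(list(times = out$times, positions = out$positions,
                         positions_wrapped = out$positions_wrapped,
                         velocities = out$velocities, types = system$types,
                         box = system$box, kinetic_T = out$kinetic_T,
                         pressure = out$pressure, momentum = out$momentum,
                         params = params, seed = seed),
                    class = "dpd_trajectory")
  attr(traj, "unwrapped") <- TRUE
  traj
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf("<dpd_trajectory> %d frames x %d beads, t in [%.2f, %.2f] tau\n",
              length(x$times), length(x$types),
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  cat(sprintf("  mean kinetic T = %.4f, box = %.2f x %.2f x %.2f\n",
              mean(x$kinetic_T), x$box[1], x$box[2], x$box[3]))
  invisible(x)
}
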