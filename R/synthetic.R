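#' Six reference GMO/ethanol/water/Met formulations
#'
#' The standard composition series F1-F6 used throughout: GMO/ethanol/
#' water/Met = 64/x/30/5 (w/w/w/w) with ethanol parts x = 0, 2, 4, 6, 8,
#' 10.
#'
#' @return List of six [formulation()] objects.
#' @examples
#' reference_formulation_table()[[4]]   # F4: 64/6/30/5
#' @export
reference_formulation_table <- function() {
  eth <- c(0, 2, 4, 6, 8, 10)
  lapply(seq_along(eth), function(i)
    formulation(paste0("F", i), gmo = 64, ethanol = eth[i], water = 30,
                met = 5))
}

#' Generate a synthetic SAXS peak list with known ground truth
#'
#' Peaks at q = 2 pi sqrt(N) / a for the first `n_peaks` allowed
#' reflections of the chosen symmetry, optionally starting `offset`
#' reflections in (so `offset = 3` for Pn3m starts at the sqrt(6)
#' reflection). Each peak is perturbed multiplicatively by
#' Normal(0, noise_rel). The generating truth is attached as attribute
#' `"truth"`.
#'
#' @param group Symmetry, one of `names(saxs_groups())`.
#' @param lattice_constant Ground-truth lattice constant (Angstrom).
#' @param n_peaks Number of peaks.
#' @param noise_rel Relative noise SD (>= 0).
#' @param seed RNG seed.
#' @param offset Number of leading allowed reflections skipped (default 0).
#' @return A [peak_list()] with attribute `truth`.
#' @examples
#' gen_saxs_peaks("Pn3m", 134, n_peaks = 2, noise_rel = 0, offset = 3)
#' @export
gen_saxs_peaks <- function(group, lattice_constant, n_peaks = 4,
                           noise_rel = 0, seed = 1, offset = 0) {
  groups <- saxs_groups()
  if (!group %in% names(groups)) stop("unsupported symmetry: ", group)
  if (noise_rel < 0) stop("noise_rel must be non-negative")
  seqN <- groups[[group]]
  if (offset + n_peaks > length(seqN))
    stop("offset + n_peaks exceeds the stored reflection sequence")
  N <- seqN[(offset + 1):(offset + n_peaks)]
  q <- 2 * pi * sqrt(N) / lattice_constant
  q <- with_seed(seed, q * (1 + rnorm(n_peaks, 0, noise_rel)))
  q <- sort(q)
  pk <- peak_list(q, sample = sprintf("synthetic_%s", group))
  attr(pk, "truth") <- list(group = group,
                            lattice_constant = lattice_constant,
                            N = N, noise_rel = noise_rel, offset = offset,
                            seed = seed)
  pk
}

#' Generate a synthetic Franz-cell series with known flux and lag
#'
#' The target profile Q(t) = max(0, Jss (t - Tlag)) is inverted exactly
#' through the aliquot-correction relation in sampling order
#' (C_n = (A Q_n - V0 sum C_i) / V), then multiplied by (1 + eps) noise.
#' With zero noise, [cumulative_amount()] applied to the result returns
#' the target profile exactly.
#'
#' @param Jss Steady-state flux (ug cm^-2 h^-1, >= 0).
#' @param Tlag Lag time (h).
#' @param times Sampling times (h), ascending.
#' @param V,V0,A Cell geometry, see [permeation_series()].
#' @param noise_rel Relative concentration noise SD.
#' @param seed RNG seed.
#' @param label Series label.
#' @return A [permeation_series()] with attribute `truth`.
#' @export
gen_permeation_series <- function(Jss, Tlag = 0.3,
                                  times = c(0.5, 1, 2, 3, 4, 5),
                                  V = 10, V0 = 1, A = 0.785,
                                  noise_rel = 0, seed = 1, label = "synthetic") {
  if (Jss < 0) stop("Jss must be non-negative")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be ascending")
  Q <- pmax(0, Jss * (times - Tlag))
  C <- numeric(length(Q))
  for (n in seq_along(Q)) {
    prior <- if (n > 1) sum(C[1:(n - 1)]) else 0
    C[n] <- (A * Q[n] - V0 * prior) / V
    if (C[n] < -1e-9)
      stop("inversion produced a negative concentration; Tlag/times inconsistent")
    C[n] <- max(0, C[n])
  }
  C <- with_seed(seed, C * (1 + rnorm(length(C), 0, noise_rel)))
  C <- pmax(0, C)
  s <- permeation_series(times, C, V = V, V0 = V0, A = A, label = label)
  attr(s, "truth") <- list(Jss = Jss, Tlag = Tlag, noise_rel = noise_rel,
                           seed = seed)
  s
}

#' Generate a synthetic xenograft study with known inhibition
#'
#' Per-mouse exponential tumor growth
#' V(t) = V0 exp(r (1 - inhibition_g) t) with lognormal measurement noise
#' of coefficient of variation `noise_cv`; caliper diameters L and W are
#' back-solved from V with a fixed aspect ratio L/W. Terminal weights are
#' proportional to each mouse's terminal volume within its group and
#' scaled so the group mean equals `w0 (1 - inhibition_g)` at zero noise —
#' hence [inhibition_rate()] on the generated weights recovers the
#' generating inhibition exactly when `noise_cv = 0`.
#'
#' @param n_per_group Mice per group (>= 2; default 6).
#' @param growth_rate Exponential growth rate r (1/day; default 0.31, which
#'   takes a 75 mm^3 implant to ~1.7 cm^3 in 10 days).
#' @param inhibition_by_group Named vector of inhibition fractions in
#'   \[0, 1); the first entry (conventionally the control) should be 0.
#' @param days Measurement days (default 0:10).
#' @param noise_cv Lognormal measurement CV (default 0.2).
#' @param seed RNG seed.
#' @param V0 Implant volume (mm^3, default 75).
#' @param aspect Fixed L/W aspect ratio (default 1.2).
#' @param w0 Control-group mean terminal weight (g, default 1.73).
#' @return List with `measurements` (mouse_id, group, day, L_mm, W_mm) and
#'   `weights` (mouse_id, group, weight_g), plus attribute `truth`.
#' @export
gen_tumor_study <- function(n_per_group = 6, growth_rate = 0.31,
                            inhibition_by_group = c(I = 0, II = 0.11,
                                                    III = 0.06, IV = 0.64),
                            days = 0:10, noise_cv = 0.2, seed = 1,
                            V0 = 75, aspect = 1.2, w0 = 1.73) {
  if (n_per_group < 2) stop("n_per_group must be at least 2")
  if (any(inhibition_by_group < 0 | inhibition_by_group >= 1))
    stop("inhibition values must lie in [0, 1)")
  gnames <- names(inhibition_by_group) %||%
    as.character(seq_along(inhibition_by_group))
  sdlog <- sqrt(log(1 + noise_cv^2))
  with_seed(seed, {
    meas <- list()
    wts <- list()
    for (g in seq_along(inhibition_by_group)) {
      inh <- inhibition_by_group[[g]]
      r_eff <- growth_rate * (1 - inh)
      Vterm <- numeric(n_per_group)
      for (m in seq_len(n_per_group)) {
        id <- sprintf("%s_m%d", gnames[g], m)
        v_true <- V0 * exp(r_eff * days)
        noise <- if (noise_cv > 0)
          exp(rnorm(length(days), -sdlog^2 / 2, sdlog)) else rep(1, length(days))
        v_obs <- v_true * noise
        # V = 0.5 L W^2 with L = aspect * W  =>  W = (2 V / aspect)^(1/3)
        W <- (2 * v_obs / aspect)^(1 / 3)
        L <- aspect * W
        meas[[length(meas) + 1]] <- data.frame(
          mouse_id = id, group = gnames[g], day = days, L_mm = L, W_mm = W,
          stringsAsFactors = FALSE)
        Vterm[m] <- v_obs[length(days)]
      }
      wt <- w0 * (1 - inh) * Vterm / mean(Vterm)
      wts[[length(wts) + 1]] <- data.frame(
        mouse_id = sprintf("%s_m%d", gnames[g], seq_len(n_per_group)),
        group = gnames[g], weight_g = wt, stringsAsFactors = FALSE)
    }
    out <- list(measurements = do.call(rbind, meas),
                weights = do.call(rbind, wts))
    attr(out, "truth") <- list(inhibition_by_group =
                                 setNames(as.numeric(inhibition_by_group),
                                          gnames),
                               growth_rate = growth_rate, V0 = V0,
                               aspect = aspect, w0 = w0,
                               noise_cv = noise_cv, seed = seed)
    out
  })
}

#' Generate a synthetic water-density field of known phase
#'
#' `bicontinuous_cubic` builds a positive-shifted Schwarz-D nodal field
#' cos x cos y cos z - sin x sin y sin z with one period per box (both
#' level sets of the D nodal surface percolate along all three axes);
#' `lamellar` builds 1 + cos(2 pi k z / L); `disordered` a positive
#' constant plus white noise. Additive Gaussian noise of amplitude `noise`
#' (times the field SD) is applied on top, and the field is shifted/clipped
#' to stay non-negative.
#'
#' @param phase One of `"bicontinuous_cubic"`, `"lamellar"`,
#'   `"disordered"`.
#' @param grid_n Grid points per axis.
#' @param box Box edge (scalar or length 3).
#' @param noise Additive noise amplitude relative to the field SD.
#' @param seed RNG seed.
#' @param k Lamellar wavenumber (periods per box, default 2).
#' @return A [density_field()] with attribute `truth`.
#' @export
gen_density_field <- function(phase, grid_n = 32, box = 10, noise = 0,
                              seed = 1, k = 2) {
  if (length(box) == 1) box <- rep(box, 3)
  ng <- rep(as.integer(grid_n), length.out = 3)
  xs <- lapply(1:3, function(d) (seq_len(ng[d]) - 0.5) / ng[d])
  grid <- switch(
    phase,
    bicontinuous_cubic = {
      X <- array(2 * pi * xs[[1]], dim = ng)
      Y <- array(rep(2 * pi * xs[[2]], each = ng[1]), dim = ng)
      Z <- array(rep(2 * pi * xs[[3]], each = ng[1] * ng[2]), dim = ng)
      nodal <- cos(X) * cos(Y) * cos(Z) - sin(X) * sin(Y) * sin(Z)
      2 + nodal
    },
    lamellar = {
      Z <- array(rep(xs[[3]], each = ng[1] * ng[2]), dim = ng)
      1 + cos(2 * pi * k * Z)
    },
    disordered = array(1, dim = ng),
    stop("unsupported phase: ", phase)
  )
  with_seed(seed, {
    s <- sd(as.vector(grid))
    amp <- if (phase == "disordered") 0.1 else noise * s
    if (phase == "disordered" || noise > 0)
      grid <- grid + array(rnorm(prod(ng), 0, max(amp, 1e-12)), dim = ng)
    grid <- pmax(grid, 0)
    fld <- density_field(array(grid, dim = ng), box)
    attr(fld, "truth") <- list(phase = phase, noise = noise, seed = seed,
                               k = k)
    fld
  })
}
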