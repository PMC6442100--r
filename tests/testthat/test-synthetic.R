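test_that("the reference formulation table carries the six standard compositions", {
  forms <- reference_formulation_table()
  expect_length(forms, 6)
  expect_equal(forms[[1]]$mass_parts[["ethanol"]], 0)
  expect_equal(forms[[6]]$mass_parts[["ethanol"]], 10)
  for (f in forms) {
    expect_equal(f$mass_parts[["gmo"]], 64)
    expect_equal(f$mass_parts[["water"]], 30)
    expect_equal(f$mass_parts[["met"]], 5)
  }
})

test_that("every generator is deterministic under a fixed seed", {
  expect_identical(gen_saxs_peaks("Pn3m", 134, 4, 0.02, seed = 5),
                   gen_saxs_peaks("Pn3m", 134, 4, 0.02, seed = 5))
  expect_identical(gen_permeation_series(1000, 0.3, noise_rel = 0.05, seed = 5),
                   gen_permeation_series(1000, 0.3, noise_rel = 0.05, seed = 5))
  expect_identical(gen_tumor_study(seed = 5), gen_tumor_study(seed = 5))
  expect_identical(gen_density_field("disordered", 16, seed = 5)$grid,
                   gen_density_field("disordered", 16, seed = 5)$grid)
  # seeded generators do not disturb the caller's RNG stream
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(gen_tumor_study(seed = 5))
  expect_identical(runif(1), before)
})

test_that("generators record ground truth sufficient for recovery checks", {
  pk <- gen_saxs_peaks("Ia3d", 150, 4, 0.01, seed = 2)
  tr <- attr(pk, "truth")
  expect_equal(tr$lattice_constant, 150)
  expect_identical(tr$group, "Ia3d")
  g <- gen_permeation_series(800, 0.25, noise_rel = 0.02, seed = 2)
  expect_equal(attr(g, "truth")$Jss, 800)
  ts <- gen_tumor_study(seed = 2)
  expect_named(attr(ts, "truth")$inhibition_by_group,
               c("I", "II", "III", "IV"))
})

test_that("zero-noise tumor study reproduces the generating inhibition exactly", {
  ts <- gen_tumor_study(inhibition_by_group = c(I = 0, II = 0.11,
                                                III = 0.06, IV = 0.64),
                        noise_cv = 0, n_per_group = 6, seed = 1)
  w <- split(ts$weights$weight_g, ts$weights$group)
  out <- efficacy_summary(w, control = "I")
  expect_equal(out$inhibition_rate[match(c("II", "III", "IV"), out$group)],
               c(11, 6, 64), tolerance = 1e-9)
  # measurement table is well-formed: L >= W > 0, exponential growth
  expect_true(all(ts$measurements$L_mm >= ts$measurements$W_mm))
  expect_true(all(ts$measurements$W_mm > 0))
  m1 <- subset(ts$measurements, mouse_id == "I_m1")
  v <- tumor_volume(m1$L_mm, m1$W_mm)
  expect_equal(v, 75 * exp(0.31 * m1$day), tolerance = 1e-6)
})

test_that("noisy tumor studies recover the generating inhibition within 5 points on average", {
  truth <- c(I = 0, II = 0.11, III = 0.06, IV = 0.64)
  recovered <- vapply(1:200, function(s) {
    ts <- gen_tumor_study(inhibition_by_group = truth, noise_cv = 0.2,
                          n_per_group = 6, seed = s)
    w <- split(ts$weights$weight_g, ts$weights$group)
    out <- efficacy_summary(w, control = "I")
    out$inhibition_rate[match(c("II", "III", "IV"), out$group)]
  }, numeric(3))
  bias <- rowMeans(recovered) - 100 * truth[c("II", "III", "IV")]
  expect_true(all(abs(bias) < 5))
})

test_that("synthetic density fields are non-negative and classify as generated, also under noise", {
  for (phase in c("bicontinuous_cubic", "lamellar", "disordered")) {
    fld <- gen_density_field(phase, grid_n = 24, noise = 0, seed = 1)
    expect_true(all(fld$grid >= 0))
    expect_identical(classify_phase(fld)$label, phase, info = phase)
  }
  # robustness at 10% of the field SD over 20 seeds
  for (s in 1:20) {
    for (phase in c("bicontinuous_cubic", "lamellar")) {
      fld <- gen_density_field(phase, grid_n = 24, noise = 0.1, seed = s)
      expect_identical(classify_phase(fld)$label, phase,
                       info = sprintf("%s seed %d", phase, s))
    }
  }
})

test_that("zero-noise SAXS generation round-trips through indexing for all symmetries", {
  for (grp in names(saxs_groups())) {
    pk <- gen_saxs_peaks(grp, 120, n_peaks = 4, noise_rel = 0)
    asg <- index_peaks(pk)
    expect_identical(asg$space_group, grp)
    expect_equal(asg$lattice_constant, 120, tolerance = 1e-9)
  }
  expect_error(gen_saxs_peaks("Fd3m", 100), "unsupported")
})
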