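---
title: "Mesoscale screening of GMO cubic-phase formulations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale screening of GMO cubic-phase formulations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cubiphase` implements a complete in-silico pipeline for screening
glyceryl-monooleate (GMO) lyotropic liquid-crystal formulations of a
hydrophilic drug (metformin hydrochloride, "Met"), together with the
downstream analytics used to characterize such formulations in the
laboratory: SAXS peak indexing, Franz-cell permeation kinetics, and
xenograft efficacy metrics. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic-data
generators do and do not emulate.

## The mesoscale model

### Bead representation

Each GMO molecule is split into two bonded beads: a hydrophilic head `A`
(glycerol backbone plus the ester carboxyl, M ≈ 119 g/mol) and a
hydrophobic tail `B` (the oleoyl chain, M ≈ 237 g/mol). Water, ethanol and
Met are single-bead species, with one water bead representing three water
molecules — the conventional degree of coarse-graining for aqueous DPD,
and the value under which the bead-count arithmetic of the standard
compositions comes out right (for F4, water beads are ~78% of the
non-GMO beads). Compositions in mass parts are converted to bead counts
proportional to mole numbers, with the A and B counts forced equal
(`map_composition()`).

### Interactions

Pairwise mixing energetics enter as Flory–Huggins χ parameters
(`chi_matrix`). Three pairs carry values estimated for this system by
atomistic simulation: χ(B, water) = 5.1, χ(B, ethanol) = 0.5,
χ(water, A) = −1.1. The remaining pairs are shipped defaults chosen to
respect the qualitative picture — ethanol miscible with water, Met and
the A head; the B tail repelling all polar species; A and B moderately
incompatible:

| pair | χ | origin |
|------|----|--------|
| B–water | 5.1 | estimated |
| B–ethanol | 0.5 | estimated |
| A–water | −1.1 | estimated |
| water–ethanol | −0.3 | default |
| ethanol–Met | −0.5 | default |
| water–Met | −0.5 | default |
| A–ethanol | −0.2 | default |
| A–Met | −0.3 | default |
| A–B | 2.0 | default |
| B–Met | 4.0 | default |

Every entry is overridable (`default_chi_matrix(overrides = ...)`), and a
provenance matrix distinguishes estimated values from defaults. A single,
composition-independent χ is used per pair and per run; in reality χ for
hydrogen-bonding pairs varies with local composition, which is a known
limitation of this stage. An alternative estimation route from Hildebrand
solubility parameters, χ = v_ref(δi − δj)²/RT, is provided
(`chi_from_solubility()`); being a squared difference it cannot produce
the negative χ of hydrogen-bonding pairs, and it warns accordingly.

χ maps onto DPD conservative repulsions by the standard Groot–Warren
linear rule a_ij = a_ii + 3.27 χ_ij at bead density ρ = 3 (the 3.27
coefficient is specific to ρ = 3; other densities require an explicit
coefficient).

### Dynamics

The engine (`dpd_run()`) integrates soft conservative repulsion
F_C = a_ij(1 − r/r_c)r̂, pairwise dissipative drag
F_D = −γw(r)²(r̂·v_ij)r̂ and symmetric random kicks
F_R = σw(r)θ_ij r̂/√dt, with harmonic A–B bonds
(k = 100 kT/r_c², r_0 = 0.7 r_c, no angle terms). Units are r_c = kT = 1.
Defaults are the standard, well-characterized parameterization:
ρ = 3, a_ii = 25, γ = 4.5, σ = √(2γkT) = 3 (fluctuation–dissipation is
enforced at construction), dt = 0.04, and the modified velocity-Verlet
scheme with prediction factor λ = 0.65. The pair noise θ_ij is uniform
with unit variance, generated once per pair so Newton's third law holds
exactly and total momentum is conserved to round-off. Neighbor search
uses cell lists with cell edge ≥ r_c, falling back to all-pairs for boxes
under three cells per axis; the two paths agree to 10⁻¹² and are tested
against a brute-force enumeration oracle. Coordinates are wrapped each
step; unwrapped copies are tracked for displacement statistics. A fixed
seed gives a bit-reproducible single-threaded trajectory.

Per frame the engine records kinetic temperature, the diagonal
pressure-tensor components (ideal part plus conservative/bond virial —
the dissipative and random contributions average to zero and are
excluded so that the ideal-gas limit is exact), and total momentum.

## Screening observables

**Water-density field.** Water beads are binned on a regular grid
(default 16³) and averaged over frames; the field integral recovers the
water bead count to 1%.

**Phase classification** (`classify_phase()`) uses three diagnostics on
the mean-thresholded field and its 3-D structure factor:

1. *Lamellar*: one wavevector direction family (reduced integer
   direction, sign-canonical) carries ≥ 60% of the off-origin spectral
   power.
2. *Disordered*: the spectrum is flat. Flatness is judged by low-k
   enrichment — the mean per-mode power inside the ball of normalized
   frequency ≤ 0.25, divided by the median per-mode off-origin power.
   A flat (counting-noise) spectrum scores ≈ 1 on this ratio regardless
   of grid size or frame count; structured mesophases concentrate power
   at small wavevectors and score well above the default threshold
   of 3. A naive "maximum peak over median" rule would fail here: the
   maximum of thousands of exponentially distributed noise modes always
   exceeds a few times their median, so flatness must be judged on a
   region average, not a single mode.
3. *Bicontinuous cubic*: not lamellar, not flat, and both the water-rich
   and water-poor threshold sets percolate across all three periodic
   axes (6-connectivity, periodic in the transverse axes, open along the
   tested axis). This operationalizes "two interpenetrating water/lipid
   networks" without attempting a space-group assignment.

Anything else is *intermediate* (the class that absorbs, e.g., stalk-like
transition structures). The rules are evaluated in the order
lamellar → disordered → bicontinuous, which keeps random fields from
being called bicontinuous merely because a 50/50 random set percolates
(site percolation at p = 0.5 is well above the 3-D threshold of ≈ 0.31).
A constant field classifies as disordered with a warning. All thresholds
are configurable and echoed in the diagnostics, from which the label can
be re-derived.

**Water diffusivity** (`water_diffusivity()`): mean squared displacement
over water beads with multiple time origins (origins spaced at half the
lag — 50% overlap — for variance reduction), then D = slope/6 by least
squares over the last half of the curve (configurable). The estimator is
validated to 5% on constructed Gaussian random walks of known D. The
statistical error of a single-trajectory MSD grows toward the largest
lags (few independent origins), which is why validation walks use many
walkers and short lag windows.

**Interfacial tension** (`surface_tension()`): the planar-slab estimator
γ = (L_N/2)⟨P_NN − (P_T1 + P_T2)/2⟩, with the factor 1/2 for the two
interfaces of a periodic slab. For non-planar morphologies the same
anisotropy estimator is reported flagged as an effective value only.

## The screening loop

`run_screen()` simulates every candidate formulation over several seeds
(default 3), classifies each replicate, and combines replicates by
majority label (ties fall to `intermediate`) and mean diffusivity.
"Proper fluidity" is operationalized as maximal water diffusivity — the
fluidity indicator of this pipeline — among the formulations that retain
a bicontinuous cubic microstructure; diffusivity ties break toward the
higher ethanol fraction. The rule is exposed as the pure function
`select_formulation()` and unit-tested against brute-force enumeration.
If no candidate is bicontinuous the report says so and selects none.

### Desk-scale study conditions

The default conditions were chosen once as the smallest scale at which
the qualitative observables (microstructure class, diffusivity trend)
are past their initial transient, checked by comparing against runs
several times longer: ~2500 beads (a ≈ 9.4 r_c box at ρ = 3),
6000 equilibration + 12000 production steps (720 τ total), sampling
every 100 steps, 16³ classification grid, 3 seeds. These are
deliberately far below publication-grade mesoscale runs (which use
larger boxes and an order of magnitude more steps); conclusions at this
scale are qualitative. Two consequences are documented rather than
hidden:

- A box of ~9–10 r_c holds only a couple of mesophase repeat distances,
  so ordered phases are identified by percolation topology and spectral
  anisotropy, not by Bragg-peak indexing of the simulated field.
- Spontaneous ordering of the high-ethanol formulations into lamellar
  stacks is kinetically demanding. In probe runs up to 3200 τ the F6
  composition remained a bicontinuous sponge under the shipped default χ
  set; a single composition-independent χ per pair evidently does not
  encode the curvature change that drives the lamellar transition at
  high ethanol. The acceptance suite states the lamellar expectation for
  F6 honestly and the corresponding check documents this limitation when
  it fails.
- The ethanol–diffusivity trend across F1–F4 is resolvable as a rank
  correlation over seeds, but the pairwise differences between adjacent
  compositions are comparable to seed-to-seed variation, so the identity
  of the single most fluid bicontinuous candidate is not reliable at
  this scale. The selection rule itself is exact and unit-tested; its
  desk-scale input is noisy.

## Experimental-analysis modules

**SAXS indexing** (`index_peaks()`): observed q positions are assigned to
contiguous runs of the allowed reflection sequences of Pn3m
(√2:√3:√4:√6:√8…), Im3m (√2:√4:√6:√8…), Ia3d (√6:√8:√14:√16…), 2-D
hexagonal (1:√3:√4:√7…) or a lamellar stack (1:2:3…), with up to three
leading reflections allowed to be unobserved. The lattice constant comes
from a zero-intercept least-squares fit of q = 2π√N/a, and the
assignment with the smallest RMS relative residual wins. Two-peak
patterns are genuinely ambiguous — √8/√6 equals √4/√3 exactly — so exact
ties are resolved toward the deepest consistent assignment (largest
offset) and then by a fixed symmetry priority (Pn3m first). This is the
convention under which a GMO cubic-phase pattern reported as a 6:8
spacing ratio indexes as Pn3m with the conventionally quoted lattice
constant; the alternative (smallest-offset) reading of the same two
peaks would return a lattice constant smaller by √2 with no physical
information to decide between them. Peak sets whose best residual
exceeds 2% are reported unassignable, and a ratio-only mode reports
observed q ratios verbatim for patterns (like 4:5 or 3:4 two-peak
lamellar-type data) that no ideal indexing reproduces — deliberately not
reinterpreted.

**Permeation** (`cumulative_amount()`, `flux_and_lag()`,
`enhancement_ratio()`): the aliquot-corrected cumulative amount
Q_n = [C_nV + V_0ΣC_i]/A assumes the replaced medium is drug-free (sink
condition). The "linear portion" for the flux/lag fit defaults to
t ≥ 1 h — dropping only the first point of the conventional 0.5–5 h
schedule — and the window used is always reported; a negative fitted lag
is clamped to zero with a flag. Defaults V = 10 ml, V0 = 1 ml,
A = 0.785 cm² match the vertical Franz cell geometry for mouse skin.

**Efficacy** (`tumor_volume()`, `inhibition_rate()`, `compare_groups()`):
caliper volume 0.5·L·W², inhibition (W_blank − W_test)/W_blank × 100%
reported to two decimals (half-up — the convention that reproduces
hand-reported rates exactly; full precision is retained as an
attribute). Group comparison uses a two-sample t-test for two groups and
one-way ANOVA followed by the Student–Newman–Keuls stepwise procedure
otherwise, with studentized-range quantiles computed numerically
(`ptukey`) rather than read from tables, and the harmonic mean group
size for unbalanced designs.

## Synthetic data

Every input class the pipeline consumes can be generated with known
ground truth and a fixed seed (bit-identical output; the caller's RNG
stream is untouched):

- `gen_saxs_peaks()` — reflections of any supported symmetry with
  multiplicative Gaussian q noise.
- `gen_permeation_series()` — exact inversion of the aliquot-correction
  relation from a target flux/lag line, then multiplicative noise. The
  inversion tests the pipeline's own equation rather than simulating
  membrane diffusion.
- `gen_tumor_study()` — exponential per-mouse growth
  V = V₀exp(r(1 − inhibition)t) with lognormal measurement noise
  (positivity-preserving, conventional for caliper data); L and W are
  back-solved from V at a fixed aspect ratio. Terminal weights are
  proportional to terminal volume within each group and scaled so the
  zero-noise group mean reproduces the generating inhibition exactly —
  exponential growth alone would not, since it turns an inhibition
  fraction into a rate deficit.
- `gen_density_field()` — a positive-shifted Schwarz-D nodal field
  (cos x cos y cos z − sin x sin y sin z; both level sets percolate
  triply), a cosine stack, or constant-plus-noise.

What these generators do *not* emulate: raw scattering intensities,
instrument resolution and background, chromatograms, biological
between-mouse covariance, or the kinetics of real phase formation.
Passing the recovery suites therefore demonstrates that the analysis
chain inverts its own declared data models at the stated noise levels —
not that it would be robust to every artifact of real instruments.

## Numerical conventions and edge cases

- Exactly overlapping beads exert no pair force (the soft potential has
  no defined direction at r = 0; overlaps are legal and transient).
- Boxes smaller than 3 r_c per axis use all-pairs search; minimum image
  assumes box ≥ 2 r_c.
- Degenerate inputs error early with named messages: zero-water
  compositions in the ratio, W > L calipers, non-positive control
  weights, zero-variance group comparisons, wrapped-only trajectories in
  the diffusivity estimator, duplicate q values in the lattice fit.
- Reported 2-decimal values round half away from zero; full precision is
  always retained programmatically.

## Known limitations

- One χ per pair per run; concentration-dependent χ is out of scope.
- The phase classifier distinguishes four classes only; cubic space-group
  assignment (Pn3m vs Im3m vs Ia3d) from simulated fields is not
  attempted.
- Interfacial tension for non-planar phases is an effective anisotropy
  value.
- Desk-scale DPD runs are qualitative; they do not reproduce
  publication-scale structures bit-wise, and the high-ethanol lamellar
  transition is not reached under the shipped defaults (see above).
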