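---
title: "Models and methods behind channelflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind channelflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelflux)
```

channelflux compares water and glycerol transport through aquaglyceroporin
channels — the motivating system is human AQP7 against the bacterial
glycerol facilitator GlpF — across three experimental scales: static atomic
structures, solute-scale permeation dynamics, and whole-cell osmotic flux.
This vignette records the models, the tunable parameters, and the design
choices that were genuinely open, in enough detail that a maintainer can
judge what a passing test suite does and does not demonstrate.

## Channel geometry from structures

Structures are read from PDB files into a plain atom table with Bondi van
der Waals radii assigned by element (unknown elements fall back to 1.70 Å
with a warning). Alternate locations are resolved to the highest-occupancy
copy; insertion codes are kept alongside residue numbers without
renumbering.

The pore profiler is HOLE-style: the channel axis is either two anchor
points or the principal axis of a pore-lining CA selection (oriented with
the extracellular side at +z, placing the selectivity filter near
z ≈ +7.5 Å). At each axial position the probe-sphere centre is optimised in
the normal plane by deterministic Nelder–Mead, started from the previous
slice's centre, maximising the clearance
`min_i(|centre − atom_i| − vdw_i)`. On analytic ring fixtures the profiler
is exact to the in-plane search tolerance (10⁻³ Å); on real structures the
absolute diameter carries a method tolerance of roughly ±0.3 Å because the
underlying algorithm and radius set behind any published constriction
number are rarely stated.

Buried surface area uses Shrake–Rupley point counting on a deterministic
golden-spiral lattice (default 960 points, probe 1.4 Å), with
`BSA = SASA(A) + SASA(B) − SASA(A∪B)`. The two motif groups are extracted
*in isolation* from the rest of the protein — the standard isolated-pair
interface definition. Whether published NPA-motif interface areas were
computed in isolation or in the whole-protein context is usually ambiguous;
the isolated convention is the package's documented choice, and comparisons
against printed values should allow for it.

Superpositions are least-squares optimal rigid transforms (Kabsch, SVD with
the determinant sign corrected so reflections are excluded). Torsions
follow the IUPAC convention; note that an IUPAC torsion is *invariant*
under reversing the atom order and is negated by a mirror reflection — the
tests assert exactly these two properties.

## Permeation dynamics

### The synthetic landscape

All solute-scale stages are exercised against a one-dimensional potential
of mean force built from Gaussian terms. The default AQP7-like landscape
has a 4.0 kcal/mol selectivity-filter barrier centred at z = +7.5 Å, a
−1.5 kcal/mol well across the NPA region (z ∈ [−5, +4] Å), and a
~1 kcal/mol cytosolic barrier at z = −5 Å; the GlpF-like variant raises the
barrier to 4.5 kcal/mol and replaces the well with a shallow +0.5 kcal/mol
feature. These five numbers parameterise the landscape the analysis is
meant to resolve; they are fixed once and the tests measure *recovery* of
them, never agreement with tuned values.

The propagator is overdamped Euler–Maruyama,
`z ← z − (D/kT)·G′(z)·dt + sqrt(2 D dt)·ξ`, with reflecting walls at
±25 Å, D = 100 Å²/ns (the order of magnitude for a small solute in water;
only ratios and recovery matter, not absolute rates), kT = 0.596 kcal/mol
(300 K), and a stability guard `D·dt·max|G′|/kT < 0.1 Å` evaluated over the
region the walker can actually sample (the whole box unbiased, the
restraint centre ±5σ under an umbrella). The default dt = 2.5 × 10⁻⁴ ns
satisfies the guard on both default landscapes.

For equilibrium checks, walkers are initialised directly from the target
Boltzmann density by inverse-CDF sampling, and the histogram test compares
the mean over independent walkers with the analytic density using the
standard error across walkers. Within-walker autocorrelation makes a naive
per-bin binomial σ invalid, and at a 4+ kcal/mol barrier a single 10⁵-step
run does not mix between basins; the replica design tests that the
propagator *preserves* the equilibrium density (catching force-sign,
noise-amplitude and boundary errors) without requiring barrier-crossing
statistics it cannot have. Bins whose expected count is below the normal
regime are excluded from the 3σ comparison.

### Events

Site visits use a hysteresis state machine: a visit opens when z enters the
site interval (default NPA, z ∈ [−5, 4] Å, lateral cutoff 6 Å) and closes
only when z leaves the interval expanded by 1 Å, so boundary-hugging
oscillations count once; visits shorter than the minimum dwell (default
1 ns) are dropped. A sub-dwell excursion therefore merges into one visit —
whether published visit counts did the same is unknowable from print, so
the criteria are configurable and should be reported alongside results.
Translocations require passage from beyond one bulk boundary (defaults
z_top = +12, z_bottom = −8 Å, the bulk onsets flanking the selectivity
filter) to beyond the other without first returning. Visitation rates are
`Σ visits / (n_pores × Σ time)` with the SEM of per-replica rates (n−1
denominator).

### Umbrella sampling and WHAM

The generator runs one biased Langevin trajectory per window (default 25
windows, centres −15…+15 Å every 1.25 Å, k = 2.5 kcal/mol/Å², 2 × 10⁵
steps of 5 × 10⁻⁵ ns per window, first 10% discarded, samples thinned by
10). The window span ends where the bulk anchor region begins (|z| ≥ 15 Å),
and the 1.25 Å spacing respects the `3·sqrt(kT/k)` overlap rule — a wider
spacing triggers a warning, and WHAM refuses chains whose neighbouring
windows share no occupied bin.

WHAM itself is the standard self-consistent iteration on bin probabilities
and window offsets, converged to 10⁻⁷ kcal/mol on the offsets (at most 10⁵
iterations), with the profile anchored to zero mean over |z| ≥ 15 Å. Two
numerical choices matter and were set from measurement on exact
Boltzmann-sampled windows: the histogram bin width defaults to 0.1 Å
because at k = 2.5 the bias varies by more than kT across a 0.25 Å bin in
window tails, which produces a ≈0.15 kcal/mol systematic error in the well
depth (mid-bin bias); and windows default to 10 ns because the
reconstructed profile accumulates window-offset noise across the barrier
like a random walk, and shorter windows leave that walk comparable to the
0.3 kcal/mol recovery band the tests enforce. With these defaults, barrier
and well recovery errors over five seeds stay within ±0.2 kcal/mol with
SD < 0.3.

### Permeability

Two single-channel estimators are provided and kept distinct: event
counting (`p_d = v_w · k₀`, with k₀ complete permeation events per ns) and
collective diffusion (`p_f = v_w · D_n`, with n(t) the dimensionless
collective coordinate advancing by `Σ dz_i / L` and D_n from an
origin-constrained MSD fit). v_w defaults to one water molecule,
18 cm³/mol ÷ N_A ≈ 2.99 × 10⁻²³ cm³. Conversion to an areal coefficient in
cm/s requires an explicit membrane area per channel — there is no hidden
default, because any such number silently fixes the comparison scale.

Occupancy-segmented permeability splits the water event stream into
contiguous glycerol-bound and glycerol-free (apo) segments, drops segments
shorter than 5 ns to suppress boundary transients, and estimates the
counting permeability per class; an absent class is reported as absent,
never as zero. The companion generator draws completed, directed
permeation events as Poisson counts at class-dependent rates — the
sub-event "hop" granularity adds nothing to rate-ratio recovery, which is
what the fixture exists to test (an 80-fold apo/bound contrast is recovered
within 20% at ≈3.2 μs of schedule).

## Oocyte physiology

The oocyte is a sphere: `r = sqrt(A/π)`, `V = 4/3 π r³`, with the true
membrane area exceeding the geometric surface by a folding factor (default
9, the conventional allowance for microvilli). Osmolalities convert as
1 mOsm = 10⁻⁶ mol/cm³ and V_w = 18 cm³/mol. Pf comes from the ordinary
least-squares slope of V(t)/V₀ over the first 60 s after the solution
change via `Pf = slope·V₀ / (S·V_w·Δosm)`.

One correction matters at realistic permeabilities: over 60 s an oocyte
with Pf ≈ 2 × 10⁻³ cm/s swells by ~9%, so the OLS slope reflects
mid-window conditions while the naive formula uses t = 0 values,
underestimating Pf by ≈6%. `estimate_pf()` therefore evaluates S and Δosm
at the window midpoint, inferring the internal osmolality from volume
conservation (`osm_in(t) = osm_in(0)·V₀/V(t)`, valid while the bath
contributes no permeant influx during the brief window). With the
correction the closed loop against the forward model recovers the
generating Pf to ≈0.1%.

The forward model integrates
`dN_s/dt = P_s·S·(C_out − N_s/V)` and
`dV/dt = Pf·S·V_w·(Osm_in − Osm_out)` with S recomputed from V each step
and the impermeant internal amount held fixed; `deSolve::lsoda` handles the
stiffness and step control, piecewise over the bath protocol. The model
reproduces the qualitative signature that motivates it: with high Pf *and*
substantial glycerol permeability (an AQP7-like spec, Pf = 0.8 × 10⁻³
cm/s, P_gly = 3 × 10⁻⁵ cm/s), a 270 mOsm glycerol bath first shrinks the
cell, then glycerol influx reverses the gradient and the cell swells —
paradoxical swelling — while P_gly = 0 gives monotone shrinkage, and
normo-osmotic baths with rising glycerol give monotonically increasing
swelling rates.

Group comparisons use Welch's unequal-variance t test and the
Holm–Bonferroni step-down at familywise α = 0.05: p-values are ordered and
the k-th smallest is compared with α/(m−k+1), stopping at the first
non-rejection. Channel-dependent permeability is
`Pf* = mean(group) − mean(day-matched control)` with SEMs combined in
quadrature.

## Synthetic data: what it does and does not emulate

The generators provide Boltzmann-consistent 1-D dynamics on an
aquaglyceroporin-shaped landscape, umbrella-biased sampling of it, analytic channel geometries,
orientation tracks with prescribed order parameter (a mixture of perfectly
axial and isotropic draws whose weight equals the target P1),
occupancy-modulated permeation streams, and noisy oocyte recordings from
the forward model (multiplicative log-normal area noise, default 0.2%).
All are deterministic under a fixed seed.

They deliberately do **not** emulate: three-dimensional pore geometry or
orientation-position coupling, force-field physics, correlated
multi-molecule motion, finite video-segmentation artefacts in areas, or
batch effects between oocyte harvests. Passing tests therefore demonstrate
that the *estimators* are correct and calibrated on data satisfying their
assumptions — not that those assumptions hold for any particular
laboratory or simulation dataset.

## Problem sizes

Defaults used by the test suite and the acceptance script: 10⁵-step
equilibrium runs (20 walkers per landscape), 25 umbrella windows × 10 ns,
6 × 10⁶-step visit runs per well depth (≥200 events each), 3.2 μs of
segmented permeation schedule, and 20-oocyte assays at 1 Hz sampling for
60 s. These sizes put every recovery statistic comfortably inside its
tolerance band while keeping a full run on one core in the minutes range.

## Known limitations

* The pore profiler reports the largest inscribed-sphere radius per slice;
  it does not trace a connected path and can jump between disconnected
  voids in pathological geometries.
* WHAM error bars are not computed (no bootstrap/MBAR); recovery bands come
  from repeated synthetic datasets instead.
* The collective-diffusion estimator assumes uncorrelated increments when
  fitting the MSD through the origin; strongly correlated single-file
  dynamics would need block-averaged uncertainties.
* The sphere model ignores osmotically inactive volume; Pf values inherit
  whatever bias that convention carries, consistently across groups.
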