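# channelflux

Quantitative analysis of water and glycerol transport through
aquaglyceroporin channels, for structural biologists and channel
physiologists who need the same numbers at three scales:

* **structure** — pore-radius profiles, selectivity-filter constriction
  diameters, side-chain χ1/χ2 rotamers, ligand shifts between aligned
  homologs, and buried surface area of the NPA motif pair, from PDB files;
* **permeation dynamics** — binding-site visits, residence times,
  translocation events and orientation order parameters (P1 = ⟨cos θ⟩)
  from solute tracks; free-energy profiles ΔG(z) reconstructed from
  umbrella-sampling windows by WHAM; single-channel water permeability from
  event counting (p_d = v_w·k₀) or collective diffusion (p_f = v_w·D_n),
  optionally segmented by glycerol occupancy of the pore;
* **cell physiology** — osmotic water permeability
  Pf = (dV/V₀/dt)·V₀/(S·V_w·Δosm) from oocyte swelling recordings,
  channel-dependent Pf\* against day-matched controls, a coupled
  water/solute flux model that reproduces paradoxical swelling in
  hyperosmotic glycerol baths, and the Welch-t / Holm–Bonferroni testing
  procedure.

A synthetic-data module generates every input with known ground truth —
overdamped Langevin dynamics on a double-barrier PMF, umbrella-biased
sampling, analytic channel fixtures, occupancy-modulated permeation
streams, and simulated oocyte recordings — so the entire pipeline runs and
is tested with no external downloads.

## Worked example

Reconstruct the free-energy landscape of glycerol permeation from
synthetic umbrella-sampling data, then read off its features:

```r
library(channelflux)

wins <- make_umbrella_dataset(aqp7_pmf(), seed = 1)   # 25 windows, 10 ns each
prof <- wham(wins)                                    # ΔG(z), bulk-anchored
f <- profile_features(prof)
cat(sprintf("SF barrier: %.2f kcal/mol | NPA well: %.2f kcal/mol\n",
            f$barrier, f$well))
#> SF barrier: 4.10 kcal/mol | NPA well: -1.41 kcal/mol
```

The generating landscape has a 4.0 kcal/mol selectivity-filter barrier and
a −1.5 kcal/mol NPA well; the reconstruction recovers both within the
package's stated 0.3 kcal/mol band.

Normalise raw site-visit counts into a per-pore visitation rate (three
replicas of 1 μs, four monomeric pores, 24 visits in total):

```r
visitation_rate(c(8, 8, 8), n_pores = 4, time_per_replica = 1)
#> <visitation rate: 2.00 +/- 0.00 per pore per us (24 visits, 4 pores)>
```

Simulate the paradoxical-swelling experiment: an oocyte expressing a
channel with both high water and high glycerol permeability, dropped into
a hyperosmotic (270 mOsm) glycerol bath, shrinks briefly and then swells
as glycerol influx reverses the osmotic gradient:

```r
spec <- forward_model_spec(Pf = 0.8e-3, P_s = c(glycerol = 3e-5))
bath <- bath_protocol(start = 0, osm = 270, glycerol = 260)
tr <- forward_model(spec, bath, duration = 90, dt = 1)
cat(sprintf("V(10s)/V0 = %.4f, V(90s)/V0 = %.4f, osm_in(90s) = %.0f mOsm\n",
            tr$V[11] / tr$V[1], tr$V[91] / tr$V[1], tr$osm_in[91]))
#> V(10s)/V0 = 0.9963, V(90s)/V0 = 1.0197, osm_in(90s) = 371 mOsm
```

With `P_s = c(glycerol = 0)` the same bath produces monotone shrinkage.

The vignette (`vignettes/channelflux-methods.Rmd`) documents the models,
default parameters, and numerical choices. `inst/cli/channelflux.R` is a
thin command-line front end over `run_stage()`/`run_report()` for
config-driven, provenance-tracked runs.

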