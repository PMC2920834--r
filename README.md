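# iontoggle

Sodium ions modulate class A GPCRs (the dopamine D2 receptor among them) from
a deep allosteric site: an ion entering the transmembrane channel visits an
orthosteric site *a* (near Asp3.32, z ≈ −5 Å on the channel axis), an
intermediate site *b* (z ≈ −7.5 Å), and the allosteric site *c* (Asp2.50,
z ≈ −15 Å). When the ion passes the Trp6.48 "rotamer toggle switch"
(z ≈ −12 Å), the tryptophan side-chain dihedral χ₂ (CA–CB–CG–CD1) flips from
0° to 100° and locks — the conformation associated with the receptor's
inactive state. `iontoggle` implements the complete analysis pipeline by
which this mechanism is quantified, exercised end-to-end on a synthetic
Langevin model whose true energy surface encodes the reference energetics, so
that every stage is verifiable against ground truth without all-atom MD.

The package is aimed at computational structural biologists who want tested,
reusable implementations of these analyses:

* **Model potential + generator** — a 4-degree-of-freedom
  (x, y, z, χ₂; χ₁ as uncoupled noise) channel potential

      U(z, χ, x, y) = V_z(z) + (1 − s(z))·V_ab(χ) + s(z)·V_c(χ)
                      + ½ k_xy (x² + y²) + wall(z),
      s(z) = 1 / (1 + exp((z − z_T)/λ)),

  with Gaussian well/bump amplitudes solved numerically so the stationary
  points hit the reference energetics (sites a/b equal, site c 1.5 kcal/mol
  lower; a–b saddle 1 kcal/mol; b→c crossing 3 kcal/mol; rotamer barriers
  3 kcal/mol in the a/b regime and 4 kcal/mol at site c), verified at build
  time by an independent dense-grid scan; plus an overdamped Langevin
  (Euler–Maruyama) integrator, bit-reproducible given a seed.
* **Well-tempered metadynamics** over (z, χ₂): periodic Gaussian deposition
  with height decay w₀·exp(−V/(k_B ΔT)), the final-bias free-energy estimator
  F(s) = −(γ/(γ−1))·V(s, t_end), replica averaging with per-cell error maps,
  basin location with sub-cell refinement, and exact minimax-path barriers on
  the 8-connected, χ-periodic grid graph.
* **Density → chemical potential maps**: 3D voxel occupancy grids, μ(r) =
  −k_B T · ln(ρ(r)/ρ_bulk) relative to a bulk concentration (150 mM by
  default), isosurface thresholding with connected components.
* **CV analysis**: IUPAC-signed dihedrals, idealized Trp side-chain placement,
  site segmentation and dwell episodes, circular rotamer statistics by site,
  Kabsch superposition / RMSD.
* **Contacts**: per-anchor contact frequencies within a cutoff conditioned on
  a binding site, with anchor placement solved by quadrature against the
  stationary ion distribution.
* **IO**: deterministic TSV collective-variable tables, multi-frame XYZ,
  OpenDX scalar grids, YAML run configs.

## Worked example

```r
library(iontoggle)

pot <- build_default_potential()

## one long unbiased trajectory (50 ns at the model's time scale)
tr <- simulate_trajectory(pot, generator_config(steps = 5e6, seed = 7))
rotamer_state_by_site(tr)
#>   site n_frames chi2_mean chi2_sd
#> 1    a     7457         1      32
#> 2    b     7364         2      36
#> 3    c    35180        99      18

contact_frequency(tr, default_anchor_set(pot), site = "c")
#> Contact frequencies (cutoff 2.50 A, site c, 35180 frames):
#>   anchor frequency
#>  Asp3.32      0.0%
#>  Asp2.50     99.9%
#>  Ser7.46     41.0%
#>  Asn7.45     18.4%
#>  Ser3.39     10.1%

## replica metadynamics and the averaged free-energy surface
runs <- lapply(1:5, function(i) {
  r <- run_wtmetad(pot, wt_params(),
                   generator_config(steps = 2e6, stride = 200, seed = i))
  fes_from_bias(r$bias)
})
fes <- replica_statistics(runs)
summary(fes)
#> FES summary
#>   basins:
#>  region      z chi     value
#>       a  -4.96 359  1.456290
#>       b  -7.52 358  1.349559
#>       c -15.07 100 -0.000913
#>   b->c barrier: 3.31 kcal/mol (saddle z -12.10 A)
#>   rotamer barriers: a/b 3.26, c 4.04 kcal/mol
#>   site c below a/b by 1.35 kcal/mol
#>   basin replica error: median 0.307, max 0.645 kcal/mol
```

Reading the output: while the ion sits in sites a/b its χ₂ stays near 0°;
site-c frames sit near 100° ("locked") — the toggle. The site-c contact
pattern reproduces the reference percentages (Asp2.50 ~100%, Ser7.46 ~41%,
Asn7.45 ~18%, Ser3.39 ~10% within 2.5 Å). The reconstructed surface recovers
the true basin positions (−5/−7.5/−15 Å; χ at 0°/100°), the ~3 kcal/mol
crossing at the switch position, the 3 and 4 kcal/mol rotamer barriers, and
site c favored by ≥1 kcal/mol — with sub-kcal/mol replica errors in all
basins (the full 25-replica protocol tightens these further).

`plot(fes)` draws the free-energy surface, `plot(fes, "error")` the replica
error map, and `plot(tr)` the z / χ₂ time series. `run_experiment()` drives
the three preset designs (one long run, many short replicas, metadynamics
replicas) from a YAML config and writes TSV/OpenDX/JSON artifacts.

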