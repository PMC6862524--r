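# aggfold

Analysis of peptide **self-association** and **aggregation-driven folding**
in multi-chain trajectories.

Many short cationic antimicrobial peptides are partly disordered as isolated
monomers in water and only fold into their functional α-helix at an
amphipathic interface. Multi-copy simulations of such peptides (the canonical
example here is the 20-residue bombinin H2, `IIGPVLGLVGSALGGLLKKI`) show two
coupled processes: the chains coalesce into ever larger aggregates, and,
inside the aggregates, individual chains switch irreversibly from a compact
helix-loop-helix conformation to the straight single-helix state. `aggfold`
packages the complete analysis chain needed to quantify both processes, plus
a deterministic trajectory *emulator* that generates multi-chain test data
with scripted aggregation and straightening events and a ground-truth event
ledger.

The package is aimed at structural bioinformaticians who want a reproducible,
dependency-light re-implementation of this trajectory methodology in R —
either to analyse their own multi-model PDB trajectories or to benchmark
detectors against synthetic data with known ground truth.

## What it computes

* **Geometry** — Kabsch superposition, per-residue RMSF, radius of gyration
  R_g, minimum-image distances in periodic boxes.
* **SASA** — Shrake–Rupley solvent-accessible surface area, decomposed by
  residue class (hydrophobic / polar / charged) and the polar-to-hydrophobic
  ratio σ_p/hphb(t) = A_polar(t) / A_hydrophobic(t).
* **Helix states** — dihedral-window helix assignment; per-chain
  classification into *single-helix* (residues 5–17 continuously helical),
  *helix-loop-helix* (two helical segments around a break) or *disordered*;
  state occupancy in 10 ns windows.
* **Ensembles** — GROMOS conformational clustering (greedy neighbour-count,
  0.3 nm RMSD cutoff) and Cartesian backbone PCA (essential dynamics) on the
  60 backbone atoms (N, Cα, C) of a 20-residue chain, with eigen-RMSF
  profiles and per-frame projections.
* **Aggregation** — chain contact graphs under the minimum-image convention
  (0.5 nm = 5 Å neighbour cutoff), connected-component aggregate series
  n_aggregates(t) and max_size(t), per-residue intermolecular contact counts
  grouped by conformational state, and neighbour attribution at event times.
* **Kinetics** — first stable straightening transition per chain (50 ns
  persistence window, 80% occupancy), the folded-count step function N_h(t),
  and the sigmoid saturation model

      N_h(t) = h_max / (1 + exp(-k (t - t_1/2)))

  fitted by nonlinear least squares, where `h_max` is the saturation count,
  `t_1/2` the half-saturation time and `k > 0` the rate/shape parameter
  (equal to −λ of the equivalent decreasing-exponent form).

## Worked example

Reconstruct the folding kinetics of the published per-chain transition
schedule (nine chains straighten at 22–1516 ns) and fit the sigmoid:

```r
library(aggfold)

schedule <- bombinin_transitions()
sc <- scenario(duration_ns = 2000, noise_sigma_nm = 0,
               straightenings = data.frame(time_ns = schedule$time_ns,
                                           chain = schedule$chain))
traj <- generate_trajectory(sc)
traj
#> trajectory: 27 chains, 2565 atoms, 2001 frames (0 to 2000 ns), box 15 x 15 x 15 nm

states <- state_series(traj)
transitions <- detect_transitions(states, persistence_ns = 50)
transitions
#>   chain time_ns
#> 9     a      22
#> 7     V      25
#> 8     W      70
#> 5     F     404
#> 4     E     735
#> 1     A     903
#> 2     B     917
#> 3     D     931
#> 6     J    1516

nh <- folded_count(transitions, traj$times)
fit <- fit_sigmoid(traj$times, nh)
fit
#> sigmoid_fit: h_max 9.656, t_half 646.8 ns, k 0.002416 /ns (rss 776.3)
```

The detector recovers all nine scripted transitions at their scheduled times;
N_h(t) saturates at 9 of 27 chains; and the fitted sigmoid places the
half-saturation time between the early small-oligomer transitions and the
late 27-mer ones.

For end-to-end runs there is a pipeline interface (`run_config`,
`run_simulate`, `run_analyze`) that writes all module outputs as TSV tables
plus a JSON summary, and a thin command-line wrapper in
`inst/cli/aggfold.R`. See the methods vignette
(`vignettes/aggregation-folding.Rmd`) for the model, parameter and design
documentation.

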