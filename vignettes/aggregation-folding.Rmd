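---
title: "Methods: self-association and aggregation-driven folding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-association and aggregation-driven folding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aggfold)
```

# The problem

Short cationic antimicrobial peptides such as bombinin H2
(`IIGPVLGLVGSALGGLLKKI`, +2e at neutral pH, 25% glycine) are marginally
structured in water: an isolated monomer prefers a compact helix-loop-helix
conformation with the break at Gly10–Ser11 and only occasionally visits the
straight single-helix state that is believed to be the membrane-active fold.
When many copies share a box, two coupled processes unfold: the chains
self-associate into growing aggregates, and within the aggregates individual
chains straighten — essentially irreversibly — into the single-helix state.
`aggfold` quantifies both processes from multi-chain trajectories and ships a
kinematic generator that produces such trajectories with *known* ground truth
so that every detector in the package can be validated end to end.

# The reduced chain representation

Chains are represented by their backbone heavy atoms (N, Cα, C, O) plus one
side-chain pseudo-atom per non-glycine residue, named CB, placed along the
idealised Cα→Cβ direction at the rotamer-averaged distance of the side-chain
heavy-atom centroid and carrying the full side-chain mass. This keeps every
analysis in the package meaningful — compactness (mass-weighted R_g),
class-decomposed surface area, contacts — at a small fraction of all-atom
cost. Radii: a standard protein van-der-Waals set for backbone atoms
(N 0.155, Cα/C 0.170, O 0.152 nm) and a residue-class radius for the
pseudo-atom (hydrophobic 0.240, polar 0.210, charged 0.260 nm, the charged
value reflecting long lysine/arginine-like side chains).

The default residue-class scheme is charged = {K, R, D, E}, polar =
{S, T, N, Q, C, Y, H, W}, hydrophobic = {A, V, L, I, M, F, P, G}. Placing
glycine and proline with the hydrophobics follows the observation that in a
Gly/Pro-rich peptide the collapse of total surface area on aggregation is
carried almost entirely by the apolar component; the scheme is a plain named
vector and fully user-overridable. Histidine is treated as neutral at
physiological pH; net charge uses formal charges only (Lys/Arg +1, Asp/Glu
−1, free termini +1/−1), with no pKa model.

# Conformer templates

`build_ideal_helix()` chains canonical bond geometry (Engh–Huber-like values)
with the classic 3.6₁₃ α-helix dihedrals (φ, ψ) = (−57.8°, −47.0°). With
this geometry the 20-residue helix has a per-residue rise of ~0.154 nm, a
Cα1–Cα20 axial extent of 2.93 nm and a mass-weighted R_g of 0.98 nm, inside
the 0.9–1.1 nm band that characterises the straight state. The slightly
shifted φ relative to the often-quoted (−57, −47) is deliberate: it is the
textbook 3.6-residues-per-turn parameterisation and keeps the rise at the
canonical 1.5 Å.

`build_bent_conformer()` creates the helix-loop-helix template by rebuilding
the chain from internal coordinates with the ψ dihedrals of the two hinge
residues (default 10 and 11) lowered by a common offset, solved (1-D root
finding) so that the principal axes of the two helical segments subtend the
requested angle. We rebuild from internal coordinates rather than rigidly
rotating the C-terminal arm because a rigid rotation about the hinge
midpoint breaks covalent geometry — at a 120° bend it collapses the hinge
Cα–Cα distance from 0.38 to 0.20 nm. The internal-coordinate bend keeps all
bond lengths and angles canonical, leaves every dihedral outside the two
hinge residues exactly helical, and drives the hinge ψ values ~55° outside
the helical window, so the loop is decisive rather than marginal under
noise. At the default 120° bend the template has R_g ≈ 0.65 nm, inside the
0.55–0.80 nm compact-state band, with the hinge serine side chain still
solvent-exposed on the elbow.

# The trajectory generator

`generate_trajectory(scenario(...))` is a *kinematic emulator*, not a
physics simulator: no force field, no thermostat, no solvent. It emulates
exactly the observable structure that the analysis modules consume:

* **Initial state.** `n_chains` copies (default 27) of the bent template on
  a cubic grid (default 5 nm spacing, 15 nm periodic box, i.e. 13 mM), all
  in the compact state, with optional per-chain initial rotations.
* **Merge events** `(time, a, b)`: the aggregate containing chain `b`
  approaches the aggregate containing `a` along their centre-of-mass line at
  constant velocity, reaching a 1.0 nm standoff one frame before the event
  and docking to a 0.35 nm minimum atom gap exactly at the event time. The
  standoff guarantees that, under the 0.5 nm contact cutoff, first contact
  is registered at the scheduled frame and never earlier. After a merge the
  joined aggregate moves as one body; an optional per-aggregate random walk
  (`rigid_diffusion_sigma_nm`) is off by default so that scripted aggregate
  series are exactly clean.
* **Straightening events** `(time, chain)`: the chain's template is replaced
  by the straight conformer, Kabsch-superposed onto its location at that
  moment — the transition is instantaneous between frames, matching the
  "snap" character of the observed transitions.
* **Noise.** I.i.d. Gaussian displacement per atom coordinate per frame.
  The default σ = 0.005 nm was calibrated once against the state
  classifier: at this level the two templates classify correctly in ≳99.8%
  of noisy frames (occasional flicker, as in real data), while at 0.01 nm
  dihedral jitter already scrambles 10–25% of labels. Scenarios that test
  exact event reconstruction use σ = 0.
* **Ground truth.** The full event schedule is attached to the trajectory as
  a ledger (and written as TSV by the pipeline), so detectors are tested
  against the exact script, never against themselves.

What the generator does *not* emulate: diffusive encounter kinetics (merges
are scripted, not emergent), internal helix breathing, partial/transient
unfolding, solvent effects, and any energetics. Consequently, passing tests
demonstrate that the *analysis* is correct and self-consistent on data with
known truth — not that the package reproduces the physics of a real
molecular-dynamics trajectory. Quantities that depend on all-atom detail
(absolute SASA levels, cluster occupancies of a real 2 μs run, absolute
transition times) are out of scope by design.

Trajectories are stored as multi-model PDB (one MODEL per frame, CRYST1 box,
chain identifiers per chain). Frame times are written as
`REMARK 250 FRAME i TIME_NS t` with full double precision so they round-trip
exactly; coordinates round-trip to the format's 10⁻³ Å resolution. The
reader validates MODEL/ENDMDL nesting and per-model atom counts and names
the offending model on failure. Internally all coordinates are nm; PDB I/O
converts to/from Å.

# Analysis conventions and numerical choices

* **Superposition** is Kabsch/SVD with the proper-rotation correction;
  degenerate (collinear) point sets are rejected. The quaternion
  characteristic-polynomial method serves as an independent oracle in the
  tests, never as the implementation.
* **RMSF** fits every frame to the *first* frame (an option fits to the mean
  structure), fitting on all atoms of the chain by default and reporting
  per-residue Cα fluctuations. For pure isotropic noise σ the per-residue
  RMSF converges to σ√3; the suite checks 2000 frames to within 5%.
* **SASA** uses Shrake–Rupley with a 0.14 nm probe and 960 golden-spiral
  quadrature points per atom (quadrature error < 0.5% on an isolated
  sphere; doubling the points changes the bent-template total by < 1%).
  Chains are assumed whole (the generator never wraps them); per-class
  totals pool all chains of a frame.
* **Helix assignment** is a dihedral-window criterion: residue helical iff
  φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] and it sits in a run of ≥ 4 such
  residues; termini are never helical. A hydrogen-bond-based assigner
  (DSSP/STRIDE-class) is intentionally not re-implemented: the state
  definitions used here reduce to "is the residue 5–17 span continuously
  helical", which the dihedral test answers directly, and the assignment
  function is an isolated seam where an external assigner could be plugged
  in. State calls on residues 5–17: all helical → *single-helix*; ≥ 2
  helical runs of ≥ 3 residues separated by a break → *helix-loop-helix*;
  otherwise *disordered* (an explicit third label, since real monomers also
  visit genuinely unfolded conformations). Requiring *all* of 5–17 for the
  single-helix call is the strictest reading; both the span and the run
  thresholds are arguments.
* **Occupancy** is reported over fixed `[k·w, (k+1)·w)` windows (default
  w = 10 ns); a final partial window reports its own frame count.
* **GROMOS clustering** computes all pairwise RMSDs with per-pair optimal
  superposition (matching the behaviour of the original tool, and unlike
  the single global fit used for PCA), then greedily extracts the frame
  with the most neighbours within the 0.3 nm cutoff. Tie rule: the earlier
  frame index wins — the algorithm's original description is silent and
  determinism requires a rule. Output clusters are ordered by size.
* **Cartesian PCA** fits frames to the starting conformation on the
  selection (default backbone N, Cα, C — 60 atoms, 180 coordinates for a
  20-residue chain), mean-centres with the trajectory mean, and
  eigendecomposes the unweighted covariance. Eigenvalues are clipped at
  zero against round-off; the eigenvalue sum equals the covariance trace to
  1e-8 and projections of the fitting trajectory have variance equal to
  their eigenvalue. `eigen_rmsf()` scales per-atom eigenvector norms by
  √eigenvalue.
* **Aggregates** are connected components (via `igraph`) of the chain
  contact graph: two chains are adjacent iff any inter-chain atom pair is
  closer than the cutoff under the minimum-image convention. The default
  0.5 nm cutoff is the 5 Å neighbour criterion; the aggregate-counting and
  neighbour-listing analyses share it, which the package assumes
  equivalent. A centroid/radius pre-filter skips distant chain pairs.
* **Contacts** are counted at atom-pair level and attributed to the
  residues of both atoms (a residue pair in contact through k atom pairs
  contributes k); a deduplicated mode (each residue pair at most once per
  chain pair and frame) is provided because the residue-level convention is
  genuinely ambiguous. Means are grouped by the chain's state label.
* **Transition detection** takes the first entry into single-helix whose
  occupancy over the following 50 ns window is ≥ 0.8. Both knobs are
  arguments: the stability of straightening is a qualitative observation
  ("irreversible"), not a printed criterion, so the window and threshold
  are explicit, configurable choices. The folded count N_h(t) is
  right-continuous (a transition at t counts at t).
* **Sigmoid fit.** The saturation model is fitted as
  N_h(t) = h_max / (1 + exp(−k (t − t₁/₂))) with k > 0 by
  Levenberg–Marquardt least squares (`minpack.lm`), initialised from the
  terminal count, the half-terminal crossing and the 10–90% rise span, with
  a small multi-start grid on failure. The printed form of the model uses
  exp(+λ(t − t₁/₂)), which increases with t only for λ < 0; we therefore
  fit the monotone-increasing parameterisation and report both k and
  λ = −k. At t = t₁/₂ the fitted curve equals h_max/2 identically.

# Problem sizes

The shipped tests and the acceptance script run entirely on generated data:
single-chain bend sweeps of 25–60 frames for PCA/clustering, 40-frame
two-basin sets for the clustering oracle, 30-atom random clusters against a
10⁵-sample Monte-Carlo surface oracle, a 2000-frame single-chain trajectory
for the RMSF noise limit, full 27-chain scenarios (2565 atoms) for the grid,
coalescence and transition-schedule reconstructions, and 2000-point series
for the kinetics fits. These sizes were chosen so each check is
statistically decisive for its tolerance while the whole suite stays
interactive.

# Known limitations

* The reduced representation cannot reproduce absolute all-atom SASA values;
  only relative and class-resolved behaviour is meaningful.
* The generator's merges are choreographed; the package does not model (and
  its tests cannot validate detectors against) diffusion-limited encounter
  statistics.
* Only orthorhombic (in practice cubic) boxes are supported, and β-sheet,
  3₁₀ or turn assignment is out of scope — the state vocabulary is exactly
  {single-helix, helix-loop-helix, disordered}.
* `fit_sigmoid` assumes a monotone saturating count; it rejects flat series
  and is not meant for non-monotone observables.
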