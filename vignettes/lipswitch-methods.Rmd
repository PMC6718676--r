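---
title: "Docking geometry, switched energies and transfer kinetics: the methods behind lipswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Docking geometry, switched energies and transfer kinetics: the methods behind lipswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipswitch)
```

## The problem

Lipid-transfer proteins of the ORP/Osh family shuttle phosphatidylserine
(PS) and phosphatidylinositol-4-phosphate (PI4P) between organelle
membranes. Understanding how such a protein docks onto a bilayer — how
high its center of mass sits above the headgroup plane, whether the
mouth of its lipid-binding pocket reaches the interfacial region, how
its C-terminal helix is tilted, and which residues actually touch the
membrane — requires a small set of well-defined geometric observables
computed frame by frame from molecular-dynamics-style trajectories.
Alongside the structural picture, the functional readout of transfer
activity comes from fluorescence assays whose raw intensities must be
normalized into extracted or delivered lipid, and family membership and
electrostatic character are established at the sequence level.

`lipswitch` implements this analysis machinery as a tested, reusable R
package, together with synthetic-data generators that produce
trajectories, traces and sequence sets with *known ground truth*, so
every stage can be validated end to end without any external download.

## Membrane docking metrics

All heights are measured against the **membrane reference plane**: the
arithmetic mean z of the headgroup nitrogen atoms (atom name `"N"`) of
the upper leaflet. The per-frame observables are

* **h** — the z distance between the protein's center of mass and the
  plane (signed; negative means below the plane);
* **h_entry** — the z distance between the plane and the joint mass
  center of all atoms of the three pocket-entry residues (129, 185 and
  190 by default), a proxy for whether the pocket mouth has reached the
  interfacial region;
* **theta** — the angle of the 346–356 helix segment. The segment axis
  is the first principal component of the segment's CA coordinates,
  with its sign fixed toward increasing residue number. PCA is used
  rather than an endpoint vector because it is robust to coordinate
  jitter; the endpoint variant is available (`axis_method =
  "endpoints"`) as a cross-check.

The angle is reported **against the membrane plane** by default (0° =
helix lying flat, 90° = perpendicular). A complementary `angle_ref =
"normal"` convention is exposed because both conventions circulate in
the literature; plane-referenced values were chosen as the default
because the docking figures this analysis style reproduces use them.

**Contact fractions.** A residue is in contact in a frame when the
*signed* z distance between its center of mass and the plane is
strictly below the threshold (default 5 Å; the comparison is `<`, so a
residue sitting exactly at the threshold is not a contact). Using the
signed rather than absolute distance means residues *below* the plane —
inserted loops — always count as contacts, which is the behaviour a
docking analysis wants. Whether an absolute-distance rule was intended
in prior work is ambiguous; the signed choice is deliberate and
flagged here. The contact fraction f is the percentage of analyzed
frames in contact.

**Masses.** Residue and protein centers of mass use unit masses by
default. This is exact for the single-pseudo-atom residues of the
synthetic fixtures, and for real all-atom residues it deviates from the
mass-weighted center by well under the 0.5–1 Å jitter the metrics
already tolerate. Physical masses (inferred from the first letter of
the atom name) are available via `masses = "physical"`.

**Sampling.** `sample_series()` emits one (h, h_entry, theta) sample
per stride; frames are laid out at `t = k × frame_interval`, so a
500 ns trajectory analyzed every 100 ps yields exactly 5000 samples
per observable.

RMSD uses closed-form Kabsch superposition (SVD of the
cross-covariance, reflection-corrected); RMSF superposes every frame
onto the time-averaged structure (two refinement sweeps), then reports
per-residue root-mean-square displacement from the average.

## Switched interaction energies

Protein–membrane nonbonded energies are pairwise sums over all
cross-pairs of

* Coulomb: `332.0636 · q_i q_j / r` kcal/mol (CHARMM constant, charges
  in elementary units, r in Å), and
* Lennard-Jones: `4 ε_ij [(σ_ij/r)¹² − (σ_ij/r)⁶]` with
  Lorentz–Berthelot combining (arithmetic σ, geometric ε),

both multiplied by a C¹-continuous cubic potential switch
`S(x) = 1 − 3x² + 2x³`, `x = (r − r_on)/(r_off − r_on)`, that takes the
interaction from full strength at `r_on = 10 Å` to exactly zero at
`r_off = 12 Å`. The production MD engines this emulates treat
electrostatics with particle-mesh Ewald, which has no meaning on a
small non-periodic fixture; applying the same switch to both terms is
therefore a deliberate desk-scale approximation, and absolute energy
magnitudes from this module are not comparable to values computed with
Ewald summation on full solvated systems. The vectorised evaluation is
tested to agree with the brute-force O(N²) double loop to 1e-9
kcal/mol.

## Accessible surface area

`shrake_rupley_asa()` samples each atom's expanded sphere (VDW radius +
probe, default probe 1.5 Å) with a deterministic golden-spiral point
set (default 960 points — no RNG, so ASA values are exactly
reproducible), and counts a point accessible when it lies outside every
other expanded sphere. Tests pin the single-sphere case to the
analytic `4π(r+probe)²`, the two-sphere case to the closed-form buried
spherical cap, and convergence (doubling the point count moves a
50-atom total by < 1%). The default radii are a standard element-keyed
set; they intentionally are *not* bit-compatible with any particular
legacy ASA program, and are configurable. `delta_asa()` subtracts
per-residue ASA of a full structure from that of a residue-subset
(truncated) structure, so positive values mark surface that the
deleted segment — e.g. an N-terminal lid — was covering.

## Assay quantification

With calibration anchors F0 (signal before protein addition), Fmax
(full-transfer or fully-bound reference) and Fmin (buffer-only):

* extraction% `= 100 (1 − (F − F0)/(Fmax − F0))`;
* transport normalization `F_Norm = (F − F0)/(Fmax − F0)`, the exact
  complement of extraction% (an identity the tests verify on random
  inputs);
* delivered ligand `= accessible × F_Norm` µM, where `accessible =
  total_lipid × ligand_mole_fraction × accessible_fraction`. The
  accessible fraction defaults to 0.5 (outer leaflet of a large
  unilamellar vesicle), which reproduces both standard configurations:
  200 µM lipids at 5% ligand → 5 µM, and 80 µM at 2% → 0.8 µM;
* bound% `= 100 (F − Fmin)/(Fmax − Fmin)`;
* dissociation traces carry no stated calibration and are min–max
  normalized, flagged as a convention.

The **initial transport rate** is the ordinary-least-squares slope of
delivered(t) over the first eight samples strictly after protein
injection, which at the default 0.5 s sampling span 4 s; the fit keeps
a free intercept so an injection artifact in the first point cannot
bias the slope. The per-protein turnover is `slope × 60 /
protein_conc` (lipids · min⁻¹ · protein⁻¹), normalizing by the total
injected protein concentration without a soluble-fraction correction.
Because the signal over a finite window is exponential, not linear,
the expected OLS slope is `accessible × k × c(k)` with the closed-form
finite-window factor `c(k) = cov(t, 1 − e^{−kt})/(k · var(t))` over the
eight sample times; the tests check the fitted slope against this
expectation rather than against the naive `accessible × k`.

`fit_transfer_k()` recovers the rate constant by Levenberg–Marquardt
nonlinear least squares of `F0 + (Fmax − F0)(1 − e^{−k(t−t_inject)})`,
holding the calibration anchors fixed by default (freeing them is an
option); the starting value comes from the early-slope/amplitude
ratio, and the fit is constrained to k ≥ 0.

## Sequence analysis

Motif semantics are **literal substrings** — the family signature
`EQTSHHPP` and the PS-recognition motif `LPTFILE` are literal patterns
— with a lone `x` accepted as a single-position wildcard; a full
pattern grammar is out of scope. Overlapping occurrences are all
reported. `filter_by_motifs()` retains sequences containing every
required motif and reports per-motif counts; absolute retained counts
from historical database snapshots are not reproducible and are not a
goal — only the filtering mechanics are.

Net charge is `(#K + #R) − (#D + #E)` with histidine neutral at pH ≈ 7
(configurable) and termini ignored — the convention under which a
lysine-rich N-terminal region scores "+4". Mutation presets follow the
lid charge-neutralization series (`L69D`; `4A` = D38A/D39A/D41A/E42A;
`5A2G` = 4A plus D43G/D44G/E45A, i.e. seven anionic residues
neutralized, Δcharge +7); every mutation checks the residue actually
present at the target position, so numbering drift fails loudly. No
reference protein sequence ships with the package — presets apply to
any user-supplied sequence under those guards.

## The synthetic-data generators

The generators define the study conditions for all recovery tests:

* **Bilayer** (`build_bilayer()`): headgroup-only pseudo-lipids — a
  single "N" atom per lipid — because every in-scope metric references
  only the headgroup-nitrogen plane. Defaults: 1000 lipids, 70/30
  neutral/anionic mix (counterion count 300 = |total anionic charge|),
  leaflet separation 38 Å (a typical fluid-PC phosphate–phosphate
  distance; nothing downstream depends on it beyond signs), ~181 Å
  patch (≈65 Ų per lipid), 1 Å z jitter. Species counts use
  largest-remainder apportionment with deterministic ties (anionic
  species first, then the upper leaflet).
* **Docking trajectories** (`simulate_docking_trajectory()`): a rigid
  pseudo-protein (synthetic construct, not derived from any deposited
  structure) is translated/rotated so its COM height and segment angle
  follow a piecewise-linear schedule *exactly*, then i.i.d. Gaussian
  noise (default 0.5 Å in the approach preset) is added to every atom
  coordinate. The schedule is therefore the ground truth; per-atom
  isotropic noise was chosen because it makes contact-fraction
  recovery tolerances computable from binomial statistics (residue-COM
  noise shrinks as `noise_sd/√atoms_per_residue`). The approach preset
  starts ~54 Å above the plane — a solvated pose well clear of the
  membrane — but its approach *kinetics* are scripted, not physical.
* **Transport traces** (`simulate_transport_trace()`): exponential
  transfer `F0 + (Fmax − F0)(1 − e^{−k(t−t_inject)})` plus additive
  Gaussian noise. The default rate constant k = 0.02 s⁻¹ was chosen
  once as realistic for this assay class (an initial rate of order
  0.1 µM/s over a 5 µM accessible pool implies k of this order).
* **Sequence sets** (`generate_sequences()`): motif-free random
  backgrounds (rejection-sampled) with the motif planted by
  substitution in a recorded fraction, re-drawn until it occurs
  exactly once, so planted positions are exactly what the scanner must
  find.

All generators are pure functions of (inputs, seed): they set the RNG
locally and restore the caller's state.

What the generators deliberately do **not** emulate — lipid tails and
their dynamics, water and explicit ions, membrane undulations and
curvature, protein internal flexibility, photobleaching and
instrument drift in traces — bounds what passing tests show: they
validate the *analysis machinery* (the estimators recover known truth
under Gaussian noise), not the physics of real membranes or the
photochemistry of real assays.

## Numerical choices and degenerate inputs

* Heights are signed; in-plane translations of the whole system leave
  every metric unchanged (tested).
* The contact comparison is strict (`<`), so threshold-exact distances
  do not count.
* PCA axes from SVD; segments whose atoms coincide are refused as
  degenerate rather than returning an arbitrary axis.
* Kabsch applies the determinant correction, so reflections are never
  returned; superposed RMSD ≤ raw RMSD always.
* The switch window requires `0 < r_on < r_off`; pair distances of
  exactly zero (overlapping atoms) are an error, not an Inf.
* Apportionment ties break deterministically (anionic, then upper
  leaflet), so bilayer composition is reproducible across platforms.
* Largest-remainder counts equal `round(n_lipids × anionic_fraction)`
  whenever the quota is exactly representable.
* Trace times must be strictly increasing at read time; calibration
  gaps are deferred to the operation that actually needs the missing
  anchor.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at sizes chosen to exercise every code path while staying quick
on a single CPU: bilayers of 20–1000 lipids, docking runs of 5–5000
frames (the full 500 ns × 100 ps grid is exercised once to confirm
the 5000-sample contract), 50 × 50 atom energy fixtures, 50-atom ASA
clusters, 100-seed Monte-Carlo kinetics recovery at 621 points per
trace. These sizes are the package's own validation choices; all are
parameters, and nothing prevents running the same estimators on
larger inputs.

## Known limitations

* Energies are desk-scale: no periodicity, no Ewald electrostatics,
  no intra-protein terms; only relative/structural conclusions are
  meaningful.
* ASA radii are a generic element-keyed set, not a faithful clone of
  any specific legacy program's table.
* The unit-mass COM default is an approximation for all-atom residues
  (exact for the pseudo-atom fixtures).
* Motif matching is literal; degenerate-position patterns beyond a
  single wildcard are unsupported.
* The dissociation-trace normalization is a min–max convention, as no
  calibrated anchors are defined for that assay mode.
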