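# lipswitch

Analysis toolkit for studies of lipid-transfer proteins (the ORP/Osh
family and relatives) docking onto membranes. It bundles, as one
tested R package, the quantitative machinery such a study needs:

* **Docking geometry from trajectories** — multi-model PDB input; the
  membrane reference plane (mean z of upper-leaflet headgroup
  nitrogens); the protein center-of-mass height *h*, the lipid-pocket
  entry height *h_entry* (mass center of residues 129/185/190), and
  the tilt *θ* of the 346–356 helix segment against the membrane
  plane; per-residue membrane contact fractions *f* (% of frames with
  signed z distance < 5 Å); Kabsch RMSD and per-residue RMSF.
* **Switched interaction energies** — pairwise Coulomb
  (`332.0636 q_i q_j / r`) and Lennard-Jones
  (`4 ε_ij [(σ_ij/r)¹² − (σ_ij/r)⁶]`, Lorentz–Berthelot combining)
  protein–membrane sums, both taken smoothly to zero between 10 and
  12 Å by the cubic switch `S(x) = 1 − 3x² + 2x³`.
* **Accessible surface area** — deterministic Shrake–Rupley ASA
  (golden-spiral sampling, probe 1.5 Å) and per-residue ΔASA between a
  full-length and a truncated structure, quantifying what a deleted
  lid was covering.
* **Assay kinetics** — fluorescence calibrations F0/Fmax/Fmin;
  extraction % = `100(1 − (F − F0)/(Fmax − F0))`; transport
  normalization `F_Norm = (F − F0)/(Fmax − F0)` and delivered ligand
  `accessible × F_Norm` µM (5 × F_Norm for the 200 µM / 5% /
  outer-leaflet configuration); bound % =
  `100 (F − Fmin)/(Fmax − Fmin)`; initial rates from an 8-point / 4 s
  OLS fit after protein injection, reported per minute per protein;
  exponential rate-constant fitting.
* **Sequence motifs and charge** — literal-motif scanning and
  filtering (EQTSHHPP signature, LPTFILE PS motif), peptide net charge
  `(#K + #R) − (#D + #E)`, and guarded mutation presets (L69D, 4A,
  5A2G) with Δcharge accounting.
* **Synthetic data with ground truth** — headgroup-only bilayer
  patches (70/30 neutral/anionic by default, counterions = |anionic
  charge|), scripted rigid-body docking trajectories with Gaussian
  noise, exponential transport traces, and motif-planted sequence
  sets, so every estimator is validated against known truth.

## Worked example

Build a charged bilayer patch, dock a rigid pseudo-protein along a
scripted schedule with 0.5 Å atom noise, and recover the geometry:

```r
library(lipswitch)

build_bilayer(bilayer_spec(n_lipids = 1000, anionic_fraction = 0.30),
              seed = 1)
#> <lip_bilayer> 1000 headgroup atoms (300 anionic), 300 implied counterions

bl  <- build_bilayer(bilayer_spec(n_lipids = 200, patch_side = 115,
                                  z_jitter_sd = 0.5), seed = 1)
sch <- docking_schedule(c(0, 1, 5), c(54, 12, 12), c(60, 10, 10),
                        noise_sd = 0.5, seed = 1)
sim <- simulate_docking_trajectory(pseudo_protein(), bl, sch,
                                   frame_interval = 100, duration_ns = 5)

tail(sample_series(sim$trajectory, every = 100), 3)
#>    time_ns      h h_entry theta_deg
#> 48     4.8 12.098   5.027    10.160
#> 49     4.9 12.042   5.799    12.596
#> 50     5.0 11.908   5.220    10.571

subset(contact_fractions(sim$trajectory, threshold = 5), f > 0)
#>    residue_id  f
#> 25        129 46
#> 26        185  2
#> 27        190 20
```

After the approach (54 Å → 12 Å, tilt 60° → 10°) the protein sits with
its center of mass ~12 Å above the headgroup plane, the pocket entry
~5 Å above it, the helix segment nearly flat — and the three
pocket-entry residues are the only ones in membrane contact, 2–46% of
frames each.

Quantify a transport assay (200 µM lipids, 5% ligand → 5 µM
accessible; 0.2 µM protein; 2% amplitude noise):

```r
cfg <- assay_config(200, 0.05, 0.5, protein_conc = 0.2)
tr  <- simulate_transport_trace(k = 0.02, F0 = 100, Fmax = 500,
                                t_inject = 10, noise_sd = 8, dt = 0.5,
                                duration = 310, seed = 4, config = cfg)
initial_rate(tr$trace, cfg)
#> <lip_rate_result> initial rate 0.07034 uM/s (21.1 lipids/min/protein), R^2 = 0.555

fit_transfer_k(tr$trace)$k
#> [1] 0.01991
```

The 8-point linear fit converts the normalized signal into an initial
delivery rate in µM/s and a per-protein turnover (slope × 60 /
protein); the full-trace exponential fit recovers the generator's rate
constant (0.02 s⁻¹) to within its standard error.

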