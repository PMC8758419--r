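# poregate

Structural annotation of tetrameric ion-channel pore models as **open** or
**non-conductive**, for structural biologists and simulators working on
voltage-gated sodium (and related) channels.

A channel pore can be closed without being sterically blocked: when the
activation-gate constriction is hydrophobic and narrow, water leaves it and
ions face a prohibitive free-energy barrier (*hydrophobic gating*). Whether
a pore model is open therefore depends jointly on its radius profile, the
hydration free energy of the gate, and the hydrogen-bond register of the
pore-lining helix — an α→π transition (i+4→i vs. i+5→i backbone hydrogen
bonds) inserts one residue into the helical register and rotates downstream
sidechains, flipping a conserved asparagine into the pore lumen.

`poregate` implements the full annotation pipeline:

* **Helix annotation** — DSSP-criterion backbone H-bond detection,
  α/π/3₁₀/defect classification, conserved-Asn sidechain H-bonds.
* **Pore geometry** — axis fitting for pseudo-C4 bundles, HOLE-style radius
  profiles (mean/SD/extremes over frames), pore-lining residues, and the
  pore-centred (x, y) orientation of the Cα→Cγ vector (x > 0 ⇒ pore-facing).
* **Solvent analysis** — axial water number density,
  ΔG(z) = −kT ln(n(z)/n_bulk) hydration profiles, per-frame wet/dry gate
  classification.
* **Energetics** — PMF window averaging with SD error bars, reference
  shifting, barrier extraction; short-range Coulomb + Lennard-Jones
  residue–ion energies; RMSD-cutoff (0.1 nm, single-linkage) pose
  clustering with medoid representatives; Henderson–Hasselbalch ionization
  and log P → ΔG partition arithmetic.
* **Model building** — the π-model register-shift recipe: gapped
  template/target alignment (one position upstream) and deterministic
  backbone threading, applied per chain or symmetrized across a tetramer.
* **Synthetic data** — ideal α/π/3₁₀ helices, C4 toy channels with a
  tunable gate, water fields Boltzmann-distributed against an imposed
  ΔG*(z), noisy PMF window ensembles, and planted ligand-pose clusters.

Everything runs on plain-text inputs (PDB, multi-model PDB trajectories,
CSV profile tables, FASTA alignments); no downloads are required anywhere.

## Worked example

Build a register-shifted (π) model from an ideal α-helical template and
annotate it:

```r
library(poregate)

h   <- make_ideal_helix(30, "alpha", first_resno = 200)
aln <- build_shift_alignment(poregate:::chain_sequence(h, "A"),
                             register_shift("A", 207, 225))
thr <- thread_backbone(h, aln)
hb  <- detect_backbone_hbonds(thr)
hb[hb$offset == 5, ]
#>   chain donor_resno acceptor_resno offset     energy
#> 4     A         207            202      5 -0.7063447
#> 5     A         208            203      5 -1.5556172
#> 6     A         209            204      5 -2.2230887
#> 7     A         210            205      5 -2.2230887
```

The first shifted residues (207–210) now donate i+5→i bonds back to the
unshifted flank — the π-helix signature. On the hydration side:

```r
gate <- data.frame(height = 12.55, center = -10, width = 6)  # 3 kcal/mol
tr   <- sample_waters(gate, n_frames = 2000, seed = 20260926)
sp   <- attr(tr, "spec")
dens <- water_density_profile(tr, pore_axis(), sp$z_range,
                              sp$cylinder_radius, sp$bin_width,
                              bulk_density = sp$bulk_density)
fe   <- hydration_free_energy(dens, 300)
fe$dg[which.min(abs(fe$z + 10))]
#> [1] 12.77922
```

The density→ΔG estimator recovers the imposed 12.55 kJ/mol gate barrier to
within the Poisson sampling error (~0.15 kJ/mol at these sizes). Drug
arithmetic:

```r
ionization_fraction(9.3, 7.4, "base")
#> base with pKa 9.30 at pH 7.40: 99% charged, 1% neutral
logp_to_dg(1.49, 298)
#> [1] -8.500694
```

The numbered drivers under `analysis/` run the same pipeline end to end
(helix annotation → register-shift model → pore hydration → energetics and
drugs) and write their tables under `results/`.

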