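---
title: "Annotating channel pore models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating channel pore models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Voltage-gated sodium channels conduct through a central pore whose
intracellular end — the activation gate — is lined by hydrophobic residues.
A pore can be non-conductive without being sterically occluded: if the gate
constriction is hydrophobic and only a few Angstrom wide, water leaves it
(hydrophobic gating), and an ion facing a dewetted gate sees a prohibitive
free-energy barrier. Deciding whether a given structural model represents an
open, conductive state therefore requires more than a radius profile: one
needs the hydration behaviour of the gate, the backbone hydrogen-bond
pattern of the pore-lining helix (an α→π transition rotates downstream
sidechains by roughly a quarter turn and can flip a conserved polar residue
into the pore), and the energetics of ions and blockers along the pore axis.

`poregate` implements that annotation pipeline as composable operations on
structures, trajectories and 1D profiles, together with synthetic generators
that make every stage testable end to end without any external data.

## Coordinate and unit conventions

Coordinates are Angstrom throughout; densities are nm⁻³; energies are stored
in kJ/mol with kcal/mol available where the literature mixes both
(1 kcal = 4.184 kJ; kT at 300 K = 2.4943 kJ/mol = 0.5961 kcal/mol). The
pore axis points toward the extracellular side (+z), and the z origin is
placed so that the activation gate of a pore domain falls near z = −10 Å.
Trajectories are multi-model PDB natively — the test surface is
download-free — and all frames of a trajectory must hold the same atoms in
the same order; this congruence is enforced at construction, so no
downstream operation can receive inconsistent frames.

## Backbone hydrogen bonds and helical patterns

`detect_backbone_hbonds()` pairs each amide donor with its best carbonyl
acceptor using the DSSP electrostatic model,

$$E = 0.084 \left(\frac{1}{r_{ON}} + \frac{1}{r_{CH}} - \frac{1}{r_{OH}}
      - \frac{1}{r_{CN}}\right) \cdot 332\ \mathrm{kcal/mol},$$

accepting bonds below −0.5 kcal/mol. This is the community-default
criterion; a purely geometric alternative (N···O ≤ 3.5 Å, N–H···O ≥ 120°)
is selectable. Amide hydrogens, absent from X-ray models, are rebuilt
1.01 Å from N opposite the bisector of the N–CA and N–C(prev) bonds. A
donor with both an i+4 and an i+5 acceptor below threshold keeps the
lower-energy bond, with exact ties resolved toward the smaller offset, so
annotation is deterministic.

`classify_helix_pattern()` labels a residue `pi` only if it actually
participates in an i+5→i bond; a residue that merely lost its expected i+4
bond is a `defect`, never `pi`. This distinction matters at register
boundaries, where disrupted i+4 bonds and genuine π bonds co-occur.
Unpaired carbonyls are reported only where an i+4 donor position exists
inside the segment, so ordinary C-terminal fraying is not misreported as a
defect.

### Ideal helix dihedrals

The fixture generator builds helices from ideal internal coordinates
(N–CA 1.458, CA–C 1.525, C–N 1.329, C=O 1.231 Å; ω = 180°). For the
α-helix it uses the textbook (φ, ψ) = (−57°, −47°) and for 3₁₀
(−49°, −26°). For the π-helix we deliberately use the classic *ideal
repeat* (−57°, −70°) — 4.2 residues/turn, ~1.0 Å rise — rather than the
average values reported for observed π-segments (−76°, −41°): repeated with
ideal bond geometry, the observed-average pair places O(i)···N(i+5) at
~4.0 Å and O(i)···N(i+4) at 2.8 Å, i.e. it does not reproduce i+5 bonding,
whereas the ideal repeat yields exclusively i+5 bonds. Observed π-helices
are short and irregular, so their mean dihedrals need not correspond to any
self-consistent repeating geometry.

## Pore geometry

The pore axis of a pseudo-C4 channel is fitted from four subunit
selections: the origin is the pooled centroid and the direction is the
normal of the best-fit plane through the four subunit centroids. (The
naive choice — the leading principal component of all atoms — fails for
wide, short bundles, where the in-plane spread exceeds the helix length.)
Planar inputs, which have no extent along the axis, are rejected.

The radius profile is HOLE-style but deliberately simpler: with a straight
axis and a slab of half the bin width per bin, the pore radius is the
minimum over in-slab atoms of (axial distance − vdW radius), floored at
zero, using a fixed element table (C 1.70, N 1.55, O 1.52, S 1.80,
H 1.20 Å). The pore here is four-fold symmetric and near-straight, and the
slab-minimum rule is exactly testable against an analytic cylinder. Bins no
atom covers are reported at a probe cap (default 10 Å) and flagged rather
than silently interpolated. Profiles aggregate mean, SD and extremes over
frames, matching how such profiles are usually drawn (dark shade SD, light
shade extremes).

The sidechain-orientation metric places the residue's Cα at the origin,
takes x̂ from Cα toward its own projection onto the pore axis (so
**positive x means pore-facing**), ẑ along the axis and ŷ = ẑ × x̂, and
reports the (x, y) components of the Cα→Cγ vector. The "pore-center point"
is taken per residue (the projection of its own Cα) — the closest literal
reading when a single center is not otherwise defined — and the metric is
invariant under rigid motions and translations along the axis. One point is
emitted per chain; callers aggregate across subunits as they see fit.

## Water density and hydration free energy

`water_density_profile()` counts water oxygens per axial bin inside a
sampling cylinder (default radius 8 Å — wide enough to cover the pore,
narrow enough to exclude membrane waters) and converts to nm⁻³. Bulk
density is estimated from the two outermost 5 Å z-bands or supplied
explicitly (33.4 nm⁻³ is the ambient-water-like default used by the
synthetic generator). The hydration free energy is the Boltzmann inversion

$$\Delta G(z) = -k_BT \ln \frac{n(z)}{n_{bulk}},$$

with first-order error propagation (kT·sd/mean). Bins with zero observed
density cannot be inverted; they are reported at a cap (default
+25 kJ/mol) and flagged, rather than as infinities — published hydration
profiles truncate similarly, and the cap is an explicit parameter. Error
bars are standard deviations over frames; a stride parameter controls
which frames enter (profiles in the literature typically use ~1 ns
spacing), since the equilibration cutoff is a judgement call we leave to
the caller.

Per-frame wetting at the gate is classified by count: a frame is wet when
the gate window holds at least a threshold fraction (default 0.1) of the
bulk-expected water count for that volume. The state depends only on the
count series and the threshold, so transition counting is trivially
reproducible.

## The synthetic water field and what passing tests show

`sample_waters()` draws, per frame and axial bin, a Poisson count with mean
$n_{bulk} e^{-\Delta G^*(z)/k_BT} \pi r^2 \Delta z$ against an imposed
Gaussian-sum profile ΔG*(z), with positions uniform in the bin cylinder.
It is the exact statistical inverse of the density→ΔG estimator, which is
the point: estimator recovery can be tested to quantitative tolerances.
Conditions for the recovery experiments are fixed at bulk 33.4 nm⁻³,
cylinder radius 10 Å, z ∈ [−31, 31] Å with 2 Å bins (the grid is chosen so
that z = −10 Å, the activation gate, is a bin center), a gate barrier of
12.55 kJ/mol (3 kcal/mol — the scale of the hydration barrier of a
dewetted α-model gate) with σ = 6 Å, and 2000 frames. At these sizes the
Poisson error at the barrier peak is ≈ 0.15 kJ/mol, and the whole
experiment runs in under a second.

Because every frame of a trajectory must hold the same atom count while
Poisson counts fluctuate, frames are padded to the ensemble maximum with
inert placeholder particles parked ~100 Å below the sampled range; they can
never enter an analysis window. The generator emulates only the axial
statistical structure of pore water: point oxygens, no water geometry,
no membrane, no protein excluded volume, no time correlation between
frames. Passing recovery tests therefore validates the *estimator* and its
error model, not the molecular realism of any simulation.

## PMF post-processing

PMFs arrive as external tables (the output of adaptive-bias simulations;
the biasing itself is out of scope). `average_pmf()` implements the
tail-window protocol: profiles estimated at regular intervals over the end
of a run are averaged per bin, and the error bar is the standard deviation
over that window set — the population SD, since the windows *are* the data
set being summarised, not a sample from a larger one (the two-window
worked example 0 and 2 kJ/mol then gives mean 1, SD 1). Reference shifting
subtracts the value at an anchor bin (bulk water or bilayer center);
barrier height is max-over-region minus min-over-baseline and is exactly
invariant under shifting. Ties at the maximum resolve to the smaller z.

## Interaction energies, clustering, drug arithmetic

Residue–ion interaction energies are plain short-range sums within a 12 Å
cutoff: $f q_i q_j / r + 4\varepsilon[(\sigma/r)^{12} - (\sigma/r)^6]$ with
f = 138.935 kJ·nm/(mol·e²) and Lorentz–Berthelot combination. Charges and
LJ parameters must be supplied — the package does not guess force-field
parameters, and a missing parameter is an error naming the atom.

Pose clustering follows the cutoff scheme: two snapshots share a cluster
if the RMS distance of the ligand position is below the cutoff
(default 0.1 nm) from any other member — single-linkage connected
components, computed by union-find and verified in the tests against an
independent graph-components implementation. Distances are computed
*without* re-superposition by default, because the pose position in the
channel frame is the variable of interest; an optional superposition flag
exists. Clusters order by size (ties: smallest member index), and the
representative is the medoid — the member minimizing mean RMS distance to
its cluster — as a concrete reading of "the center of the most populated
cluster".

Ionization fractions are Henderson–Hasselbalch: a base is charged with
fraction $1/(1+10^{pH-pK_a})$. The operation takes pH explicitly; at
pH 7.4 a pKa of 9.3 gives 99% charged, while a pKa of 7.56 gives 59% —
figures of ~70% quoted for lidocaine imply a somewhat lower pH than 7.4,
so no attempt is made to reproduce them at fixed pH. Partition free energy
is $\Delta G = -\ln(10)\,R\,T\,\log P$ (log P 1.49 at 298 K →
−8.5 kJ/mol).

## Register-shift model building

The π-model recipe is a one-position upstream register shift across a
helix segment, encoded as a gapped pairwise alignment: one gap in the
template row immediately before the first shifted residue, one in the
target row immediately after the last. Inside the region target residue k
pairs with template residue k−1; the flanks stay identity-aligned.
Threading then copies the template partner's backbone (N, CA, C, O)
verbatim onto each paired target residue. The gap-bridged residue — the
target residue left over the template gap — receives linearly interpolated
backbone positions between its threaded neighbours and is flagged
low-confidence; interpolation (rather than deletion) keeps the chain
continuous for annotation. No restraint-based refinement or sidechain
rebuilding is applied: the construction is deterministic and exactly
testable, and refined models are expected to come from dedicated modelling
tools when needed. Re-applying a shift to an already-shifted structure is
refused (the operation does not compose). Applied to an ideal α-helical
template, the threaded model donates i+5→i bonds from the first shifted
residues back to the unshifted flank — the π signature — with a helical
defect at the register boundary.

## Degenerate inputs and numerical tie-breaks

* Empty radius-profile slabs → probe cap + flag; never NA.
* Zero-density bins → ΔG cap + flag; never ±Inf.
* Equal-energy H-bond acceptors → smaller offset wins.
* Equal PMF maxima → smaller z wins.
* Clustering uses strict `<` at the cutoff, matching the "less than"
  phrasing of the cutoff scheme.
* All generators are pure functions of (parameters, seed) and restore the
  caller's RNG state.

## Problem sizes

The test suite and the reproduction script use 15–30 residue helices,
four-helix toy channels of ~300–400 atoms, 2000-frame water fields,
10-window PMF ensembles and 200-frame pose sets. These sizes put every
statistical check at least ~3 standard errors away from its tolerance
while keeping the full suite near ten seconds.

## Known limitations

* The radius profiler assumes a straight, near-axial pore; curved-channel
  (spline) pathfinding is out of scope.
* Backbone threading does not rebuild sidechains; orientation metrics on
  threaded toys use pseudo-Cγ atoms placed by the toy-channel generator.
* The synthetic water field has no inter-frame correlation, so wetting
  *kinetics* (transition rates) on synthetic data are not meaningful —
  only state classification is.
* Binary trajectory formats (XTC/DCD) are supported only through the
  multi-model-PDB adapter contract: convert externally, then analyse.
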