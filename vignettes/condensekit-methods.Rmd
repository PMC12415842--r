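---
title: "condensekit: models, conventions, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{condensekit: models, conventions, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(condensekit)
```

This vignette is the package's own account of the science it
implements: the statistics, their assumptions, the tunable parameters
with their defaults and units, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design
was genuinely open. It states no empirical result that the test suite
or the acceptance script does not itself compute.

## The system this toolkit targets

Phase-separating multidomain proteins — full-length FUS is the
archetype — combine long intrinsically disordered regions (a
low-complexity prion-like domain, arginine–glycine–glycine-rich
stretches) with small folded domains (an RNA-recognition motif, a
RanBP2-type zinc finger held together by a Zn²⁺–cysteine tetrad). The
same residue-level interactions that compact a single chain in dilute
solution — π–π and cation–π contacts of Tyr/Phe/Arg, hydrogen bonding
of Gln/Ser, electrostatics of Asp/Glu/Arg/Lys — also cross-link chains
inside the condensed phase. All-atom simulations of such systems
produce (a) single-chain ensembles and (b) slab phase-coexistence
trajectories, and both need the same family of analyses.

Units everywhere: lengths in Å, times in ps, masses in amu, energies in
kcal/mol. The one exception is the flat-bottom restraint block, whose
parameters are conventionally printed in nm and are kept in nm.

## Contacts: summed heavy-atom pairs, not binary occupancy

Two residues are "in contact" when any pair of their heavy (non-H)
atoms is at distance `d < 4.5` Å (strict inequality — a tie at exactly
the cutoff does not count; some convention had to be picked, and this
one is asserted in the tests). The per-pair statistic is the **number**
of heavy-atom pairs under the cutoff, summed per frame and averaged
over frames. Relative to a binary definition this grades interaction
strength — a stacked Tyr–Tyr pair contributes tens of atom pairs, a
grazing backbone brush one or two — at the documented cost of a bias
toward large planar side chains. The bias is real and shows up in our
own planted-structure tests (below).

Same-chain pairs with sequence separation `|i − j| ≤ 4` are excluded
("five-residue proximity": separation 5 is the first one counted); the
window is a parameter of `contact_params()`. The intermolecular channel
ignores the window entirely, and `intra + inter = total` holds
elementwise. Minimum-image distances are used whenever the model
carries an (orthorhombic) box.

The kernel is a brute-force C++ double loop over heavy atoms
(`O(N²)` with squared-distance comparison) — at the system sizes this
package targets (≤ ~10⁴ heavy atoms per frame) a cell list buys little
and costs auditability. The test suite holds the kernel to *exact*
equality with an independent pure-R residue-pair double loop on 50
random frames.

Derived tables: per-position profiles (both endpoints credited, so the
profile sums to twice the matrix total), domain-block aggregates (grand
total conserved; positions outside every range collect in an
"unassigned" block with a warning), the 210-bin residue-type pair table
(ratios sum to 1; rankings invariant under uniform scaling), per-type
contacts normalised by sequence abundance, and Pearson correlation
between two tables. Bins that are zero in **both** tables are dropped
before correlating — structural zeros shared by two sparse tables would
otherwise inflate `r`.

## The F–R stacking pair correlation g(r, θ)

For each phenylalanine ring (CG, CD1, CD2, CE1, CE2, CZ) and arginine
guanidinium (CZ, NE, NH1, NH2), `r` is the distance between the
mass-weighted centres of those side-chain heavy-atom groups (minimum
image), and `θ` the angle between the two best-fit plane normals.
Normals come from the smallest principal axis of the centred group —
robust to non-exact planarity; their sign is meaningless, so `θ` is
folded into [0°, 90°]. Histogram bins are 0.6 Å × 2.5°, `r_max` 12 Å by
default.

Raw counts over-represent perpendicular orientations and large
distances simply because the `(r, θ)` measure grows like `r² sin θ`.
Each bin is therefore divided by the **exact integral** of `r² sin θ`
over the bin, `[Δ(r³)/3]·[Δ(−cos θ)]`, rather than by the bin-centre
value — the difference matters precisely where stacking lives: a bin
touching `θ = 0` has a finite exact volume but a vanishing bin-centre
weight. The overall normalisation constant of the estimator is not
pinned down by the definition, so `g` is rescaled to mean 1 over
sampled bins (recorded in the object; switchable off).

Two estimator properties worth knowing, both measured during
development and reflected in the tests:

* Under sampling that is uniform with respect to `r² sin θ dr dθ`, the
  corrected `g` is flat (χ² against the exact bin volumes, p > 0.01 at
  10⁵ samples).
* The argmax of corrected `g` is only a faithful mode estimator when
  the planted geometry sits where the correction is locally flat-ish or
  maximal — i.e. at the physical stacking geometry `θ ≈ 0`. A tight
  cluster planted at `θ = 5°` with realistic angular noise (~3.5° sd
  from 0.1 Å coordinate jitter) has its *counts* mode in the right bin
  but its *g* mode dragged into the lowest-θ bin, because the `1/sin θ`
  weight grows faster across the noise cloud than the density falls.
  That is a property of the estimator, not an implementation artefact;
  the acceptance test plants at (4.5 Å, 0°) — a bin centre at the
  face-to-face stacking geometry — where mode recovery is unambiguous.

Whether intramolecular F–R pairs should enter the condensate `g` is not
settled by the definition; `accumulate_g(intermolecular_only = )`
provides both.

## Chain metrics

`Rg` is mass-weighted by default (`sqrt(Σ mᵢ|xᵢ − x_com|²/Σ mᵢ)`),
`Dee` is the distance between the CA atoms of the chain's first and
last residues (endpoints had to be defined; CA–CA is the convention
here). Chains are made whole across periodic boundaries before any
dimension metric — a bonded-neighbour walk shifts each residue by box
vectors to stay within half a box of its predecessor — because wrapped
coordinates otherwise dominate both metrics.

Autocorrelation functions are mean-removed and variance-normalised;
the integrated autocorrelation time uses the Sokal self-consistent
window (smallest `W ≥ c·τ(W)`, `c = 5`). An AR(1) process with
`φ = 0.9` has the closed form `τ = (1+φ)/(1−φ) = 19`, which the tests
require within 20%. The equilibration suggestion is deliberately crude
(smallest 5%-grid prefix whose removal brings the running mean within
one sd of the second-half mean) — it mimics the "inspect the ACF, drop
the first stretch" workflow, and in the report pipeline the default
policy is simply to drop the first 20% of frames unless told otherwise.

**Hull hydrodynamic radius.** The convex hull of the heavy atoms
captures the rugged solvent envelope that an equivalent sphere of the
bare `Rg` misses. The implementation: a pure-R incremental 3-D hull
(volume from fan tetrahedra, verified against closed forms for the
cube and tetrahedron), then

```
Rh = F(p) · ( (3 V_hull / 4π)^{1/3} + w )
```

with hydration shell `w = 2.8` Å (one water diameter) and `F(p)` the
Perrin translational friction factor of a prolate ellipsoid with axial
ratio `p` taken from the covariance of the selected atoms (the hull
*vertex* covariance was tried first and rejected: the vertex set is
tolerance-sensitive, so rotating the frame could change `Rh` by ~0.4%;
the atom covariance is exactly invariant). All constants are recorded
in the result's metadata. Because the published reference program for
hull-based `Rh` cannot be redistributed or fetched here, the
independent check is a clearly-labelled synthetic stand-in oracle
(`inst/extdata/hullrad_oracle_synthetic.py`): the same documented
formula implemented in Python over scipy's independent hull. Agreement
(required within 1%, observed ~1e-9 relative) certifies the hull
computation and the downstream arithmetic through two unrelated code
paths; it cannot certify the constants themselves, which are a
documented modelling choice.

RMSD uses Kabsch superposition restricted to proper rotations
(`det = +1`; a mirror image scores nonzero by design), fit and measure
selections separable. RMSF superposes all frames on their mean
structure, refines the mean once, and reports per-atom fluctuation;
a separate `fit` subset lets a mobile atom be measured without letting
it contaminate the alignment.

## Slab profiles and ion partitioning

Density profiles bin atom masses along z (default bin 2.5 Å) after
recentring each frame so the protein centre of mass sits at the box
midpoint — slabs drift, and without recentring the time-average smears
the interface. Conversions: 1 amu/Å³ = 1660.54 mg/mL; counts/Å³ ×
1.66054·10⁶ = mM. Binning is exhaustive, so per-component mass is
conserved exactly (asserted to 1e-9 relative), and the profile is
invariant under whole-box z-translations.

The dense phase is the largest contiguous run of bins (circular) whose
smoothed protein density exceeds half the plateau (plateau = mean of
the top decile of smoothed bins; threshold is a parameter). "No dense
phase" is a result, not an error.

Ion partitioning uses the electroneutrality closure: inside the
condensate the fixed protein charges must be balanced by the mobile
ions, so `Na(z) = bulk + c_anionic(z)` and `Cl(z) = bulk +
c_cationic(z)`, with cationic = Arg + Lys (His optional, neutral by
default since protonation is system-specific) and anionic = Asp + Glu,
counted at one site per residue (the CA position). The closure's
defining invariant, `Cl(z) − Na(z) = c_cat(z) − c_an(z)`, holds
identically up to one ulp of round-off from the bulk additions. A
net-positive protein therefore predicts — and the synthetic slab
generator plants — a dense-phase Cl⁻ excess over Na⁺.

## Flat-bottom restraints

The restraint potential keeps native hydrogen-bond donor–acceptor
distances near their reference without fighting thermal motion:

```
V(r) = ½k(r−r0)²               r < r0
     = 0                       r0 ≤ r ≤ r1
     = ½k(r−r1)²               r1 < r ≤ r2
     = ½k(r2−r1)(2r−r2−r1)     r > r2
```

with defaults k = 20 kcal·mol⁻¹·nm⁻², r0 = 0.27, r1 = 0.30,
r2 = 0.35 nm. The printed unit "kcal/nm²" is read as per-mole (a
per-particle energy would be nonsensical at this magnitude). The
published piecewise conditions contain a duplicated range and omit the
harmonic-outside branch's interval; the form above is the unique C¹
continuous completion — both branches give `½k(r2−r1)² = 0.025`
kcal/mol and slope `k(r2−r1) = 1.0` kcal·mol⁻¹·nm⁻¹ at `r2` — and the
tests verify continuity by branch-equality at machine precision rather
than by finite differences (which can only shrink like slope × ε).

H-bond pairs are derived geometrically (N donors, O acceptors,
d ≤ 3.5 Å, ≥ 2 residues apart; D–H···A ≥ 120° when hydrogens exist,
else a carbonyl-direction filter), keeping pairs present in ≥ 50% of
the models of a multi-model input. This is a stand-in for
experimentally derived bond lists, which are usually not published.

## The synthetic-data generator: a stated world

Every analysis stage is tested against data with planted, known
structure. The generator is a *test bed*, not a physical sampler:

* Backbones are freely-jointed CA walks at 3.8 Å bonds — no excluded
  volume, so chains are maximally collapsed relative to real IDPs.
  Consecutive-bond lengths are exact by construction.
* Side chains are pseudo heavy atoms on a deterministic local frame
  within ~2.5 Å of the CA. Only the heavy-atom **count** per residue
  type is faithful, plus exact planar geometry for PHE rings (C–C
  1.39 Å) and ARG guanidinium groups (C–N 1.33 Å), and named CB/SG
  atoms for CYS so zinc analyses resolve.
* Folded domains are rigid compact clusters, generated once and
  rigidly re-placed each frame — RMSD of a rigid domain is exactly
  zero, which is the point.
* Planted contacts bridge the walk so the two CA atoms meet at the
  requested distance in every frame, and the side chains are placed
  into the interface, as a genuinely bound pair's would be. Without
  that engagement a planted contact is indistinguishable from the
  transient collisions of the collapsed backbone (measured: 3/20 seeds
  recovered vs 20/20 with engagement on a designed sequence).
* Slabs place chain centres inside the dense z-extent with per-frame
  rigid jitter, pseudo-water uniformly (single beads carrying the full
  18.0153 amu), and ions uniformly plus planted dense-region excesses;
  the protein's net formal charge is compensated by extra counterions
  placed in the dense region (Donnan-style).
* Everything is a pure function of the spec, seed included.

Consequently a green test establishes that the **estimators** recover
planted structure under stated noise — it says nothing about force
fields, sampling, or real conformational ensembles, whose headline
observables (multi-microsecond Rg/Rh distributions, ~500 mg/mL
condensate densities) are out of desk-scale reach by construction.

Because the summed-heavy-atom statistic scales with residue size, the
planted-contact recovery world uses a glycine background with ARG/TYR
at the planted sites: on a fully random sequence, bulky neighbours of
the planted pair (whose proximity is itself induced by the planting)
can out-count a small planted pair. This is the statistic's documented
size bias, surfaced by our own generator — not a failure of either.

## Degenerate inputs and tie-breaks

* Empty atom selections warn (they are legal); empty frame ranges and
  empty trajectory files error.
* `plane_normal` on collinear atoms errors; hull construction on
  coplanar points errors.
* Constant series: ACF defined as 1 at lag 0 and 0 elsewhere, with a
  warning.
* Ties at the contact cutoff are excluded (strict `<`); knot-boundary
  assignment in the restraint potential is `≤` on the flat side, which
  is observationally irrelevant since branch values coincide there.
* PDB residue numbering is preserved as written; chains with blank
  chain id become chain "A"; elements are inferred from names when the
  element column is blank, and unknown elements fall back to a carbon
  mass with a warning.

## Known limitations

* XTC input requires the Python/MDAnalysis bridge; PDB and DCD are
  native. Only orthorhombic boxes are supported.
* The hull-Rh constants (2.8 Å shell, prolate Perrin factor) are a
  documented modelling choice cross-checked against a synthetic
  stand-in oracle, not against the original published program.
* The ion-partition closure is the simplest electroneutrality model;
  it ignores ion–ion correlations and activity effects.
* Contact kinetics (lifetimes, on/off rates) and SASA are out of
  scope.
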