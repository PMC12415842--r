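# condensekit

Trajectory analysis for all-atom simulations of phase-separating
multidomain proteins — the kind of system typified by full-length FUS,
where disordered low-complexity and RGG regions carry folded RRM and
zinc-finger domains, and where the same residue-level interactions that
compact a single chain also drive liquid–liquid phase separation into a
protein-dense condensate.

The package is aimed at simulators who already have trajectories (from
GROMACS/Amber/OpenMM or similar) and want the condensate-specific
analyses in one tested, scriptable toolkit. It deliberately runs no MD
itself.

## What it computes

**Summed heavy-atom contacts.** Two residues are in contact when any of
their heavy-atom pairs is closer than 4.5 Å; the residue-pair statistic
is the *number* of such heavy-atom pairs (not a 0/1 occupancy), averaged
over frames, with same-chain pairs within a 5-residue sequence window
excluded. Contact maps carry intra- and intermolecular channels,
per-position profiles, domain-block aggregates, residue-type pair
ratios (210 unordered type bins summing to 1), per-type
abundance-normalised contacts, and Pearson correlations between
conditions (e.g. dilute vs condensed).

**π-stacking pair correlation.** For every phenylalanine ring /
arginine-guanidinium pair, `r` is the distance between the side-chain
heavy-atom centres of mass and `θ` the angle between the two plane
normals, folded into [0°, 90°]. The 2-D histogram (0.6 Å × 2.5° bins) is
corrected by the exact per-bin integral of the `r² sin θ` volume
element,

```
g(r, θ) ∝ Σ_F Σ_R δ(r − r_FR) δ(θ − θ_FR) / (r² sin θ)
```

so a low-θ, ~4–5 Å peak indicates genuine face-to-face stacking rather
than the geometric abundance of perpendicular orientations.

**Chain dimensions and stability.** Per-frame radius of gyration and
end-to-end distance (with PBC-unwrapped chains), autocorrelation
functions with a Sokal-windowed integrated autocorrelation time and an
equilibration suggestion, a convex-hull hydrodynamic radius
(equivalent-sphere radius of the hull + 2.8 Å hydration shell × Perrin
prolate shape factor), Kabsch-superposed RMSD (proper rotations only)
and RMSF for folded domains, and Zn–S distance / Zn–S–Cβ angle reports
for zinc-finger coordination.

**Slab condensate profiles.** Per-component mass densities (mg/mL) and
ion concentrations (mM) along z with protein-COM recentring, dense/
dilute phase assignment, and the Donnan-style ion-partition prediction
`Na(z) = bulk + c_anionic(z)`, `Cl(z) = bulk + c_cationic(z)`, whose
difference equals the local fixed-charge concentration identically.

**Flat-bottom restraints.** The piecewise potential (zero on
[r0, r1], harmonic outside, linear with bounded force beyond r2;
defaults k = 20 kcal·mol⁻¹·nm⁻², r0/r1/r2 = 0.27/0.30/0.35 nm), H-bond
pair derivation from a native structure, and tabular export.

**Synthetic data.** A seed-reproducible generator of single chains and
multi-chain slabs with planted contacts, planted stack geometries,
rigid folded domains, pseudo-water and Na/Cl — the test bed for every
stage above. See the methods vignette for what it does and does not
emulate.

## Worked example

```r
library(condensekit)

spec <- synthetic_spec(seed = 7, chain_length = 60, frames = 5,
                       planted_contacts = data.frame(res_i = 10,
                                                     res_j = 50,
                                                     distance = 4.0))
m <- generate_chain(spec)
m
#> SystemModel: 488 atoms, 60 residues, 1 chain(s), 5 frame(s)
#>   components: protein=60

cm <- ensemble_contact_map(m)
cm
#> ContactMatrix: 60 positions, 5 frame(s), 1 chain(s); mean total contacts/frame = 3665.4
cm$total[10, 50]          # the planted pair, mean heavy-atom pairs/frame
#> [1] 10.4

pair_ratio_table(cm)      # residue-type interaction ranking
#> PairRatioTable: total contacts/frame = 3665.4
#>   type_i type_j contacts      ratio rank
#> 1    LYS    TRP    135.0 0.03683091    1
#> 2    ARG    TRP    121.8 0.03322966    2
#> ...

rh <- hullrad_rh(m, 1)    # convex-hull hydrodynamic radius
sprintf("Rh = %.2f A (hull %.0f A^3)", rh$rh, rh$hull_volume)
#> "Rh = 16.67 A (hull 9289 A^3)"

flat_bottom_potential(0.25)   # kcal/mol, harmonic branch below r0
#> [1] 0.004
```

The contact total (3665 heavy-atom pairs/frame for 60 residues) reflects
the collapsed freely-jointed test backbone, not a physical ensemble; the
planted pair registers in every frame while random collisions average
out. The Rh of ~17 Å is the hull radius of that compact 60-mer plus the
hydration shell and shape correction.

## Command line

```sh
inst/cli/condensekit synth --out chain.pdb --seed 3 --length 50 --frames 10
inst/cli/condensekit contacts --in chain.pdb --out out/ --cutoff 4.5
inst/cli/condensekit slab --in slab.pdb --out out/ --bin 2.5
```

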