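---
title: "Methods: ligand-in-pocket conformer analysis with pocketconf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-in-pocket conformer analysis with pocketconf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pocketconf)
```

# The problem and the model

A flexible ligand bound in a receptor pocket — the motivating system is a
secosteroid hormone in the ligand-binding domain of its nuclear receptor —
occupies not one geometry but an ensemble of conformers whose relative
free energies decide which pose dominates. pocketconf implements the full
desk-scale analysis around that question: define the pocket, enumerate
candidate poses systematically, relax and deduplicate them, weight them by
a Boltzmann distribution, decompose the binding energy, map the
noncovalent contacts in real space, and post-process electronic spectra of
the bound versus free chromophore.

The package deliberately separates the *method* from the *energy engine*.
Every stage that needs energies talks to a backend contract — a list with
`energy(structure)` and `gradient(structure)` functions — so a
semiempirical or DFT engine can be slotted in where available. The backend
that ships is a Dreiding-style nonbonded force field; it is a surrogate in
accuracy but a complete, differentiable, deterministic energy model, which
is what the pipeline's logic actually requires.

## Active-site definition

The site is selected at residue level: a residue enters whole or not at
all. Two readings of "within a radius of the ligand" are implemented,
because they differ materially:

* `com_sphere`: a residue is included when any of its atoms lies within
  the radius of the ligand's centre of mass;
* `any_atom` (default): included when the minimum residue-atom to
  ligand-atom distance is within the radius.

A 6 Å centre-of-mass sphere around a ~20 Å elongated ligand is
geometrically much smaller than a 6 Å any-atom shell, and only the latter
produces pocket sizes of several hundred atoms; both modes are kept so
either convention can be reproduced, with `any_atom` as the default.
Waters are parsed but excluded from selection by default: in the
motivating structure they sit at the pocket rim and do not mediate
ligand contacts.

Protonation is template-based for the standard states at pH 7.4
(Asp/Glu deprotonated, Lys/Arg protonated, His as the neutral Nε
tautomer, Ser/Thr/Tyr/Cys neutral, one backbone amide hydrogen per
non-proline residue). Only polar and charged positions receive
hydrogens — the polar-hydrogen representation of classic biomolecular
force fields — because only those states matter downstream (hydrogen
bonding, electrostatics); no pKa calculation is attempted. The operation
counts hydrogens already present, so it is idempotent.

Cutting residues out of a chain exposes unsatisfied backbone valences;
each cut amide nitrogen receives one hydrogen at 1.01 Å along the former
N→C direction and each cut carbonyl carbon one at 1.09 Å along the former
C→N direction (standard bond lengths; the choice only needs to be
chemically sensible since added hydrogens are relaxed afterwards). When
the parent structure is available the true direction to the removed
neighbour is used and genuine chain termini are left uncapped; without a
parent, an idealised direction opposite the existing bonds is
constructed.

## Conformer enumeration

Scanning is a full Cartesian product: each chosen dihedral is rotated in
fixed increments (default 90°) over 0–360°, with the input pose defining
the 0° reference, jointly with a rigid translation grid (default
3×3×3 points at ±1 Å per axis). Output order is deterministic and
lexicographic, and the closed-form record count is checked before
building anything; a configurable cap refuses combinatorial explosions
with the count in the message.

Poses that bury a ligand atom inside a site atom are removed by a van der
Waals overlap filter (pairwise distance below 0.7 times the sum of Bondi
radii). Survivors are relaxed by L-BFGS-B over the free atoms only —
by default all ligand atoms plus site hydrogens, with site heavy atoms
frozen — until the largest gradient component drops below
10⁻⁴ kcal/mol/Å or 2000 steps. A relaxed pose can be verified as a true
minimum by a central-difference Hessian (step 10⁻³ Å) over the free
coordinates: no eigenvalue below −10⁻⁶ (the tolerance absorbs rigid-body
modes); at non-stationary points the check reports `NA` rather than
guessing.

Deduplication greedily clusters records in ascending energy order: a
record is distinct when its best-superposition RMSD (Kabsch, proper
rotations only) to every kept record exceeds the threshold (default
0.5 Å). The output is idempotent under re-deduplication and sorted by
energy.

## Energetics

The force field sums, over atom pairs in scope, Lennard-Jones 12-6 with
Lorentz–Berthelot combination (Dreiding van der Waals parameters),
Coulomb electrostatics (constant dielectric, or the distance-dependent
screening ε(r) = r) with the constant 332.0637 kcal·Å/(mol·e²), and a
12-10 hydrogen-bond well `D[5(R/r)¹² − 6(R/r)¹⁰]` on declared
donor-H···acceptor pairs (defaults D = 9.5 kcal/mol, R = 2.75 Å;
per-pair overrides are allowed, which is also how the synthetic tethers
are expressed). 1-2 and 1-3 pairs are excluded when a bond list is
supplied. Harmonic valence restraints (bond stretches at
700 kcal/mol/Å², 1-3 distances at 150 kcal/mol/Å²) can be switched on
for flexible chains; their equilibria are taken from an explicit
reference geometry so every evaluation restrains towards the same shape.
Analytic gradients are implemented for every term and are checked against
central differences in the test suite.

The two-layer combination
`E = E_high,model + E_low,real − E_low,model` treats the whole ligand as
the model region — no covalent boundary, hence no link atoms; a ligand
covalently fused to the site is refused. In the shipped pipeline the
"high" level is the force field with exact electrostatics and the "low"
level the same field with distance-dependent screening; with external
engines the same combiner applies unchanged.

Boltzmann populations use the overflow-safe max-shift form at a default
temperature of 298.15 K with R = 1.98720425864×10⁻³ kcal/(mol·K); they
are invariant to adding a constant to all energies, sum to one, and reach
the uniform and winner-take-all limits at high and low temperature.

The binding decomposition `E_bind = E_complex − (E_site + E_ligand)`
relaxes the bound complex and an unbound state built from the same
topology — the ligand displaced far enough (10⁶ Å) that every
interaction vanishes — so all terms come from one consistent backend; the
isolated ligand is relaxed separately to split the unbound energy into
its site and ligand components. The dissociation-constant bridge is
`ΔG = RT ln(K_d / 1 M)`.

## Noncovalent interaction analysis

The promolecular density is a sum of non-interacting spherical atomic
densities, each expressed as a sum of simple exponentials
`c·exp(−r/ζ)` (atomic units, r in bohr). The shipped shell table (H–Ar)
was fitted in-house: single-ζ Slater-model atomic densities with
Clementi–Raimondi effective exponents were reduced to one exponential per
principal shell by log-linear regression over each shell's own
low-density window — the region NCI analysis actually probes. The table
is versioned inside the package so results are bit-reproducible; its fit
error grows in the nuclear-core region, which NCI masks out anyway
(density cutoff 0.05 au). Gradients and Hessians are closed-form
derivatives of the exponential sum; no finite differences are used.

The reduced density gradient is
`s = |∇ρ| / (2(3π²)^{1/3} ρ^{4/3})`; the interaction-type coordinate is
`sign(λ₂)ρ` with λ₂ the middle eigenvalue of the density Hessian,
computed by a vectorised closed-form symmetric 3×3 eigenvalue solver with
deterministic ordering. Points classify as attractive below −δ, van der
Waals within ±δ, repulsive above +δ, with δ = 0.01 au by default (the
qualitative "≈ 0" band made concrete). Grids are axis-aligned at
0.2 bohr spacing with 2 Å padding by default (the pipeline uses
0.4 bohr over the ligand's bounding box to keep toy runs fast);
the recommended surface isovalue 0.3 au is carried in the cube metadata.
Intermolecular masking keeps points where each fragment contributes at
least a 5 % share of the total density.

Hydrogen bonds are detected geometrically: a hydrogen within a
covalent-radius cutoff of an electronegative donor (O/N/S), an
H···acceptor distance of at most 2.5 Å and a D-H···A angle of at least
120°, with the role (ligand→protein or protein→ligand) assigned from the
donor's fragment.

## Spectral post-processing

Stick transitions broaden as Gaussians in the wavelength domain,
`I(λ) = Σ_k f_k exp(−4 ln2 (λ−λ_k)²/fwhm²)`, with a 20 nm FWHM default
and a 120–400 nm grid at 0.1 nm. Broadening in wavelength (rather than
energy) matches how plotting tools apply an FWHM quoted in nm; amplitudes
are proportional to oscillator strength, which cancels on normalisation.
λmax is the global maximum with ties resolved towards the longer
wavelength; predominant-transition shifts are signed (positive =
bathochromic) and antisymmetric; intensity changes are plain relative
percentages. The HOMO–LUMO gap helper takes the highest-energy occupied
and lowest-energy unoccupied entries so degenerate labels behave.
Character labels (LE/ICT/ECT) are carried as annotations only — their
assignment would require orbital densities this package does not compute.

# The synthetic-data generator

`make_toy_complex()` builds the study conditions at desk scale: a
flexible all-trans heavy-atom chain (default six atoms, two scanned
dihedrals, elements drawn from C/N/O) inside a rigid pocket, with a
*known, planted* global minimum on the scan grid. The planting mechanism
is geometric and pair-specific: every chain atom is tethered to two
dedicated attractor atoms through narrow 12-10 wells centred exactly on
the planted pose (well depth 15 kcal/mol, optimum at the placement
distance). Two distance tethers per atom plus chain rigidity pin the
planted configuration uniquely — one tether per atom would leave a mirror
ambiguity on each dihedral circle — and because each well rewards only
its designated atom, registry-shifted or reflected folds collect nothing.
Attractor positions are chosen deterministically as the sterically safest
directions on a small radius ladder, keeping every scan pose
clash-feasible; an inert helium cage (default 40 atoms at 8 Å) provides
the pocket walls without perturbing the energy ordering. The generator
verifies by brute force that the planted tuple is the scan-grid argmin
before returning, and an optional engineered clash pose places a small
blocker that eliminates exactly one requested grid combination.

What the toy does *not* emulate: real protein topology, chemically
meaningful valences, solvent, polarisation, or the rugged near-degenerate
landscapes of real pockets. Passing the planted-recovery and pipeline
tests therefore demonstrates that the machinery — enumeration order,
constraint handling, minimisation, deduplication, population analysis —
is correct, not that the surrogate force field is accurate for real
complexes.

All generator randomness flows through one explicit seed; the global RNG
state of the caller is saved and restored.

# Numerical choices and problem sizes

* Scan defaults: 90° increments, 3×3×3 translations at ±1 Å; the default
  toy pipeline therefore enumerates 16 × 27 = 432 poses, which keeps the
  end-to-end run near a minute on one CPU. Property suites use the
  16-pose dihedral grid and twenty generator seeds.
* Clash scale 0.7, deduplication threshold 0.5 Å, convergence
  10⁻⁴ kcal/mol/Å or 2000 steps: fixed defaults, all exposed as
  arguments.
* Ties and degeneracies: λmax ties resolve to the longest wavelength;
  Kabsch superposition enforces determinant +1 and refuses fewer than
  three non-collinear atoms (the two-point degenerate RMSD is defined
  without superposition); the 3×3 eigenvalue solver clamps its
  trigonometric argument to [−1, 1].
* PDB dialect: missing element columns fall back to atom-name inference
  (two-letter symbols are tried for HETATM records so halides parse);
  alternate locations keep the highest occupancy, ties first-listed;
  ANISOU/CONECT are ignored. These policies are applied on top of bio3d's
  parser rather than re-implementing one.
* Determinism: no stage of the conformer machinery uses randomness;
  pipeline manifests include MD5 checksums of every output, and the test
  suite asserts byte-identical re-runs.

# Design decisions that were genuinely open

* **Which distance rule defines the pocket.** Both readings are
  implemented as modes rather than picking one silently; the any-atom
  shell is the default because a centre-of-mass sphere of practical radii
  cannot reach a pocket of several hundred atoms around an elongated
  ligand.
* **What "distinct" conformers means.** Reported conformer counts in
  this field rarely state a similarity rule; the package declares one
  (greedy best-superposition RMSD at 0.5 Å, lowest-energy representative)
  and exposes the threshold.
* **Joint versus interleaved translation scanning.** The full Cartesian
  product is implemented; it is the only reading that makes the record
  count a closed form.
* **Valence terms.** Nonbonded-only by default (fragments are rigid
  during scanning); harmonic bond and 1-3 restraints with an explicit
  reference geometry are available because relaxing a flexible chain
  against a purely nonbonded surface is meaningless.
* **Unbound state for the binding decomposition.** Computed by far
  displacement within one topology rather than by re-deriving separate
  parameter sets for each subsystem, so the three energies of the
  decomposition always share a backend.

# Known limitations

* The force field is a surrogate: no polarisation, no solvation, generic
  parameters; quantitative binding energies for real complexes require an
  external engine behind the backend contract.
* Promolecular densities are approximate by construction and the shipped
  exponential fits degrade in the nuclear-core region (masked out by the
  NCI density cutoff, but visible in raw cube files).
* Protonation is rule-based at fixed pH; histidine tautomer choice is a
  convention (Nε), not a prediction.
* Link-atom boundaries (ligand covalently bound to the receptor) are out
  of scope for the two-layer combiner.
* Ring-pucker sampling and receptor flexibility are not modelled; the
  scan moves torsions of an otherwise rigid ligand inside a frozen site.
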