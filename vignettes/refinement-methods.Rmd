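---
title: "Evaluating post-docking MD refinement of peptide-protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating post-docking MD refinement of peptide-protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peprefine)
```

## The problem

Linear peptides such as histone H3 tails are hard ligands for fast
molecular docking: they are large and flexible, they bind shallow pockets
on reader domains with micromolar affinity, and their interfaces are
extensively hydrated.  Docked poses therefore often start many Angstrom
away from the experimental binding mode, and the standard remedy is
post-docking refinement by molecular dynamics (MD) — typically an initial
restrained equilibrium MD, a simulated-annealing (SA) stage, and
optionally a fully flexible stage, run on a complex whose interface was
explicitly hydrated beforehand so that no void cavities distort the early
dynamics.

`peprefine` implements everything around such refinements that does not
require running MD itself: the structural bookkeeping (PDB/MOL2 I/O, atom
correspondence, Kabsch superposition), the refinement quality metrics,
interface hydration editing and water-placement scoring, a per-residue
interaction energy decomposition, machine-readable definitions of six
refinement protocols, and a deterministic synthetic-structure generator
that makes every one of those components testable at desk scale.

## Metrics

**RMSD.** The ligand error of a calculated complex is the heavy-atom RMSD
to the experimental reference,
$\mathrm{RMSD} = \sqrt{\sum_i \lVert C_i - R_i\rVert^2 / N_H}$,
computed after superposing the calculated complex onto the reference by a
least-squares (Kabsch) fit of the *target* C-alpha atoms.  The ligand is
never re-fit, so rigid motion of the whole snapshot is absorbed while
genuine ligand displacement is not.  Atom pairs are identified by (chain,
residue index, atom name); snapshots and references share a topology, so
no alignment heuristics are needed.  Reflections are forbidden in the fit
(determinant +1), because only physical rigid motions are meaningful.

**Improvement.** Refinement quality is the drop from the docked start to
the best refined frame, $\Delta\mathrm{RMSD} =
\mathrm{RMSD_{start}} - \mathrm{RMSD_{best}}$, also expressed as a
percentage of the start.  The docked start is treated as the frame at
t = 0, so a run that never improves reports a zero (not negative)
improvement; stage filters allow the best-frame search to be restricted
to a protocol stage.

**Residence frequency.**  Kinetic stability of an improved pose is
measured as the number of frames whose RMSD improves on the start by at
least a cutoff (default 1 Angstrom), divided by the simulation time in
ns.  With the 0.1 ns snapshot interval used throughout, RF is at most
10 per ns; empirically, complexes with RF above 0.5 per ns hold their
refined pose throughout the trajectory.  The RF denominator is the full
analyzed simulation time even under stage filters, and the docked start
itself is excluded from the count.

## Hydration editing and water scoring

Pre-MD hydration merges a hydrated target with the docked ligand: any
water whose oxygen lies strictly closer than `dmin` = 1.75 Angstrom to a
ligand heavy atom is removed as a whole residue.  Interface waters are
those within 3.5 Angstrom (non-strict) of heavy atoms of *both* partners.
Predicted water positions are validated against reference positions by
one-to-one greedy matching on ascending oxygen–oxygen distance, counting
a match strictly below the 1.5 Angstrom tolerance; the success rate is
the matched percentage of the reference set, undefined (not zero) for an
empty reference.  Greedy matching is deterministic and coincides with the
optimal assignment whenever sites are separated by more than twice the
tolerance, which the synthetic layouts guarantee; ties are broken by the
lower residue id.  All distances use oxygen atoms only, since hydrogen
positions are unreliable before equilibration — for the same reason
bridging waters (simultaneously within 3.5 Angstrom of a polar N/O atom
on each partner) are identified by distance alone, with no H-bond angle
criterion.

## Per-residue interaction energy

The target–ligand interaction energy is a pairwise sum over all
(target atom, ligand atom) pairs with no distance cutoff,
$E_\mathrm{inter} = E_\mathrm{LJ} + E_\mathrm{Coulomb}$, decomposed per
ligand residue (waters and ions excluded).  The Lennard-Jones term uses
Amber-convention parameters with $R_{ij} = R_i + R_j$ and
$\varepsilon_{ij} = \sqrt{\varepsilon_i \varepsilon_j}$, so the pair
minimum is $-\varepsilon_{ij}$ at $R_{ij}$; atom types are assigned by a
residue/atom-name lookup with element fallbacks.  The Coulomb term uses
Gasteiger–Marsili PEOE partial charges and a sigmoidal distance-dependent
dielectric $\varepsilon_r(r) = A + B/(1 + k e^{-\lambda B r})$ with
$B = \varepsilon_0 - A$.  Two deliberately distinct constants share the
symbol $\varepsilon_0$ in the field's notation: the vacuum permittivity
inside the Coulomb prefactor, and the bulk-water dielectric constant
(78.4 at 25 °C) that sets the long-range asymptote; the package keeps
them as separate named quantities.  The dielectric constants default to
the Mehler–Solmajer parameterization (A = −8.5525, λ = 0.003627,
k = 7.7839), the standard source for this functional form.  Energies are
reported in kcal/mol with the electrostatic constant 332.06 (charges in
e, distances in Angstrom); the published analyses are qualitative about
units, so this conventional system was chosen once and is used
consistently.

The PEOE implementation iterates charge transfer across perceived bonds
with damping $(1/2)^n$ over six iterations, electronegativities
$\chi(q) = a + bq + cq^2$ with the published element/hybridization
coefficients, and conserves total formal charge exactly.  Bonds are
perceived from covalent radii; hybridization from connectivity degree.
Charges agree with OpenBabel's independent Gasteiger routine to better
than 0.01 e on test molecules.  Nonpolar hydrogens can be merged into
their carbons after assignment (`mergeNonpolarH()`), matching the
polar-hydrogen preparation common in docking pipelines; both all-atom and
united modes are available because published per-residue energy figures
do not state which was used.  Isolated monoatomic ions keep their nominal
ionic charge.

## Protocols P1–P6

The six built-in refinement protocols differ in stage lengths,
SA temperature ceiling, target restraints and peptide length:

| id | initial MD | SA stage | final flexible MD | restraints | peptide |
|----|-----------|----------|-------------------|------------|---------|
| P1 | 5 ns | 20 ns, max 323 K (10 ns hold) | 20 ns | target heavy atoms | full |
| P2 | 5 ns | 20 ns, max 353 K (10 ns hold) | 20 ns | target heavy atoms | full |
| P3 | 15 ns | 40 ns, max 323 K (30 ns hold) | — | target heavy atoms | full |
| P4 | 10 ns | 30 ns, max 323 K (20 ns hold) | — | binding site released | full |
| P5 | 15 ns | 40 ns, max 323 K (30 ns hold) | — | target heavy atoms | truncated |
| P6 | 10 ns | 30 ns, max 323 K (20 ns hold) | — | binding site released | truncated |

The 323 K ladder climbs 300–310–323 K and back in 2.5 ns plateaus with
the ceiling held for the remaining stage time; the P2 ladder climbs
300–311 K and then in 14 K steps to 353 K in 1.2 ns plateaus with a
10 ns hold.  The P2 plateau arithmetic totals 19.6 ns against the nominal
20 ns stage; the final 300 K plateau is extended to 1.6 ns to fill the
stage, a reconciliation the package makes explicitly rather than
silently.  Schedules are rendered as annealing points with plateau start
and end at each temperature and a 0.01 ns set-point ramp between
plateaus, keeping annealing times strictly increasing as GROMACS
requires; only plateau durations are specified by the protocol design,
so the rendering treats transitions as effectively instantaneous.

`emitMDP()` writes the parameter document of any stage (steepest-descent
and conjugate-gradient minimization with thresholds 1000 and
10 kJ mol⁻¹ nm⁻¹, 2 fs step, v-rescale thermostat, Parrinello–Rahman
barostat, PME, 11 Angstrom van der Waals cutoff, LINCS,
1000 kJ mol⁻¹ nm⁻² position restraints, 10 ps output) as deterministic
key–value text that round-trips through its own parser.  The final
flexible stage exists only for P1/P2 — it was dropped from later
protocols after contributing no further improvement — and requesting it
elsewhere is an error, not a silent default.

Three quantities the published protocol figure leaves unprinted are
explicit, overridable defaults here: the binding-site release radius for
P4/P6 (5 Angstrom, a standard contact-shell definition), the P5
restraint scheme (target heavy atoms, as in the P1–P3 pattern of limited
target flexibility), and the truncation length for P5/P6 (5 residues,
the tightly bound N-terminal head analyzed throughout the refinement
literature on these systems).  Truncation caps the new C-terminus by
mirroring the carbonyl oxygen into an OXT carboxylate position.

## The synthetic-structure generator

`makeToyComplex()` builds a rigid toy target — two extended strands
flanking a shallow groove, plus one structural Zn²⁺ ion carried with the
target for restraint purposes — and a linear histone-H3-tail peptide
(prefix of ARTKQTARKSTGGKAPRKQLA) lying in the groove with real PDB atom
naming and idealized internal-coordinate geometry, so selections,
truncation, bond perception and MOL2 typing are exercised realistically.
The docked pose is the reference peptide rigidly displaced so the
starting RMSD is exact by construction (default 8 Angstrom, a typical
fast-docking error on these systems; the published set spans about 8–27).

`makeTrajectory()` interpolates the ligand from docked toward reference
with per-atom Gaussian noise (default sigma 0.1 Angstrom), then rescales
each frame's deviation so its fitted RMSD is pinned exactly — raw noise
would make improving-frame counts stochastic, and the generator's
contract is that every planted quantity is recovered *exactly* by the
corresponding metric.  Improving frames sit 1.5 Angstrom below the
start (safely past the 1 Angstrom RF cutoff), non-improving frames 0.4
Angstrom below, and the improving block is placed at the end of the run
as in a converging refinement.  Every frame also receives a random
rigid-body displacement that the target-C-alpha fit must absorb.  The
default 400 frames at 0.1 ns spacing correspond to a 40 ns stage
extracted at the snapshot interval.  All randomness uses R's
Mersenne-Twister generator seeded locally, so a seed plus configuration
is bit-reproducible and the caller's RNG stream is untouched.

`makeHydrationLayout()` plants interface waters (default 12) at
midpoints of close target–ligand atom pairs, kept at least 3.6 Angstrom
apart so greedy matching provably equals the optimal assignment, plus
far-away bulk waters (default 30).  The predicted set displaces a stated
fraction of the reference oxygens by 0.5 Angstrom (inside the match
tolerance) and the rest by 2.0 Angstrom (outside), so the planted success
rate is exact; the default fraction 0.86 mirrors the mean pre-MD
hydration performance reported on systems with crystallographic
interface waters.

What the generator does *not* emulate: force-field physics, realistic
peptide energetics, solvent structure, or target flexibility.  Passing
tests on these fixtures demonstrates that the bookkeeping and arithmetic
are correct — trajectories from real MD engines will of course not have
pinned RMSD values, and real water networks are not 3.6 Angstrom-spaced.

## Numerical choices and degenerate inputs

* Superposition requires at least 3 non-collinear paired atoms; the
  rank of the centred coordinate cloud is checked explicitly.
* Altloc records keep the highest occupancy, first on ties.
* Stripping uses strict `<` (a water exactly at dmin survives);
  interface membership uses non-strict `<=`; matching uses strict `<`
  ("below the tolerance").
* A zero interatomic distance in the energy double sum is an error, not
  an infinity.
* An empty water reference set yields an undefined (NA) success rate.
* Coordinates are written at the PDB's 3-decimal precision and round-trip
  exactly at that precision.

## Scale of the shipped checks

The test-suite simulations are sized to run in seconds on one CPU —
trajectories of tens to 400 frames, peptides of 4–15 residues, targets of
up to 20 residues.  These sizes exercise every code path (the metrics are
O(atoms × frames) and the energy sum O(N_T × N_L)); nothing in the
algorithms depends on system size beyond runtime.

## Known limitations

* The package evaluates and prepares refinements; it does not run MD,
  build topologies, solvate boxes, or predict water positions (an
  upstream water-prediction tool provides the hydrated target; its
  parameters are recorded in configuration only).
* The Amber-style LJ table covers protein atoms, water and Zn at
  element/name granularity, not the full force-field type system.
* Gasteiger charges on structures lacking hydrogens are chemically crude
  (the scheme was parameterized for complete valences); supply polar
  hydrogens where charges matter.
* The restraint matrix of the published protocol figure is not fully
  recoverable from text; the defaults above are explicit assumptions and
  every one is overridable.
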