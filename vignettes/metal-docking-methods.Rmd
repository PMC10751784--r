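---
title: "Metal-aware docking: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metal-aware docking: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mcdock` docks metal–organic complexes into rigid protein pockets. This
vignette explains the interaction model, the search and fitting
algorithms, the tunable parameters, what the synthetic fixtures emulate
(and what they do not), and the numerical choices a maintainer would
want written down.

## The interaction model

The intermolecular energy is a sum over ligand–receptor atom pairs of a
Lennard-Jones term and a screened Coulomb term.

**Lennard-Jones.** Two functional forms, both parametrized by a well
depth ε (kcal/mol) and the position of the minimum R\_min (Å), and both
with minimum value −ε at r = R\_min:

* generic van der Waals contacts use the 12-6 form
  ε[(R\_min/r)¹² − 2(R\_min/r)⁶];
* hydrogen-bond-like contacts use the narrower 12-10 form
  ε[5(R\_min/r)¹² − 6(R\_min/r)¹⁰].

Non-metal pairs are built from AutoDock4-style self parameters
(arithmetic-mean R\_min, geometric-mean ε), with 12-10 donor–acceptor
pairs for HD–NA/OA (R\_min 1.90 Å, ε 5.0) and HD–SA (2.50 Å, ε 1.0).

**Metal types.** A metal is its own atom type. Because coordination
bonds and hydrogen bonds are both short, directional, and polar, the
metal–acceptor interactions (NA, OA, SA) use the 12-10 form; a 12-6
metal–HD term approximates metal-assisted deprotonation (a cysteine
S–H proton that would leave on coordination). The R\_min values are
fixed at 1.00 (HD), 2.20 (NA), 2.25 (OA), and 2.30 (SA) Å, so only the
four well depths remain free; they live in an `lj_params` table and are
what the Monte Carlo scheme fits. The metal–metal well depth is held at
the iron-like 0.010 kcal/mol: metal centres in different molecules are
essentially never within van der Waals range of each other.

**Directionality via the vacancy dummy.** A zero-charge, zero-parameter
pseudo-atom (type DD) is placed at the metal's vacant coordination
site: at distance 2.0 Å (a typical first-sphere bond length; the choice
only scales the marker, it carries no energy) along the negated,
normalized sum of the metal-to-ligator unit vectors. When that sum is
degenerate (‖Σ‖ < 0.2 — square planar, octahedral, linear), the
direction falls back to the best-fit-plane normal of the ligators,
oriented toward the half-space with fewer ligand atoms; exact ties take
the orientation whose first non-zero component is positive, purely for
determinism. A saturated, balanced sphere (CN = 6) has no vacancy and
asks the user to disable the option instead of guessing. The dummy's
sole effect on the energy is the angular weight w = cos²θ (zero beyond
90°) multiplying the attractive well of the metal–NA/OA/SA terms,
where θ is the angle between the metal→dummy and metal→acceptor
directions. Without a dummy the metal wells are isotropic (w = 1), the
correct behaviour for coordinatively saturated compounds.

**Electrostatics.** 332.06·q\_iq\_j/(ε(r)·r) with the Mehler–Solmajer
sigmoidal distance-dependent dielectric. Charges are read from the
extended XYZ column or PDBQT file; the package never computes them (the
upstream quantum step — geometry optimization and class-IV charges — is
out of scope by design). AutoDock4's desolvation term is omitted: the
fitting scheme optimizes only the metal ε values, and at the pair
counts used here desolvation is a near-constant offset.

Cutoffs default to 8 Å (Lennard-Jones) and 20 Å (electrostatics); there
are no precomputed grids — systems at this scale are summed directly,
with the pair kernel in compiled code.

## Atom typing and the torsion tree

Deterministic rules over the perceived bond graph: H bonded to N/O/S →
HD, other H → H; carbon in a detected aromatic ring (5- or 6-ring of
C/N/O/S, ring carbons with ≤3 neighbours, RMS out-of-plane < 0.15 Å) →
A, else C; nitrogen with no bonded hydrogen and fewer than three heavy
neighbours (an available lone pair) → NA, else N; O → OA; S → SA.
Bonds are perceived at 1.15 × the covalent-radius sum, 1.25 × for pairs
involving the metal (dative bonds are longer).

Rotatable bonds are acyclic single bonds between non-terminal heavy
atoms, excluding amide C–N bonds (carbonyl detected by a C–O distance
under 1.30 Å) and any bond touching the metal or its first coordination
sphere: the coordination core is kept rigid, as the complex geometry is
assumed pre-optimized upstream. More than 10 rotatable bonds is an
error — pose search is not reliable beyond that. The tree root is the
atom whose removal leaves the most balanced fragments (ties to the
lowest index), and a genome is (translation of the root, unit
quaternion about the root, torsion angles).

## Pose search

Each docking consists of `n_runs` (default 10) independent genetic
algorithm runs; each run contributes its best genome as one pose, and
poses are reported sorted by energy — deliberately without clustering
or deduplication, so "10 poses" means "10 run bests". Defaults
(population 50, 100 generations, two-point crossover at 0.8, Gaussian
mutation at 0.2 with 0.2 Å / 5° scales, elitism 1, Solis–Wets local
search on the top 10 % per generation) are desk-scale: small enough to
iterate with, large enough to solve the bundled problems. An
`autodock`-like preset (population 150, longer runs) exists for harder
systems.

Two engine details matter and are worth stating plainly:

* **Soft-core search stage.** During evolution, each pair potential is
  flattened inside the radius where its repulsion reaches `soft_cap`
  (default 0.5 kcal/mol). This smears the very narrow hydrogen-bond and
  metal wells (widths of a few tenths of an Å) into wide funnels the
  population can actually find — the same role grid smoothing plays in
  grid-based engines. Capping only the repulsion would create an
  unphysical sink at overlap, so the whole pair term is plateaued.
* **Exact final polish.** Each run's best genome is then re-minimized
  under the exact potential (an intermediate stage at cap 20 first,
  then Nelder-Mead restarts on an offset parametrization, which keeps
  the polish translation-invariant). Reported pose energies always come
  from the exact potential at the reported coordinates.

Out-of-box excursions of the root atom incur a quadratic penalty rather
than rejection, keeping the fitness landscape informative.

## RMSD and the fitting objective

Docked poses live in the receptor frame, so pose RMSD is computed **in
place**, without re-superposition; Kabsch superposition exists
separately for the structural-similarity tools. All atoms are compared
when both structures have hydrogens (dummies always excluded), else the
comparison downgrades to heavy atoms with a message. The
"element-matched" mode solves, per element, the optimal assignment
(exhaustive to 8 equivalent atoms, Hungarian beyond) to handle
symmetry-equivalent atoms; the fitting default is "ordered". The
fitting objective is the flat arithmetic mean of the per-pair, per-pose
RMSD matrix — equal to the mean of per-pair means when every pair
contributes the same number of poses.

## Monte Carlo well-depth fitting

Starting from ε = 2 kcal/mol for each of HD, NA, OA, SA, the optimizer
sweeps the parameters once in that fixed order; each parameter receives
250 proposals drawn uniformly on [0, 7] kcal/mol. After every proposal
the whole training set is re-docked under the trial table and the mean
RMSD recomputed; the default acceptance is greedy (accept iff
RMSD\_i ≤ RMSD\_b, the best so far, carried across sweeps — whether the
original scheme reset it between sweeps is not documented, and carrying
it is the conservative choice). A Metropolis mode
(exp(−ΔRMSD/T)) is available behind `acceptance = "metropolis"` for
rugged objectives but is off by default. Every docking evaluation uses
a fresh seed derived from the master seed, and the full history
(parameter, proposal, objective, accepted flag, seed) is returned for
audit and replay. Failed dockings skip their pair with a warning rather
than abort a long fit.

## What the synthetic fixtures emulate

The generators exist so every contract above is testable without
downloads; they are study conditions, not tuning knobs.

`make_toy_complex()` builds a heteroleptic complex: metal at the
origin, ideal first-sphere geometry (linear to octahedral; CN 5 is
square-pyramidal with a +z vacancy), amine-like N ligators with donor
hydrogens plus one bare O and — from CN 4 — one bare S ligator, and an
alkyl arm supplying the requested rotatable bonds. The heteroleptic
sphere is essential: a homoleptic ammine complex is rotationally
quasi-degenerate, and no pocket can then make the planted orientation
uniquely optimal. Charges are chemically plausible fractions summing to
the stated formal charge; a 0.02 Å seeded jitter distinguishes seeds.

`make_pocket()` surrounds a randomly oriented planted pose with a
typed-atom pocket: a thiolate-like SA acceptor exactly at the metal
pair's R\_min on the vacancy axis, a donor-hydrogen probe facing the
unique O ligator, a weaker donor probe at the unique S ligator, and a
sparse neutral-carbon cast of the ligand surface (one probe at the
optimal pair distance outside each solvent-facing atom). The two
direction constraints — dummy axis onto the acceptor, metal→O axis onto
its probe — pin the full orientation; the S probe breaks the remaining
N-ligator pseudo-symmetry; the cast rewards the planted shape
everywhere. Because the idealized geometry is not an exact stationary
point of the full potential, the planted pose is relaxed to its local
minimum at generation time and the relaxed pose is the reference; it is
then verified to score below thousands of random poses. These pockets
are abstract typed shells, not proteins: passing the recovery test
shows the engine finds a well-defined global optimum in a realistic
energy model, not that it ranks real binding modes correctly.

`make_fit_problem()` produces minimal pockets for parameter recovery:
the complex sits in a stiff neutral cast cage, and one acceptor of the
target type is placed 0.6 Å beyond its optimal distance on the vacancy
axis. The docked position balances the ε-dependent pull toward the
acceptor against the cage, so the pose shifts smoothly and
monotonically with ε; with references computed under the true depths,
the mean-RMSD objective has its minimum at the true depths by
construction. `mock_dock()` — rigid-translation BFGS plus Nelder-Mead
refinement, deterministic to ~10⁻⁴ Å — stands in for the full engine
during fitting tests; it honours the same calling convention, so the
real `ga_dock()` can be swapped in.

## Numerical choices and degenerate inputs

* Coincident atoms are guarded by flooring pair distances at 0.05 Å.
* Quaternions are renormalized after every genetic operator; a zero
  quaternion falls back to identity.
* PDB alternate locations resolve to the highest occupancy (ties keep
  the first listed); multi-model files require an explicit model.
* PDBQT files are written in torsion-tree traversal order (root group
  first), the order the BRANCH grammar requires; reading inverts the
  format and re-perceives bonds.
* The balanced-sphere threshold (‖Σ‖ < 0.2) and the plane-normal
  tie-break exist only to make dummy placement deterministic on
  symmetric spheres; for any sphere with a genuine vacancy the negated
  vector sum decides.
* Problem sizes in the bundled tests (pockets of ~25 ligand and ~10
  receptor atoms, 5 pockets, 250 Monte Carlo proposals per parameter
  over 4 training pairs, 5 seeds) were chosen so the whole suite runs
  comfortably on a laptop while still exercising every contract.

## Known limitations

* The receptor is rigid; no flexible side chains, no ensemble docking.
* Scores are not calibrated free energies; ranking within one system is
  the only claim.
* Protonation states and partial charges must be supplied; pH is
  recorded, not acted on.
* Aromaticity detection is geometric (planarity + composition), which
  is adequate for sensible 3D input but not a substitute for a
  cheminformatics perception stack.
* The fingerprint (hashed element paths, 2048 bits) is one reasonable
  choice among many; conclusions from the similarity matrices depend on
  it only mildly, but bit-level compatibility with any external tool is
  not claimed.
* TM-score correspondence comes from sequence alignment or a user
  mapping; full structure-based alignment search is out of scope.
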