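# mcdock

Metal-aware docking of metal–organic complexes into rigid protein
pockets, in R.

Standard docking force fields have no parameters for transition-metal
centres, so metal complexes — a growing class of anticancer agents,
catalysts, and probes — cannot be docked out of the box. `mcdock`
extends AutoDock-style scoring with explicit metal atom types:

* the metal–acceptor interactions (with acceptor nitrogen NA, oxygen OA,
  and sulfur SA) are modelled as hydrogen-bond-like **12-10
  Lennard-Jones wells**, E(r) = ε·[5(R\_min/r)¹² − 6(R\_min/r)¹⁰], with
  fixed R\_min values of 2.20, 2.25, and 2.30 Å;
* a **12-6 metal–HD term** (R\_min 1.00 Å) approximates metal-assisted
  deprotonation of cysteines and similar residues;
* the metal–metal well depth is held at the iron-like 0.010 kcal/mol;
* a zero-charge, zero-parameter **dummy atom** placed at the vacant
  coordination site makes the metal's hydrogen-bond-like wells
  directional (a cos²θ weight on the attractive term, gated at 90°);
* the four metal well depths ε(HD), ε(NA), ε(OA), ε(SA) are **fitted by
  Monte Carlo sampling**: uniform proposals on [0, 7] kcal/mol, 250 per
  parameter, accepted greedily when the mean all-atom RMSD between
  docked poses and reference coordinates over the whole training set
  does not increase.

Pose search is a genetic algorithm over rigid translation, orientation
(unit quaternion), and torsion angles, with Solis–Wets local refinement,
a soft-core search stage, and an exact-potential final polish. Dataset
curation utilities (hashed path fingerprints + Tanimoto similarity for
the compounds, TM-score for the proteins) pick the held-out test
complex as the entry least similar to the rest of its set.

The package is aimed at computational chemists who want a transparent,
scriptable, fully testable implementation of this workflow at desk
scale. Partial charges are *ingested* (extended XYZ column or PDBQT),
never computed: the quantum-chemistry step stays outside.

## A worked example

Generate a toy pocket with a planted pose and dock the complex back:

```r
library(mcdock)

pk  <- make_pocket(pocket_spec(), seed = 2)   # Ru complex, thiolate-like site
res <- ga_dock(pk$ligand, pk$receptor, pk$params, pk$box,
               n_runs = 10, seed = 7)
print(res)
#> <dock_result> 10 poses (seed 7)
#>   best -16.275 kcal/mol, worst -13.418 kcal/mol

summary(res, reference = pk$reference)[1:4, ]
#>   pose    energy run         rmsd
#> 1    1 -16.27521   1 1.048289e-05
#> 2    2 -16.10666   3 1.441431e+00
#> 3    3 -16.09240  10 1.524570e+00
#> 4    4 -15.15302   2 3.729540e+00
```

The best run re-finds the planted pose essentially exactly (10⁻⁵ Å
all-atom RMSD at the planted energy, −16.275 kcal/mol); the remaining
runs land in nearby or decoy minima at higher energy. Fitting the four metal well depths on a
generated training set with planted values (5.6, 2, 1, 0.2 kcal/mol):

```r
fp  <- make_fit_problem(seed = 1)
fit <- mc_optimize(fp$pairs, mock_dock, samples_per_param = 250, seed = 101)
print(fit)
#> <mc_fit> metal Ru, greedy acceptance, 1000 proposals
#>   eps (kcal/mol): HD 5.670  NA 2.000  OA 0.989  SA 0.201
#>   RMSD 0.0734 -> 0.0002 A (19 accepted)
```

Every planted depth is recovered to better than 0.1 kcal/mol. A thin
command-line interface wraps the same functions
(`inst/cli/mcdock.R dock|rmsd|fit-params|curate|make-fixtures`).

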