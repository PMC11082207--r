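# revscreen

Ligand-based reverse screening for small-molecule target prediction in R.

Given a query compound, which of the proteins in a bioactivity knowledge
base is it most likely to bind? `revscreen` answers by the *similarity
principle*: a compound that closely resembles the known actives of a protein
is itself likely active on it. The package is aimed at computational
chemists and chemical biologists who need fast, interpretable target
prediction — deconvoluting phenotypic screens, assembling polypharmacology
panels, prioritizing repurposing hypotheses — and at method developers who
want a fully testable reference implementation of the validation
methodology that goes with it.

## The engine

Every compound is described twice:

* **Shape.** Up to 20 conformers are generated per compound; each conformer
  is encoded as an 18-dimensional **ES5D** vector: atoms are embedded in a
  5D space (Cartesian coordinates plus scaled Gasteiger partial charge and
  atomic lipophilicity contribution) and, for each of six reference
  centroids, the mean, standard deviation and cube-rooted third central
  moment of the atom–centroid distances are stored. The shape similarity of
  molecules *i*, *j* is the Manhattan-based score over the best conformer
  pair,

  `M_s(i,j) = 1 / (1 + d_ij / 18)`,

  with `d_ij` the smallest Manhattan distance over all conformer pairs.

* **Chemical structure.** A path-based 1024-bit fingerprint (linear
  fragments of 1–7 atoms, FP2 dialect); the structural similarity is the
  Tanimoto coefficient `T_c`.

For a query against one target, the **3D-Score** and **2D-Score** are the
maxima of `M_s` and `T_c` over the target's known actives. The probability
that the target is hit comes from a binary logistic model,

`P = 1 / (1 + exp(-c1·3D-Score - c2·2D-Score - C))`,

with coefficients fitted separately for 51 molecular-size classes (≤10,
11…59, ≥60 heavy atoms in the query) on planted active/inactive training
pairs at a 10:1 inactive:active ratio, monitored by 10-fold cross-validated
Matthews correlation, and smoothed across classes by a cubic polynomial.
Screening a query against every target and sorting by probability yields a
ranked target list; validation measures **success@rank k** — the percentage
of external queries whose experimentally known target appears in the top
*k* — optionally stratified by molecular size, by the bioactivity knowledge
of the target (number of known actives) and by the chemical diversity of
its actives (number of Bemis–Murcko or Oprea scaffolds).

## Worked example

A seeded synthetic bioactivity universe stands in for a curated knowledge
base: each target owns an analog series built from a distinct ring-system
core (actives), decoys from unrelated cores supply measured inactives and
gray-zone records, and a few analogs per target are held out as external
test compounds.

```r
library(revscreen)

universe <- generate_universe(fixture_spec(
  n_targets = 6, actives_per_target = 12, n_decoys = 40,
  heldout_per_target = 3, seed = 42))

compounds <- rbind(universe$training$compounds[, c("compound_id", "smiles")],
                   universe$test[, c("compound_id", "smiles")])
descriptors <- featurize(compounds, conformers = 5, seed = 42)

pairs <- build_training_pairs(universe$training, descriptors,
                              ratio = 10, seed = 42)
model <- smooth_coefficients(fit_size_models(pairs))
cross_validate(pairs, k = 10, seed = 42)
#>   mcc_cv mcc_sd precision recall     k     n
#> 1  0.581  0.195     0.975  0.406    10   671

screening  <- build_screening_set(universe$training)
prediction <- reverse_screen(universe$test, screening, descriptors, model)
records    <- evaluation_records(prediction, universe$truth)
success_at_rank(records, c(1, 3, 6))
#>   cutoff success     n
#> 1      1     100    18
#> 2      3     100    18
#> 3      6     100    18
```

All 18 held-out analogs rank their true target first: each query's best
2D-Score against its own target's actives (here 1.0 for several queries,
e.g. `CPD00013 → P00001`, probability 0.68) dominates every cross-target
similarity, which is exactly the planted structure the generator
guarantees. The cross-validated MCC of 0.58 with high precision and modest
recall reflects the 10:1 class imbalance at the 0.5 probability threshold —
ranking quality, not threshold classification, is what the screen uses.

`autoplot()` on a success curve, `plot_stratified_success()` on a
stratified table, and `tidy()`/`glance()` on descriptor and model objects
give the usual tidyverse views. A thin command-line front end over the same
functions ships in `inst/cli/revscreen.R`
(`fixtures` / `featurize` / `curate` / `train` / `cv` / `screen` /
`evaluate`).

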