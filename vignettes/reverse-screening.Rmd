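---
title: "Ligand-based reverse screening: model, training and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand-based reverse screening: model, training and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(revscreen)
```

`revscreen` predicts the protein targets of a small molecule by comparing
it to the known actives of every candidate target and converting the two
best similarities — one for 3D shape, one for 2D chemical structure — into
a probability with a size-stratified logistic model. This vignette explains
the model and its assumptions, the tunable parameters and the defaults,
what the synthetic data generator does and does not emulate, and the
numerical and design choices made where the design was genuinely open.

## The similarity features

**Standardization.** All structure identity in the package is canonical
SMILES equality after a fixed standardization: keep the largest organic
fragment (unsalting/desolvation), neutralize the net charge where
chemically valid, re-kekulize during normalization, and emit the canonical
SMILES. The canonical form stored is the aromatic notation, because it is a
fixed point of re-canonicalization: standardizing twice equals
standardizing once, which the overlap-removal and held-out-set logic relies
on. Stereochemistry is preserved, so enantiomers remain distinct compounds.

**ES5D shape descriptors.** Each conformer is an atom cloud in a
5-dimensional space: the three Cartesian coordinates (Å), the Gasteiger
partial charge scaled by 25 Å/e (the established convention for
charge-augmented shape descriptors), and the atomic lipophilicity
contribution scaled by 10 Å per log unit. The lipophilicity scaling is not
prescribed anywhere; 10 Å/log was chosen once so that the per-atom range of
that dimension (roughly −0.6 to +0.9 log units for common atom types, i.e.
−6 to +9 Å after scaling) is comparable to the coordinate spread of
drug-sized molecules, and it is exposed as `logp_scale` for sensitivity
analysis. Atomic lipophilicity uses a coarse-grained Wildman–Crippen table
keyed on SYBYL atom types (aromatic vs aliphatic carbon, amine vs aromatic
nitrogen, halogens, …) rather than the full 68-type SMARTS scheme; the
descriptor needs per-atom contributions on the right scale, not
publication-grade logP.

Six reference centroids encompass the structure: the 5D barycentre; the
atom furthest from it; the atom furthest from that atom; and three extremal
points on the axis perpendicular to the spatial plane of the first three,
probing the charge maximum, the charge minimum and the lipophilicity
maximum. For each centroid the mean, standard deviation and sign-preserving
cube root of the third central moment of the atom–centroid distances are
stored — 18 numbers per conformer, invariant under rigid rotation and
translation (verified to 1e−9 in the test suite). Degenerate geometries
(fewer than three atoms, collinear structures) duplicate the barycentre so
the descriptor always has 18 components; a single neutral atom maps to the
zero vector.

**Conformers.** The 3D embedding is rule-based and deterministic: one base
geometry with Gasteiger charges, then torsion driving of the rotatable
bonds in 120° steps, ranking rotamers by a quadratic steric-overlap penalty
(contact distance 2.2 Å between atoms three or more bonds apart) and
keeping the `conformers` least-clashing rotamers (default 20, the standard
ensemble size for shape screening). For molecules with more than five
rotatable bonds the 3^k torsion grid is subsampled to 243 combinations
under the user seed. The embedding runs in an isolated subprocess with the
package's interposer library preloaded, which pins the generator's entropy
source: featurization is a pure function of (structures, parameters), and
the test suite asserts bit-identical reruns. This procedure approximates a
vendor-grade low-energy conformer ensemble; it does not do force-field
energy minimization of each rotamer, which is acceptable here because the
ES5D moments are dominated by gross shape, not by sub-ångström detail.

**Fingerprints and similarities.** The 2D descriptor is the path-based
1024-bit fingerprint (linear fragments of 1–7 atoms, FP2 dialect, computed
by OpenBabel); 2D similarity is the Tanimoto coefficient, with the
empty-versus-empty case defined as 0 (no evidence of similarity). 3D
similarity is `M_s = 1/(1 + d/18)` where `d` is the smallest Manhattan
distance between any conformer pair of the two molecules. Two fingerprints
can be identical for distinct compounds (substructure saturation, salt
forms, stereoisomers); such pairs are kept as distinct compounds
throughout.

## Data model and labelling

Activity records carry a measure type (IC50, EC50, Ki, KD, Kic, Km), a
value in µM (nanomolar inputs are converted on read), an assay class and a
species. A compound–target pair is **active** when any qualifying
measurement is ≤ 10 µM, **inactive** when all are ≥ 100 µM, and **gray**
otherwise; gray pairs enter neither training label. When active and
inactive evidence conflict for the same pair, activity wins — this matches
the construction of the gray zone, which only exists between the two
thresholds. Extraction filters keep compounds with 5–80 heavy atoms
(inclusive) and records with permitted measure types, assay classes and
species, reporting per-criterion removal counts. Externality of a test set
is enforced by canonical-structure equality against the training set plus
restriction to targets the screen can actually find.

## Training the size-stratified logistic models

For each target, every known active becomes a positive pair whose scores
are its best similarities to the target's *other* actives (self-comparison
is excluded by compound identifier, so a structural twin under a different
identifier legitimately scores 1). Negatives are drawn per target from the
measured inactives plus the *alleged* inactives — compounds never reported
active on that target (gray pairs excluded) — sampled uniformly without
replacement to 10 negatives per active under the user seed. Sampling is
stratified per target so that every target's actives get their own
complement; whether the reference methodology sampled per target or
globally is not stated, and per-target stratification is the choice that
keeps the class balance uniform across targets.

Pairs are stratified by the heavy-atom count of the query into 51 classes
(≤10, 11–59 singly, ≥60) and one binary logistic model is fitted per class.
The default fit minimizes the summed log-loss plus an L2 penalty of
`1/(2C)` times the squared slope norm with `C = 1` and an unpenalized
intercept — exactly the default objective of the logistic implementation
the training recipe is built on. The penalty matters: planted analog series
make many size classes perfectly separable, where the unpenalized maximum
likelihood estimate diverges and its sign pattern becomes arbitrary;
`reg_c = Inf` is available for the penalty-free fit. The fit is an
in-package penalized IRLS (tolerance 1e−10), cross-checked in the tests
against an independent penalized-regression package on non-degenerate data;
it also accepts classes with a single positive, which occur in sparse size
classes.

Internal robustness is monitored by 10-fold cross-validation with plain
row-level random folds — no grouping by molecule or target, matching the
shuffled construction of the training files — scoring held-out folds at the
0.5 probability threshold with Matthews correlation (defined as 0 when a
denominator factor vanishes), precision and recall. A fold that ends up
single-label is resampled once, then reported as an error.

Finally the three coefficient curves (`c1`, `c2`, `C` as functions of the
class identifier) are replaced by their unweighted degree-3 least-squares
polynomials evaluated at all 51 classes. Unweighted smoothing is the
default (the alternative of weighting by class size is a documented option
via the raw table); when fewer than four classes were fitted the degree
drops automatically, and classes never seen in training receive
extrapolated coefficients with a warning — at desk scale only a band of
classes is populated, and queries are expected to fall inside it.

## Screening and ranking

A query is scored against every target of the screening set (the active
part of the training set, organized by target, species-filtered to human by
default). Its probability per target uses the smoothed coefficients of its
own size class. Targets are ranked by decreasing probability with a
deterministic tie-break — descending 2D score, then descending 3D score,
then target identifier — chosen so that ranks are reproducible and
testable; ties are otherwise arbitrary because the probability is a
monotone function of the two scores. An optional similarity floor
(`min_2d`, `min_3d`) mimics the speed prefilter of applicative tools:
actives below the floor are treated as dissimilar; it is off by default and
the tests pin that it does not move top-of-list ranks on the reference
fixture.

## Validation methodology

Evaluation reduces a screen to one record per query: the best (minimum)
rank over the query's experimentally known targets — "success" means
retrieving at least one of them. `success_at_rank()` turns records into the
success-versus-cutoff curve; stratifiers partition the same records by
query size class, by the known-active count of the best-ranked known
target (default bins ≤10, 11–100, 101–1000, >1000), or by the number of
distinct Murcko/Oprea scaffolds among that target's actives. Bin assignment
for multi-target queries follows the best-ranked known target; expanding a
query into all its targets is available by evaluating each truth pair
separately. The enrichment factor is defined as
`EF(c) = (success/100) / (c / n_targets)` — the observed success rate over
the expectation of a uniform random ranking; published headline enrichment
folds are not derivable from their stated quantities, so no printed
enrichment value is treated as a reference.

**Scaffolds.** The Murcko scaffold is the wire-like framework: iteratively
strip terminal atoms, keep ring systems plus linkers, make all atoms
equivalent and level all bond orders. The Oprea scaffold abstracts further
by contracting every acyclic degree-2 linker atom so each linker becomes a
single edge (parallel edges collapse). Both are canonicalized via the
anonymized graph's canonical SMILES — canonical *within this package*;
string-level compatibility with external scaffold tools is not a goal, and
the exact rule set (leaf stripping; anonymization; linker contraction) is
the package's documented interpretation of the two published abstraction
levels. Acyclic molecules have the empty scaffold and are excluded from
scaffold counts but kept in molecule totals. A compound enters the
*distinct test set* only when its Murcko **and** Oprea scaffolds occur in
no training compound.

**Physicochemical space.** Seven descriptors (MW, Wildman–Crippen WLOGP,
Ertl TPSA, rotatable bonds, fraction of sp3 carbon, H-bond acceptors and
donors) summarize each set; the overlap of two distributions is the
Z-factor `1 − 3(σ_tr + σ_ts)/|µ_tr − µ_ts|`, undefined at equal means and
strongly negative for heavily overlapping distributions. Tests against the
published summary rows use ±0.02 absolute slack because the printed means
and standard deviations are themselves rounded; only rows whose mean
difference is large enough for that rounding not to dominate (TPSA, MW,
HBA) are asserted.

## The synthetic universe

`generate_universe()` builds a seeded toy bioactivity world: each target
owns a distinct two-ring core and an analog series enumerated from a 6×6
substituent grid (H, F, Cl, CH3, OCH3, NH2 by default); actives get
log-uniform potencies in (0.01, 10] µM, decoys from ten separate cores
provide measured inactives (≥100 µM, 25% of decoys), gray records
((10, 100) µM, 5%) and alleged inactives; a fixed number of analogs per
target is held out as the external test set, guaranteed absent from
training by canonical structure. Substituent cells that are equivalent
under ring symmetry collapse after standardization, so sampling uses the
deduplicated pool per core. The defaults — 20 targets × 30 actives, 120
decoys, 5 held-out analogs per target — are the reference study conditions
for the end-to-end tests; `poor_targets` degrades the first targets to two
mutually dissimilar actives to probe the knowledge stratification.

The generator *plants* the similarity principle: every held-out analog's
best fingerprint similarity inside its true target's actives exceeds its
best cross-target similarity. The target cores were curated once so the
full substituent grid satisfies this margin, and the held-out analogs are
selected deterministically (greedy widest own-margin under a conservative
cross-core bound) so the property holds by construction for any seed; the
generator still asserts it on every run. Consequently, passing rank
recovery shows the engine faithfully propagates a real similarity signal
through featurization, training and ranking — it does **not** show how the
engine behaves on real pharmacology, where activity cliffs, promiscuous
scaffolds, assay noise and heavily shared chemotypes violate the planted
margin. The stratification fixtures likewise demonstrate direction
(knowledge-rich targets are easier), not calibrated magnitudes.

## Numerical choices and degenerate inputs

* Logistic fit: penalized IRLS, tolerance 1e−10; constant features get a
  zero slope; single-label classes are skipped with a warning
  (`fit_logistic` on single-label input is an error).
* MCC with a zero denominator factor is 0; confusion counts are
  accumulated in double precision (the four-way product overflows 32-bit
  integers).
* Tanimoto of two empty fingerprints is 0.
* ES5D on degenerate geometry falls back to barycentre duplication; the
  third moment keeps its sign via the cube root, so units stay in Å.
* Coefficient tables serialize to JSON at 17 significant digits, which
  round-trips doubles bit-exactly.
* Tie-breaks in ranking are fully specified (probability, 2D score,
  3D score, target identifier), making screens byte-reproducible.

## Problem sizes

The reference end-to-end study runs 20 targets × 30 actives + 120 decoys
(720 training compounds, 100 held-out queries) with one conformer per
compound and the 10:1 negative ratio (6,600 training pairs over ~8
populated size classes); the packaged multi-conformer paths are exercised
on smaller fixtures with up to 5 conformers. These sizes were chosen to
keep the full synthesis–train–screen cycle in the low minutes on a single
CPU while leaving every code path of the large-scale method exercised; the
statistical behaviour (success rates, stratification direction, null
calibration) is stable across seeds at these sizes.

## Known limitations

* The conformer ensemble is rotamer-based without force-field refinement;
  ring conformations beyond the embedded geometry are not sampled.
* Atomic lipophilicity is a SYBYL-type-level approximation of the
  Wildman–Crippen scheme.
* Scaffold strings are canonical only within the package.
* Protonation is taken as produced by the standardization contract
  (neutralization), an approximation of "protonated as at physiological
  pH"; pKa-dependent protonation is out of scope.
* The synthetic universe does not emulate property-matched decoys, assay
  noise on labels, or inter-target chemotype sharing.
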