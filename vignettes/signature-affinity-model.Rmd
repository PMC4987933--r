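---
title: "Cutoff-scanning signatures and the affinity model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cutoff-scanning signatures and the affinity model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindsig)
```

## The model

`bindsig` treats a protein–small molecule complex as a labelled geometric
graph. Heavy atoms are nodes; each node carries a set of pharmacophore
classes out of eight (hydrophobic, positively ionisable, negatively
ionisable, H-bond acceptor, H-bond donor, aromatic, sulfur, neutral).
The signature of a complex is built from cumulative pairwise-distance
distributions: for each unordered class pair and each cutoff on a distance
grid, the number of atom pairs whose distance does not exceed the cutoff.
Two blocks are computed — pairs among the binding-pocket atoms (protein
heavy atoms within `pocket_radius` of any ligand atom) and pocket–ligand
cross pairs — and a block of twelve ligand physicochemical descriptors is
appended. A Gaussian process regresses −log₁₀(Kd|Ki) on this vector.

The underlying assumptions are worth stating plainly:

* **Binding strength is read off interatomic distance patterns around the
  bound ligand.** The signature contains no force-field terms, no
  explicit electrostatics or solvation; whatever physics it captures is
  mediated by counts of typed atom pairs at increasing ranges.
* **The pose is taken as given and assumed meaningful.** Featurizing a
  bad docking pose yields a confident-looking signature of the wrong
  geometry.
* **Typing is coarse.** An atom's classes come from a residue/atom lookup
  (protein) or from element plus bonded environment (ligand); there is no
  pH model, no tautomer or charge assignment. Histidine, for instance, is
  typed aromatic with donor/acceptor nitrogens rather than positive.
* **Affinity labels are comparable across complexes.** Kd and Ki values
  are pooled on the −log₁₀ molar scale; IC50 values, which depend on
  assay setup, are excluded by default, as are censored ("<", ">", "~")
  measurements, which would corrupt a squared-error regression.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `pocket_radius` | 8.0 | Å | pocket membership (closed boundary); first and second contact shells around the ligand |
| `d_min`, `d_max`, `step` | 1.0, 30.0, 0.5 | Å | cutoff grid; 59 cutoffs spanning bonded contacts to long-range arrangement |
| `heavy_atoms_only` | TRUE | — | deposited PDBs carry hydrogens inconsistently; geometry is read from heavy atoms |
| `normalize` | RAW_COUNTS | — | cumulative counts; `PER_PAIRCOUNT` divides by the block's pair count when pocket sizes vary wildly |
| `bond_tolerance` | 0.45 | Å | slack over summed covalent radii for ligand bond perception |
| GP `kernel` | RBF + white noise | — | smooth similarity decay plus an explicit label-noise term |

The grid and radius defaults follow the cutoff-scanning convention of
dense short-to-medium-range sampling. They are deliberately configurable:
the signature schema embeds a configuration hash, and models refuse
vectors built under a different configuration, so a retuned radius can
never silently meet a model trained under another one. With the default
grid the vector has 36 × 59 × 2 + 12 = 4,260 positions.

Feature standardization uses training data only (means and scales are
stored in the model); the target stays in pK units, which are already
well scaled (roughly 2–12 across affinity benchmarks). Kernel
hyperparameters — length scale, signal and noise standard deviations —
are optimized by L-BFGS on the log marginal likelihood from data-driven
initializations (median pairwise distance; target SD), with box bounds of
e⁸ around the initial values to keep the search numerically sane. The
exact GP is O(n³) in the training size; at the few-thousand-complex scale
of affinity benchmarks this is tractable and no sparse approximation is
used.

## Ligand chemistry

PDB HETATM records carry no bonds, so a heavy-atom bond graph is
perceived from geometry (distance ≤ covalent radius sum + 0.45 Å). The
graph drives ligand pharmacophore typing and the connectivity-level
descriptors. Aromaticity for typing uses the graph plus bond lengths
(5/6-membered rings of C/N/O/S with short mean bond length and no
sp3-like branching); lengths are stored on the edges, so typing remains a
pure function of the bond graph, invariant to rigid motion. The
chemistry-heavy descriptors — molecular weight with implicit hydrogens,
Crippen-type logP, Ertl-type TPSA, donor/acceptor counts, molar
refractivity, sp3-carbon fraction, formal charge — are computed by Open
Babel (via `ChemmineOB`) on the same atoms, so the additive-contribution
schemes are the field-standard implementations rather than ad-hoc tables.
An SDF sidecar with explicit bonds overrides perception when bond orders
matter. Note that formal charge perceived from a hydrogen-free PDB block
is usually 0: protonation states are simply not encoded in the input.

## What the synthetic generator does and does not emulate

Every test runs offline against generated structures: a ligand template
with idealized literature geometry (benzene, acetate or neopentane) at
the origin, surrounded by a seeded random shell of real residues (ALA,
LYS, ASP, PHE, SER) with correct atom names, plus optional waters and a
sulfate decoy to exercise the cleanup rules. Labels come from a
*declared* linear model over named signature features plus Gaussian noise
(0.3 pK by default). The default label model weights short- and
medium-range hydrophobic cross-contacts (weights 0.045, 0.008, 0.02 on
three cross-block features, intercept 2), scaled once so synthetic
affinities span roughly 3–13 pK like a curated affinity set.

The generator validates *code paths, not chemistry*: residue shells are
random, poses are not energetically meaningful, and the label model is
linear by construction. Passing the recovery tests therefore shows that
the pipeline computes the declared features correctly and that the GP can
learn a known mapping through them — it says nothing about predictive
accuracy on real complexes, which depends on training data the package
does not ship.

## Numerical choices

* Distances are double-precision Euclidean distances between atom
  centers; cutoff membership is `d ≤ c` with no tolerance fudge.
  Coordinates are parsed from text once; all invariance claims are about
  the parsed geometry. Rewriting PDB *text* quantizes coordinates to
  three decimals (up to ~2·10⁻³ Å distance perturbation), which is why
  the in-memory `transform_complex()` exists alongside the text-level
  `rigid_transform()`.
* Alternate locations keep the highest-occupancy copy; ties prefer
  alt-loc "A", then first occurrence. Multi-model files keep the first
  MODEL (crystallographic benchmark sets are single-model).
* Ligand auto-selection takes the heteroatom group with the most heavy
  atoms; ties break by chain then residue number, and the choice is
  logged. When this rule would pick the wrong group (a large cofactor),
  an explicit `ligand_key` overrides it.
* Multi-label atoms increment every class combination of an atom pair
  exactly once; class pairs are unordered (36, not 64) because atom
  pairs are undirected.
* Cross-validation folds are a seeded shuffle dealt round-robin, so fold
  sizes differ by at most one and the partition is reproducible; all
  seeded randomness saves and restores the caller's RNG state.
* Fold of size one is only accepted as leave-one-out (k = n); otherwise
  a fold with fewer than two points is an input error.

## The permutation null is biased, and by how much

The negative control retrains the regressor on permuted labels and pools
out-of-fold predictions into one Pearson correlation. Under the null a
correctly-regularizing GP collapses to the training-fold mean, and the
pooled statistic then has a *built-in* negative bias of −1/√m for fold
size m (−0.32 for folds of 10): each held-out fold's labels anticorrelate
with the mean of the remaining data. Paradoxically, the better the model
recognizes that there is no signal, the stronger the bias; values near
zero would arise only from a noise-interpolating, under-regularized fit.
The package therefore estimates the null level as the mean over ten
permutation draws rather than trusting a single draw, and the observed
level should be read against the −1/√m yardstick, not against zero.

## Problem sizes in the shipped checks

The test-suite and acceptance script use 100 random toy complexes for the
exact counting cross-check, 10 complexes × 20 random rigid motions and
permutations for bit-exact invariance, 200 labeled complexes (10-fold CV)
for ground-truth recovery and 100 for the permutation null — sizes chosen
to exercise every code path with comfortable statistical margins while
keeping a full run in the minutes range on a single CPU.

## Known limitations

* No mmCIF input, no assembly generation, no protonation or side-chain
  repair; covalently linked het groups are not distinguished from
  ligands.
* The protein typing table is a curated reconstruction (versioned, and
  swappable); reasonable people could type a handful of atoms
  differently, and models are bound to the table version they were
  trained with.
* The descriptor panel is a standard physicochemical dozen, declared in
  the schema; it is not claimed to match any particular published
  descriptor list.
* Exact GP training does not scale past tens of thousands of complexes.
* Prediction quality on real data is bounded by the realism of the pose
  and by the training set; the package ships no trained weights.
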