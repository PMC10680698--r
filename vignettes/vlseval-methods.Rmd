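---
title: "Methods: retrospective VLS evaluation with vlseval"
author: "vlseval authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective VLS evaluation with vlseval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlseval)
```

# The evaluation model

A retrospective virtual ligand screen asks whether a receptor model,
combined with a scoring protocol, can rank known active compounds
above presumed inactives. `vlseval` decomposes that protocol into the
two decisions that matter in practice and evaluates each combination:

1. **Pose selection.** Docking produces several candidate poses per
   compound per receptor model (conventionally the top ten). A
   *selector* scorer X chooses one pose per compound — the pose with
   the minimal X score, all scores being normalized to lower-is-better
   at table ingestion (energy-like convention; scorers whose native
   orientation is higher-is-better are sign-flipped once, on input).
2. **Compound ranking.** A *ranker* scorer Y orders compounds by the Y
   score of their selected poses. The combination is written
   `"X|Y"`; X and Y need not coincide, and the package's scheme
   matrix evaluates every selector x ranker combination in one call.

Over an ensemble of receptor conformers, the pose pool of a compound
is formed across all models *first*, and a single selector argmin is
taken over the pooled set. The compound is therefore represented by
its best pose in its most favorable conformer — this is what lets an
ensemble combine pockets that each recognize only part of the
chemotype spectrum. The alternative reading (select per model, then
take the ranker-minimum across models) differs only when the selector
ordering across models conflicts with the ranker ordering; we fix
pool-first as the default because it makes the ensemble invariant
guarantees exact: the pooled selector score can never be worse than
any per-model selector score, and adding a model can never hurt the
selected pose's selector score.

Ties are resolved deterministically everywhere — pose id, then model
id, then compound id — so rankings are bit-reproducible.

# Metrics

ROC AUC is computed as the Mann-Whitney concordance probability on a
0-100% scale: the percentage of (active, non-active) pairs where the
active scores strictly better, with tied pairs counted at half credit.
This is identical to the trapezoidal area under the tie-grouped ROC
curve (tied thresholds advance the curve diagonally), and both routes
are cross-checked against each other and against a brute-force pair
enumeration in the test suite. 50% means no recognition; below 50% is
anti-predictive. The early enrichment factor at fraction *f* is the
active rate in the best `ceiling(f*N)` compounds divided by the
overall active rate; its null expectation is 1 and its ceiling is the
inverse overall active rate.

Activity cliffs — pairs of similar compounds with large potency
differences — are reported at Tanimoto similarity >= 0.85 and
|delta pActivity| >= 2 by default. The similarity floor of 0.85 marks
"minute structural change" on a radius-2 circular fingerprint; the
delta floor of 2 log units corresponds to the ~100-fold potency swings
typical of published cliff pairs. Because the fingerprint is
2D-connectivity only, stereoisomer pairs score similarity 1.0 and are
caught even though their structures differ in three dimensions — by
design, since stereo cliffs are among the most instructive.

# Library curation choices

* **pActivity.** All potencies are converted to -log10(concentration
  in molar). Units are taken from an explicit unit column (M, mM, uM,
  nM, pM); no unit guessing. Mixed measure types (IC50, Ki) are
  recorded but treated uniformly on the pActivity scale.
* **Strict cutoffs.** "Actives of pIC50 > X" uses strict inequality: a
  compound at exactly the cutoff is inactive. When a compound carries
  several measurements for one receptor/site, the most potent decides
  — a compound is active if any reliable measurement passes.
* **Fingerprints.** Hashed circular substructure fingerprint, radius
  2, 2048 bits, 2D-connectivity only. Input SMILES are round-tripped
  through OpenBabel's stereo-free canonical SMILES before graph
  extraction, which guarantees that equivalent SMILES (and
  stereoisomers) map to identical bit sets regardless of atom order or
  kekulization of the input.
* **UPGMA.** Chemotype clustering uses unweighted average linkage on
  Tanimoto distances, implemented in-package so that ties merge the
  pair whose lexicographically smallest member id is smallest, and a
  cut labels each cluster by its lexicographically first compound id.
  Both choices make cluster labels stable under permutation of the
  input. The default cut height of 0.6 Tanimoto distance separates
  discovery-program chemotypes cleanly on the synthetic benchmark; it
  is a configuration parameter, not a law.

# Decoy selection

Decoy matching follows the DUD-E convention: a candidate qualifies if
it falls within every property window of at least one active
(defaults: +/-25 Da molecular weight, +/-1.0 logP, +/-1 H-bond donor,
+/-2 acceptors, +/-2 rotatable bonds, exact formal charge) and its
Tanimoto similarity to *every* active is below 0.35. The decoy:active
ratio is a pooled quota — 54 decoys per active means
`54 * n_actives` decoys in total, with no per-active allocation —
matching how fold-ratios are reported in screening practice. Ties
among qualifying candidates are broken by a seeded draw over
candidates sorted by id, so selection is invariant to pool order.
A shortfall is an error that reports per-active qualifying counts
rather than silently returning fewer decoys.

# Structure geometry

All distances are in Angstrom. BW (Ballesteros-Weinstein) annotations
come from a user-supplied mapping table rather than a live database
query, keeping the package fully offline; loop-style ("45.52") and
helix-8 ("8.49") generic numbers are carried as opaque labels.
Superposition is a least-squares Kabsch fit over matched backbone
atoms (matched by generic number where both structures are annotated,
by chain/residue number otherwise); the test suite checks rigid-
transform invariance to 1e-6 Angstrom and agreement with a numerical
optimization oracle. Structures with alternate locations keep altloc
A. Mutation edits are bookkeeping only: shrinking substitutions
truncate the side chain at C-beta, growing substitutions add
placeholder atoms at occupancy 0 with no invented coordinates.

## Induced-fit fragment specifications

The fragment builder turns a receptor-ligand complex into a
declarative refinement recipe. Seed residues lie within 5.5 Angstrom
of the ligand at residue granularity. Contiguous seed segments are
expanded to the mode's minimum length — 9 residues for orthosteric
complexes, 18 for allosteric — by alternating N-/C-terminal growth
starting N-terminal; at a chain terminus the open end compensates.
Whether the original procedure grew segments symmetrically or
directionally is not documented anywhere we could find, so the
alternating rule was fixed for determinism. Overlapping segments
merge; annotated disulfide partners are pulled in so no S-S bond is
split across the included/excluded boundary (an independent validator
re-checks all invariants on every built spec). Mobility follows the
binding mode: orthosteric complexes sample TM1, TM2 and TM7 with full
backbone freedom and everything else side-chain-only; allosteric
complexes free TM6 and TM7-H8, keep TM1-TM2 and TM3 backbones
stationary with side-chain sampling, and omit TM4/TM5 entirely.
Fragment-end backbone atoms are tethered, plus (orthosteric) the
backbone carbons at BW 2.53/2.56/2.60/2.63; hydrogen-bond distance
restraints of 1.8-2.4 Angstrom at weight 1.0 reference the side
chains at BW 1.39/3.32/7.36/7.39/7.40/7.44 (orthosteric) or the
backbone amides at 8.49/8.50 (allosteric). Sampling directives record
10,000 (orthosteric) or 100,000 (allosteric) pre-minimization steps
and 1e6 global Monte Carlo steps. Executing the refinement is out of
scope; the spec is the product.

# The synthetic benchmark

The generator exists so that every pipeline stage can be exercised,
and the induced-fit phenomena reproduced, without proprietary docking
output. Its default configuration is the benchmark's study condition,
fixed once: 3 chemotypes x 30 actives with true pActivity uniform in
[7.5, 10.5], 30 inactives in [5, 7], a 20-fold decoy excess, 3
receptor conformers with compatibility 1.0 to their cognate chemotype
and 0.2 otherwise, 10 poses per compound-conformer pair, and two
scorers: a strict one (lambda = 0.9) and a tolerant one
(lambda = 0.2).

Scores follow the model stated in `?synthetic_config`: native poses of
actives score `-(alpha * pActivity * (1 - lambda*(1 - C[k,j])) + beta)
+ noise` with alpha = 2, beta = 5, noise_sd = 1; everything else draws
from N(-8, 3) truncated below at the theoretical native optimum. With
these constants a fully compatible native pose of a 7.5-10.5 active
sits at -20 to -26 while background rarely passes -20, so cognate
screens approach (but do not trivially saturate) 100% AUC, while a
strict scorer on a non-cognate conformer collapses toward the
background and lands near the 50-70% band — the dynamic range observed
in real retrospective screens. Chemotype fingerprints are realized as
random 120-bit templates with 15% per-compound bit replacement, which
puts within-chemotype Tanimoto similarity far above between-chemotype
similarity; decoy property vectors are drawn inside the windows of a
random active, with a 20% deliberate violation rate so the decoy
selector's rejection path is exercised.

What the generator does *not* emulate: real molecular geometry (poses
are score rows, not coordinates), correlated scorer errors, assay
noise structure, or a distinct third scorer family. Passing the
recovery tests therefore shows that the *pipeline logic* — pooling,
scheme decoupling, metric computation — reproduces the induced-fit
phenomenology when the data contain it; it says nothing about any
particular docking engine's accuracy on real compounds.

The helix-bundle generator provides geometry fixtures: ideal
alpha-helical Calpha traces (rise 1.5 Angstrom, twist 100 degrees,
radius 2.3 Angstrom, hence ~3.83 Angstrom consecutive Calpha spacing)
on user-specified axes with BW-style numbering, and optional per-helix
rigid shifts for a second conformational state.

# Numerical and scale choices

* AUC and curve areas agree to 1e-9; UPGMA ties use a 1e-12 distance
  tolerance; attribution sums default to 1e-6 tolerance in
  scorer-native units.
* Degenerate inputs are defined, not crashed: two empty fingerprints
  have similarity 1 (with a warning), an empty compound table yields
  an empty library with a warning, an all-tied score vector gives AUC
  exactly 50 and a diagonal ROC.
* Test and benchmark problem sizes were chosen so the full suite runs
  in well under a minute of compute per module: 500 random screens of
  up to 200 compounds for the AUC oracle sweep, 1,000 permutations of
  a 45 vs 2,430 screen for the null calibration, 200 random 6-leaf
  matrices for the UPGMA oracle sweep, and 10 seeds of the full
  1,920-compound benchmark for the phenomenon-recovery medians. These
  sizes give the medians and means room to concentrate without
  approaching any runtime constraint.

# Known limitations

* Fingerprints and descriptors depend on OpenBabel's perception
  (aromaticity, donor/acceptor definitions, additive logP); other
  toolkits will produce different absolute values, though all
  within-package comparisons are self-consistent.
* The decoy selector matches properties against *any* active (the
  DUD-E style), not per-active quotas; libraries with very
  heterogeneous actives may want per-active matching.
* `select_decoys` and clustering are O(actives x pool) and O(n^2) in
  compounds respectively; they are meant for curated libraries
  (10^2-10^4 compounds), not database-scale screening.
* Mutation edits do not rebuild side-chain geometry; downstream
  modeling must handle occupancy-0 placeholders.
* The fragment builder assigns helix identity by majority vote of a
  fragment's BW numbers; exotic annotations (split helices, chimeras)
  may need manual mobility overrides.
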