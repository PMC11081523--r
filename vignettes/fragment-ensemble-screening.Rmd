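---
title: "Fragment-aware consensus ensemble screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-aware consensus ensemble screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Virtual screening campaigns start from vendor libraries of $10^6$--$10^7$
compounds, of which a vanishing fraction is active against any one target.
`fragfocus` curates a *focused* library for a single protein target from a
modest table of measured bioactivities: it learns what known actives look
like -- both as whole-molecule fingerprints and as recurring
class-discriminative substructures -- and keeps only library compounds that
a panel of six classifiers unanimously calls active. The package
reimplements this pipeline end to end and ships a synthetic benchmark
generator so every stage can be exercised and tested without external data.

## Data model and labelling

A compound record carries an identifier, a canonical SMILES (Open Babel
canonical aromatic form via ChemmineOB), an optional potency in nM with its
measurement type (Kd, EC50, IC50 or percent inhibition), and an optional
activity label. Choices worth stating:

* **Duplicates** collapse to the most potent record (`potency_nm` minimum);
  records without potency lose ties. Structures differing only by
  unspecified stereochemistry are treated as duplicates; distinct fully
  specified stereoisomers are kept apart, since bioactivity tables encode
  stereo inconsistently.
* **Labels** derive from a potency cutoff of 10,000 nM: strictly below is
  active, at or above is inactive. A value exactly at the cutoff is deliberately
  assigned the conservative (inactive) side. Mixed potency types are
  compared on raw nM without conversion; percent-inhibition records are
  never cutoff-labelled.

## Prefilters

Screening libraries are cleaned with two standard filters before anything
else: PAINS substructure alerts (the published 480-pattern A/B/C SMARTS
catalogue, shipped in `inst/extdata/` so results do not drift with toolkit
versions; molecules are hydrogen-expanded before matching because many
patterns bind explicit hydrogens) and a QED floor (compounds with QED
$\le$ 0.25 removed; the threshold is inclusive). PAINS is applied first
only so the removal accounting is deterministic -- the kept set is
order-independent.

QED is the mean-weighted desirability of Bickerton et al.: eight
properties (MW, ALOGP, HBA, HBD, PSA, ROTB, AROM, ALERTS), each mapped
through an asymmetric double sigmoid fitted to oral drugs, combined by a
weighted geometric mean. The desirability parameters and alert SMARTS are
the published ones; MW/ALOGP/PSA come from Open Babel (Wildman--Crippen
logP, TPSA), the counts from SMARTS and the package's own ring perception.
Two alert patterns are multi-component counting rules ($\ge$3 ester
groups, $\ge$4 fluorines) and are implemented as match-count thresholds.
Open Babel's logP/TPSA differ from other toolkits' by small amounts on
some nitrogen/sulfur groups; tests therefore pin the desirability stage
exactly (on reference property values) and the end-to-end score on
hydrocarbons, where all backends agree.

## Fragment mining

The core of the package is a miner for *ring-complete, class-discriminative
substructures*: connected heavy-atom subgraphs that occur in at least 1% of
the actives (minimum support) and at most 20% of the inactives (maximum
support). Molecule-level support is used throughout -- a molecule either
contains at least one embedding of a fragment or it does not.

Design:

* **Ring completeness.** Units are bridge bonds and minimal rings (all
  shortest cycles through each ring bond). A candidate subgraph is a
  connected union of units in which every ring bond brings along at least
  one of its minimal rings, so partial rings never appear. A fragment may
  still end on a ring atom reached through an acyclic bond.
* **Enumeration.** Candidates are enumerated per active molecule (ESU over
  the unit graph, capped by `max_fragment_atoms`, default 15 heavy atoms)
  and deduplicated across molecules by a canonical code for small labelled
  graphs (lexicographically minimal serialization over an
  isomorphism-invariant family of vertex orders). Atoms are typed by
  element, formal charge and aromaticity; bonds by order or aromaticity.
* **Support counting** is subgraph monomorphism (VF2-style backtracking in
  C++), not generation-based counting: a chain mined from an acyclic
  region still counts as contained in a saturated ring. The fragment
  universe is anchored to the active class -- a subgraph must occur
  ring-completely in at least one active to be considered.
* **Pruning.** Active support is anti-monotone, so candidates are
  processed in increasing size and evaluated only when all recorded
  remove-one-unit parents passed (Apriori). The inactive-support cap is
  *not* anti-monotone and is applied only as an output filter.
* **Order.** The library is sorted by descending active support, then
  ascending size, then lexicographic SMILES, so feature columns are stable
  across runs.

The mining configuration mirrors the classical substructure-mining setup
(1% / 20% supports, ring mining on); the 15-atom cap and the exact matching
conventions (charge equality, aromatic bonds as their own bond type,
implicit hydrogens) are this package's documented defaults, not inherited
settings.

Because mined fragments can carry an aromatic atom without its complete
ring, standard SMILES cannot always represent them faithfully; the library
file therefore stores an explicit atom/bond encoding next to a display
SMILES, making the round trip lossless.

Correctness is tested against an independent brute-force oracle (pure R:
edge-subset enumeration, its own ring perception, its own isomorphism and
embedding matchers) on dozens of seeded small-molecule datasets, where the
miner must agree *exactly*, fragment for fragment and support for support.

## Featurization

Each molecule becomes `n_bits + |library| + 1` columns:

1. **Fingerprint bits** (default 1024): a hashed circular
   (Morgan/extended-connectivity style) fingerprint computed on the
   package's heavy-atom graphs. The initial atom invariant is
   hydrogen-agnostic (element, charge, aromaticity, degree, bond-order
   sum); each iteration up to the radius (default 2, the common
   diameter-4 variant) hashes the sorted neighbour invariants. The
   implementation is in the package's C++ and is deterministic across
   platforms. Hashed bit positions are toolkit-specific in any circular
   fingerprint; what matters downstream is determinism and locality, both
   tested.
2. **Fragment similarities**: Tanimoto between the molecule's fingerprint
   and each library fragment's fingerprint, computed under the same
   configuration directly on the fragment graphs. The choice of fragment
   fingerprint is underdetermined in principle; one shared configuration
   keeps the similarity well defined.
3. **Fragment match count**: how many library fragments embed in the
   molecule as substructures (an alternative similarity-threshold
   definition is available behind `match_definition` for sensitivity
   analysis).

Bits and similarities are left unscaled; scaling is a per-member concern
(below).

## The ensemble

Six member classifiers: regularized logistic regression (glmnet),
k-nearest neighbours, kernel SVM (e1071), random forest (ranger), gradient
boosted trees (xgboost) and a single-hidden-layer feed-forward net (nnet).
Members that are scale-sensitive (linear, kNN, SVM, net) standardize
features on the training data; tree members take raw features. Class
imbalance is handled by balanced class weights where the member supports
them; there is no resampling.

**Tuning.** Each member is tuned by seeded random search (default 300
trials; the packaged study uses 20) over documented spaces, scored by
stratified k-fold cross-validation (default 10 folds; the packaged study
uses 5). The objective is mean CV precision subject to a recall floor of
0.25: a pure precision objective is degenerate (predict almost nothing),
so trials below the floor rank strictly below any trial above it. The best
trial is refitted on the full training data. Determinism: the same seed
reproduces the same trials, folds, and fitted members.

Two pragmatic member-level choices: the SVM's Platt probability model is
fitted only for the final refit (during CV the logistic-squashed decision
value is used, which crosses 0.5 exactly at the class boundary), and the
net screens its inputs to the top 256 columns by absolute two-sample
t statistic computed on its training fold -- full-batch BFGS scales
quadratically with the weight count, and the screen keeps the member
honest (fold-local, supervised only by training labels) while making it
tractable at 1300+ features. The kNN member tunes k only; distance
weighting is not exposed by the underlying implementation.

**Consensus.** A compound's votes are the number of members whose positive
probability is at least 0.5. The default decision requires all six votes.
Two provable properties are asserted at run time and in tests: the
unanimous positive set is the intersection of member positive sets (so the
ensemble's false positives cannot exceed any member's), and the positive
set shrinks weakly as the threshold rises.

**Evaluation.** Confusion-count metrics are computed from their defining
ratios and identity-tested to 1e-12; ROC curves/AUC come from pROC;
average precision is the interpolation-free step sum. A screening-oriented
extra is the false-positive rate on an assumed-inactive pool (a random
commercial-directory stand-in) as a function of the vote threshold.

## Screening and diversity analyses

`screen_library()` streams a `.smi` file in chunks (constant memory;
chunking provably cannot change results, and a test verifies it), skipping
and counting corrupt records, and reports the vote histogram, per-threshold
pass counts and the reduction fraction. Diversity tooling for the focused
library: pairwise Tanimoto similarity matrices; k-medoid cluster
representatives (default 30 clusters, medoid = representative; the
partitioning method is this package's choice, seeded and deterministic);
and a deterministic principal-component projection of fingerprints to 2-D
(component signs fixed by the largest loading). The fragment-match/label
profile bins compounds at {0, 1--4, 5--9, 10--19, >=20} matches and reports
the active fraction per bin.

## Counterfactual explanations

A counterfactual is a minimally modified molecule whose predicted class
flips. Variants are produced by seeded token-level edits of the SMILES
string (atom substitutions within aromatic/aliphatic alphabets, small
insertions, deletions, bond-order changes); *validity is guaranteed by
filtering every candidate through the parser* rather than by a
grammar-safe representation -- no SELFIES implementation exists in R, and
the parse filter achieves the same contract (every returned variant
parses, is unique, and excludes the base). Flipped variants are ranked by
fingerprint Tanimoto to the base -- the model's own representation -- and
the top k returned; the ranking is tested against exhaustive recomputation
over the generated pool. An empty result is valid and flagged with a
warning. Fragment-overlap annotation reports, per library fragment,
whether the base matched it and whether the variant retained, lost or
gained it.

## The synthetic benchmark

The generator emulates the statistical structure the pipeline assumes, not
any real target's chemistry:

* **Actives** (default 50) are decorated planted scaffolds -- distinctive
  fused ring systems (indole, quinazoline, benzofuran by default; up to
  five available) -- at 90% penetrance (deterministic count, so the
  planted-recovery tests are not at the mercy of binomial noise).
  Active substituents are drawn from a polar/H-bonding enriched pool with
  probability `substituent_bias` (default 0.7): real bioactivity series
  share decoration chemistry as well as scaffolds, and without this the
  scaffold-free 10% of actives would be information-free, making member
  AUC on a small test set a coin flip rather than a property of the
  method.
* **Inactives** (default 450, the 1:9 imbalance typical of bioactivity
  tables) are single-ring decoys except for a 2% planted contamination.
* **Potencies** are log-normal per class (log10 means 2.6 and 5.0, SDs
  0.5/0.4 -- roughly 400 nM actives vs 100 uM inactives), and labels are
  re-derived through the 10,000 nM cutoff, so generator and labeller agree
  while a small, realistic crossover fraction lands on the other side.
* **Negative pool and stream**: the pool (990 compounds) is scaffold-free
  and disjoint from the paired benchmark; the stream mixes decoys with
  planted molecules at a configurable fraction (Bernoulli per record,
  duplicates possible, as in vendor libraries).

Everything is drawn from curated templates with substituent slots, so
every generated SMILES parses by construction, and every draw depends only
on the seed.

What passing on this benchmark does and does not show: the planted signal
is strong and scaffold-driven, so members reaching test AUC >= 0.9 and the
screen enriching planted actives says the pipeline's plumbing and learning
machinery work; it says nothing about real-target chemistry, assay noise,
activity cliffs, or scaffold hopping, none of which the generator
emulates.

## Problem sizes and numerical choices

The packaged study uses 500 training compounds, a mined library of several
hundred fragments, a 990-compound negative pool and a 10,000-compound
stream, with tuning reduced to 20 trials and 5 folds -- sizes chosen so the
full study runs comfortably on a laptop core while exercising every code
path at realistic shape. Degenerate inputs are handled explicitly: empty
datasets round-trip, single-class training errors, single-class AUC is
reported as undefined while count metrics are still computed, an
all-negative consensus yields an empty focused library with exact
accounting, and subgraph enumeration carries a per-molecule safety cap
(200,000) with a warning. Support-threshold comparisons are done on
support fractions (count/n vs the configured fraction), which is exact at
the boundaries actually exercised (1% of 200, 20% of 100) because both
sides share the same floating-point representation.

## Known limitations

* Aromaticity, canonicalization and SMARTS semantics are Open Babel's;
  other toolkits disagree on edge cases (as do their logP/TPSA
  parameterizations, hence the tolerance structure in the QED tests).
* Fingerprint bit positions are implementation-specific; models and
  libraries are portable only within this package's featurizer.
* The miner's fragment universe is anchored to the active class; a
  fragment occurring only non-ring-completely in every active is not a
  candidate.
* Counterfactual edits explore a local token neighbourhood; they can miss
  flips requiring coordinated multi-site changes.
* No docking, pose filtering, probability calibration or stacking: scope
  ends at the focused library and its explanations.
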