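---
title: "Scaffold enrichment and cost-sensitive screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold enrichment and cost-sensitive screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

ScaffoldScreen analyses heavily imbalanced small-molecule screens — the
regime of the PubChem miR-21 modulator assay, where ~1% of ~300k compounds
score active and a luciferase counter-screen disqualifies most of those.
This vignette is the package's account of its models, parameter choices and
limitations. It states no result that the test suite and
`scripts/acceptance.R` do not themselves compute.

## The data model

A molecule is a 2D heavy-atom graph: atoms carry element, formal charge and
an aromatic flag; bonds carry order 1, 2, 3 or aromatic (its own order, not
1.5). Hydrogens are implicit; every "atom count" in the package, including
the MCS merge threshold, means heavy atoms. Multi-fragment records (salts)
are reduced to their largest fragment before descriptor or MCS work, with a
logged count — public bioassay SDF exports are silent about salt handling,
so the package standardizes and says so.

Matching policy (both `isSubstructure()` and the MCS): atoms must agree on
(element, aromatic flag); bonds on order, aromatic distinct from single;
formal charge is ignored. Embeddings are subgraph *monomorphisms*: a
3-carbon path matches cyclopropane, and the common subgraph of two
molecules may omit bonds between mapped atoms. Aromatic-vs-Kekulé
mismatches are avoided by perceiving aromaticity at parse time
(alternating 6-rings of neutral C/N; 5-rings with two double bonds and a
lone-pair N/O/S heteroatom) — deliberately minimal, covering the common
heteroaromatics rather than the full Hückel rule.

## Curation

PubChem-style banding is a total partition of the score range: 40–100
active (boundaries inclusive), 0 inactive, 1–39 inconclusive. Counter-screen
filtering removes flagged records from the active class entirely — they are
artifacts, not evidence of inactivity — and never touches the other
classes; the arithmetic 3282 scored actives − 2399 flagged = 883 retained
is exercised in the tests. Inconclusives are excluded from all modeling.
The train/test split (default 20% test) is stratified by class: at 0.3%
prevalence an unstratified split can contain no actives at all.

## Descriptors (179 columns)

The published descriptor tool for this assay family (PowerMV) prints only
block sizes — 147 pharmacophore fingerprints, 24 weighted Burden numbers, 8
properties — not its atom-typing rules or bin edges. The package therefore
fixes a documented scheme that reproduces the counts exactly, and treats
bit-level equivalence as out of reach:

- **Pharmacophore-pair bits (147).** Six atom classes (H-bond donor,
  acceptor, positive ionizable, negative ionizable, hydrophobe, aromatic;
  rule table on `assignPharmacophoreClasses()`), 21 unordered class pairs ×
  7 shortest-path bins ({1,2,3,4,5,6,≥7} bonds) = 147. A bit is set only by
  *distinct* atom pairs in the same fragment: an atom carrying both classes
  of a pair does not by itself fire the pair, so single-heteroatom molecules
  like ethanol set no (donor, acceptor) bit.
- **Burden eigenvalues (24).** The classical Burden matrix — diagonal =
  atomic weight; bonded off-diagonal 0.1 × bond order (aromatic 1.5) with
  +0.01 when either end is terminal; 0.001 elsewhere — under three atomic
  weightings: Pauling electronegativity, Gasteiger-style PEOE partial
  charges (6 damped iterations over heavy atoms plus implicit hydrogens,
  hydrogen charges folded back), and a coarse additive logP contribution
  table (recorded in the matrix metadata as `coarseXLogP-1`). Per scheme,
  the 4 smallest and 4 largest eigenvalues, ascending; molecules with < 4
  atoms pad with the clamped extreme eigenvalue, so a single atom yields its
  three weights repeated.
- **Properties (8).** MW, additive logP, Ertl-style TPSA (N/O fragment
  contributions), donor and acceptor atom counts, rotatable bonds (non-ring
  single bonds between non-terminal heavy atoms), cyclomatic ring count,
  heavy atoms. The source tool's own list of 8 is unpublished; this list is
  an emulation and is documented as such.

Constant-bit filtering removes binary columns taking one value across the
dataset (never continuous columns), records the retained mask, and is
idempotent. On the original corpus this reduced 179 to 154 columns; that
number depends on the corpus and is not asserted anywhere.

## Cost-sensitive classification

Class imbalance makes plain accuracy useless, so both classifiers score
compounds and a *minimum expected misclassification cost* rule thresholds
the score: with false-positive cost 1 and false-negative cost `c`, predict
active when `p > 1/(1+c)`; ties go to inactive. Raising `c` lowers the
threshold and rescues rare actives at the price of false positives, so the
package searches `c` over a serial schedule (geometric 1–2–5 ladder up to
1e5, covering both the tens scale a Naive Bayes needs and the 1e4 scale a
vote-fraction forest needs) and selects the largest `c` whose stratified
5-fold cross-validated false positive rate stays within the cap
(default 0.20 — "approximately 20%" implemented as a hard, configurable
constraint). CV scores are computed once; the ladder only moves the
threshold, which also makes the monotonicity of the predicted-active count
in `c` exact. Cost sensitivity by thresholding (not reweighting or
resampling) is chosen because it is deterministic and is literally the
minimum-expected-cost decision rule.

The Naive Bayes is written from scratch: Bernoulli likelihoods with Laplace
α = 1 for bits, Gaussian likelihoods with σ floored at 1e-9 for continuous
columns, posteriors in log space and normalized. The random forest is a
contract around a ranger probability forest (100 trees, √m features per
split, Gini, unlimited depth — the forest internals are this package's
defaults, not published values); its score is the fraction of trees voting
active. Consensus screening intersects per-model predicted-active id sets.

The original study's headline test metrics (TPR ≈ 55–60%, FPR ≈ 19–20%,
AUC ≈ 73–77%) were obtained on the 333k-compound corpus with an unpublished
cost schedule and cannot be reproduced from the paper alone; the package's
acceptance checks instead assert the *properties* those numbers express:
the tuned cost keeps CV FPR ≤ 0.20 while strictly improving TPR over the
cost-1 baseline, and both classifiers exceed 0.8 held-out AUC on assays
with planted descriptor effects.

## Evaluation

Rates follow the textbook definitions (TPR = TP/(TP+FN), FPR = FP/(FP+TN),
accuracy, specificity); BCR is the mean of sensitivity and specificity.
Undefined rates (an empty class) are NaN with a warning, never silent
zeros. ROC sweeps all thresholds; the trapezoid AUC equals the Mann–Whitney
pair statistic with ties counted 1/2 (the tie convention is ours; the
source is silent). Internally rates live in [0,1]; percentage display is
left to callers. A printed-table BCR that disagrees slightly with the BCR
recomputed from its own row (66 vs 67.2, 70 vs 70.6 in the source) was
noted during development; the package implements the stated definition and
does not chase the printed rounding.

## MCS clustering and enrichment

`mcs()` finds a maximum *connected* common subgraph exactly, as a maximum
c-connected clique on the modular product graph: product vertices are
atom-compatible pairs; c-edges join pairs whose two sides share a bond of
equal order; any other distinct-atom pair is a d-edge (the common subgraph
may omit bonds). The branch-and-bound prunes with the best-found size, a
distinct-atoms-remaining bound, and a reachability filter that discards
candidates not c-reachable from the current clique. Molecules beyond 40
heavy atoms, or searches past the node budget (2e6), return the best clique
found and are flagged inexact; all oracle tests run in the exact regime.

Clustering is LibMCS-flavoured greedy agglomeration: level 1 is the input
molecules; at each level the cluster pair with the largest representative
MCS merges (each cluster at most once per level), provided the MCS has ≥ 10
heavy atoms — the merge threshold applies to merges only, leaves are
exempt — and the merged representative *is* that MCS; up to 6 levels. Ties
break by smaller combined member count, then lexicographically on the
representatives' canonical codes (an individualization-refinement canonical
form), so builds are deterministic given input order; the reference tool's
internal order is unpublished. Top-level clusters drop singletons (a
singleton's "scaffold" is just the molecule).

Each surviving scaffold is counted in the active and inactive libraries
(each molecule at most once) and tested with Pearson chi-square, df = 1,
*without* Yates continuity correction — the published table values (e.g.
1144.377) reproduce only without the correction, which the acceptance tests
verify to ±0.01 together with the enrichment factors (±0.01; the source
truncates EF to two decimals). Selection keeps scaffolds with active-set
frequency strictly > 1% (with 883 actives that means ≥ 9 occurrences),
p < 0.01 and EF > 2, all strict, sorted by descending EF; `c = 0` gives an
infinite EF, which passes. The chi-square itself is delegated to
`stats::chisq.test`; occurrence counting uses all compounds of both curated
classes, the totals under which the published statistics reproduce.

## The synthetic assay generator

`generateAssay()` emulates the corpus shape every stage assumes: 500 scored
actives against 20,000 inactives (the study-scale 302k inactive set is
emulated at a size that keeps a full pipeline run around a minute; the
statistics are checked with sampling bands, not point values), integer
scores uniform on 40–100 for actives and 0 for inactives (the real score
distribution is unpublished), a counter-screen flagging 73.1% of scored
actives (mirroring 2399/3282) independently of scaffold membership, and
three planted scaffolds at 10% frequency among actives versus 0.1% among
inactives.

Molecules come from a ring-and-linker grammar (benzene, pyridine,
pyrimidine, pyrrole, furan, thiophene, imidazole, cyclohexane, piperidine,
quinoline; joined by direct bonds, methylene/ethylene, ether, amine,
carbonyl, vinylene, oxymethylene) decorated with 0–2 small substituents.
Two design choices make the planted signal *identifiable* and are worth
stating plainly:

- Background molecules in both classes are decorated draws from a per-assay
  pool of 25 background scaffolds, so every background chemotype is common
  (~4% of either library). A rare background chemotype hit twice among ~135
  curated actives would otherwise look significantly enriched purely by
  sampling — with common chemotypes, a chance double-hit is nowhere near
  the p < 0.01, EF > 2 selection region.
- Planted scaffolds are drawn to be mutually dissimilar and dissimilar from
  the background pool below the 10-atom merge threshold, so planted
  clusters cannot be absorbed into background clusters during
  agglomeration.

What the generator does **not** emulate: realistic medicinal-chemistry
property distributions, activity cliffs, assay noise in scores, correlated
descriptor structure, or actives whose activity has no structural cause.
Passing recovery tests therefore shows the pipeline recovers planted
structure under the stated statistical shape — not that it would rank
scaffolds correctly in any real screen.

Planted *descriptor* effects (for the classification checks) are simulated
directly at the matrix level by `simulateDescriptors()`: 10 fingerprint
bits at P(bit|active) = 0.8 vs P(bit|inactive) = 0.2 over a 0.3 background
rate, continuous columns uninformative standard normal. This decouples the
classifier checks from the descriptor chemistry; the end-to-end pipeline
also exercises the real featurization path.

## Numerical choices and degenerate inputs

Laplace α = 1; Gaussian σ floor 1e-9; posteriors in log space (the direct
product formula is verified to 1e-12 on small cases); cost ties predict
inactive; ROC ties 1/2; chi-square requires (a, c) not both zero and errors
on impossible counts; banding errors outside [0,100]; splitting and CV
error when a class is smaller than 5 records or k folds; MCS of molecules
with no shared atom is the empty graph; canonical codes cap the
individualization search (molecular automorphism groups are tiny in
practice). All randomness flows through explicit integer seeds, and seeded
operations restore the caller's RNG state.

## Problem sizes used by the shipped checks

The test suite runs the oracle comparisons on 200 random pairs (≤ 8 heavy
atoms) for both MCS and substructure matching, 50 random score sets for
AUC, and the full recovery pipeline on five seeded default-size assays
(500/20,000); `scripts/acceptance.R` repeats the headline computations with
three pipeline seeds derived from `--seed`. These sizes keep the whole
suite within a few minutes on one CPU while leaving every statistical check
in its asymptotic regime.

## Known limitations

- SMILES coverage is the organic subset plus bracket charges/hydrogens;
  stereochemistry and isotopes are accepted and discarded (the pipeline is
  2D). Supported elements: B, C, N, O, F, Si, P, S, Cl, Br, I.
- Aromaticity perception is rule-of-thumb, not full Hückel; exotic
  aromatic systems should be supplied in aromatic SMILES form.
- Descriptors are an emulation of an unpublished scheme: column *counts*
  and semantics match, individual values will not match the original tool.
- The MCS is exact only up to 40 heavy atoms / the node budget; beyond
  that results carry an `exact = FALSE` flag.
- Random-forest persistence relies on R serialization; only the Naive
  Bayes model has a portable JSON format.
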