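---
title: "Heat map molecule coloring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat map molecule coloring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmheatmap)
```

## The problem

High-throughput screening models built with linear support vector machines
on sparse substructure fingerprints predict well on large, diverse compound
collections, but a prediction value alone does not tell a medicinal chemist
*which part* of a molecule drives the prediction. This package implements a
heat map coloring: every bond of a compound receives a score derived from
the weights of a trained linear model, and the scores are rendered as a
red–orange–green gradient on a 2D depiction. Green marks substructures the
model associates with the positive (active) class, red with the negative
class.

The approach requires a fingerprint whose features can be mapped back to
atoms and bonds. We therefore use an explicit-growth circular substructure
fingerprint (an ECFP variant) that records, for every hashed feature,
exactly which atoms and bonds each occurrence covers.

## The model

A screening set is $\ell$ labeled fingerprints $(\mathbf{x}_i, y_i)$,
$x_{ij} \in \{0,1\}$, $y_i \in \{-1,+1\}$. A linear SVM learns the
discriminant

$$ f(\mathbf{x}) = \mathbf{w}^\top \mathbf{x} + b, $$

whose sign is the predicted class and whose magnitude is a confidence
proxy. Because $\phi$ is the identity, the weight $w_j$ of feature $j$ is
directly interpretable, in the spirit of a Free–Wilson analysis: strongly
positive weights mark substructures important for activity, strongly
negative weights mark inactive or counteracting substructures. The weights
are relative importances, not binding-affinity contributions — the SVM is
a classifier, not a regression model.

The solver is the classical dual coordinate descent algorithm for
L2-regularized L1-loss (hinge) linear SVC, with the negative class's cost
multiplied by a class weight $W_{-1}$ and the bias handled as an augmented
constant feature. No liblinear binding exists in the supported R
environment, so the algorithm is implemented in C++ inside the package; a
test cross-checks it against scikit-learn's liblinear on a fixture. The
solver's coordinate order is shuffled with an internal deterministic RNG,
so fits are bit-reproducible for a given seed on every platform. On
non-convergence the package warns with diagnostics rather than erroring
(matching liblinear's behaviour), because a single extreme grid point
(e.g. $C = 256$ on noisy data) should not abort a whole grid search; the
flag is recorded on the model.

## The fingerprint

Every heavy atom is a center. Iteration 0 is the center alone; iteration
$i+1$ absorbs the attachment-point atoms (the not-yet-member neighbors)
and exposes their neighbors as new attachment points. A substructure's
bond set contains all bonds among member atoms **plus the bonds out to
attachment points** — this inclusion is what lets even an iteration-0
feature color its incident bonds. Growth for a center stops once the
attachment set is empty (the whole connected component is covered), so a
fully-covered substructure is emitted once, not once per remaining
iteration, which would artificially multiply its weight in the coloring.

Atoms are labeled by Daylight-style invariants: atomic number, heavy
degree, attached hydrogen count, formal charge, aromaticity flag, ring
flag. Hydrogens are atom attributes rather than graph nodes: all rendered
output is heavy-atom bonds, and the hydrogen count still enters the
invariant, so no information the encoding uses is lost.

Each substructure is serialized to a canonical certificate of its
attachment-marked induced subgraph (attachment points carry a reserved
wildcard label `*`, since any atom can match there). The certificate is
computed by color refinement with individualization on ties — a proper
canonical form, so the fingerprint is invariant to atom input order by
construction, not merely in expectation. The certificate is hashed with
64-bit FNV-1a, masked to `hash_bits` bits (default 22, i.e. a $2^{22}$
feature space; the default depth is 4). FNV-1a is a fixed-constant,
platform-stable hash: persisted models remain valid across sessions.

When two distinct certificates hash to one id, the collision is kept
visible (`collision_stats()`), and the feature's provenance contains the
occurrences of *all* colliding substructures, so a model weight flows to
every bond set that caused the collision. Identical (atom set, bond set)
occurrences arising from different centers (e.g. the two centers of
ethane's C–C feature) are stored once; they are indistinguishable, and
counting them twice would double that feature's contribution.

## From weights to colors

The score of bond $b$ is

$$ s_b = \sum_{f :\, b \in B(f)} w(f), $$

summed over every feature occurrence whose bond set $B(f)$ contains $b$.
Optionally each contribution is divided by $|B(f)|$ (`size_normalize`),
spreading a feature's weight evenly over its bonds; the default is off —
for diverse screening sets the scaffold matters most, and colorings are
smoother without equal distribution.

Scores are mapped to $[0,1]$ by $\nu = (s - s_{\min})/(s_{\max} -
s_{\min})$ with two choices of context:

* **single-molecule**: extremes of the current compound — maximal
  within-molecule contrast, no absolute scale (the prediction value is
  shown alongside to compensate);
* **full-set**: extremes over the whole training set plus the compounds of
  interest — one shared affine map, so cross-compound differences remain
  comparable, at the cost of washing out small within-molecule contrasts.

Both are increasing affine maps of the same scores, so the within-molecule
ranking of bonds is identical under either mode. Numerical conventions:
a degenerate context ($s_{\max} = s_{\min}$, e.g. an all-zero model) maps
every bond to the neutral $\nu = 0.5$ rather than asserting unresolvable
importance; scores outside a full-set context (possible for external
compounds) are clamped to $[0,1]$.

The gradient runs red $(255,0,0)$ → orange $(255,165,0)$ → green
$(0,200,0)$ as two linear sub-gradients: for $\nu \le 0.5$ each channel
mixes the negative and mid anchors at $t = 2\nu$; above, the mid and
positive anchors at $t = 2\nu - 1$. Both sides reach the mid color exactly
at $\nu = 0.5$, so the combined map is continuous. Channels are rounded
half-up to integers (the rounding convention is a documented choice; the
original renderer's is unstated). Anchors are configurable.

## Evaluation protocol

`evaluate_cv()` is a repeated two-deep (nested) cross-validation:
stratified 5-fold outer, repeated twice by default. Inside each outer
training portion only, features occurring in fewer than 3 molecules are
discarded, and $C$ and $W_{-1}$ are selected by a stratified inner 2-fold
search over $\log_2 C \in \{-5,\dots,8\}$ and $\log_2 W_{-1} \in
\{-4,-2,0\}$, maximizing mean inner AUC. The selection metric is AUC (the
universal metric across imbalanced screening sets); ties break toward the
smaller $C$, then the smaller class weight — simpler models first. Inner
folds are drawn fresh per outer fold and held fixed across the grid scan.
A poison-probe test verifies that features present only in a held-out fold
never reach that fold's model.

## The synthetic world

Real screening sets cannot ship with the package, so the generator builds
labeled libraries with planted, weighted substructures — the structural
premise the method rests on (actives share weighted substructures,
inactives lack them). Molecules are assembled by joining random
alkyl/aryl/heteroaryl scaffold pieces and 0–2 uninformative decoy
fragments at random open valences; fragment attachment guarantees valid
valences and realistic substructure sharing, unlike random graphs.

Defaults state the world used by the tests: an activating
furan-carboxamide planted in 100% of actives and 0% of inactives (a clean,
separable signal), and a deactivating trichloromethyl group in 80% of
inactives and 10% of actives — so some actives carry a genuinely
negative-weighted substructure, the case the coloring must resolve. Label
noise (default 0) flips labels after assembly; the ground-truth annotation
keeps the pre-noise assignment. The recovery statistic is the fraction of
true actives whose planted bonds outscore (mean $\nu$) the rest of their
bonds.

What a green test establishes: on data whose discriminative substructures
are known, the pipeline's colors point at them. What it does not
establish: performance on real chemical matter with activity cliffs,
correlated scaffolds, or assay noise structure — the library's diversity
is far below a real HTS deck, and its decoys are not property-matched.

## Other design decisions

* **Chemistry I/O** is a self-contained SMILES (organic subset + bracket
  atoms) and SDF V2000 reader/writer; no R cheminformatics toolkit is
  available in the supported environment. Aromatization of Kekulé input
  uses a simplified Hückel rule (5–7-membered rings, sp2-capable atoms,
  $\pi$-count $\equiv 2 \bmod 4$) covering benzenoid, pyridine-, furan-,
  thiophene- and pyrrole-type rings; exotic aromatic systems must arrive
  pre-aromatized. Inputs are expected to be pre-standardized
  (neutralized, canonical tautomers); the package applies only default
  sanitization.
* **Indices are 1-based** throughout (R convention), including exported
  provenance and coloring tables.
* **Depth semantics**: `depth` is the maximum iteration index (depth 4
  means iterations 0–4), configurable at fingerprint time and pinned in
  saved models, which refuse fingerprints from a different configuration.
* **Layout** is a deterministic Kamada–Kawai embedding seeded from a
  circular arrangement; depictions are schematic, and visual parity with
  any particular drawing toolkit is a non-goal.

## Limitations

Count fingerprints, the original implicit-update ECFP, nonlinear kernels,
3D/binding-pocket visualization, tautomer canonicalization and atom-based
rendering as a default are all out of scope. The coloring explains the
model, not the chemistry: it is only as good as the model's AUC, and
substructure importances are meaningful only within the model's
applicability domain.
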