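---
title: "Property-matched decoy generation: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property-matched decoy generation: models, metrics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoygen)
```

## The problem

Structure-based virtual screening benchmarks rank known binders (*actives*)
against presumed non-binders (*decoys*). If the decoys differ from the
actives in bulk physicochemical properties — molecular weight, logP,
hydrogen-bond counts, charge — a scoring method can separate the classes
without performing any molecular recognition (*artificial enrichment*).
Conversely, decoys that are too structurally similar to the actives risk
being undiscovered binders (*false negative bias*). `decoygen` generates
decoys tailored to each active: property-matched by construction, but
structurally dissimilar, and it quantifies the residual bias of any
active/decoy set.

## The generative model

The generator is a graph-to-graph variational model. Training data are pairs
of molecules (A, B) from a library that satisfy three criteria: (i)
identical heavy-atom count and identical counts of C, N, O, S, Cl and F;
(ii) Euclidean distance between z-normalized property vectors below a
threshold (0.20 for the high-dimensional property set, 0.07 for the
eight-property set); (iii) Morgan-fingerprint (radius 2, 1024 bits) Tanimoto
similarity at most 0.15. Because criterion (i) is an exact equality, the
library is bucketed by composition and only within-bucket pairs are scanned
— this is lossless, and `build_pairs` is tested against a brute-force
all-pairs oracle.

The model encodes a molecule with gated-graph-style message passing and
decodes a new molecule bond-by-bond, breadth-first, from a pool of atoms
initialized to the active's exact element counts (so criterion (i) holds by
construction; the pool and a partial seed graph can be overridden). At every
step the permitted actions are: attach a pool atom to the focus atom with a
given bond order, close a ring to an already-placed atom, or finish the
focus atom. Actions violating an element's maximum valence are masked, so
every generated molecule is chemically valid — this is asserted over 10^4
generations in the test suite.

### Desk-scale architecture

The reference problem is GPU-scale; this package deliberately fits on one
CPU. The message-passing weights are *frozen random projections* (random
graph features); the trainable parameters are the linear readouts that
produce the latent Gaussian (mean and log-variance), the linear action head
that scores construction steps, and a linear atom-type head. Gradients of
these linear layers are exact and are optimized with Adam. This keeps
training deterministic, fast and dependency-free while retaining the
architecture's contract: encoder and decoder see the molecular graph only
through message passing, and the decoder is conditioned on the active's
embedding concatenated with a latent sample (the posterior of the target
molecule during training; standard-normal noise at generation). Defaults —
latent dimension 8, hidden dimension 16, two message-passing steps, KL
weight 1 with linear warm-up over the first half of training — are
desk-scale choices; none of these sizes is claimed to reproduce the
reference model.

### The reweighted action loss

The action term of the reconstruction loss is not the plain cross-entropy
but

$$L = -\bar f \, \log\!\left(\frac{p(x_j)\, f(x_j)}{\sum_i p(x_i)\, f(x_i)}\right),$$

where the sum runs over permitted actions, $f(x_i)$ is the reciprocal
training-set frequency of the local subgraph action $x_i$ would create, and
$\bar f$ is the mean of $f$ over permitted actions. With all $f$ equal the
expression reduces algebraically to $-\log p(x_j)$; the test suite asserts
this identity numerically over 10^4 random distributions. The effect of
non-uniform $f$ is to penalize actions that would introduce rare subgraphs.

Two design choices were open here:

* **Extent of the "induced subgraph".** We use the radius-1 environment of
  the newly created bond: the bond order plus both endpoints' element,
  charge and incident-order multiset. This keeps the table small and the
  generation-time lookup exact.
* **Which graphs to count.** `build_frequency_table` counts bond
  environments in complete molecules (the documented operation contract).
  The *model's* table is built by `assembly_frequency_table`, which counts
  each bond's environment *at the moment of its creation* during the
  canonical breadth-first reconstruction of every training molecule. The
  decoder only ever sees partial graphs, so counting assembly-time
  environments makes the lookup keys at generation time identical to the
  keys that were counted — otherwise nearly every action would look
  "unseen" and the reweighting would collapse to a constant penalty.
* **The stop action.** Finishing an atom creates no subgraph. Giving stop a
  fixed small $f$ systematically biases generation toward premature
  termination, because at the optimum the sampling distribution is
  proportional to the data distribution times the subgraph frequency. Stop
  therefore takes the geometric mean of the competing bond actions' $f$,
  which is scale-neutral: the reweighting redistributes probability among
  bond actions only. Unseen keys get add-one smoothing so $f$ is always
  finite.

## Selection of the final decoy set

For each active, `n` candidates are generated (1000 in the benchmark
protocol), deduplicated by canonical form, and filtered by heavy-atom-count
difference and doppelganger score with an iterative relaxation: thresholds
start at a heavy-atom difference of 0 and doppelganger <= 0.25, and are
relaxed alternately (+1 atom, +0.05 doppelganger) until at least 100
candidates survive. The printed protocol states only the stopping rule; the
starting point and step sizes are this package's choice, and the full
relaxation trace is returned with every run so it can be audited or
overridden. Final decoys are the candidates with the smallest sum of
normalized property difference and LADS score, ties broken by canonical
SMILES so selection is deterministic and order-invariant.

The LADS (latent actives in decoy set) penalty is implemented as the mean,
over the decoy's functional-fingerprint bits, of the fraction of actives
containing that bit; it is 0 for a decoy sharing no environment with any
active and maximal for a decoy identical to an active. The defining
publication of the score describes a weighted occurrence of active-derived
fingerprint environments; this package's exact formula is the one above,
validated against a hand-computed toy case in the tests.

## Bias metrics

* **DOE score.** For each active, all other actives (positives) and all of
  the target's decoys pooled (negatives) are ranked by ascending Euclidean
  distance in z-scored property space; tied distances are interpolated
  linearly (a diagonal segment). The per-active score is the exact integral
  of |ROC − diagonal| over false-positive rate (trapezoids, with segments
  split at diagonal crossings), and the DOE score is the mean over actives.
  This construction is the unique reading under which the two printed limits
  hold exactly: 0 for property-identical populations and 0.5 for complete
  separation — both asserted analytically in the tests, alongside
  equivalence with a brute-force enumeration oracle to 1e-10 on over a
  hundred random instances. Distances are rounded to nine significant
  digits before ranking so that mathematically tied distances are not
  separated by floating-point noise.
* **Doppelganger score.** Per decoy, the maximum functional-fingerprint
  (FCFP6-like: radius 3 over donor/acceptor/aromatic/halogen/basic/acidic
  atom roles, folded to 1024 bits) Tanimoto similarity to any active; the
  mean and maximum over decoys are reported.
* **AVE.** The asymmetric validation embedding bias
  $(H_{VA \to TA} - H_{VA \to TD}) + (H_{VD \to TD} - H_{VD \to TA})$, where
  $H$ is the threshold-averaged nearest-neighbor hit rate between a
  validation class and a training class, averaged over cross-validation
  folds. The threshold grid is uniform with 50 points from 0 to the maximum
  pairwise normalized distance of the target set (the grid density is a
  documented, configurable default).
* **ML separability.** 1-nearest-neighbor and random-forest classifiers
  trained on every non-empty subset of the properties (2^k − 1 subsets)
  under stratified cross-validation, scored by ROC AUC. The 1NN score is
  continuous (distance to nearest decoy minus distance to nearest active),
  which yields a proper ROC; the forest is fixed at 100 trees with recorded
  seeds. On permuted labels the mean AUC is 0.5 within Monte-Carlo
  tolerance (asserted over 20 seeds).

The normalization population is stated per context: the training library
for pair building; the target's actives together with the candidate decoys
for selection; the target's actives plus decoys for all assessment metrics.
Zero-variance properties are flagged and their scale clamped to 1.

## Property registries

Three registries are built in: `dude6` (MW, logP, rotatable bonds, H-bond
donors, H-bond acceptors, net charge), `dekois8` (MW, logP, HBD, HBA,
rotatable bonds, positive and negative charge counts, aromatic ring count)
and `extended27`, a 27-descriptor superset including the synthetic
accessibility score. The authoritative high-dimensional descriptor list of
the reference work is not public, so `extended27` is an explicit,
user-overridable default built from common topological and physicochemical
descriptors; nothing downstream depends on its exact membership. logP is an
atom-contribution method (a reduced Wildman–Crippen typing, recorded in
report metadata as `wildman_crippen_reduced_v1`); formal charge is read
from the structure as drawn — no pKa model. The synthetic accessibility
score combines circular-fragment frequencies against a bundled reference of
224 curated drug-like and common small-molecule structures with penalties
for size, ring fusion, spiro atoms and macrocycles, mapped to [1, 10]
(1 = easy to make). Its reference population is deliberately compact; the
score is calibrated for ordering and range, not for agreement with any
external implementation's absolute values.

## Chemistry model and its limits

Molecules are heavy-atom graphs with implicit hydrogens, formal charges and
an explicit aromatic bond class perceived at parse time. The default atom
vocabulary is C, N, O, F, S, Cl, Br, I with standard valences and common
charged variants; rarer elements (e.g. phosphorus) are admitted by passing
an extended vocabulary. Stereochemistry, tautomers, protonation-state
enumeration and 3D conformers are out of scope. Aromaticity perception on
kekulized input covers 5- and 6-membered rings of C/N/O/S with a
six-electron count (benzene-, pyridine-, pyrrole-, furan-, thiophene-like
systems and their fusions); it is not a full Hückel treatment. Canonical
SMILES are produced by partition refinement with individualization on
residual ties, so isomorphic graphs always yield identical strings — the
property that deduplication and tie-breaking rely on.

## What the fixtures do and do not show

The fixture generator assembles random valence-respecting molecules (tree
growth plus ring closures) and synthetic property populations with a
controllable class separation (the offset is spread over all property axes
so that it survives per-column z-scoring; `separation = 0` is one common
distribution, large separations give disjoint clusters). Fixture molecules
have realistic composition and descriptor diversity but no bioactivity;
passing tests demonstrate the correctness of the algorithms and the
qualitative behavior of the pipeline (e.g. final-set DOE decreasing in the
number of candidates per active), not screening performance on real
targets. Problem sizes in the test suite — an 80-molecule training library,
candidate counts up to 1000 per active, 10^4 validity checks — are the
package's desk-scale study conditions.

## Numerical and degenerate-input choices

* Seeds: every stochastic entry point takes a seed; a global seed fans out
  to per-stage seeds through a fixed string-labelled hash. Scoped seeding
  restores the caller's RNG state.
* Degenerate normalization (constant property): scale clamped to 1 with a
  warning; DOE on fully constant populations is 0 by the tie rule.
* Two empty fingerprints: Tanimoto defined as 0 with a warning.
* Decoder dead ends cannot occur (stop is always permitted); decode
  failures from other causes are counted and reported, never silently
  dropped.
* `p(x_j) = 0` in the reweighted loss is clamped to machine epsilon with a
  warning.
* Training divergence (non-finite loss) aborts with the last finite-loss
  parameters.

## Known limitations

The published pair counts for the full-scale libraries are not reproducible
from the printed description (they depend on an unstated pair-multiplicity
rule and normalization population); the pair builder exposes a
`max_pairs_per_molecule` cap, default unlimited, pruned by smallest
property distance. Full-scale benchmark replication (hundred-target
datasets, GPU-scale training) is outside this package's scope; the metric
suite, however, applies unchanged to any externally supplied actives and
decoys files.
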