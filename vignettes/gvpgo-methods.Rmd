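---
title: "Predicting protein function from predicted structures: models and methods"
author: "gvpgo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein function from predicted structures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most proteins will never have experimentally determined functions, while
predicted tertiary structures are now available for essentially every
known sequence.  `gvpgo` implements a structure-based multi-label
classifier that assigns Gene Ontology (GO) terms to a protein given (i) an
AlphaFold-style backbone model with per-residue pLDDT confidences stored
in the B-factor column and (ii) a per-residue sequence-embedding matrix
from a protein language model (consumed as a pluggable input; a
deterministic stub generator stands in during testing).  Around the
predictor the package provides the full experimental apparatus: GO-DAG
machinery, CAFA-style protein- and term-centric evaluation, Naive and
BLAST-transfer baselines, and a synthetic-data module that makes every
component testable without downloads.

## Geometric featurization

From backbone N, C-alpha and C atoms we derive:

* a k-nearest-neighbour graph on C-alpha atoms (default k = 30,
  configurable; the value is a graph-connectivity choice, not a physical
  constant) with Euclidean edge distances, encoded for the model by 16
  Gaussian radial basis functions spanning 0–20 Å;
* unit **edge vectors** from source to destination C-alpha;
* **orientation vectors** to the same backbone atom of the preceding and
  following residue, for all three atom types (undefined at termini,
  flagged);
* **side-chain vectors**: the unit N→CA and CA→C bond directions;
* backbone **dihedrals** phi/psi/omega, encoded as (sin, cos) pairs to
  avoid the wrap-around discontinuity at ±180°;
* canonical per-residue local frames (Gram–Schmidt on CA→C and CA→N),
  available for downstream use and tested for properness (det = +1).

Distances, torsions and vector norms are invariant under rigid motions;
the vector features are equivariant.  Because everything that ultimately
reaches the transformer stack is scalar, predictions are invariant under
rotation and translation of the input model by construction — the test
suite verifies this to 1e-4 and observes agreement at machine precision.

**Confidence masking.** Residues with pLDDT below 0.9 (the published
threshold; pLDDT is normalized from the file's 0–100 scale to 0–1 on
read) have their geometry masked: torsions and orientation/side-chain
vectors touching them are zeroed with defined-flags false, and they are
excluded from the kNN graph entirely.  Their amino-acid token, pLDDT
value and sequence embedding are retained, so the model still sees the
residue and its (low) confidence.  Masking low-confidence residues out of
the graph, rather than only zeroing coordinates, avoids creating spurious
short edges at the arbitrary origin.

## The geometric vector perceptron

A GVP layer operates jointly on scalar channels $S_n$ and vector channels
$V_v \in \mathbb{R}^{v\times3}$:

$$V_h = W_h V_v,\quad S_h = \lVert V_h\rVert_2,\quad
S_m = W_m\,[S_h; S_n] + b,\quad V_\mu = W_\mu V_h,$$
$$v_\mu = \lVert V_\mu\rVert_2,\quad
V' = \sigma^+(v_\mu)\odot V_\mu,\quad S' = \sigma(S_m),$$

with $h = \max(v, n)$.  The vector-path maps mix channels only (never the
three spatial coordinates) and carry no bias — this is exactly what makes
$V'$ rotation-equivariant and $S'$ invariant, a property the tests check
over 100 random rotations at 1e-6.  We take $\sigma$ = ReLU and
$\sigma^+$ = logistic gate, the standard choices for this layer family
(configurable); the scalar path's affine map carries a bias, which is
safe for equivariance.  Norms are computed as
$\sqrt{x^2+y^2+z^2+\varepsilon}$ with $\varepsilon = 10^{-8}$ so
gradients stay finite at zero vectors; the same floor keeps the row-wise
gating differentiable.

**Message passing.**  The encoder first embeds node features (dihedral
sin/cos, pLDDT, sequence embedding as scalars; orientation and side-chain
vectors as 8 vector channels) with one GVP, then applies two
message-passing blocks (the published depth).  A message for edge
$j\to i$ is a GVP applied to the concatenation of both endpoint states
with the edge's RBF-encoded distance (scalar) and unit edge vector
(vector channel); messages are mean-aggregated, added residually, and the
scalar channels are layer-normalized (vector channels receive no
normalization, which would break equivariance).  A second per-node GVP
with residual completes each block.  Hidden widths default to 128 scalar
channels (anchored by the published embedding width) and 16 vector
channels (our choice, configurable).

## Encoder, GO-query decoder, loss

The per-residue embedding entering the transformer is the element-wise
**sum** of five 128-dimensional streams: amino-acid token embedding, the
scalarized GVP output (scalar channels plus vector-channel norms, linearly
projected), dihedral sin/cos, the sequence embedding, and pLDDT (embedded
by a linear map of the scalar; the choice of a linear rather than binned
embedding is ours).  Summation rather than concatenation keeps all
streams in one space; the alternative is configurable at the code level
but summation is the default reading of the published description.

The encoder applies standard bidirectional multi-head self-attention
layers (default 4; the published tuning is not recoverable, so the count
is small and configurable).  The decoder receives one learned query
embedding per candidate GO term: each layer runs self-attention over the
query set (letting the model learn term co-occurrence), cross-attention
with keys/values from the residue context, and a feed-forward block — all
without attention masks, since a label set is unordered (hence also no
positional encoding on queries; permuting the query table permutes the
outputs identically, which is tested).  A shared linear head plus
logistic map yields one confidence per term.

Training minimizes the weighted binary cross-entropy
$-\frac1T\sum_f [\,3.0\,y_f\log p_f + (1-y_f)\log(1-p_f)\,]$ (positive
weight 3.0 per the published recipe, compensating the sparsity of
positive labels), with Adam (published defaults: learning rate 1e-4,
batch size 8, eight attention heads), gradient accumulation over the
batch, global-norm clipping at 1.0, early stopping on validation loss
with patience 5, and checkpointing of the best epoch.  The loss is
computed from logits via softplus for numerical stability; the
user-facing probability form clamps at 1e-7 with a warning.  All layers'
backward passes are hand-derived and validated against central finite
differences at 1e-4 on the full model.

## GO machinery and evaluation

The OBO reader supports the subset the ontology actually uses (`is_a`,
`relationship: part_of`, `alt_id`, `is_obsolete`); both edge types
propagate, following CAFA convention.  Annotations propagate by ancestor
union; prediction scores propagate by descendant maximum.  Information
content is $IC(f) = -\log_{10}(\mathrm{Occur}_f/\mathrm{Occur}_{all})$
where $\mathrm{Occur}_f$ counts distinct proteins annotated with $f$
*after propagation* (which automatically subsumes descendant
occurrences, and avoids double-counting a protein annotated with two
descendants) and $\mathrm{Occur}_{all}$ counts propagated
(protein, term) pairs.  Candidate terms are those annotated to at least
50 training proteins (configurable; the synthetic experiments use 10, in
proportion to their corpus).

Protein-centric metrics follow the CAFA definitions: precision at
threshold $t$ is averaged over the $m(t)$ proteins with at least one
prediction at $t$; recall and the Smin components are averaged over all
$n$ evaluated proteins.  Where the published misinformation formula
prints summation limit $m$ over a divisor $n$, we follow the
full-evaluation reading (average over all $n$).  Namespace roots are
excluded everywhere; namespaces never mix; proteins with no truth terms
in a namespace are excluded from that namespace's $n$.  The threshold
grid is 0.01–1.00 in steps of 0.01, with an exact mode sweeping every
distinct confidence (used by the oracle-equivalence tests, which compare
against independently coded exhaustive-threshold and pairwise-comparison
oracles at 1e-9).  Term-centric AUROC is rank-based with half credit for
ties — which is why the Naive baseline, whose scores are identical for
every protein, scores exactly 0.5.

## The synthetic generator: what it emulates, and what not

Backbones are built by sequential internal-coordinate (NeRF) atom
placement from ideal bond lengths (N–CA 1.458 Å, CA–C 1.525 Å, C–N
1.329 Å) and angles, so requested torsions are reproduced exactly —
geometry tests are analytic rather than approximate.  pLDDT profiles are
high-confidence (0.91–0.99) with, in 30% of proteins, one low-confidence
segment (20% of residues at 0.55–0.85), mimicking the disordered-segment
signature of real AlphaFold models.

The planted rule labels each protein by backbone **chirality**
(right-handed helix, phi/psi = −57/−47, versus its mirror image) plus a
sequence motif (`CWC`, present with probability 0.5) mapped to a second
ontology branch.  Chirality was chosen deliberately: mirror-image
backbones have identical pairwise distances and identical norms of every
vector feature, so the torsion sign is the *only* channel carrying the
class — making the permutation-importance control interpretable.  With a
conformational rule like helix-versus-sheet, distances, orientations and
torsions are all mutually redundant, and permuting any single feature
need not degrade an ensemble that can fall back on the others (the
published importance analysis shows exactly this pattern of small
deltas).  Permutation importance here shuffles a feature across all
residues pooled over the evaluation set — the standard recipe; shuffling
within a protein would be a no-op for conformationally uniform chains.

The pairwise identity table scores motif-sharing pairs as near-homologs
(0.85–0.98) against a 0.20–0.45 background, so the identity
decontamination filter has signal.  The stub sequence embeddings are
deterministic functions of (residue identity, position, seed), hence
residue-type-informative by construction.

What passing these tests shows: the architecture trains, is exactly
equivariant, and can extract a geometric signal that no scalar shortcut
leaks.  What it does not show: performance on real proteomes — real
structures have irregular geometry, real GO corpora are far larger and
power-law distributed, and real language-model embeddings carry
evolutionary signal the stub lacks.

## Problem sizes and numerical choices

The learnability experiment trains a reduced model (d_model 64, 4 heads,
2 GVP blocks with 32/4 channels, 1 encoder + 1 decoder layer, k = 8,
learning rate 1e-3 — scaled to the small corpus) on 200 noiseless
proteins of length 20–32 (80/10/10 split) for up to 30 epochs; it
reaches validation Fmax 1.0 on the chirality ontology, and permuting
dihedrals degrades Fmax by ≈0.18 while permuting pLDDT changes nothing.
Metric oracles run on 50 seeded random instances; equivariance suites on
100 seeded rotations; propagation laws on 1000 random DAGs.

Other numerical details: layer normalization uses eps 1e-5; kNN ties
break by residue order (note that ideal-geometry backbones contain exact
distance ties, so equivariance tests jitter coordinates by 0.02 Å);
torsions of collinear atom quadruples are flagged undefined rather than
NaN; a single-residue chain featurizes with empty graph and zeroed
geometry (with a warning); an all-masked protein is an error ("no
confident residues"); training aborts with a diagnostic on non-finite
loss.  Determinism: every stochastic step (initialization, shuffling,
permutation) derives its seed from the configuration seed; two runs with
the same seed reproduce loss histories to 1e-6.

## Limitations

The package trains on CPU-scale problems only; the full-scale recipe
(tens of thousands of proteins, thousands of candidate terms) would need
the same code on accelerated hardware.  Fragmented AlphaFold entries are
treated as one-file-one-protein; multi-chain complexes, side-chain
torsions and solvent accessibility are out of scope, as are weighted-Fmax
and normalized-Smin evaluation variants.
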