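---
title: "Scoring protein-protein docking models with an equivariant GVP-GNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-protein docking models with an equivariant GVP-GNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grank)
```

## The problem

Computational docking produces hundreds to thousands of candidate structures
("decoys") for a protein-protein complex; only a handful resemble the true
(native) assembly. A scoring function must rank the near-native decoys above
the wrong ones. grank implements such a scorer: an atom-level graph neural
network built from geometric vector perceptrons (GVPs) that regresses the
fraction of native contacts, f-nat, of each decoy and ranks decoys per
complex by the predicted value.

## Model

**Input graph.** The decoy is reduced to its interface: the atoms having at
least one atom of the partner chain within 8.5 Å. Only the five elements
C, N, O, S, H are modeled. Nodes are atoms; directed edges connect every
ordered pair of atoms within 4.5 Å (intra- and inter-chain alike). Node
scalars are the one-hot element; each edge carries a 16-component Gaussian
radial-basis encoding of its length (centers evenly spaced on [0, 4.5] Å,
width equal to the spacing) and the unit vector from source to target.

**Network.** Node and edge features are lifted by one GVP each into
(scalar, vector) tuples, then processed by a stack of blocks, each a graph
propagation layer followed by a point-wise feed-forward layer:

- propagation: the message on edge $j \to i$ is
  $m_{j\to i} = \phi(\mathrm{concat}(h_{V_j}, h_{E_{j\to i}}))$ with $\phi$
  three chained GVPs; the node update is
  $h_{V_i} \leftarrow \mathrm{LayerNorm}\!\left(h_{V_i} +
  \tfrac{1}{k'}\,\mathrm{Dropout}\!\left(\sum_{j\in N(i)} m_{j\to i}\right)\right)$
  where $k' = |N(i)|$; a node with no neighbours skips the aggregation term;
- feed-forward:
  $h_{V_i} \leftarrow \mathrm{LayerNorm}(h_{V_i} + \mathrm{Dropout}(\phi(h_{V_i})))$
  with $\phi$ two chained GVPs.

After the blocks, a final GVP reduces every node to scalars, a mean pool
averages nodes within each graph, and two dense layers produce one score.

**GVP form.** Each GVP mixes vector channels linearly ($V_h = W_h V$), feeds
the channel norms into the scalar path
($s' = \sigma(W_s s + W_n\,\mathrm{rownorm}(V_h) + b)$, $\sigma$ = ReLU on
hidden layers), and emits vectors by a second linear mix gated per channel by
a sigmoid of a linear map of the pre-activation scalars (the vector-gated
form). Because scalars only ever see vector *norms* and vector operations are
channel-wise linear, scalar outputs are invariant and vector outputs
equivariant under any orthogonal transform — including reflections — so the
final score is invariant under all rigid motions of the input coordinates.
The LayerNorm normalizes the scalar channel per node (without learned affine
parameters) and scales the vector channel by the root-mean-square of its
norms; dropout removes whole 3-vectors. Both choices preserve equivariance
exactly; the non-affine norm also keeps the hand-derived backward pass simple.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| interface cutoff | 8.5 Å | atom joins the graph if within this of the partner chain |
| edge cutoff | 4.5 Å | atoms closer than this are connected |
| n_rbf | 16 | radial basis functions per edge |
| node dims | (100, 16) | scalar / vector channels per node (reference architecture) |
| edge dims | (32, 1) | scalar / vector channels per edge |
| blocks | 5 | GVPConv repetitions (reference architecture) |
| dropout | 0.1 | rate inside the block updates |
| batch size | 64 | decoys per optimizer step |
| learning rate | 1e-4 | Adam step size |
| epochs | 50 | passes over the training decoys |

Training minimizes the mean squared error against f-nat with Adam (canonical
moment parameters, no weight decay, no schedule, no clipping), reshuffling
examples each epoch with a fold-and-epoch-derived seed, and retains the
parameters of the epoch with the lowest validation loss. Fold models are
ensembled by averaging their scores.

The final dense layer is initialized at zero. This standard regression-head
initialization matters at small step budgets: with a few hundred optimizer
steps at learning rate 1e-4, a randomly initialized output layer spends most
of the budget correcting its random output scale, whereas the zero-initialized
head puts every step into shaping the readout.

## Quality labels

Ground truth against the native structure follows the CAPRI conventions:

- **f-nat**: fraction of native cross-chain residue contacts (any heavy-atom
  pair within 5 Å) reproduced by the decoy; hydrogens are graph nodes but
  never enter labeling.
- **lRMSD**: superpose decoy on native by the receptor backbone (N, CA, C, O)
  with the Kabsch algorithm, then measure RMSD over the ligand backbone.
- **iRMSD**: optimal backbone RMSD over the native interface residues (any
  heavy atom within 10 Å of the partner chain).
- **CAPRI class**: high / medium / acceptable / incorrect from the standard
  threshold table (high: f-nat ≥ 0.5 and lRMSD ≤ 1 or iRMSD ≤ 1; medium:
  f-nat ≥ 0.3 and lRMSD ≤ 5 or iRMSD ≤ 2; acceptable: f-nat ≥ 0.1 and
  lRMSD ≤ 10 or iRMSD ≤ 4); the table is overridable.
- **binary near-native label**: f-nat ≥ 0.3, the boundary counting as
  positive (the convention at exactly 0.3 is fixed here for determinism).

The Kabsch superposition uses SVD with a determinant correction so only
proper rotations are returned; the correction also resolves degenerate
(collinear or coplanar) point sets deterministically.

Interface membership for featurization is atom-level (exactly the atoms in a
cross-chain pair within 8.5 Å), not whole residues; decoys whose contact set
is empty cannot be scored and are excluded, with the count reported in the
run manifest.

## Ranking metrics

All assessment is per complex, never pooled: ROC-AUC (computed by midrank
concordance, ties counting one half), PR-AUC (threshold sweep over distinct
scores with step-wise interpolation — precision held constant between recall
points), the hit-rate curve `hit_rate(k) = N_hits(k) / N_pos`, and the
success rate (fraction of complexes with ≥ 1 positive in the top k).
Complexes without a single positive are left out of assessment. Distribution
summaries report the median and the 25/75% quantiles with linear
interpolation between order statistics. Ranking ties are broken
lexicographically by model id, but the AUCs are tie-order independent.

## The synthetic benchmark

The generator stands in for a docking benchmark so every stage is exercisable
without downloads. Each native complex is a pair of gently curved coarse
backbones (3.8 Å residue spacing, N/CA/C/O plus one side-chain pseudo-atom
with elements drawn as C 0.6, N 0.15, O 0.2, S 0.05, one amide hydrogen).
The two chains face each other and are slid to van-der-Waals contact
(closest heavy-atom pair at ~3.2 Å), which yields 15-25 native residue
contacts for the default 8 residues per chain — dense enough that f-nat
varies almost continuously over decoys. Decoys perturb the ligand chain
rigidly: rotation about its centroid (random axis) and translation (random
direction), with magnitudes drawn from a severity-ordered grid of
translations {0, 0.5, 1, 2, 4, 8, 16} Å crossed with rotations
{0, 5, 15, 45}°. Labels are computed by the labeling machinery, never assumed
from the construction.

What the generator does *not* emulate: side-chain chemistry and packing,
internal (non-rigid) deformation, hydrogen-bond geometry, the size of real
interfaces (hundreds to thousands of atoms), and docking-energetics-driven
decoy distributions (real decoy sets cluster near energy minima; the grid
here is uniform by design). Tests passing on this benchmark therefore
demonstrate that the machinery is correct and that the network can recover a
planted geometry-quality signal at small scale — not that the learned weights
transfer to real docking data.

## Problem sizes and numerical choices

The packaged experiments run on one CPU: the default benchmark is 40
complexes × 20 decoys (≈ 96 atoms per complex, ≈ 1200 directed edges per
interface graph), trained with the reduced configuration — node dims (32, 4),
edge dims (16, 1), 2 blocks, a 1024-wide dense head — for 30 epochs, which
the training module supports alongside the full 5-block reference
architecture. The wide head is the one place the desk-scale configuration is
*larger* than the reference: at a few hundred optimizer steps, a wide
zero-initialized head behaves like kernel regression on the pooled features
and converges within the step budget, whereas a narrow random head does not;
its extra cost is negligible next to the graph convolutions. Evaluation of
the held-out complexes uses the median per-complex Spearman correlation
between score and f-nat.

Numerical details fixed for reproducibility: LayerNorm epsilon 1e-6; the
norm gradient is guarded at exactly zero vectors; RBF centers include both
interval endpoints; the edge unit vector points from message source to
target; Adam bias correction is applied from step 1; all random draws
(initialization, shuffling, dropout, decoy transforms) derive from one user
seed through a fixed integer hash, and R's global RNG state is restored after
every seeded operation so library calls do not perturb user code.

## Known limitations

- CPU-scale only; no GPU path and no attempt to reproduce externally trained
  weights.
- Two-chain complexes only; model/native residue numbering must agree
  (labeling errors out on mismatch rather than aligning sequences).
- The published CAPRI table has wedge conditions beyond the reconstruction
  used here in rare corner cases; the table is config-overridable.
- The gated-GVP inner form is one of two published variants; the
  equivariance contracts hold for both, and the choice is fixed here.
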