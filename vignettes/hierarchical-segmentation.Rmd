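---
title: "Hierarchical segmentation with a conditional softmax over label trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical segmentation with a conditional softmax over label trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salt)
```

## The model

Multi-organ segmentation labels are naturally hierarchical: the body
contains the thoracic cavity, the thoracic cavity contains the lungs and the
mediastinum, the mediastinum contains the pericardium, and so on. A
conventional softmax head treats the `N` classes as unrelated, so nothing
stops a network from marking a voxel as "heart" outside the pericardium.
This package instead represents the classes as a rooted tree in which every
class has exactly one parent, and replaces the softmax with a *conditional*
softmax over that tree.

For a node $n$ with siblings $S(n)$ (the children of its parent), the
network's raw score $s_n$ is normalized only within the sibling group:

$$ q_n = \frac{e^{s_n}}{\sum_{m \in S(n)} e^{s_m}}, $$

and the unconditional probability of $n$ is the product of conditionals
along its root path $A(n)$ (ancestors and $n$ itself):

$$ p_n = \prod_{a \in A(n)} q_a, \qquad q_{\text{root}} = 1 .$$

Three structural consequences follow, and all three are enforced exactly
and verified in the tests:

* the children of every node partition its probability mass
  ($\sum_{c} p_c = p_{\text{parent}}$, leaves sum to 1);
* a child can never exceed its parent ($p_c \le p_{\text{parent}}$), so no
  voxel is "heart" without also being "pericardium";
* on a flat tree (root plus leaves) the whole construction collapses to the
  ordinary softmax, bit-for-bit.

The known cost of the construction is *vanishing probabilities*: a chain of
$d$ maximally uncertain binary decisions leaves the deepest node with
probability $2^{-d}$. This is a property, not a bug — the package exposes it
as a closed-form check — but it means very deep or very unbalanced trees
trade per-leaf confidence for structural consistency.

### Matrix and bitwise representations

Everything above is driven by three `N × N` matrices (`treeMatrices()`):
adjacency (parent→child edges), reachability (ancestor-or-self; the
reflexive transitive closure of adjacency), and the sibling matrix. Chaining
is evaluated in log space as one sparse matrix product,
$\log p = (\log q)\,R$, which is immune to underflow for deep trees.

For evaluation, each node additionally receives a fixed-width bit code of
its ancestral path (`encodePaths()`): the bit budget is split into one field
per depth level, wide enough for the largest sibling rank at that level plus
the reserved 0 ("level unoccupied"), and a node's mask is all-ones over the
levels it occupies. Ancestor queries then reduce to one masked comparison,
`(code[n] & mask[a]) == code[a]`, and the prefix property is tested to
reproduce the reachability matrix exactly. Any layout with this prefix
property is equivalent for every consumer in the package; the per-depth
fixed-width fields were chosen because they make the ancestor test a single
masked compare and keep the table at `N × B` bytes.

## Supervision

A voxel labeled with node $t$ supervises its whole path: the target is the
reachability column of $t$ (`encodeTargets()`), which activates $t$ and all
its ancestors. Two loss components consume this encoding:

* **Path cross-entropy** — $-\log p_t$, the sum of sibling-softmax
  cross-entropies along the path. A voxel labeled at an *internal* node
  (mixed-depth or partially curated data) penalizes only the decisions down
  to that node and says nothing about its children.
* **Tree soft Dice** — per non-root node, soft Dice between the probability
  channel and the multi-hot target with additive smoothing
  $\varepsilon = 10^{-5}$; the loss is one minus the mean over included
  nodes.

The hybrid loss is the equally weighted sum (weights 1/1, the common
segmentation practice; both weights are exposed). Voxels outside the
supervision mask contribute nothing — the package guarantees *exactly*
nothing: the loss of a volume annotated on every fifth slice equals the loss
of the retained slices alone, which is how sparse expert annotations are
meant to be consumed.

Two conventions in the Dice term were genuinely open and are worth stating.
A node absent from the target with (numerically inevitable) nonzero
predicted mass would otherwise contribute a near-zero Dice for every voxelwise
irrelevant class; we include a target-absent node only when the prediction
assigns it at least one voxel-equivalent of probability mass, so materially
false-positive nodes are penalized while untouched classes do not dilute
the mean. Second, an empty supervision mask defines the loss as 0 with a
warning rather than `NaN`, so accidental all-background crops do not poison
a training average.

The analytic gradient of the full hybrid loss with respect to the raw
scores is implemented alongside (`saltLossGradient()`) and checked against
central finite differences at $10^{-6}$ tolerance. One subtlety deserves
note for re-implementers: the sibling-sum of reachability indicators equals
the *strict*-ancestor indicator of the parent, not ancestor-or-self — a
sibling group only enters either loss when the target path continues past
its parent.

## Evaluation

`hierarchicalDice()` scores every node with ancestor-or-self membership: a
voxel labeled "L4" counts toward "L4", "lumbar spine" and "spine" alike, so
a prediction that is right about the region but wrong about the sibling
still earns the parent credit. The computation runs entirely in the encoded
space — the volumes are reduced once to a joint label table and per-node
membership is resolved by masked code comparisons — and is tested to be
bit-identical to materializing every node's mask. Nodes absent from both
volumes are reported as not applicable and excluded from means, so empty
classes inflate nothing.

`nsd()` is the normalized surface Dice: the symmetric fraction of boundary
voxels lying within a physical tolerance (default 3 mm) of the other
surface. Boundaries are 6-connected erosion residues; distances are exact
Euclidean distances between voxel centers under anisotropic spacing,
computed by a separable lower-envelope distance transform written in C++
and oracle-checked against brute-force all-pairs distances. Conventions for
degenerate inputs: both surfaces empty scores 1, exactly one empty scores 0.

`bootstrapCI()` is the percentile bootstrap (default 1000 rounds, 2.5/97.5
percentiles) over per-case scores, seed-reproducible. Because the headline
mean of a segmentation study can average over labels, cases, or label×case
pairs, the report keeps per-node rows and lets the caller choose the
aggregation.

## Harmonizing heterogeneous label sets

Forcing several annotation sources into one single-parent tree needs four
operators, all voxel-count conserving:

* `mergeChildren()` — relabel all descendants to a parent (five lung lobes
  → one lung);
* `splitByRegion()` — partition one structure among ordered spatial regions
  with a declared fallback (an aorta crossing mediastinum, pericardium and
  abdomen becomes three single-parent pieces; first matching region wins);
* `completeWithOther()` — append an `"<parent> other"` leaf wherever
  children fail to cover their parent, making every internal node exactly
  the union of its children;
* `fuseAnnotations()` — combine two volumes; the deeper (more specific)
  node wins, depth ties keep the primary source, and the number of
  overridden voxels is reported. The tie rule is a package choice — the
  combination of a sparse curated source with a dense automatic one does
  not dictate one — and is deliberately conservative toward the primary
  source.

The shipped configuration `body_tree_synthetic.yaml` encodes a whole-body
hierarchy with 145 labels excluding the root and 113 leaves, including
per-vertebra and per-rib bone labels, split vessel segments and "other"
completions. The detailed vertebra/rib composition is a synthetic
reconstruction (hence the filename): it is anatomically conventional but
not copied from any dataset's label list.

## Preprocessing

`preprocessVolume()` reorients to Left-Posterior-Inferior, resamples to
1.5 mm isotropic spacing and normalizes Hounsfield units from
$[-1024, 1024]$ to $[0, 1]$ (clip, then scale — the order matters for metal
and air values outside the window). Images interpolate trilinearly; label
maps use nearest-neighbour and therefore can never invent labels. Output
voxel centers are aligned to the first input center, which makes
subdividing resamples exact at original grid points and the whole pipeline
idempotent — an already normalized volume passes through unchanged (the
intensity step detects a $[0,1]$ range and skips itself). `randomCrop()`
draws `192 × 192 × 48` windows (any size at test scale) uniformly over valid
offsets, zero-padding smaller volumes symmetrically with the padding
excluded from supervision.

## Synthetic phantoms and the training demonstration

The phantom generator (`makePhantom()`) renders nested ellipsoids/boxes —
one shape per tree node, child strictly inside parent, sibling leaves
disjoint — and labels each voxel with the deepest containing node, so the
ground truth is hierarchically consistent by construction and every
harmonization and metric oracle is exact on it. The default spec emulates a
thorax on the normalized CT scale: air background 0.02, soft-tissue body
0.52, an air-rich cavity 0.25, an organ 0.57 with a denser core 0.66, and
Gaussian noise of sd 0.02 (≈ 40 HU). These contrasts are CT-plausible;
what the phantom deliberately does *not* model is texture, partial-volume
boundaries, anisotropy artifacts or inter-patient variability — so passing
tests demonstrate the correctness of the machinery, not clinical accuracy.

`trainToySegmenter()` is a two-layer network (3×3×3 convolution into 8
ReLU channels, then 1×1×1 onto the node channels) with the SALT head and
hybrid loss, trained with Adam (lr 0.05) for 200 steps on seeded 32³ crops
of 64³ phantoms. Inputs are standardized by a fixed affine map before the
first convolution. On held-out phantom geometry it reaches a mean leaf Dice
above 0.95 — the point being that gradients flow correctly through the
chained conditional head end to end, at desk scale on one CPU in about a
minute.

## Numerical choices and problem sizes

* Sibling softmax subtracts the per-group maximum; chaining happens in log
  space; probabilities are clamped away from 0 only when logged.
* Greedy top-down decoding is the default (descend into the largest
  conditional until a leaf), which guarantees a hierarchy-consistent path;
  leaf-argmax decoding is available and the two are compared on a measured
  fixture where they disagree on under 5% of voxels. Ties break to the
  lowest node index, deterministically.
* Test and acceptance problem sizes — 100 flat fixtures, trees up to 200
  nodes on 32³ fields, 16³ grids for bit-identity checks, two 64³ training
  phantoms — were chosen so the whole suite runs in minutes on one CPU
  while still exercising every code path at realistic depth.

## Known limitations

* Single-parent trees only: structures that genuinely span several parents
  must be split spatially (the package provides the operator, but choosing
  the regions is modeling work).
* The conditional factorization concentrates uncertainty multiplicatively;
  for very deep trees consider intermediate-level reporting rather than
  leaf-level argmax.
* `hierarchicalDice()` requires both volumes on the same grid and spacing;
  resample first.
* The toy trainer is a demonstration, not a segmentation model; it has no
  downsampling path and will not capture long-range context.
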