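---
title: "Branch-robustness scoring and HDR segmentation: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-robustness scoring and HDR segmentation: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neuroretriever)
```

This vignette is the package's account of the science it implements: the
model and its assumptions, the parameters that matter, what the synthetic
phantoms do and do not emulate, and the choices made where the design was
genuinely open. Everything quantitative stated here is computed by the test
suite or the acceptance script; the vignette adds the reasoning.

## The segmentation model

The pipeline assumes a sparsely labeled fluorescent image: one (or few)
bright tree-shaped neurons over a background whose statistics vary with
imaging depth. Three empirical regularities carry the whole method:

* intensity is higher on proximal fibers than on distal ones, and higher
  on signal than on noise — but with local exceptions ("weak points")
  where a fiber's cross-section dips to near-background intensity;
* the neuron is a tree: almost every signal voxel belongs to a branch
  with either deep descendant structure or substantial length;
* background clutter, even when it touches the neuron at low thresholds,
  is structurally shallow — its connected pieces are short and carry no
  deep branch hierarchy.

Thresholding at a single global intensity therefore cannot work in
general: the threshold that removes clutter also removes the weak points
and severs everything downstream. Instead, the image is thresholded at a
whole sweep of levels; each level is traced into a branch hierarchy by the
codelet tracer; each voxel earns a per-level branch score reflecting the
structural importance of its branch; and the per-level scores are summed
into the branch robustness score (BRS). The super-level set of the BRS at
a cutoff `m` — the HDR mask — then behaves like a spatially adaptive
threshold: bright, structurally important regions are kept even where a
single global threshold would have to choose between them and the noise.

Both sources of evidence combine multiplicatively in the BRS: a voxel's
branch must score at some level (structure), and the voxel must survive
enough levels for the sum to reach `m` (intensity). This is why a weak
point's own voxels — which survive only the lowest levels — can still
enter the mask: at those levels they belong to an upstream branch with
deep descendant structure, which scores heavily.

## The tracer

Tracing operates on a voxel set and a soma seed. The geodesic source
field (path distance from the soma plus one, breadth-first under the
set's connectivity) scaffolds a moving *codelet*: at position `i` it is
the connected voxel set with source-field values in {i−1, i, i+1},
launched at i = 2 so that it initially covers values 1–3. Its
center-of-mass trajectory defines the skeleton; its splitting into
connected components defines branch points. Three behaviors are
deliberately conservative:

* **Branch-point retraction.** The recorded branch point is pulled two
  codelet steps back along the parent centerline, and the gap to each
  child's start point is filled with interpolated central points. The
  split is detected only after the children's codelets separate, i.e.
  downstream of the anatomical junction; retraction compensates.
* **First-claim exclusion.** Voxels claimed by an earlier branch are
  never re-entered. Fluorescent blobs and touching fibers would otherwise
  create cycles that the tree model forbids; first-claim breaks each
  cycle deterministically at the meeting front, at the cost of slightly
  arbitrary territory assignment there. Branch processing order is
  first-in-first-out, so re-tracing the same input is bit-identical.
* **Spur handling.** Codelet components smaller than 2 voxels never spawn
  branches. Thick or bumpy fibers still produce short "armpit" pockets at
  junctions; `prune_spurs()` removes short terminal spurs and merges the
  resulting single-child chains. The scoring sweep prunes at 10 central
  points (half of the default length requirement) before measuring each
  tree: without this, background fuzz touching a fiber fragments its
  trace into sub-threshold pieces and the whole fiber scores zero at
  exactly the level where it matters most (the lowest one). The final
  re-trace of a segmented neuron is pruned the same way for clean SWC
  output.

Length is measured in codelet steps, i.e. source-field levels. On
diagonal fiber runs a step covers up to √3 voxels of arc length, so
step-lengths systematically undercount Euclidean length by up to ~40%.
This is inherent to the level-set definition of the codelet and is the
reason the phantom generator's default segment lengths (30–55 voxels) sit
well above the default length requirement.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `t_step` | 2 (8-bit), 10 (12-bit) | intensity levels | sweep increment |
| `n` | 50 | — | number of sweep levels; width = (n−1)·t_step |
| `b_max` | 10,000 | branches | cap used to raise t1 over percolating background |
| `L0` | 20 | voxels (steps) | branch-length requirement of the score |
| `G0(1)` | data-driven, ≥ 20 | generations | depth requirement at the lowest level |
| `m` | 40 | score points | BRS cutoff of the HDR mask |
| connectivity | 26 | — | voxel neighborhood |

`G0(1)` is the 75th percentile (nearest-rank) of all branches' generation
counts at the lowest level, floored at 20; it decays linearly to 1 at the
top of the sweep (`G0(j) = max(⌈G0(1)(1 − t_j/t_max)⌉, 1)`), with
`N0 = 3 G0` throughout. `t_max` here is the top of the *sweep*, not the
bit-depth maximum: the decay is meant to reach 1 where the sweep ends.

Two parameters deserve scale awareness. `L0 = 20` voxels corresponds to
6.4 µm at the original imaging resolution — small relative to real
terminal branches but half the length of a typical phantom segment in
codelet steps; package examples on 128³ phantoms therefore use `l0 = 10`.
Similarly `m = 40` assumes scores summed over 50 levels with realistic
branch counts; on small phantoms with ~60 branches the appropriate `m`
for fine-detail work is much smaller (the weak-point demonstrations use
`m = 2`), which mirrors the published practice of tuning `m` down from
its default when distal detail matters.

## Numerical choices and degenerate inputs

* **Threshold semantics:** `threshold_volume(v, t)` keeps intensity ≥ t
  and > 0, so t = 0 and t = 1 both select the nonzero support and
  raising t is strictly nested.
* **Mask boundary:** voxels with BRS equal to `m` are kept (the discard
  rule is "BRS below m"); a `strict` flag flips this. `m = 0` yields the
  BRS support rather than the whole volume.
* **Component ordering:** connected components sort by size, ties by the
  (z, y, x)-lexicographically smallest member, making every partition and
  every downstream decision deterministic.
* **Class boundary:** a perfect match (S_Global = 1) is Class I; the
  class intervals are closed on the left.
* **Degenerate principal axes:** for near-equal principal moments
  (relative gap < 1e−6) the axis comparison is done per degenerate block
  via the singular values of the cross-projection, so symmetric objects
  compare to themselves with D_PA = 0 instead of depending on an
  arbitrary eigenvector basis.
* **Empty / tiny inputs:** an all-zero volume yields no soma candidates
  and the pipeline fails in its first stage with a stage-tagged error; a
  soma component smaller than 3 voxels traces to a degenerate one-point
  tree; an empty HDR mask raises an error carrying the BRS histogram as
  a diagnostic.
* **Soma seeding across the sweep:** when a threshold eliminates the soma
  voxel itself, the nearest surviving voxel within 3 voxels seeds that
  level; if none survives, the level contributes zero scores and a
  warning.

## The phantom generator

`generate_phantom()` grows a random binary tree from a soma ball
(radius 5, ≈ 520 voxels), rasterizes it as tubes (radius 1.5) with
per-generation intensity decay (200 × 0.9^generation on 8-bit), and adds
background: per-z-slab Gaussian noise plus sparse bright salt voxels.
Defaults model a *clean* acquisition — sub-percolation background (slab
means 0.2–1.0, sd 0.8) whose surviving voxels at the lowest sweep levels
form scattered specks rather than a connected sponge. Noisier
configurations are explicit choices in the relevant tests. Design points:

* **Weak points** are rendered as a low-intensity thread of skeleton
  voxels bridging an otherwise-erased tube cross-section. A single dim
  voxel inside a radius-1.5 tube would not gate connectivity — the
  surrounding cross-section voxels would carry the connection — so the
  carve-and-bridge construction is what actually reproduces the
  threshold-versus-breakage dilemma at voxel scale.
* **Self-avoidance** keeps an air gap of ~2 voxels between tube surfaces
  of different lineages, because 26-connectivity bridges diagonal gaps up
  to √3: without the gap, unrelated fibers fuse and the ground-truth tree
  is not what any tracer could recover. Lineages that cannot be placed
  after 20 attempts terminate early; single-child chains left by such
  terminations are merged in the ground-truth tree, which is therefore
  always a proper branching tree.
* **Tangled scenes** place a second neuron and translate it until the
  measured adjacency fraction (voxels of one neuron within Chebyshev
  distance 1 of the other) matches the requested overlap; a target of 0
  requires dilated-disjoint placement and raises a generation error when
  the volume cannot accommodate it.

What the phantoms deliberately do not emulate: optics (no point-spread
function, so tubes have hard edges), photobleaching, anisotropic voxel
spacing, and multi-neuron labeling statistics. Consequences for
interpreting green tests: passing on phantoms shows the pipeline's logic
is correct under the method's own assumptions — it does not certify
performance on real stacks, where PSF blur softens exactly the
weak-point/noise contrast the phantoms idealize, and where anisotropic
z-sampling makes 6- vs 26-connectivity a real choice rather than a
default.

## Study sizes used by the checks

The properties are exercised at sizes chosen to keep a full 50-level
sweep at interactive runtimes: ten 128³ clean phantoms (~60 branches
each) for end-to-end Class-I recovery, three 96³ weak-point phantoms for
the strict advantage of HDR masking over an exhaustive single-threshold
sweep, and 100/50/100 randomized cases for the geodesic, scoring and
similarity oracles. A 128³ sweep traces in roughly 5–7 s on one core.

## Known limitations

* Tangled neurons are segmented together (both labels appear in the
  output); splitting them is out of scope, matching the method's own
  reported failure mode.
* Branch counts on traced images exceed ground truth by a few spurs when
  fibers pass within ~2 voxels of each other; pruning recovers the exact
  count in the large majority of seeds but not all.
* The `n`-key quirk of YAML 1.1 means the threshold-count field must be
  quoted (`'n': 25`) in config files.
* Radius estimation, spine detection and any atlas-level processing are
  out of scope; SWC output carries a constant radius of 1.
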