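# neuroretriever

Automatic segmentation of a single fluorescently labeled neuron out of a
noisy 3D image stack, without committing to any single global intensity
threshold.

Sparse labeling techniques (e.g. MARCM in *Drosophila*) produce stacks in
which one bright neuron sits in a background whose noise level varies with
imaging depth, and in which otherwise-bright fibers are interrupted by
low-intensity **weak points**. Any single global threshold then faces a
dilemma: a low threshold keeps the weak points (and the full arbor) but
also keeps attached background clutter, while a high threshold cleans the
background but severs every fiber downstream of a weak point, producing a
"broken" reconstruction. This package implements a segmentation pipeline
that resolves the dilemma with an effectively position-dependent threshold,
plus the quantitative metrics used to validate segmentations and a
deterministic synthetic phantom generator with voxel-level ground truth.
It is aimed at people building single-neuron reconstruction pipelines and
at method developers who need a controlled test bed.

## Method

1. **FAST tracing.** For a voxel set (the image thresholded at *t*) and a
   soma seed, every voxel is coded by its *source field* — geodesic path
   distance from the soma plus 1. A *codelet* at position *i* is the
   connected set of voxels with source-field values {i−1, i, i+1}; it is
   launched at i = 2 and advances one level per step. The trajectory of its
   center of mass gives the branch's central points; when the codelet
   splits into two or more components, the branch ends at a branch point
   (retracted two steps back along the centerline) and each component
   seeds a child branch. The result is a rooted branch hierarchy.

2. **Branch scoring.** For every branch *i* at threshold *t_j*, with
   *G_i* descendant generations, *N_i* descendant branches and length
   *L_i* (in codelet steps), every voxel *k* of the branch scores

        BS_k(j) = max(G_i − G0(j), 0) + ⌊N_i / N0(j)⌋ + ⌊L_i / L0⌋ + λ_i(j)

   where λ_i(j) = max over offspring *p* of ⌊L_p / L0⌋ when
   G_i < G0(j) and N_i < N0(j) (a short upstream branch inherits credit
   for carrying a long downstream fiber), and the eligibility parameters
   decay with the threshold: G0(j) = max(⌈G0(1)·(1 − t_j/t_max)⌉, 1),
   N0(j) = 3·G0(j). G0(1) is the 75th percentile of the generation counts
   at the lowest threshold, floored at 20.

3. **Branch robustness score (BRS).** The image is swept over n = 50
   thresholds (t_step = 2 for 8-bit, 10 for 12-bit data, so the sweep
   spans 98 and 490 intensity levels respectively); each sweep position is
   traced and scored, and per-voxel scores are summed:
   BRS(k) = Σ_j BS_k(j). A voxel scores highly if its branch is
   structurally important *and* it is bright enough to survive many
   thresholds. When background clutter percolates at the lowest
   thresholds, t1 is raised in whole steps until the traced branch count
   is at most B_max = 10,000.

4. **HDR segmentation.** The high-dynamic-range mask keeps voxels with
   BRS ≥ m (default m = 40; smaller m keeps finer detail). Intersecting
   the mask with the nonzero raw image and keeping the soma's connected
   component yields the segmented neuron, which is re-traced for the final
   skeleton (exported as SWC).

5. **Validation metrics.** Two segmentations are compared through four
   normalized structural distances — center-of-mass displacement D_CM,
   radius-of-gyration difference D_RG, normalized principal inertia
   moment distance D_I, principal-axis misalignment D_PA — plus voxel
   recall R and precision P. The global similarity

        S_Global = [(1 − D_RG) + (1 − D_CM) + (1 − D_I) + (1 − D_PA) + R] / 5

   is classed as I (≥ 0.9), II ([0.7, 0.9)) or III (< 0.7). Precision is
   excluded from S_Global by design: automatic segmentations keep real but
   faint structure that human raters trim, which depresses P without
   representing error.

## Worked example

Segment a synthetic 128³ phantom end to end and compare the result with
the generator's ground truth:

```r
library(neuroretriever)

ph   <- generate_phantom(phantom_spec(seed = 42))      # 128^3, 8-bit
soma <- detect_soma(ph$volume)[1, ]                    # (64, 64, 64)
sched <- build_threshold_schedule(ph$volume, soma)
brs  <- accumulate_brs(ph$volume, soma, sched, l0 = 10)
seg  <- segment_neuron(ph$volume, build_hdr_mask(brs, m = 40), soma)
tree <- measure_branches(prune_spurs(trace_skeleton(seg$voxels, seg$soma)))
compare_segmentations(ph$labels[[1]], seg$voxels)
```

which prints:

```
<threshold_schedule> n=50, t_step=2, t in [4, 102] (width 98) [t1 raised by b_max guard]
<brs_field> 128x128x128 volume, max BRS 444, 22676 voxels scored
<segmented_neuron> 22664 voxels, soma (64,64,64), m = 40
<skeleton_tree> 59 branches (29 branch points), soma (64,64,64)
<similarity_report> S_Global = 0.9999 (Class I)
  D_CM=0.0002 D_RG=0.0000 D_I=0.0001 D_PA=0.0000 recall=1.0000 precision=0.9998
```

The guard raised t1 from 2 to 4 because the phantom's depth-varying
background connects into the arbor at t = 2; the sweep then spans
intensities 4–102. All 22,664 segmented voxels but 4 are true neuron
voxels (precision 0.9998) and every ground-truth voxel is recovered
(recall 1), so the comparison lands deep in Class I. `run_pipeline()`
wraps the same steps and writes the segmented TIFF, the SWC skeleton, the
BRS volume and a JSON run report; `inst/cli/nr.R` exposes the pipeline and
its stages (`run`, `simulate`, `trace`, `score`, `segment`, `compare`) as
a command-line tool.

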