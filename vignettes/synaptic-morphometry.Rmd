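---
title: "3D synaptic morphometry with synmorph: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{3D synaptic morphometry with synmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmorph)
```

## The analysis this package implements

Volume electron microscopy (FIB/SEM) of cortical neuropil yields stacks of
aligned serial sections from which every synaptic junction in a ~500 µm³
block can be reconstructed in 3D. A morphometric analysis of such data has
four pillars, and `synmorph` implements all of them as reusable, tested
components:

1. **Type**: each junction is asymmetric (AS, excitatory, prominent
   postsynaptic density) or symmetric (SS, inhibitory, thin PSD). In human
   temporal cortex AS outnumber SS roughly 95:5.
2. **Shape**: the synaptic apposition surface (SAS) — the surface of
   apposition between pre- and postsynaptic membranes — is macular (a
   continuous disk), perforated (one or more holes), horseshoe-shaped (a
   deep boundary indentation) or fragmented (two or more disconnected
   pieces).
3. **Postsynaptic target**: spine head, spine neck, or dendritic shaft,
   with shafts split by whether the target dendrite is spiny or aspiny; a
   spine can only be called a spine if it can be traced to its parent
   dendrite, otherwise the target is *unknown*.
4. **Counting**: junctions are counted inside an unbiased 3D counting
   frame — a rectangular prism with three acceptance and three exclusion
   planes — and count tables are compared with omnibus 2×k Pearson
   chi-square tests, partitioned 2×2 tables, and nonparametric size
   comparisons (Kruskal–Wallis, Mann–Whitney, Kolmogorov–Smirnov).

The real image stacks behind published human studies are not publicly
deposited, so the package ships a **synthetic scene generator** with full
ground truth, plus the published count tables of a human transentorhinal
cortex layer II study (bundled as plain-text count files; see
`reference_counts()`) for an exact table-reproduction mode.

## The synthetic scene generator

`generate_scene()` emulates a neuropil block as a labeled voxel volume on
an anisotropic grid (default 5 × 5 × 20 nm, the usual FIB/SEM resolution:
5 nm/pixel in-plane, 20 nm milling step).

* **Dendritic shafts** are capsule sweeps arranged as a jittered
  quasi-parallel bundle with per-dendrite tilt (up to ~12°). A fully random
  placement of capsules cannot reach realistic volume fractions by
  rejection sampling alone; a jittered bundle can, and local
  quasi-parallelism is a reasonable idealisation of dendritic neuropil at
  the 10 µm scale. Radii are ~300 ± 30 nm.
* **Spines** are spherical heads (default 220–250 nm radius) on thin
  cylindrical necks (80 nm radius, 400 nm length), attached at random
  positions and angles and required to be fully contained in the volume.
* **Junctions** are curved slabs conforming to the host surface: the
  planar source mesh of the junction's shape class is wrapped onto the
  host sphere or cylinder (geodesically for spheres, isometrically for
  cylinders), and the slab is carved into voxels whose centres fall inside
  the radial shell of the configured PSD thickness and the mesh's
  footprint. Voxel-centre carving keeps the voxel count an *unbiased*
  estimator of slab volume at any grid resolution, which the type
  classifier exploits.

Composition defaults are the study conditions of the bundled reference
tables: AS fraction 0.95; target mix per type from the control target
table (e.g. 59.1% of AS on spine heads, 53.6% of SS on spiny shafts);
shape mix per type from the control shape table (83.8% of AS macular);
SAS areas log-normal per shape class with means matched to the published
control means (~88·10³ nm² macular up to ~360·10³ nm² fragmented) and
`sdlog = 0.6`. The log-normal family is an assumption taken from the
right-skew of published SAS area histograms; the distribution is
configurable. Synapse density defaults to 0.5 µm⁻³, the order reported
for this tissue.

Deliberate simplifications, all visible in `scenario_config()`:

* Junction areas are truncated to host capacity (a neck of 80 nm radius
  cannot carry a 300·10³ nm² perforated plate); this mirrors the much
  smaller sizes of real neck synapses but means per-target area
  distributions are not exactly the configured log-normals.
* Placement is staged rejection sampling: a junction that cannot be
  seated at its drawn size within a share of the retry budget is rebuilt
  40% smaller, down to the configured minimum, before the generator gives
  up with a diagnostic. The recorded ground-truth area is always the
  realized mesh area, so measurements stay consistent; the upper tail of
  the drawn size distribution is softly truncated in crowded scenes.
* SAS area parameters depend on shape class only, not on AS/SS type.
* No axons, boutons, vesicles, glia or EM texture — the generator makes
  *label* volumes, not images. Passing tests on these scenes demonstrates
  the correctness of the measurement and classification machinery, not
  robustness to segmentation noise in real micrographs.

PSD thickness encodes type with means of 40 nm (AS) and 15 nm (SS) and a
coefficient of variation of 0.08, keeping better than 3:1 separation —
the geometric correlate of "prominent versus thin" PSDs.

## SAS extraction and metrics

`extract_sas()` approximates the junction's medial surface: voxel centres
are scaled to nm, projected on their principal (PCA) plane, collected
into a fine 2D occupancy raster (pitch = the finest voxel axis) that is
morphologically closed to bridge sampling gaps from slabs thinner than
one voxel, lifted back to the mean offset along the plane normal per
cell, triangulated two triangles per cell, and boundary-smoothed to
remove voxel staircase from the perimeter. This projection-based medial
triangulation is an approximation chosen for robustness on slab-like
junctions; the extraction used by interactive reconstruction software is
not publicly specified, so no equivalence is claimed. On analytic slab
phantoms the extracted area and perimeter are within a few percent
(tested to 5%).

`sas_metrics()` computes, per mesh:

* **area** — summed triangle area (nm²);
* **perimeter** — summed length of *all* boundary loops (nm), so holes add
  perimeter;
* **curvature** — RMS orthogonal deviation of vertices from the
  area-weighted least-squares plane divided by √area. This dimensionless
  ratio is 0 for flat surfaces and grows monotonically as a disk is bent
  (property-tested); published curvature ratios are defined only
  qualitatively, so this is a declared operationalisation;
* **shrinkage correction** — EM processing shrinks tissue; the areal
  shrinkage factor p² (default 0.933, the value obtained by measuring
  tissue area before/after processing) divides areas, and √p² divides
  lengths, returning measurements to pre-processing scale.

`classify_types()` measures mean PSD slab thickness as voxel volume ×
count / SAS area and calls AS at or above a threshold. The default
threshold of 24.5 nm is the *variance-weighted* midpoint of 40 and 15 nm:
the noise of the volume/area estimator scales with √thickness, so equal
misclassification risk sits at (40·σ₁₅ + 15·σ₄₀)/(σ₁₅ + σ₄₀) ≈ 24.5 nm
rather than the arithmetic midpoint.

## Shape classification

`classify_shape()` applies a decision tree that mirrors the field's
taxonomy and is deliberately topological:

1. two or more edge-connected components → **fragmented** (multiplicity
   dominates anything else);
2. else ≥1 interior hole (boundary loops − 1, cross-checked against the
   Euler characteristic V − E + F = 2 − b) → **perforated**;
3. else indentation depth ratio ≥ 0.3 → **horseshoe**;
4. else → **macular**.

The indentation depth ratio flattens the mesh onto its least-squares
plane and measures the maximum inward distance from the outline's convex
hull to the outline, divided by the equivalent radius √(area/π). A circle
or square scores 0; the generator's C-bands score ≈ 0.7. Published work
classified shapes by visual inspection, so no quantitative horseshoe
criterion exists to match; 0.3 is a declared, configurable
operationalisation, far from both the convex (≈0) and C-band (≈0.7)
regimes, and the classifier's sensitivity to it is exercised in the test
suite by sweeping the threshold across a mesh's measured ratio.

Strongly curved meshes (e.g. a large patch wrapped most of the way around
a thin neck) can fold under projection; the classifier then falls back to
a 3D analogue — the isoperimetric quotient P/√A, ≈3.5 for compact disks
versus >5 for deeply indented bands — and flags the call
(`flattened = FALSE`).

## Target assignment

`assign_targets()` picks the postsynaptic object as the non-synapse
object with the largest face-contact area (contacts spanning both head
and neck are adjudicated by largest area, ties by lowest object ID, so
the rule is deterministic). Spine heads must trace head → neck → shaft
through the label adjacency graph; necks must trace neck → shaft; a trace
broken by the volume border yields `unknown`, reproducing the rule that
truncated postsynaptic elements cannot be conclusively identified.
Spininess is assessed *inside the volume only* (a dendrite is spiny iff
at least one neck touches it), so cropping a volume can demote a spiny
shaft to aspiny — the same truncation bias the visual procedure has; the
border-monotonicity test asserts that cropping only ever loses
information (classified → unknown, spiny → aspiny), never the reverse.

## The counting frame

`counting_frame()` is the unbiased brick: acceptance planes at the axis
minima, exclusion planes at the maxima (which three faces accept is a
convention; only the 3 + 3 structure matters). `cf_decision()` counts an
object iff it has a voxel centre in the half-open box [min, max) and no
voxel beyond an exclusion face within that face's cross-axis shadow.
Exclusion planes are **not** extended to infinity — the classical
extended-brick construction is not part of the implemented description —
and this has a known consequence: a convex object straddling *two*
partition planes at a tile corner can be counted twice in a tiling.
Additivity is therefore exact (and tested) for convex objects crossing at
most one partition plane, and the limitation is stated here rather than
patched.

## The contingency battery

`pearson_chi2()` computes X² = Σ(O−E)²/E with E_ij = T_iT_j/T, df =
(r−1)(c−1), no continuity correction; `partition_2x2()` localises an
omnibus 2×k association by testing each retained column against the
pooled rest (the default scheme, which matches the reported per-category
conditional shares, e.g. 99.0% of spine-head synapses being AS in the
control group), after discarding columns whose *observed* minimum count
falls below 5 — the discard rule is keyed to observed counts because that
is how it was applied in the source analysis. A `successive` scheme
(columns 1..j pooled vs column j+1) is available behind the `scheme`
flag for users who prefer orthogonal partitions. No multiple-testing
correction is applied by default (none is applied in the published
analyses this mirrors); `size_comparisons()` offers Bonferroni and Holm
as options, withholds groups below a configurable `min_n` (default 10)
as "not tested" rather than erroring, and otherwise delegates to R's
standard `kruskal.test`, `wilcox.test` (normal approximation with tie
correction) and `ks.test`.

The bundled reference tables reproduce to the printed decimal in 31 of 32
cells; the one exception is a printed-table inconsistency (a macular SS
percentage printed as 92.5 whose own printed count, 110 of 119, gives
92.4), which `reproduce_reference_tables()` surfaces explicitly rather
than hiding:

```{r}
rep <- reproduce_reference_tables()
subset(rep$percentages, !match)
glance(rep)
```

## Problem sizes and numerical choices

* Counting-frame interior tests are half-open per axis, so tiled frames
  share faces without double counting.
* Meshes use 48 angular sectors; a 48-gon underestimates disk perimeter
  by 0.1% and area by 0.3%, well inside the 1% oracle tolerances; areas
  are rescaled to the target exactly.
* Degenerate one/two-voxel junctions extract to a minimal valid square
  patch instead of erroring, and junctions whose thickness cannot be
  measured are flagged `indeterminate` and excluded with a logged count.
* Scenes used in the parameter-recovery tests hold 2000 junctions in a
  10 × 10 × 6 µm volume at 25 × 25 × 50 nm voxels with synapse density
  scaled up accordingly and a denser spine supply (3 µm⁻¹, 60% spiny
  dendrites) so every target class has hosts. Voxel coarsening is a
  problem-size choice: the thickness estimator is resolution-unbiased,
  and shape is classified on the scene's ground-truth-geometry meshes, so
  classification quality does not ride on the grid. Twenty seeded
  replicates are classified per run; each classification dimension's
  goodness-of-fit against the configured mix is required to clear p >
  0.05 in at least 90% of replicates, per dimension (requiring all three
  jointly in every replicate would fail ~14% of the time even with
  perfect classifiers, which is a property of the test, not the
  pipeline).
* All randomness flows through a single seeded generator per scene;
  rerunning a configuration is voxel-identical, and `run_pipeline()`
  manifests carry content hashes of every stage output.

## Known limitations

* The generator's geometry (straight quasi-parallel shafts, spherical
  heads, fixed-shape planar source meshes) is an idealisation; it carries
  class structure and measurement scale, not biological shape diversity.
* Absolute SAS size distributions of real tissue are not reproducible
  from synthetic scenes; size-related claims are covered only by ordering
  properties (e.g. perforated perimeter > macular perimeter at equal
  area).
* `extract_sas()` assumes slab-like junctions; surfaces that curve more
  than ~90° around their host are classified via the flagged 3D fallback.
* The no-extension counting frame double-counts corner-straddling convex
  objects in tilings, as discussed above.
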