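---
title: "Evaluating craniofacial superimposition techniques on synthetic skull phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating craniofacial superimposition techniques on synthetic skull phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serial 3D imaging of the craniofacial skeleton (two CT scans of the same
patient, before and after treatment) lets clinicians measure skeletal change
as the residual distance between superimposed surface models. The measurement
is only as good as the superimposition: the rigid alignment must be anchored
on *form-stable* structures, i.e. regions whose geometry is unchanged by
growth or treatment over the observation interval. `cranioreg` implements and
evaluates five classical choices of registration reference:

* **3P** — three anatomical landmarks (left/right infraorbital points and the
  left mastoid point), aligned by least-squares rigid landmark registration;
* **1Z** — the left zygomatic arch, by region-restricted robust ICP;
* **BZ** — both zygomatic arches;
* **AC** — the anterior cranial base;
* **ACF** — anterior cranial base plus the posterior foramen magnum rim
  (treated as the gold standard).

Because clinical CT pairs of this kind are not publicly shareable, the
package generates *synthetic skull phantoms* with exact ground truth and runs
the entire study design in silico: 8 patients x 5 techniques x 3 operators x
2 sessions, plus a duplicate-model control arm.

## The phantom

The phantom is deliberately stylised, not anatomically meshed. What the
evaluation needs is the reference-structure topology of the clinical workflow: form-stable structures
(a cranial-base shelf with a sella depression, a hollow foramen-magnum ring)
and treatment-altered structures (two slender zygomatic arcs, an anterior
U-shaped maxilla with incisor prongs and a piriform notch). Each structure is
an analytic solid (signed distance function) with its own rigid pose, so
every deformation has exact landmark ground truth.

Two geometric details matter and are intentional:

* the arch tubes have an *undulating radius* and the shelf top carries small
  relief bumps. A perfectly uniform arc can slide along itself and a flat
  plate can slide in its plane without changing the registration cost; real
  anatomy is irregular, and without these features region-restricted ICP
  would be rank-deficient.
* rasterisation uses a *partial-volume ramp*: voxel intensity falls linearly
  from bone (1200 HU) to background across a two-voxel shell around the true
  surface, emulating CT partial-volume averaging. Bone thresholds (300-500
  HU) then cut inside this ramp and linear edge interpolation recovers the
  surface with sub-voxel accuracy (on a 20 mm test sphere the extracted area
  is within 2% of the analytic value, and mean vertex error is ~0.005 mm at
  the mid-ramp threshold). Exact binary rasterisation (`partial_volume =
  FALSE`) is available; it produces the terraced surfaces typical of
  marching cubes on binary masks.

### Treatment and rescan models

Rapid maxillary expansion is modelled piecewise-rigidly: each hemimaxilla
translates laterally by half the total expansion (default 9 mm = 0.6 mm/day
over a 15-day activation; the midline split mirrors the opening of the
midpalatal suture), and each zygomatic arch rotates outward about a vertical
axis through its posterior root. Piecewise-rigid pieces give *exact*
landmark ground truth, which an elastic model would not.

The default arch bend is 2 degrees, i.e. ~1.4 mm of lateral displacement at
the anterior end of the arch. Bone-borne expanders transmit roughly half of
the dental expansion to the zygomatic level and the effect attenuates
superiorly, so a 9 mm expansion plausibly displaces the arches by 1-2 mm.
Larger bends (we examined 3-5 degrees) deform the arches so strongly that
arch-based registration becomes worse than landmark registration, inverting
the clinically reported ordering of the techniques.

The rescan (patient repositioning between scans) is a random rigid transform,
uniform up to 5 degrees and 4 mm, applied to the *analytic solids before
rasterisation*. Resampling voxels would convolve the registration error under
study with interpolation artifacts; re-rasterising does not.

### Operator model

Human operators vary in landmark identification and in how they outline
reference regions. The package models this as isotropic Gaussian jitter on
picked landmarks, re-projected onto the mesh surface, plus a uniform +/-20%
rescaling of each region descriptor's linear extent. The jitter SD is not
identifiable from published data; it is calibrated (SD = 0.6 mm) so that the
three-point technique's duplicate-control deviation lands in the clinically
reported range (median ~0.5 mm). Note that projection onto the surface
discards the normal jitter component, so the effective picking error is
smaller than the nominal SD.

What the generator does *not* emulate: growth, elastic soft-tissue and
sutural deformation, metal artifacts, scanner-specific noise spectra, and
segmentation differences between operators. Passing tests on phantoms
therefore demonstrate correctness of the *pipeline* (registration, metrics,
statistics) under known ground truth, not clinical performance on real CTs.
In particular, on phantoms the anterior cranial base is *exactly*
form-stable, so the AC technique is only marginally worse than ACF, whereas
the clinically reported gap on patients (about fourfold) also reflects biological
variability that the phantom deliberately excludes.

## Surface extraction and registration

Isosurfaces are extracted with a marching-cubes-family algorithm: each cell
is decomposed into six tetrahedra sharing the cell diagonal, with linear
interpolation along tetrahedron edges. The decomposition is table-free and
crack-free; vertices are welded on shared edges, so noiseless convex solids
yield closed, consistently outward-oriented meshes (Euler characteristic 2).
No smoothing is applied. Small disconnected artifact shells are removed by a
connected-component filter (components below 1% of the largest are dropped),
and meshes are decimated to a 100,000-polygon budget by uniform vertex
clustering (geometric drift bounded by the cluster cell diagonal and
reported alongside the result).

Registration proceeds in the study's two stages:

1. **Coarse alignment** on the infraorbital/mastoid landmark triple (the
   Frankfurt-horizontal analog), implemented as a rigid least-squares fit —
   exact for congruent noiseless landmarks.
2. **Robust point-to-plane ICP** restricted to the technique's region
   mask(s): area-weighted surface samples on the moving region, exact
   closest-point correspondences on the fixed region (AABB tree, identical
   to exhaustive scan), rejection of pairs hitting the boundary of the
   fixed region, trimming of the worst 10% of pairs by distance, and a
   linearised point-to-plane solve composed through the exponential map. A
   halving line search keeps the trimmed RMS non-increasing.

Numerical choices: iteration stops when the trimmed RMS changes by less than
1e-8 mm (or falls below `tolerance_mm` x 1e-5, or at 100 iterations). The
0.3 mm `tolerance_mm` default is a precision *ceiling* in the sense of the
emulated workflow; reading it as an absolute stopping RMS would freeze
duplicate-control registrations three orders of magnitude short of their
achievable accuracy. Closest-point ties are broken toward the lowest face
id, making every query deterministic. The default per-registration sample
count in the study pipeline is 4000 (the standalone default is 20000);
at 4000 samples the duplicate-control registrations still converge to
deviations below 1e-4 mm, two orders under the 0.001 mm bound of interest.

## Metrics

* **Accuracy** follows the fiducial-patch rule: three 5 mm^2 circular
  geodesic patches (anterior sella surface, posterior right and left foramen
  rim) are grown on the superimposed model; `D` is the area-weighted mean
  closest-point distance to the reference model per patch, and the accuracy
  statistic is the mean of the three patch values ("divided by three" read
  as the mean; the alternative reading — each patch value divided by three —
  would make the duplicate-control bound trivially easier, and the mean is
  the only reading under which the statistic has mm units of deviation).
  Patch sampling is deterministic (face centroids, edge midpoints and
  vertices, Simpson-style weights), so identical inputs give identical
  records.
* **Per-axis components** `Dx, Dy, Dz` are *signed means* of the
  displacement components (result minus reference closest point), preserving
  the direction of bias; positive means the result surface lies on the
  positive axis side of the reference.
* **Precision** is the displacement of the four measurement landmarks
  (left/right piriform aperture, left/right incisor analogs):
  `transform(landmark_t1) - landmark_t0`.
* **Deviation fields** for colour-mapped export are signed per-vertex
  distances (positive outside the reference surface), clamped to a cap,
  with vertices lacking correspondence within 10 mm flagged missing — the
  10 mm cutoff is the package's reading of the "software was unable to
  compare" grey-zone behaviour, which is described but not quantified in
  the emulated workflow.

## Statistics

The measurement tables feed a distance-based permutational MANOVA for
balanced crossed designs. For the accuracy analysis the model is
technique (fixed, 5) x operator (random, 3) x session (fixed, 2) on
log10-transformed deviations (zeros floored at 1e-4 mm — duplicate controls
produce deviations numerically equal to zero, and 1e-4 mm is an order of
magnitude below anything the pipeline can resolve). With Euclidean distance
on univariate data the partition reproduces classical ANOVA sums of squares
exactly, which is one of the test-suite oracles.

Pseudo-F denominators follow expected-mean-square rules for one random
factor: a fixed source is tested against its interaction with the random
factor when that interaction is in the model, everything containing the
random factor against the residual. These rules reproduce every F ratio in
the emulated study's published accuracy table from its printed SS/MS values.

P-values come from unrestricted permutation of raw data rows (default 9999;
exhaustively enumerated when the sample is small enough that all
permutations fit the budget, making the p-value exact). A Monte Carlo
asymptotic p-value is always reported alongside, computed from a
moment-matched Pearson type III fit to the sampled permutation distribution
— useful when few unique permutations exist. Pairwise a posteriori
comparisons use permutation t-tests with Bonferroni correction; dispersion
homogeneity uses distances to group spatial medians (Weiszfeld) with an
ANOVA F and permutation of the distances. Bland-Altman agreement summaries
report the median difference, IQR and a binomial order-statistic 95% CI of
the median, using mean-of-order-statistics (type 6) quantiles — the
convention of the clinical statistics software this layer mirrors, and the
definition under which the package's worked quantile examples are exact.
Bray-Curtis distance and fourth-root transformation are available as options
sharing the same engine, off by default.

## Problem sizes and determinism

The shipped study defaults — 140 x 140 x 110 voxel phantoms at 0.8 mm,
~100k-face meshes, 4000 ICP samples, 8-patient cohorts, 999-9999
permutations — were chosen so a complete cohort study runs in minutes on a
single CPU while keeping all reported quantities two or more orders of
magnitude away from their acceptance bounds. Every random draw (phantom
noise, rescan transform, operator jitter, ICP sampling, permutations) is
derived from one master seed, and end-to-end runs are bit-reproducible.

## Known limitations

* The phantom's form-stable structures are exactly rigid; real anterior
  cranial bases are only approximately so. Technique differences among
  near-perfect references (ACF vs AC) are therefore smaller here than on
  patients.
* Vertex-clustering decimation does not preserve sharp features as well as
  quadric edge collapse; with the default budget the phantom meshes are
  rarely decimated by more than a factor of ~2.
* The permutational MANOVA engine supports balanced complete crossings
  only, matching the study design; unbalanced data are rejected rather than
  approximated.
* The Monte Carlo p-value is an approximation fitted to the sampled
  permutation distribution; with very few distinct permutations its tail
  behaviour depends on the moment fit.
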