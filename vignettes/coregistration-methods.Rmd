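---
title: "Methods: co-registering micro-ultrasound and MRI with whole-mount pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-registering micro-ultrasound and MRI with whole-mount pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prostacoreg)
```

## The registration model

Micro-ultrasound (microUS) of the prostate is acquired as a rotational
fan sweep: a few hundred 2D frames, each rolled by an angle $\theta_i$
about the probe's long axis, with the first pixel row offset 2 mm from
the transducer edge. Whole-mount (WM) pathology — the ground truth for
lesion boundaries and ISUP grade — consists of axial 4.5 mm sections.
The package maps annotations from native frames to slide coordinates
through three composable transforms:

1. **Geometric placement / reconstruction.** A pixel at depth row $u$
   and along-probe column $v$ of frame $i$ sits at
   $(v s_v,\; r\sin\theta_i,\; r\cos\theta_i)$ with
   $r = u s_u + d$, $d$ the probe offset. Reconstruction populates
   parallel sagittal planes (1 mm spacing) with all samples within
   $\pm$0.5 mm of each plane and averages samples sharing a voxel bin.
   This step is purely geometric; it removes the fan geometry but not
   tissue deformation.
2. **US $\to$ MRI, 3D landmark TPS.** A rigid initialization
   (centroid and principal axes of corresponding capsule point sets,
   sign-disambiguated by least summed squared distance) is refined by a
   thin-plate spline interpolating control landmarks: three urethra
   points (apex, mid, base) and eight capsule points in each of three
   axial frames, 27 controls in total. The polyharmonic kernels are
   $U(r) = r^2\log r$ (2D) and $U(r) = r$ (3D). Accuracy is measured as
   the target registration error (TRE) on *evaluation* landmarks
   (internal fiducials) disjoint from the controls — under exact
   interpolation ($\lambda = 0$) control-point TRE is identically zero
   and meaningless.
3. **MRI $\to$ WM, 2D per slide.** Slides are matched to MRI slices by
   a human (here: nearest slice); the package validates the table's
   consistency (strictly increasing, unique, steps of
   $\mathrm{round}(4.5/1.5) \pm 1$). Capsule contours are resampled to
   64 equal-arc-length points anchored at the posterior-most boundary
   point, paired by index, aligned by a closed-form similarity
   (Umeyama; scale included because fixation shrinks the specimen) and
   refined by a capsule TPS on every 4th pair. Transition-zone Dice on
   a 0.2 mm raster scores the match.

Step errors are treated as independent and combined in quadrature,
$\sqrt{\sum_i \mathrm{TRE}_i^2}$, for both the means and the standard
errors. Landmark outliers beyond mean $+\,2\,$SD are excluded in a
single pass (not iterated) before summarising step 3.

## Annotation transport and evaluation

Reviewer polygons on native frames are sampled on a grid (1 mm default)
anchored to the polygon's bounding box, mapped to 3D by the frame
geometry, pushed through the stored chain, assigned to the WM slide
whose matched MRI window ($\pm 1.5 \times$ slice spacing, ties to the
nearer centre) contains their axial coordinate, and clustered with
DBSCAN (`eps` $= 2\times$ sample spacing so connectivity tracks
sampling density, `min_pts` $= 5$; both configurable and echoed into
reports — the source methodology names the algorithm but not its
parameters). Clusters of $\geq 3$ non-collinear points become convex
hull ROIs; border points attach to the first cluster reaching them in a
fixed scan order, making the output seed-free.

Evaluation operates at three granularities on a shared 0.2 mm raster —
finer by an order of magnitude than every registration error reported
here or in the literature, so discretisation is negligible:

* patient level: the index lesion (highest grade group, ties broken by
  size) is hit if *any* ROI touches any of its cross-sections;
* cross-section level: each clinically significant (grade group
  $\geq 2$) cross-section is an opportunity; ROIs touching none are
  *completely false*;
* pixel level: overlap, false-positive, Dice and per-slide sensitivity
  percentages. These satisfy the harmonic identity
  $\mathrm{Dice} = 2OP/(O+P)$ with $O$ the overlap fraction and $P$ one
  minus the false-positive fraction, which the test suite verifies
  against per-pixel counting oracles.

Reviewer aggregation reports mean $\pm$ SE (sd$/\sqrt{n}$) over
per-reviewer rates *and* the pooled fraction, because with three
reviewers the two differ; reviewer inclusion is a declared config echoed
into every report. Per-lesion metrics use the union of same-provenance
ROIs on the slide (whether the source methodology unioned or took the
best single ROI is not stated; the choice is declared in the report).
Specificity is deliberately not reported — at pixel granularity it is
inflated towards ~95% by benign area — and the false-positive percent
serves as its surrogate. Area stratification defaults to observed
quartiles, declared in the output, as the published bin edges are not
printed.

## The phantom: what it emulates and what it does not

The synthetic scene is an ellipsoidal gland (default semiaxes 22, 18,
15 mm, centred 24 mm anterior of the probe axis) with a bright capsule
rim, a transition zone, a curved urethra (dark 1.5 mm tube through
apex–mid–base waypoints), one to three ellipsoidal lesions with grade
groups drawn to resemble a prostatectomy cohort (index GG 2–5 weighted
8:5:1:1; mean lesion count 1.6, sd 0.6), and five internal point
fiducials. Acquisitions:

* a 300-frame fan sweep over $(-70^\circ, +70^\circ)$ — the angular
  extent of the clinical sweep is not documented, only "right to left",
  so it is a configurable package choice wide enough to cover the
  gland — with 2 mm offset, 0.5 mm in-plane sampling and optional
  Gaussian pixel noise;
* an axial MRI at 1.5 mm slices under a smooth global TPS deformation
  (default max displacement 4 mm — inside the regime a landmark
  registration must correct, cf. measured clinical TREs of ~2.2 mm);
  fields are scaled exactly (TPS is linear in its displacement targets)
  so the stated magnitude is attained, and are numerically invertible
  (forward-then-inverse $< 0.01$ mm at fiducials);
* WM sections of 4.5 mm with uniform in-plane shrinkage (default 0.95)
  and an independent smooth 2D deformation per slide (default max
  3 mm), with analytic capsule/transition-zone/lesion contours and
  ground-truth fiducial positions.

Fiducials are simulated as *point landmarks*, not image features:
landmark identification error is out of scope and modelled only as
optional Gaussian jitter (default 0). Consequently the phantom TREs
(e.g. 0.05 mm for step 2 at default settings) measure registration
machinery, not clinical accuracy — a green end-to-end test establishes
that the chain is implemented correctly, not that clinical TRE would be
2.2 mm. The phantom also deliberately omits speckle and acoustic
physics, attenuation (deeper tissue in large glands), histology
staining appearance, and reader behaviour.

## Numerical choices

* **TPS solver.** The bordered interpolation system is solved in
  centred, unit-scaled source coordinates with one iterative-refinement
  step, and kernel distances come from explicit coordinate differences
  rather than the $|a|^2+|b|^2-2ab$ expansion (which cancels
  catastrophically at $r\to 0$). Without these, control residuals are
  ~$10^{-7}$ mm; with them, ~$10^{-12}$ mm, comfortably below the
  $10^{-9}$ mm invariant the tests enforce. Centred-kernel and raw
  formulations define the same interpolant because the side conditions
  annihilate the induced extra terms; the tests verify agreement with a
  raw dense-solve oracle at probe points.
* **Mean binning** of multiple samples per voxel: unbiased and
  order-independent; samples are sorted deterministically before
  averaging so frame permutations are bit-identical.
* **Hole filling**: per-plane separable 1D linear interpolation (depth
  direction, then along-probe), no extrapolation beyond contributed
  samples; voxels outside the support keep background 0, recorded in
  metadata. Whether the original implementation interpolated in 2D per
  plane or in 3D is not documented; per-plane matches "fill holes in
  the new image planes" and is the package's choice.
* **Posterior anchor** for contour correspondence: argmin of the slide
  $z$ coordinate on a dense arc-length resampling, with parabolic
  refinement at smooth minima (skipped on flat plateaus such as a
  square's bottom edge, where the tie-break to the smaller horizontal
  coordinate stands). This rule is deterministic and rotation-robust
  for prostate-like shapes, whose posterior aspect is geometrically
  distinctive; it is the package's choice where the source methodology
  left the pairing rule unspecified.
* **Degenerate inputs**: coincident or affinely dependent TPS controls,
  collinear rigid-init point sets, self-intersecting contours,
  empty sweeps and empty correspondence tables all raise errors naming
  the offending entity; sections missing the gland are omitted with a
  message; clusters below three non-collinear points are discarded with
  a message.

## Interfaces

Landmarks travel as CSV/JSON (name, role, x/y/z mm), contours and ROIs
as JSON polygons, transforms as JSON serialisations of their
coefficients, correspondence tables as CSV; every file embeds the
coordinate convention. DICOM/NIfTI export and YAML configs, natural in
a clinical deployment, are not provided because no writer for those
formats is available in the supported dependency set; the pipeline
config is an R/JSON list instead, content-hashed into every report.

## Limitations

Known limitations beyond the phantom simplifications above: the
similarity + capsule-TPS slice registration corrects in-plane
deformation only (through-plane tilt of sections is not modelled);
slide matching is consumed as input and only consistency-checked;
convex-hull ROIs cannot represent concave lesion tracings (an
alpha-shape alternative would be the natural extension); and the
statistical comparisons between modalities (rank tests) are outside the
package's scope — it produces the per-review metric tables those tests
would consume.
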