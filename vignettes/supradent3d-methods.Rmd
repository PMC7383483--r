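---
title: "Methods: 3D morphometry and classification of impacted supernumerary teeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry and classification of impacted supernumerary teeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supradent3d)
```

## The problem

In cleidocranial dysplasia (CCD), most patients carry multiple impacted
supernumerary teeth, each typically lying close to one permanent tooth. A 3D
(CBCT-derived) characterization of such a dentition asks, for every
supernumerary tooth: which permanent tooth is it paired with; where does it
sit relative to that tooth (coronal or apical, mesial or distal, labial or
lingual); which way does its axis point (normal or inverse eruption
direction); and how does its size and crown morphology compare with the
adjacent tooth and with population norms.

`supradent3d` implements this analysis as a chain of deterministic geometric
operations over named anatomical landmarks, plus a statistical layer, and
validates the chain on synthetic dentitions and voxel phantoms with known
ground truth. Real CBCT cohorts of this kind are not publicly deposited, so
the synthetic generator *is* the study population here; what that does and
does not demonstrate is discussed at the end.

## Coordinate conventions and reference planes

All coordinates are millimetres in a right-handed patient frame: +x patient
left, +y anterior, +z cranial. Three planes anchor every call:

* **Occlusal plane** — through the central fossae of the right and left
  first molars and the incisal midline point of the central incisors.
* **Sagittal plane** — perpendicular to the occlusal plane, through the
  fossa midpoint and the incisal midline point.
* **Frontal plane** — perpendicular to the sagittal plane, through the
  central incisal edge midpoint (taken equal to the incisal midline point
  when not separately digitized).

Because the source description fixes the planes but not their sign
conventions, the package fixes them once: occlusal normal cranial, sagittal
normal toward patient left, frontal normal anterior. The orientation rule is
intrinsic to the four input points (cross-product order), so `build_frame()`
is equivariant under rigid motion — verified by property tests at 1e-9.

## Arch-local axes

Per-tooth *mesial/distal* and *labial/lingual* labels cannot be realized by
two global planes: "lingual" points in nearly opposite world directions for
an incisor and a molar of the same arch. The package therefore fits a
least-squares parabola through the occlusal centres of each jaw's permanent
teeth in occlusal-plane coordinates (`fit_arch_curve()`) and takes, at the
point of the curve nearest the tooth:

* **mesial** — the arch tangent, oriented toward the midline;
* **lingual** — the in-plane arch normal, oriented toward the arch interior
  (the centroid of the jaw's occlusal centres);
* **coronal** — the occlusal normal, flipped per jaw so it points *toward*
  the occlusal plane in both jaws.

The triad is orthonormal to machine precision. It cannot be right-handed on
both sides of the arch — left and right teeth are mirror images, so the
handedness necessarily flips across the midline; only orthonormality and the
anatomical orientations are asserted. Nearest-point projection on the
parabola solves a cubic; exactly equidistant solutions take the smaller
parameter and set a flag.

## Per-tooth morphometry

With the cervical reference line joining the labial and lingual CEJ points:

* **crown length** — cervical midpoint to the *highest point of the crown*,
  realized as the cusp tip farthest from the cervical midpoint (robust for
  tilted and inverted teeth, identical to the vertical reading for upright
  ones);
* **root length** — cervical midpoint to the apex; absent when the root
  extends out of the imaging range (`apex_in_volume = FALSE`), and such
  teeth are excluded from root-length comparisons;
* **crown diameters** — mesiodistal and buccolingual extreme-to-extreme
  distances;
* **tooth axis** — the line from the apex to the occlusal-surface centre;
  its signed inclination against the occlusal plane is measured with respect
  to the jaw-specific coronal direction, so +90° means "erupting straight
  toward the occlusal plane" in either jaw and a negative angle is the
  inverse direction. The angle uses the `atan2` form, which is
  well-conditioned at ±90° where the `acos` form loses seven digits.
  Inclinations within 1° of zero are flagged near-horizontal: the sign is
  reported but is within measurement noise of the plane.

Cusp tips closer than `merge_radius` (0.5 mm) merge into one cusp
(single-linkage), so an incisal edge digitized as a row of tips counts as a
single wide cusp. One cusp is *incisal-edge* type when its width is at least
`edge_ratio_threshold` (0.5) of the mesiodistal diameter, else *cuspid*;
two cusps are *bicuspid*; crowns under `microdont_floor` (2 mm mesiodistal)
are *obscure*. These thresholds replace visual inspection with a computable
rule and are all config-exposed. Root counts come from apex landmarks, with
roots under `root_floor` (1 mm) reported indeterminate.

## Pair identification and positional classification

Impacted teeth of initially unknown kind are clustered by occlusal-centre
proximity (single linkage, default radius 6 mm); within a pair the
longer-rooted tooth is the unerupted permanent tooth and the shorter-rooted
one the supernumerary (root length tracks odontogenic stage). Equal lengths
break toward the larger crown, flagged. Clusters of three or more are
refused with an error demanding manual status: the root-length rule only
decides pairs, and with strong displacement two neighbouring pairs can chain
into one cluster under single linkage — the proximity radius should then be
tightened to the displacement scale (it is a parameter).

Each supernumerary's **adjacent permanent tooth** is the same-jaw permanent
tooth nearest in 3D between occlusal centres (the jaw restriction reflects
that a supernumerary develops within one jaw's alveolus). The positional
call expresses the displacement between occlusal-surface centres — not
centroids — in the adjacent tooth's arch-local axes and reads each
component's sign. Components under `tie_epsilon` (0.01 mm, the order of the
smallest duplicate-measurement error) are below measurement precision: the
call defaults deterministically to apical/mesial/labial and is flagged.
The vertical call uses the signed coronal component rather than distances to
the occlusal plane; for same-jaw pairs the two readings coincide.
Supernumeraries inherit the region bin (eight bins: anterior, canine,
premolar, molar × maxilla, mandible) of their adjacent tooth, matching the
comma labelling convention (`"33,"` is the supernumerary of tooth 33).

## Statistics

* **Wilcoxon signed-rank** (supernumerary vs adjacent sizes): zero
  differences dropped (this changes n and is reported); average ranks for
  ties; `W = min(W+, W-)`. For n ≤ 25 the two-sided p is exact over all 2^n
  sign patterns, evaluated by generating-function convolution over doubled
  ranks (integers even under average-rank ties); above that, a normal
  approximation with continuity and tie corrections. The exact path is
  tested against a brute-force 2^n enumeration oracle and, on tie-free
  inputs, against `stats::wilcox.test`; type-I error at α = 0.05 is verified
  at 0.05 ± 0.01 over 10,000 null simulations.
* **z-scores** of crown mesiodistal diameters against a norm table keyed by
  (jaw, position, sex). Published norm values are not redistributed; the
  bundled default table is synthetic (derived from the generator's own
  archetypes) and clearly labelled as such.
* **Reliability**: Dahlberg's error `sqrt(Σd²/2n)` and ICC(1,1) (one-way
  random-effects, the standard reliability coefficient in orthodontic use —
  the package's reading of "interclass correlation") plus a paired t test
  for systematic error. Both are session-symmetric; Dahlberg converges to
  the per-session noise SD.
* Report tables round percentages and means to one decimal.

## The synthetic generator

`generate_dentition()` defines the study conditions:

* 28 permanent teeth (positions 1–7, four quadrants) on two parabolic
  arches at 8 mm arc spacing, occlusal centres of the mandibular arch in the
  occlusal plane; the jaws are modelled in open relation (8 mm interocclusal
  gap) so the arches are spatially disjoint. Tooth dimensions come from
  typical adult archetypes with 4% lognormal per-tooth jitter.
* Cohort structure mirrors the five-case series analysed: per-case
  supernumerary counts 1–15 (fixable to 15/10/7/6/1), unerupted permanent
  counts 10–21.
* Each supernumerary is a clone of a drawn adjacent permanent tooth
  (region probabilities from the reported per-region frequencies:
  mandibular premolar 14/39, mandibular canine 7/39, maxillary canine and
  premolar 6/39 each, maxillary molar 3/39, the remaining 3/39 split 2:1
  maxillary:mandibular anterior, mandibular molar 0; no permanent tooth
  receives two supernumeraries), scaled by a size ratio ~ N(0.7, 0.1)
  truncated to (0.3, 0.95) — supernumeraries are uniformly smaller, with
  strictly shorter roots, and molar-region ones additionally ×0.4
  (microdont, single cusp tip).
* Displacement from the adjacent tooth is drawn per axis: signs from
  Bernoulli probabilities coronal 26/39, distal 25/39, lingual 35/39;
  magnitudes |N(2, 0.5)| mm truncated to [0.5, 3.2] mm. The truncation keeps
  every pair closer than half the inter-tooth spacing (pairing provably
  unambiguous) yet non-degenerate; the source reports tendencies, not
  magnitudes, so the scale is a package choice fixed at design time.
* With probability 5/39 the supernumerary is point-reflected through its
  own landmark centroid before placement — the axis flips (inverse
  direction) while every distance, and the planted occlusal-centre
  displacement, is preserved.
* One seed drives everything; cohort case *i* re-seeds with `seed + i - 1`,
  so cohorts are reproducible and cases regenerable in isolation.

With placement probabilities at 0 or 1 the full pipeline recovers every
planted call exactly (noise-free identifiability); at the defaults, the
classified fractions over 3,900 pairs land within binomial error of the
planted probabilities. Problem sizes used by the shipped tests and scripts:
3,900 pairs (260 cases) for the positional study, 100 seeds for generator
validity, 20 phantom seeds for segmentation count recovery, 10,000 null
simulations for Wilcoxon calibration.

## Voxel phantoms

`render_phantom()` rasterizes each tooth as two capsules sharing the
cervical midpoint (crown: occlusal centre to cervical midpoint; root:
cervical midpoint to apex), over a lower-intensity alveolar bone slab, with
optional Gaussian noise; default voxel spacing 0.146 mm (any value in
(0.05, 1) mm; the shipped tests use 0.3–0.6 mm to keep volumes small).
Capsule radii are half the mean crown semidiameter, `(md + bl)/8`, with the
root at half that: full anatomical semidiameters would make neighbouring
crowns touch, as real teeth do, and touching components are inseparable by
thresholding alone (the interactive separation used on real data is out of
scope here).

`threshold_segment()` marks voxels at or above the threshold — chosen
between bone and tooth intensity; the tool deliberately has no automatic
threshold, mirroring its interactive origin — labels 26-connected
components, despeckles below `min_voxels` (10), and renumbers labels by
size. Touching teeth merge into one label by definition; consequently the
segmentation-recovery checks run on supernumerary-free dentitions, because
a supernumerary at the default 2 mm offset always interpenetrates its
adjacent tooth. This is a documented limitation of the phantom path, not of
the landmark path, which is the analysis route.

`estimate_landmarks()` recovers coarse landmarks from a component: SVD
principal axis oriented toward the opposing jaw; occlusal centre, apex and
cervical junction from the along-axis radial profile, each corrected for
the rounded capsule end by the locally measured radius; CEJ and crown
extremes from cross-section extremes. Isotropic components (no dominant
elongation) refuse to orient rather than guessing. Estimated root lengths
track planted ones at Spearman ρ ≈ 0.95 with ~0.3 mm mean error on 0.6 mm
voxels; volumes read and write as NIfTI, which carries spacing and origin.

## Design choices that were genuinely open

* **Arch-local vs global-plane side labels** — arch-local chosen because
  global planes cannot reproduce anatomical usage around the arch (above).
* **Vertical call from signed coronal components** rather than occlusal
  plane distances — equivalent for same-jaw pairs, simpler to make
  rigid-motion invariant.
* **"Interclass correlation" read as ICC(1,1)** — the standard reliability
  usage in this literature.
* **Two-sided p-values throughout** — the compared report states thresholds
  without sidedness.
* **Occlusal-surface centre of a rotated/inverted tooth** is accepted as a
  given landmark; the package does not attempt to re-derive it.
* **Region-probability remainder** (3/39 not pinned by the printed
  frequencies) split 2:1 between maxillary and mandibular anterior,
  anterior supernumeraries being more frequent in the maxilla in this
  condition.

## Limitations

The generator emulates cohort *structure* — pair geometry, positional and
directional tendencies, size ordering, region frequencies — not real
anatomy: no root curvature, no enamel/dentine contrast, no eruption
dynamics, no primary teeth, arches are exact parabolas, and placement draws
are independent across axes and teeth. Passing recovery tests therefore
demonstrates that the geometry and statistics are implemented correctly and
are invariant to the right things; it does not validate landmark
digitization or segmentation on clinical images. The phantom path is a
robustness demonstration with known merge behaviour for touching teeth;
real impacted pairs in contact need interactive or watershed separation,
which is out of scope.
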