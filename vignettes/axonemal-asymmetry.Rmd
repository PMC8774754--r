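---
title: "Scoring axonemal asymmetry in ciliary cross-sections"
author: "axosym"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring axonemal asymmetry in ciliary cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axosym)
```

## The measurement

A transverse TEM section of a motile respiratory cilium shows the 9+2
axoneme: nine peripheral microtubule doublets — each a complete A-tubule
fused to a C-shaped, incomplete B-tubule — arranged around a central pair.
The *axonemal circumference* is the closed curve joining the centers of
the nine A-tubules. In a preserved axoneme both tubules of each doublet
lie along this curve; a *rotated* doublet is tilted about its A-tubule so
that the B-tubule sits outside the curve. A section with more than three
rotated doublets carries an *axonemal symmetry break*, and a patient's
axonemal asymmetry (AA) is the percentage of cross-sections with a break
among all assessable cross-sections. In PCD cohorts the AA is high (38%
and above in the packaged study tables) even in genotypes with otherwise
normal ultrastructure, which is what makes it diagnostically interesting.

`axosym` implements this measurement end to end, from either manually
annotated tubule coordinates or rendered/recorded cross-section images.

## Circumference fitting

The circumference is fitted to the (up to nine) A-tubule centers by least
squares on *geometric* residuals — the orthogonal distances from the
points to the curve — not on an algebraic conic residual, which is biased
for partial, noisy arcs. The direct algebraic conic fit (the stable
variant of the direct least-squares ellipse method) provides the starting
point; Levenberg–Marquardt refinement then minimizes the orthogonal
distances, computed by Newton iteration on the point-to-ellipse projection
equation (the projection function is convex and decreasing in its
parameter, so the iteration is monotone and quadratically convergent).

With `kind = "auto"` (the default) an ellipse is fitted when at least six
points are available and the result has eccentricity at most 0.8;
otherwise the fit falls back to a circle (Kasa initialization, geometric
refinement of the center). The eccentricity cap rejects degenerate
ellipses that noisy or clustered detections can otherwise produce:
genuine oblique sections stay well below it (an aspect ratio of 0.85
corresponds to eccentricity 0.53).

Why an ellipse at all: sections are rarely cut exactly perpendicular to
the ciliary axis. An oblique cut at angle θ stretches the circular ring
into an ellipse whose semi-minor axis is the true ring radius and whose
semi-major axis is larger by 1/cos θ. The synthetic generator models
obliquity the same way (see below).

## The rotation call

For each doublet the signed clearance of the B-center from the fitted
curve is computed (positive outside, negative inside; magnitude =
orthogonal distance). The doublet is called rotated when

    clearance ≥ κ · r_B,       default κ = 0.5,

i.e. when at least half the B-tubule protrudes beyond the circumference.
Boundary equality counts as rotated. Only outward displacement counts:
inward-displaced B-tubules are recorded (the clearance is reported) but
never counted, because the defect as described and illustrated is an
outward swing of the doublet. κ is exposed in the configuration because
the visual rule ("the B-tubule is outside the line") does not pin down a
threshold; κ = 0.5 makes the call robust to a few pixels of
center-localization error at the default scale (r_B = 14 px) while
matching what an observer would accept as "outside".

A section is assessable when it is not flagged for microtubular
disorganization and at least 8 of 9 doublets have both tubule centers
localized. Non-assessable sections are excluded from both the numerator
and the denominator of AA; missing doublets bias the count toward
symmetry, so the 8-of-9 floor keeps that bias to at most one doublet and
the condition is flagged in reports. The break rule "more than 3" is
implemented strictly as count ≥ 4. The per-doublet tilt angle (between
the doublet axis and the local curve tangent) is reported as a continuous
supplementary metric but plays no part in the call.

## Ultrastructural classification

Per section, outer/inner dynein-arm absence is called when at most
`armMin` (default 2 of 9) doublets with a known flag bear the arm —
sections are scored as a whole and a couple of unresolvable arms are
tolerated, which is standard TEM practice; the threshold is configurable
because the classification criteria score sections, not doublets. A
central-complex defect is any central microtubule count other than 2.

Per patient, the modified BEAT-PCD classes are: Class 1 when ODA (or
combined ODA+IDA) absence exceeds 50% of cross-sections; Class 2 when
either lies in 25–50% (bounds inclusive) or the central-complex defect
rate exceeds 25%. The central-complex band is not given a percentage by
the classification table; 25% was chosen to align with the other Class-2
band and is configurable and flagged. Fewer than 50 evaluated sections
triggers a low-coverage warning rather than refusing the call.

## The synthetic generator

The generator emulates the geometry of well-preserved 9+2 cross-sections
at ~2 nm/px. Tubule radii are drawn oversized relative to the true 25-nm
microtubule (r_A = 12 px, r_B = 14 px) as a rendering convention; for the
scene to stay geometrically self-consistent, the circumference is scaled
proportionally (ring radius 60 ± 3 px), which preserves the real packing
of nine doublets around the ring — with a realistic ring-to-tubule ratio
the doublets nearly touch, exactly as in real axonemes. Obliquity is
modeled physically: the sampled ring radius is the semi-minor axis and
the major axis is stretched by 1/aspect, aspect ~ U(0.85, 1). An earlier
formulation that compressed the minor axis instead was discarded because
it packs doublets tighter than an oblique cut of a cylinder ever can.

Per section, nine A-centers are placed at 40° nominal spacing (angular
jitter sd 3°) on the sampled ellipse, with isotropic localization jitter
(sd 1 px). The zero-tilt doublet axis is the *chord* from the A-center's
curve point to the curve point one doublet length (r_A + r_B) away, so an
aligned B-tubule lies on the circumference exactly; a tilt rotates that
axis outward about the A-center. (Placing the zero-tilt axis along the
tangent instead would push even aligned B-tubules outside the curve by
the chord sagitta — about 5.6 px at the default geometry, most of the
decision boundary of κ·r_B = 7 px — so the chord construction is what
makes "aligned" mean "on the circumference".) Aligned doublets tilt as
|Normal(0°, 4°)|; rotated doublets as Normal(35°, 8°) truncated to
[15°, 75°]. The decision boundary at the default geometry corresponds to
roughly 18° of tilt, so the default rotated distribution deliberately
brushes the boundary — real rotations are not cleanly separated — while
validation tests that need exact labels use a well-separated regime
(rotated ≡ 40°, aligned ≡ 0°).

Rendering draws dark walls on a light background (standard positive TEM
contrast): complete annuli for A-tubules and the central pair, C-shaped
annuli opening toward the partner A for B-tubules, and small hook
decorations for dynein arms (rendered only to stress the detector; arm
presence is never inferred from images). Gaussian blur (σ = 2 px) and
additive Gaussian noise (sd 0.04 on the [0,1] intensity scale) complete
the image. Everything is reproducible from the scene seed.

What the generator does *not* emulate: membrane and matrix texture,
stain granularity, neighboring axonemes and debris, compound or swollen
cilia, partial sections, and true disorganization (flagged sections still
render as 9+2 geometry). Passing the synthetic benchmarks therefore
demonstrates the correctness and noise-robustness of the geometry and
detection pipeline, not clinical-grade performance on real micrographs.

## Image detection and assembly

Detection is an annular matched-filter bank: zero-mean center-surround
kernels (positive on the ring band, negative in the lumen) over the
radius band 10–16 px, maximum response across scales, greedy non-maximum
suppression at 1.2 × the minimum radius, sub-pixel peak refinement by
response centroid, and per-candidate radius selection. Each candidate
gets a *completeness* score — the fraction of 36 angular bins with wall
signal near its radius, each bin taking the strongest of three radial
samples so blur and noise do not punch spurious holes. Complete A-rings
score ~1.0; C-shaped B-tubules stay at or below ~0.92 (their opening is
partly filled by the partner A's wall, which is why they do not score
2/3); responses arising *between* structures score much lower and are
discarded below 0.6.

Assembly is structure-first, exploiting the stereotyped architecture:

1. Candidates well inside the ring of detections are split off as the
   central pair.
2. The nine-fold *A-skeleton* is picked greedily from complete rings
   (completeness ≥ 0.97) under a minimum center separation, so duplicate
   detections of one tubule never enter. A gap in the nine-fold angular
   spacing triggers A-rescue: the missing A is predicted from a
   provisional circumference fit and localized by a full-ring score
   search.
3. Each A's B-tubule is sought in its *chirality sector* — the angular
   wedge toward the neighboring A on the side where B-tubules sit (the
   axoneme is handed) — at the expected doublet spacing. Candidate Bs are
   validated and re-localized against the image by the *C-ring score*:
   the lower quartile of wall signal over the ring bins facing away from
   the A. A genuine B has wall in essentially every such bin; a spurious
   position whose annulus merely crosses other walls leaves most bins
   empty, which is what makes the lower quartile (rather than the mean)
   discriminative. A doublet whose B was lost to an overlapping neighbor
   is recovered by searching the circle of one doublet length around its
   A.
4. Handedness cannot be judged locally in degraded images (a rotated B
   sits at doublet spacing from two A-tubules), so the doublets are
   assembled under both chirality hypotheses and the one explaining more
   doublets — then scoring higher — wins. This also makes the pipeline
   invariant under image mirroring.

A section is flagged disorganized when the nine-fold skeleton cannot be
established or more than one doublet partner is unrecoverable. Arm flags
cannot be read from images and remain unknown in image-derived sections.

## Numerical and design choices

- Quartiles in cohort summaries use linear interpolation between order
  statistics (R type 7), the common default; the convention is
  configurable in principle but nothing in the packaged tables can
  adjudicate it.
- The distribution tables shipped with the cohort stage are reproduced
  from the ingested records only. The study's own printed distribution
  tables carry group sizes inconsistent with its 40 participants, so
  their printed means are documented as irreproducible and are not
  acceptance surfaces.
- HSVA token "N" in the control table is read as "Normal" in summaries;
  the raw token is preserved in the records.
- All randomness flows through explicit seeds; batch generation is
  byte-identical for a fixed seed.
- Validation problem sizes: the generator/classifier round-trip uses 100
  sections per rotated-count (1,000 in all); the image benchmark uses 200
  rendered sections at default noise plus a 50-scene paired sweep over
  three noise levels (the same scenes and noise seeds at increasing
  noise, so accuracy comparisons are paired); the simulated cohort uses
  20 patients × 50 sections.

## Known limitations

- Detection assumes one pre-cropped axoneme per image; multi-axoneme
  fields need external cropping.
- Dynein-arm presence is not detected from images.
- The rotated-doublet threshold κ and the arm-call threshold `armMin`
  parameterize conventions the underlying visual scoring rules leave
  open; sensitivity to them should be reported alongside any cohort
  result.
- True microtubular disorganization is excluded by flag, not detected
  from images; image-derived "disorganized" means the 9+2 structure
  could not be assembled, which is a proxy.
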