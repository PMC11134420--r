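---
title: "Probe coregistration methods: models, parameters and design choices"
author: "probereg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probe coregistration methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probereg)
```

## The problem

Optical neuroimaging caps hold sources and detectors at a fixed 30 mm
separation, so the cap cannot simultaneously respect the proportional
10-20/10-10 landmark system on heads of different sizes: the same
nominal optode lands on measurably different scalp locations across
participants. Digitizing the actual probe positions — here, by labeling
them on an infrared 3D surface scan — and rigidly registering the labeled
points to each participant's anatomy or to a template recovers spatial
consistency. `probereg` implements the registration itself and the four
error analyses used to validate such a digitization method against an
MRI-derived reference.

## Registration model

All registration is *control-point mapping*: correspondences between
point sets are known a priori from their labels, and the optimal rigid
transform is obtained in closed form. For corresponded sets
$\{x_i\}, \{y_i\}$ the estimate minimizes
$\sum_i \lVert sRx_i + t - y_i \rVert^2$ over rotations $R$, translations
$t$ and (optionally) a uniform scale $s$. With centered coordinates
$X_c, Y_c$ and $U \Sigma V^\top = \operatorname{svd}(X_c^\top Y_c)$,

$$R = V \operatorname{diag}(1, 1, d)\, U^\top, \qquad
  d = \operatorname{sign} \det(V U^\top),$$

so the solution is always a *proper* rotation — a head point cloud must
never be mirrored, even for pathological inputs. The translation matches
the (scaled, rotated) centroids. Because the solution is closed-form in
double precision, orthonormality, determinant and noise-free recovery are
asserted at 1e-9 rather than at loose iterative tolerances. (One caveat
discovered while testing: measuring a *rotation-angle* error through
$\arccos((\operatorname{tr} R - 1)/2)$ saturates around
$\sqrt{\varepsilon_{machine}} \approx 1.5\times 10^{-8}$ rad, so
elementwise matrix comparisons are used wherever 1e-9 resolution is
required.)

Two alignment modes are exposed:

- **landmark-based** — the transform is fitted on exactly the three
  anatomical fiducials (nasion, left/right pre-auricular points) and then
  applied to all points. This reflects realistic use, where probe
  positions are expressed relative to the participant's anatomy, and it
  inherits any fiducial-placement error.
- **landmark-free** — fiducials are excluded and the fit uses all probe
  labels shared between the two sets (matched by label, never by index).
  This isolates device and labeling error from fiducial placement.
  Labels without a partner are dropped from the fit with a warning, not
  an error, because a repeat scan may legitimately miss an occluded
  marker.

"Rigid" means $s = 1$ unless scaling is explicitly enabled. The source
text for this pipeline says rigid registration, yet heads spanning
54–61 cm circumference are mapped onto a single template; rather than
guessing which convention a given toolchain used, strict rigidity is the
default and the least-squares uniform scale is an opt-in flag, with the
`benchmark` command reporting both.

The anatomical head frame is built from the fiducials alone: origin at
the LPA–RPA midpoint, $+X$ from LPA to RPA, $+Y$ toward the nasion after
orthogonalization against $X$, $+Z = X \times Y$. Note that the nasion
generally retains a small $x$-offset in this frame (only its $z = 0$,
$y > 0$ location is definitional), since the origin is the inter-aural
midpoint rather than the nasion's foot point.

## The four analyses

Every analysis reduces to a flat collection of Euclidean distances in a
common space, tagged by optode label and by grouping unit:

1. **Cap-fixation variability** — all subjects' MRI-derived sets are
   aligned landmark-based onto the template montage; per label, distances
   are computed across subjects. The estimator is *pairwise* (all
   unordered subject pairs) by default, with *distance-to-centroid* as an
   option: the definition "distance between participants" does not pin
   down the estimator, so both are computed and reported.
2. **Accuracy** — each repeat scan is aligned to the same subject's MRI
   set under either mode; distances are per-optode scan-vs-MRI.
3. **Reproducibility** — for every unordered pair of repeat scans, the
   second is aligned onto the first; distances are per-optode
   scan-vs-scan.
4. **Inter-optode distance** — one chord (straight-line) distance per
   source–detector channel; no alignment is needed since chord lengths
   are rigid-invariant. Chords, not geodesics, because the validated
   quantities are Euclidean distances between labeled 3D points.

Pooled statistics are computed over the *flat* collection of individual
distances by default (`pooling = "flat"`); averaging per-subject means
first is exposed as `"per_subject"` because the phrase "first within the
subject and then averaged" is genuinely ambiguous — both variants appear
in the benchmark output. SDs use the $n-1$ denominator throughout.
Fiducials are excluded from all distance collections. The per-optode
summary stores full-precision mean/SD/max; the summary-table writer
rounds the maximum to an integer for display only.

The statistical comparison between analyses is a two-sided Welch
(unequal-variance) t-test on the flat distance collections — the robust
default among "t-tests" — with the variant recorded in the result
(`test_name = "welch_t"`).

## Template montage

The bundled `standard_1005` table is a **synthetic, idealized spherical
realization** of the 10-05 system (file
`extdata/standard_1005_synthetic.csv`): positions are constructed by
proportional subdivision of circular arcs on a 90 mm sphere
(circumference ≈ 56.5 cm, matching the cohort mean), covering the
full-density midline and central coronal 10-05 chains, the
circumferential ring and the interior rows at 10-10 density, with
fiducials idealized at Nz/T9/T10. It is a geometric alignment template —
adequate because only its fiducials anchor the landmark-based mapping —
not a measured electrode atlas; users comparing against a specific
toolchain's montage should load their own table via `montage()`.

## The synthetic cohort generator

The generator's defaults *are* the study design they emulate: 5 subjects,
3 repeat scans, 25 optodes forming 24 channels at a fixed 30 mm spacing,
head circumferences drawn from a normal law with mean 566 mm and SD 29 mm
clipped to 540–610 mm. (The circumference SD is read as 2.9 cm; a
2.9 mm spread is inconsistent with the stated 54–61 cm range over five
heads.)

- **Scalp** — an ellipsoid, not a template mesh: the metrics only need a
  plausible curved surface with controllable circumference. The lateral
  semi-axis is solved so the axial-ellipse perimeter (complete elliptic
  integral, evaluated by adaptive quadrature to 1e-12 relative tolerance)
  equals the requested circumference; front–back axis = 1.25 × lateral
  (typical cephalic proportions); vertical axis = 1.4 × lateral.
- **Layout** — a single serpentine spiral chain traversing the
  prefrontal, temporal and visual regions. Three *disjoint* chains cannot
  produce 24 consecutive-neighbor channels from 25 optodes
  ($\sum (k_i - 1) = 22$), so one continuous chain over the three regions
  is used; labels alternate D/S (13 detectors, 12 sources) so that every
  consecutive pair is a source–detector channel. Each next optode is
  located by root-bracketing along the surface curve until the chord to
  its predecessor equals the spacing to within 1e-6 mm (root tolerance
  1e-12 on the curve parameter).
- **Perturbations** — cap placement differs *between* subjects: a
  tangential shift (SD 6 mm per horizontal component) plus a rotation
  about the vertical axis (SD 3°), re-projected radially onto the scalp;
  fiducials are anatomical and do not move with the cap. Within subjects,
  every scanned point (fiducials included) receives independent isotropic
  Gaussian digitization noise (SD 1.2 mm per component); the MRI set is
  exact on optodes but its fiducials carry their own labeling noise
  (SD 2.5 mm). These jitter defaults were chosen once to reproduce the
  qualitative error hierarchy of real cap use — between-subject
  variability ≫ scan-vs-MRI accuracy ≫ scan-rescan reproducibility, with
  landmark-based accuracy exceeding landmark-free — and are *not*
  estimates of any physical device's jitter.
- **Randomness** — three deterministic substreams per subject (head/cap,
  fiducial noise, digitization noise), derived from
  `(seed, subject, stream)` by exact integer mixing. Cohorts and fixture
  trees are byte-reproducible, and changing one noise SD leaves the other
  streams' draws bit-identical — which turns the "fiducial noise affects
  landmark-based but not landmark-free accuracy" property into an exact
  equality rather than a statistical test.

What the simulator does **not** emulate: real scalp/mesh geometry, hair
and cap compression, anisotropic or spatially correlated scanner noise,
missing or mislabeled markers, and head-shape asymmetries. Passing tests
therefore demonstrate the correctness of the bookkeeping, registration
and statistics on data with the study's design structure — they do not
certify accuracy numbers for any particular scanner.

## Mesh defacing

The anonymization module reorients a head mesh so the nasion lies on the
$+X$ axis (rotation about $+Z$ only), removes all faces strictly below a
cutting plane, and deletes the face region inside a user-positioned
finite cylinder. Two deliberate choices: boolean subtraction is replaced
by face deletion (downstream labeling needs landmark *visibility*, not a
watertight surface, and exact mesh booleans are numerically fragile); and
faces straddling the cutting plane are kept intact rather than
re-triangulated. Faces with any vertex within `keep_radius` (default
15 mm) of a protected landmark survive the cylinder, guaranteeing the
fiducial regions remain labelable. Every operation returns or accompanies
the applied transform, because the anonymized mesh lives in a different
frame than the original and labels must move between the two losslessly.
The cutting-plane height and cylinder dimensions are user parameters
with documented defaults, not study-derived constants.

## Numerical choices and degenerate inputs

- Orthonormality/properness of rotations validated at 1e-9; noise-free
  construct-and-recover asserted elementwise at 1e-9.
- Registration refuses fewer than 3 pairs, mismatched lengths, and
  all-coincident sources; head-frame construction refuses coincident or
  collinear fiducials (threshold 1e-9 mm on the orthogonalized norms).
- File round trips print 9 decimals (sub-nanometer), making
  parse-after-write identities exact at the 1e-9 mm level; the positions
  TSV fixes 6 decimals for deterministic, byte-stable downstream
  hand-off.
- Inactive PickPoints markers are dropped at parse time and can never
  reach a computation; fiducial spellings are normalized once, at IO
  boundaries, by a case-insensitive map that is idempotent.
- Distances of degenerate Welch inputs (two zero-variance samples) are
  handled explicitly: equal means give statistic 0, p = 1.

## Problem sizes used by the test-suite

The suite exercises: 1000 random noise-free transform recoveries plus an
exhaustive 0.5°-step rotation-grid cross-check on planar 4-point
instances (for coplanar sets the optimum is provably a rotation about
the plane normal, which makes the exhaustive search tractable); exact
double-loop oracle comparisons on full 5-subject cohorts; the strict
error-hierarchy ordering on a 100-subject cohort; and 100-fixture file
round trips. These sizes were chosen as the smallest that make the
properties non-trivial while keeping the default check fast on a laptop.

## Known limitations

- The bundled montage is an idealized sphere; aligning onto a measured
  MNI-space montage will shift absolute coordinates (relative distances,
  which all four analyses use, are unaffected).
- No non-rigid warping: methods that deform the head shape to additional
  markers can reach lower landmark-based errors but are out of scope by
  design, as is any surface-based (ICP) matching or projection of probes
  onto scalp/cortex.
- The benchmark against externally deposited study data requires the
  user to download and arrange that data in the documented cohort layout
  (`read_cohort()`), optionally remapping label spellings with
  `--label-map`; the pooled published values it compares against are
  recorded in `reference_study_values()`.
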