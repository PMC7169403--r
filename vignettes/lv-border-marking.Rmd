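---
title: "Marking the left-ventricular endocardial border with a Gabor-guided anisotropic generalized Hough transform"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marking the left-ventricular endocardial border}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmark)
```

## The problem

Tracing the endocardial border of the left ventricle (LV) on a 2-D
echocardiographic still is the prerequisite for estimating chamber volumes
and the ejection fraction, and it is unreliable exactly where it matters
most: in patients with a poor acoustic window, where the lateral wall is
barely visible and manual tracing is slow and subjective. `lvmark`
implements a fully automatic marking procedure for such images: a Gabor
filter bank localizes the region of interest (ROI), an anisotropic
generalized Hough transform (GHT) localizes a *guided deformable template*
of the border, the template's uncertain lateral limb is refined to the
image evidence, and a support-vector-machine (SVM) score reports how much
the marking should be trusted. Because clinical images cannot be
redistributed, the package ships a seeded phantom generator with exact
ground truth; every quantitative claim in the test suite is made on
phantoms.

## The model

**Gabor ROI.** The real Gabor filter
$g(x,y) = \exp\!\big(-(x'^2+\gamma^2 y'^2)/2\sigma^2\big)\cos(2\pi x'/\lambda + \phi)$,
with $(x', y')$ the coordinates rotated by the orientation $\theta$, is a
windowed sinusoid whose envelope $\sigma$ is never set directly: it is
coupled to the wavelength through the half-response spatial-frequency
bandwidth $b$ (octaves),
$\sigma/\lambda = \tfrac{1}{\pi}\sqrt{\tfrac{\ln 2}{2}}\,\tfrac{2^b+1}{2^b-1}$,
which at the default $b = 1$ gives $\sigma = 0.56\,\lambda$
(`sigma_from_bandwidth()`, `bandwidth_from_sigma()`). The ROI stage
convolves the image with a small bank (4 orientations x 2 wavelengths, even
and odd phase), takes the pointwise maximum of absolute responses, Otsu
thresholds it, and keeps the largest connected component; its padded
bounding box is the search window handed to the GHT
(`filter_bank_response()`, `extract_roi()`).

**Anisotropic GHT.** A boundary template is a list of points with gradient
orientations; its R-table stores, per orientation bin (36 bins of 5
degrees across the straight angle), the polar displacements from each
boundary point to the reference point (the barycenter). A pose is
$(\mathbf{y}, S_x, S_y, \theta)$: reference position, two orthogonal
scales, rotation. Every image edge pixel (Sobel, orientation mod $\pi$)
looks up the bin of its orientation shifted by the candidate rotation and
votes at $\mathbf{y} = \mathbf{x}_B + R(\theta)\,\mathrm{diag}(S_x,S_y)\,\mathbf{r}$
for every stored displacement $\mathbf{r}$ (`build_rtable()`,
`accumulate_ght()`). Vote counts accumulate in a 5-D integer array; the
"rate" of a detection is the raw vote count at its cell, and the ten best
recognition positions are returned ranked (`top_candidates()`).

**Guided deformable template.** The septal wall is the reliably visible
side, so the canonical template (a U-shaped open elliptical arc, apex up,
sampled at 1-px arc length) keeps a thin septal limb used only for pose
localization, while the lateral limb carries a thick band (half-width 6 px
at unit scale) inside which the marking may deform. After the GHT fixes
the pose, each posed lateral point slides along its posed outward normal
by an integer offset bounded by the scaled band half-width; the offsets
maximize summed Sobel magnitude minus a smoothness penalty
$\beta\,(d_i - d_{i+1})^2$ and are solved exactly by dynamic programming
(`deform_band()`). Ties prefer the smaller absolute offset, then the
negative one, so degenerate (gradient-free) evidence returns the posed
polyline unchanged.

**Confidence.** `featurize()` reduces an accumulator to 11 summary
statistics (max, mean, population variance, peak-to-second-peak ratio with
the second peak taken outside a 5-px positional radius, Shannon entropy of
the normalized votes, the argmax pose normalized to its grid ranges, and
the vote fraction near the peak). An SVM with the cubic kernel
$(x \cdot x'/s^2 + 1)^3$ — the kernel scale $s$ set automatically to the
median pairwise distance between standardized training vectors — is
trained on such features labelled by whether the marking's mean boundary
error is within 3 px of ground truth, and reports leave-one-out
cross-validated accuracy (`train_confidence()`). At apply time the signed
margin maps through a logistic to a confidence in $[0,1]$ with 0.5 on the
decision boundary (`score_confidence()`).

## The phantom generator

`phantom_spec()`/`generate_phantom()` emulate an apical-four-chamber-like
still: a dark fan-shaped scan sector on black background; an elliptical
dark LV cavity; a myocardial band that is brightest at the endocardial
border (the intensity step sits exactly on the ground-truth boundary) and
tapers outward; a lateral wall dimmed by `lateral_attenuation` (1 = fully
invisible, the poor-window case); the neighboring chambers (RV, LA, RA)
painted as dimmer cavity/ring distractors placed relative to the posed LV;
and multiplicative speckle-like noise,
`image = clean * (1 + speckle_scale * n)` with `n` a unit-variance
Gaussian field smoothed at 1 px, fully determined by one integer seed.
The distractor chambers matter: they are the off-target clutter that makes
a full-image accumulator space confusing and hence give the ROI
restriction something real to remove.

What the phantom does **not** emulate: speckle statistics of a physical
point-spread function, attenuation and shadowing physics, valve and
papillary structures, cardiac motion. Tests passing on phantoms therefore
demonstrate the geometry and ranking machinery and the *direction* of the
ROI benefit, not clinical accuracy.

## Numerical choices

* Coordinates are 0-based `(x = column, y = row)`, y down; poses are
  reported as `(x, y)`.
* Vote placement rounds half away from zero (`std::lround`); the test
  suite's brute-force oracle mirrors this rule.
* Candidate ranking consolidates votes over a 3x3 positional neighborhood
  (`smooth_radius = 1`): integer edge-pixel coordinates smear a true
  pose's votes over adjacent position cells, and without consolidation the
  diluted peak can fall below a distractor arc. The reported rate remains
  the raw cell count, so a noiselessly stamped template still scores
  exactly its point count. `smooth_radius = 0` restores pure rate ranking.
* The edge threshold is the 0.8 quantile of nonzero gradient magnitudes
  inside the search window. At the 0.9 quantile the attenuated lateral
  wall drops out entirely on mid-attenuation phantoms and the remaining
  septal-only arc is pose-ambiguous; 0.75-0.80 is a stable plateau, and
  the default sits at its upper edge. FFT convolution residue (~1e-13) is
  clamped to zero before the quantile is taken.
* The default search grid spans scales 0.85-1.15 in steps of 0.05 and
  rotations of +/-30 degrees in steps of 10 degrees, positions covering
  the ROI box. A millesimal scale grid is representable in the printed
  report format, but a full 5-D accumulator at that resolution is far
  beyond desk-scale memory and time; the grid is a configuration
  parameter, and all pose-recovery guarantees are stated relative to the
  grid step.
* The ten rate-ranked candidates are verified before the marking is made:
  the pose whose full posed boundary has the highest mean Sobel magnitude
  becomes the `chosen` detection (the detections table itself stays
  rate-ranked). Verification is what rejects a neighboring-chamber ring
  that matches the template at the low end of the scale grid.
* Band deformation discretizes offsets at 1 px with `beta = 0.1` per px^2;
  samples outside the image score as unreachable, and a lateral point
  whose entire band is outside keeps offset zero (the whole band outside
  the image is an error).
* The sketch-to-template path thins the largest foreground component with
  Zhang-Suen thinning (implemented in the package; no installed package
  exposes one), orders the skeleton by greedy nearest-neighbor walking
  from an endpoint, and resamples at unit arc length.

## Problem sizes in the shipped checks

The packaged tests run phantoms at 256 x 256 (25 noise-free + 25 at
speckle 0.3 for pose recovery) and confidence benches of 24 phantoms at
128 x 128 over five seeds, with benign/hostile imaging conditions
interleaved (speckle up to 1.8, lateral attenuation up to 1.0) so that
markings on both sides of the 3-px labelling threshold occur. Each bench
runs two arms per phantom — the complete refined procedure, and the
direct GHT searching the whole image without the ROI, peak consolidation
or verification — and labels each arm's sample by its own marking's
error, mirroring a before/after comparison of the refinements. Oracle
equivalence is checked exactly on twenty random 64 x 64 instances with up
to 200 edge points and 200 pose cells. These sizes make the whole suite
run in minutes on one core while leaving every mechanism exercised at
full fidelity; none of the algorithmic defaults depend on image size.

## Known limitations

* The anisotropic transform shears gradient normals, but the R-table
  lookup shifts bins by the rotation only (the standard GHT
  approximation); at extreme anisotropy part of the template votes in a
  neighboring bin and the rate understates the match.
* The confidence features summarize the accumulator; the raw vote array
  is deliberately not used as a feature vector, so grids of different
  sizes are comparable but fine spatial structure of the vote mass is not
  visible to the classifier.
* Phantom benches label a marking by a single geometric criterion (mean
  boundary error at most 3 px); no reader-study surrogate is attempted.
* On these phantoms the ROI restriction does not reliably improve the
  confidence classifier: phantom marking failures are driven mostly by
  the global speckle amplitude, which the full-image accumulator encodes
  at least as well as the restricted one. The restriction's classification
  benefit is expected from spatially local clutter (neighboring anatomy,
  local window quality) that real scans have and the phantom's noise
  model does not; the corresponding packaged check documents this as an
  open expectation rather than a demonstrated property.
* Single still frames only: no cine tracking, no volume or
  ejection-fraction computation, no DICOM ingestion.

## A minimal session

```{r example, eval = FALSE}
spec <- phantom_spec(pose = pose_params(position = c(128, 115),
                                        scale = c(0.95, 1.05),
                                        rotation = pi / 18),
                     speckle_scale = 0.3, seed = 7)
ph <- generate_phantom(spec)
res <- run_pipeline(ph$image)
res$report
boundary_error(marking_boundary(res), ph$truth$boundary)
autoplot(res, img = ph$image)
```
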