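# lvmark

Automatic marking of the left-ventricular (LV) endocardial border on 2-D
echocardiography-like grayscale images, with a confidence score for each
marking.

Endocardial border delineation is the step that makes LV volumes and the
ejection fraction measurable, and it is least reliable in patients with a
poor acoustic window, where the lateral wall all but disappears. `lvmark`
implements a fully automatic procedure built around the anisotropic
generalized Hough transform (GHT):

1. **Gabor ROI** — a small bank of Gabor filters
   (σ coupled to the wavelength by the half-response bandwidth *b*:
   σ/λ = (1/π)·√(ln2/2)·(2^b + 1)/(2^b − 1), so σ = 0.56 λ at *b* = 1)
   localizes the region of interest that restricts the search.
2. **Anisotropic GHT** — a boundary template is encoded as an R-table of
   orientation-binned polar displacements toward its reference point;
   every Sobel edge pixel votes over poses **a** = (y, Sx, Sy, θ) at
   y = x_B + R(θ)·diag(Sx, Sy)·r. The ten best recognition positions are
   ranked by the maxima of the accumulator space, with the raw vote count
   as the rate.
3. **Guided deformable template** — the well-visualized septal wall acts
   as a thin guidance limb; the lateral limb carries a thick band inside
   which the border is deformed to the image gradient by exact dynamic
   programming.
4. **Confidence** — an SVM with a cubic kernel and automatic kernel scale,
   trained on accumulator-space summary features, turns the signed margin
   into a confidence in [0, 1].

Because clinical images are not redistributable, the package includes a
seeded phantom generator (`phantom_spec()`, `generate_phantom()`) that
emulates an apical-four-chamber-like still — scan sector, LV cavity and
tapered myocardial wall, dimmer neighboring chambers as distractors,
attenuated lateral wall, multiplicative speckle — with exact ground-truth
boundaries for benchmarking.

## Worked example

```r
library(lvmark)

spec <- phantom_spec(pose = pose_params(position = c(128, 115),
                                        scale = c(0.95, 1.05),
                                        rotation = pi / 18),
                     speckle_scale = 0.3, seed = 7)
ph  <- generate_phantom(spec)        # 256 x 256 image + ground truth
res <- run_pipeline(ph$image)
res$report
#> [1] "The best matching was found for scale 1.000000 and angle 0.175 in position (128, 115) with rate 43 (scales 0.950000, 1.050000)"
boundary_error(marking_boundary(res), ph$truth$boundary)
#> # A tibble: 1 x 2
#>   mean_dist hausdorff
#>       <dbl>     <dbl>
#> 1    0.0507         5
```

The report line is the procedure's one-sentence estimate: the detected
scales (0.95, 1.05) and rotation 0.175 rad are exactly the pose the
phantom was generated with, the position (128, 115) is the detected
reference point, and the rate is the number of accumulator votes at that
pose cell. The marking itself (septal limb at the detected pose plus the
deformed lateral polyline) sits 0.05 px from the true border on average.
`autoplot(res, img = ph$image)` draws it over the image;
`glance(model)` summarizes a trained confidence model.

A thin command-line driver with `phantom`, `roi`, `detect`, `mark`,
`report` and `confidence train|score` subcommands is installed under
`inst/cli/lvmark`.

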