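---
title: "Estimating minimum foot clearance from calibrated sagittal-plane video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating minimum foot clearance from calibrated sagittal-plane video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mfce)
```

## The measurement problem

Minimum foot clearance (MFC) is the local minimum, during the swing phase
of gait, of the vertical distance between the lowest point of the footwear
and the walking surface. It is the moment of highest trip risk: the foot
moves fast, the base of support is small, and an unseen obstacle taller
than the clearance will catch the shoe. Population-scale MFC data from
real walkways — rather than laboratory walkways with motion-capture
markers — requires a measurement that works on unmodified pedestrians
passing a camera.

`mfce` implements the analysis half of such a system: a consumer camera
lies at ground level beside a walkway, viewing the feet side-on, with two
parallel laser beams of known physical separation $D$ (default 164 mm)
projected onto the passing lower leg. Because the beams are parallel,
their dot-to-dot distance in millimetres is constant at any depth, so the
apparent separation $x$ in pixels calibrates the image scale **at the
pedestrian's depth**:

$$k = D / x \quad \text{(mm per pixel)}, \qquad \mathrm{MFC} = d \times k,$$

where $d$ is the pixel distance between the lowest shoe point and the
ground line at the frame where that distance is locally minimal. At a
typical 2 m camera-to-subject distance and HD resolution the scale is
about 1.59 mm/px, which bounds the attainable accuracy.

Two steps of the workflow are deliberately manual and enter as inputs:
cropping the clip to a single pedestrian, and clicking two points that
define the ground line. The package automates the remaining stages.

## Pipeline

1. **Segmentation.** A pluggable backend returns 0–2 footwear masks per
   frame. The package ships an oracle backend (synthetic truth), a
   classical background-subtraction backend for synthetic fixtures, and
   readers for externally produced masks (binary PNGs or COCO-style
   polygons) so that a trained neural instance detector can be plugged in
   without code changes. Training such a detector is out of scope.
2. **Frame states.** Each frame is classified as `NO_ONE`, `BEGIN`,
   `FULLY_VISIBLE` or `OVERLAP` from the previous state and the mask
   count. `FULLY_VISIBLE` followed by a single mask raises the occlusion
   flag: the two feet have merged in the sagittal view.
3. **Swing vs stance.** With two masks, the one whose lowest point is
   further from the ground line is the swing foot. Near-ties (double
   support, below 0.5 px) fall back to which centroid moved more since
   the previous frame; without history both stay unlabelled.
4. **Occlusion recovery.** During `OVERLAP`, the previous swing mask's
   bottom-edge point set is matched against the frame's edge map over
   rotations of ±20° in 5° steps and integer translations (±40 columns,
   ±15 rows), scored by the mean distance-transform value at the
   transformed points (chamfer matching). The best placement transforms
   the whole previous mask into the recovered swing mask.
5. **Strides.** The swing centroid's horizontal velocity (3-frame median
   smoothing) cuts the track where motion against the inferred walking
   direction or speed below 0.5 px/frame persists for 3 or more frames;
   runs shorter than 8 points cannot support a quintic and are dropped.
   Walking direction comes from the side of the image where the shoe was
   first detected.
6. **Quintic fit and MFC.** Clearance against frame index is fitted with
   a degree-5 polynomial — the lowest degree consistent with the three
   inflection points of a swing-height profile. The MFC is taken at the
   derivative root inside the stride with positive second derivative and
   lowest value, clipped at zero; the raw interior sample minimum is
   available as an alternative (`method = "raw_series"`). Boundary
   minima yield no estimate, because a minimum at the edge of the field
   of view may not be the true one.
7. **Calibration and units.** Laser dots are detected per frame by
   thresholding at a high intensity quantile, blob labelling, and
   area/circularity/alignment/separation filters, with intensity-weighted
   sub-pixel centroids; manual annotation is the fallback. Pixel MFCs are
   converted by $d \times k$; without any calibration the pipeline still
   reports pixel values and flags the run.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `D` | 164 | mm | physical inter-laser distance of the rig |
| `laser$brightness_quantile` | 0.999 | — | adaptive threshold; lighting varies between shaded and sunlit sites |
| `laser$min_area`, `max_area` | 3, 400 | px² | plausible dot sizes at HD resolution |
| `laser$min_circularity` | 0.6 | — | $4\pi A/P^2$ with perimeter = boundary-pixel count; rejects streaks |
| `laser$min_peak_margin` | 30 | intensity | a real dot peaks far above the quantile threshold; noise blobs on dot-less frames do not |
| `laser$max_column_offset` | 12 | px | beams are nearly vertical in the image |
| `detection$min_diff` | 40 | intensity | classical backend foreground threshold (~16% of range) |
| `occlusion$rotation_range/step` | ±20 / 5 | deg | foot-rotation envelope during one frame interval |
| `occlusion$translation_window_px` | ±40, ±15 | px | inter-frame foot motion at 60 fps, HD scale |
| `occlusion$edge_gradient_threshold` | 10 | intensity/px | keeps low-contrast shoe-on-shoe boundaries; Otsu available via `NULL` |
| `occlusion$motion_penalty` | 0.02 | score/px | motion-prior regularizer against identical-sole decoys |
| `trajectory$stationary_speed` | 0.5 | px/frame | stance threshold at 60 fps HD |
| `trajectory$min_points` | 8 | frames | six quintic unknowns plus slack |

All keys can be overridden from YAML (`read_mfce_config()`; schema in
`inst/extdata/config-schema.yaml`).

## Numerical choices

* **Conditioning.** Quintic fits run on abscissae affinely mapped to
  $[-1, 1]$; coefficients are reported in both bases. Noise-free quintic
  samples are recovered to better than $10^{-9}$.
* **Minima.** Derivative roots come from the companion-matrix solver
  (`polyroot`); roots are accepted as minima only strictly inside the
  stride interval and with positive second derivative. Every fit asserts
  that its second derivative (a cubic) has at most three real roots.
* **Edge maps.** Gradients are central differences; a step edge therefore
  responds on both of its sides, which would leave the sole template one
  pixel of vertical play. The edge map keeps only the dark-side pixel of
  each strong gradient, so edge pixels coincide with silhouette boundary
  pixels — the same convention as the bottom edge itself. A fixed default
  threshold (10 intensity units/px) is used instead of per-frame Otsu:
  Otsu's split of the full gradient histogram lands above the weak but
  genuine boundary between two overlapping shoes of similar darkness,
  which is precisely the edge recovery needs. Otsu remains available.
* **Chamfer ties.** Two near-identical shoes give the search an exact
  decoy: the stance sole is a copy of the swing sole template. The
  pipeline passes a constant-velocity prediction of the swing motion;
  the translation window is centred on it, candidate placements pay a
  small penalty (0.02 score units per pixel) for deviating from it, and
  residual ties resolve toward the prediction, then the smaller
  |rotation|. With no history the prediction is zero and the search is
  the plain symmetric one.
* **Degenerate inputs.** Constant frames yield "no dots found" rather
  than an error; masks below the ground line are clipped to zero
  clearance with a warning; an edge-free frame returns the untransformed
  template flagged low-confidence; strides with no interior minimum yield
  no estimate.
* **Tie conventions.** A first detection exactly on the image midline
  counts as right-to-left; equal-score laser-dot pairs prefer the higher
  summed peak, then the smaller column offset.

## The synthetic scene generator

Real deposited recordings and a trained detector are not required
anywhere: `render_scene()` builds seeded scenes with exact ground truth.
A scene contains a stationary stance shoe on the ground line, a swing
shoe translating with a smooth monotone ease while its clearance follows
a quintic built so that its derivative vanishes exactly at the stride
start and at chosen times $t_a < t_b < t_c$, with $h(t_a) = h_a$ and
$h(t_b) = h_b$ — so the true MFC is $h_b$ by construction and the curve
has exactly three inflection points. The height of the second peak
follows from the construction rather than being a free parameter. A
lower-leg band with two radially decaying laser dots appears while the
leg crosses the laser column; an illumination gradient emulates
shade-versus-sun site lighting; Gaussian intensity noise is added last,
after truth is recorded. Matching the generator's trajectory family to
the pipeline's model is deliberate: in the noise-free limit, parameter
recovery is exact up to rasterization, making end-to-end error an
unambiguous test quantity. A sinusoidal perturbation option
(`perturb_amp`) breaks that match for robustness checks.

Deliberate departures from a minimal "flat cartoon" scene, made because
they remove degeneracies real footage does not have: the two shoes have
different intensities (two real shoes rarely match exactly; a uniform
dark union would make the buried swing outline invisible to any edge
detector), and the outsole has a rocker — toe spring and heel bevel — so
the bottom edge is a distinctive arc rather than a horizontal segment
that would match any horizontal edge in the frame.

What the generator does **not** emulate: shoe texture and shading,
clothing, shadows, motion blur, compression artefacts, multiple
pedestrians, camera misalignment, and non-parallel lasers. Passing the
synthetic suite therefore demonstrates the correctness of the geometry,
state logic, matching, fitting and unit conversion — not detector
performance on real video, which is the job of the pluggable neural
backend and its own validation data.

Dataset-level draws (`generate_dataset()` / `draw_scene_specs()`) vary
direction (fair coin), true MFC uniform on [3, 30] px, shoe size ±10%,
site lighting (two shaded sites with gradient amplitude 8, one sunlit
with 30, mirroring a three-site deployment), and noise SD uniform on
[1, 5] — values chosen once as plausible for 8-bit outdoor footage.

## Problem sizes

The test suite and the acceptance evaluation use a four-fold
geometrically scaled scene (270 × 480, shoe 64 × 26 px, laser separation
40 px — `scene_spec_small()`): every quantity of interest is denominated
in pixels, so the scale factor cancels, and the reduced scenes keep a
full 40-scene evaluation within roughly a minute of CPU. The calibration
audit uses 50 seeded laser frames at 540 × 960 with separations drawn
from [60, 200] px; the end-to-end evaluation runs 20 scenes noise-free
and the same 20 geometries at noise SD 5.

## Known limitations

* The classical background-subtraction backend is a fixture tool; it
  assumes a static camera, an empty first frame, and silhouettes ≥ 40
  intensity units from the background. It makes no claim on real footage.
* Video container decoding (MP4/AVI) is out of scope; frames are read as
  PNG sequences, with extraction left to standard external tools.
* One pedestrian per clip; the state machine holds its state and warns
  if a third mask appears.
* Occlusion recovery is rigid (rotation + translation); it cannot follow
  sole deformation, and its translation grid quantizes recovery to 1 px.
* Automatic ground-plane detection and automatic clip cropping are
  intentionally not attempted; both are operator inputs.
* The quintic model assumes a complete, single swing in view; partial
  strides at the field-of-view edges are dropped rather than
  extrapolated.

## A worked example

```{r example, fig.width = 6, fig.height = 4}
spec <- scene_spec_small(seed = 7, h_b = 12)     # true MFC: 12 px
scene <- render_scene(spec)
truth <- scene$truth

res <- analyze_frames(scene$frames, truth$ground,
                      classic_backend(scene$frames[[1]]))
res$estimates[, c("stride_index", "frame_index", "d_px", "k_used", "mfc_mm")]

c(true_px = truth$mfc$d_px, true_mm = truth$mfc$mfc_mm,
  k_true = truth$k_true)

plot_stride(res$strides[[1]],
            locate_mfc(res$strides[[1]]),
            main = "Swing clearance and quintic fit")
```

The estimate agrees with the constructed truth to a fraction of a pixel;
frames recovered through the occlusion search are drawn as open circles.
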