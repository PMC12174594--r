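---
title: "Structural evaluation of predicted retinal OCT B-scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural evaluation of predicted retinal OCT B-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octeval)
```

## The evaluation problem

Generative models can translate a pre-therapeutic OCT B-scan of an edematous
macula into a predicted post-therapeutic scan. `octeval` asks a quantitative
question of such predictions: does the predicted scan carry the anatomy a
clinician would measure — central retinal thickness (CRT), maximal retinal
thickness, subretinal fluid (SRF) area, intraretinal cystoid fluid (IRC)
area — and does each quantity change in the same direction as on the real
follow-up scan?

The pipeline has five stages: (1) masks, gold or inferred, are reduced to the
four anatomical quantities; (2) each quantity's change relative to the
pre-therapeutic baseline is classified as a trend; (3) predicted and real
trends are cross-tabulated and summarized; (4) predicted and gold
measurements are compared with a normality-gated paired test and
Bland–Altman limits of agreement; (5) predicted scans are screened for
structural ruptures that would disqualify them from interpretation.

## Anatomy from masks

The stratification convention has class 1 spanning the ILM upper limit to
the RPE upper limit and class 2 the RPE upper limit to the choroid lower
limit, with row 0 at the vitreous side. Thickness is the per-column class-1
pixel count rather than a geodesic distance between traced contours: the two
are identical for simply connected bands, and counting is robust to mask
noise. CRT reads the profile at column `round(fovea_x * (width - 1))`,
rounding half away from zero so the column does not depend on the parity of
the image width.

Subretinal fluid thickens the retina, so SRF pixels — lying between the
neuroepithelium and the RPE upper limit — carry stratification label 1 and
count toward thickness, consistent with the class-1 definition above.

Areas default to raw pixel counts. The clinical report this framework
derives from prints CRT summary values that cannot be reconciled with any
plausible device pixel pitch, so no absolute calibration is assumed; the
trend framework is relative and therefore unit-free. A `pixel_geometry()`
(lateral pitch defaulting to a 9-mm scan over 1,024 columns) converts
thicknesses and areas to micrometres on request, and all trend labels are
invariant under any common rescaling — a property the test suite asserts.

## The trend rule

With threshold θ = 0.10, a quantity has *increased* when
`post > (1 + θ) · pre` and *decreased* when `pre > (1 + θ) · post`. These
margins are deliberately asymmetric (the decrease condition is
`post < pre / 1.1`, not `post < 0.9 · pre`), mirroring the clinical rule as
stated; the band between them is the tie zone. In the clinical protocol tie
cases were adjudicated by two retinal specialists; the package has no human
in the loop, so tie cases are labeled `no_change` with
`adjudication_needed = TRUE` and reported as a separate count (a strict
`tie_policy = "error"` is available). For fluid areas, absence both before
and after therapy (`both 0`) is `no_change` outright, and fluid appearing
from zero is an `increase`.

Trend tables for the clinical test set are 2-level (decrease/increase) for
the thickness quantities, because adjudication eliminated the tie zone
there, and 3-level for the fluid areas. The synthetic-cohort report uses the
3-level set for all four quantities, since tie-zone pairs genuinely occur
and nobody adjudicates them.

Presence dichotomies use a strict threshold: an area is "present" only when
strictly greater than `min_area` (default 0). Accuracy is the agreement
proportion (trace over total); sensitivity and specificity are computed over
the *real* positives and negatives. Confidence intervals are exact
Clopper–Pearson from beta quantiles. The exact method was chosen because the
boundary case — 0 successes in 4 trials — has the closed form
`1 − 0.025^(1/4) ≈ 0.602`, reproducing the printed CI bound digit for
digit; printed bounds for non-boundary cases differ from the exact interval
by up to 0.02, consistent with a different approximation having been used
there, and are not treated as replication anchors.

## Statistical protocol

Agreement between predicted and gold values uses the Shapiro–Wilk test *on
the paired differences* (not on each arm) at α = 0.05: normal differences go
to a paired *t*-test, otherwise a two-sided Wilcoxon signed-rank test with
zero differences dropped (the standard signed-rank convention). When every
difference is zero neither the Shapiro test nor either branch is defined;
the result is reported as degenerate with p = 1, which is the only honest
statement for identical samples. Limits of agreement use the sample
(n − 1) standard deviation and the 1.96 multiplier, and the within-LoA
fraction counts the closed interval. Two-sided p-values are assumed and
recorded throughout.

## The phantom generator

No clinical images are distributed with this framework, so the generator
produces what the evaluation needs and nothing more: a layered retina
described by three per-column boundary curves, a Gaussian foveal pit,
elliptical cysts strictly inside the class-1 band, parabolic SRF pockets
resting on the RPE, and a four-level piecewise-constant reflectivity image
(background 0.05, retina 0.55, sub-RPE band 0.35, fluid 0.12) under
unit-mean multiplicative gamma speckle. The reflectivities are configurable;
the defaults make fluid hypo-reflective and the sub-RPE band intermediate,
which is enough structure for a classical segmentation backend to have to
work for its result without requiring training.

The treatment effect is analytic: thickening in excess of a healthy baseline
(default 30 px on a 192-row scene — a thickness the scaling should not push
a retina below, since anti-VEGF resolves edema rather than thinning healthy
tissue) is multiplied by `thickness_scale`, cyst semi-axes by `cyst_scale`,
and SRF heights by `srf_scale`; cysts keep their relative axial position in
the band. Ground-truth change directions are therefore known exactly, and
each scene's `truth` slot is recomputed from its own rasterized masks, a
bookkeeping invariant the tests check against loop-based brute force.

The predicted-scan stand-in degrades the real follow-up scene: boundary
curves get a laterally smoothed displacement field (rescaled to the
requested marginal sd, so correlation length and magnitude are independent),
lesions are dilated or eroded with a disc kernel, the fovea annotation is
jittered, and a structural discontinuity — neuroepithelium, RPE, or entire
retina over a chosen column range — can be injected on demand so the quality
flags have something real to find. Default cohort degradation: boundary sd
1.5 px, one-pixel lesion erosion (predicted scans tend to understate fluid),
fovea jitter sd 0.01.

Cohort default ranges (scaled to the scene size from a 256 × 192 reference)
describe an edematous macula: band thickness 45–90 px against the 30-px
baseline, pit depth 6–16 px, 0–3 cysts, SRF in half of eyes, speckle 0.15,
and treatment scales `thickness_scale` ∈ [0.3, 1.3] and fluid scales
∈ [0, 1.2] — mostly improvement with occasional worsening, as in anti-VEGF
follow-up. These are the generator's study conditions, chosen once for
realism, not tuning knobs.

What the phantoms do *not* emulate: real speckle statistics and shadowing,
curved/tilted retinas, radial 16-line scan geometry, device file formats,
sublayer anatomy, or correlated multi-lesion pathology. Passing tests
therefore certify the *evaluation machinery* — measurement, classification,
tabulation, statistics — not segmentation performance on clinical OCT.

## The classical inference backend

The backend exists so the whole chain can run from images rather than gold
masks; it replaces trained detection/stratification/lesion models as the
measurement instrument, and any external backend producing the same mask
dialect can be plugged in.

On a lightly box-blurred image (3 × 3), per column: the ILM is the middle of
the first run of axial gradients above `gradient_threshold` (the blur
spreads a step edge over a short run whose midpoint sits on the true
boundary row); the choroid lower limit is the middle of the last strong
falling run; the RPE is placed by an exact change-point fit over the tissue
rows, minimizing misclassification against an intensity window
(`class2_level ± class2_tol`) that separates the sub-RPE band from
retina/fluid. Curves are median-smoothed over `smoothing_window` columns.
The fovea is the minimum of the median-smoothed thickness profile within a
central search band, ties broken toward the image center (a flat profile
thus returns the band center). Fluid candidates are class-1 pixels below
`fluid_threshold`; connected components smaller than `min_component_px` are
dropped, components touching the row directly above the RPE upper limit
become SRF, interior components IRC. `fluid_threshold = 0.30` sits near the
fluid/retina blur midpoint so component boundaries land close to the true
lesion contour (area error well under 15% for the default cysts).

Degenerate inputs are handled without exceptions: columns with no detected
tissue stay background, an all-background image yields an empty mask, and an
empty search band returns `NA` with a warning.

## Numerical conventions

* Rounding of continuous curves and the fovea column: half away from zero.
* Rasterization: class 1 occupies rows `[ilm, rpe)`, class 2 `[rpe,
  choroid)`; an ellipse covers the integer pixels satisfying
  `x²/a² + y²/b² ≤ 1`; SRF pockets have parabolic height profiles rounded
  per column.
* Ties in the RPE change-point fit resolve to the uppermost minimizing
  split; ties in fovea detection resolve toward the image center.
* Segmentation metrics: a class absent from both masks is undefined (`NA`)
  and excluded from the macro mean, avoiding 0/0; the macro average is
  unweighted over defined classes, and that choice is recorded in the
  object metadata since pixel-weighted averaging is an equally defensible
  reading.
* Determinism: scenes are pure functions of `(params, seed)` and cohorts of
  their spec; all randomness flows through the single master seed.

## Problem sizes

The shipped tests run phantoms at 128–256 columns, cohorts of 3–37 pairs,
100 random mask pairs for the brute-force oracle checks, 2,000 binomial
draws for CI coverage, 5,000 pairs for the Bland–Altman limit, and 400–500
replicates for the Shapiro-gate calibration — sizes chosen so the full suite
exercises every stage end-to-end in well under a minute of compute while
keeping Monte-Carlo error far below the asserted tolerances.

## Known limitations

* The qualified-image quality gate reduces to three discontinuity flags;
  other clinical defect types (e.g., repeated retinal structure) are not
  modeled.
* The backend's thresholds are calibrated to the phantom renderer's
  reflectivities; it makes no claim on clinical images.
* The macular-detection "accuracy" tolerance τ (default 0.02 of image
  width in `fovea_accuracy()`) has no canonical value and is exposed rather
  than inferred.
* Human-facing evaluations — authenticity grading, tie-zone adjudication —
  are out of scope by design; the package surfaces the flags instead.
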