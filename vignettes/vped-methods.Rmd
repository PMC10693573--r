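---
title: "Virtual-pathology endometrial dating: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-pathology endometrial dating: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vped)
library(dplyr)
```

## The problem

Endometrial dating estimates the day of the menstrual cycle from the state of
the uterine lining. The classical gold standard is histopathology of a biopsy
section; hormones, ultrasound and the patient's own calendar are the usual
alternatives. `vped` implements a different route: magnified images of the
endometrial *surface* show gland outlets ("pores", dark roughly-elliptical
openings) and superficial blood vessels, and the *statistical ensembles* of
their morphometric features evolve systematically through the secretory phase
(standard days 15–28). Dating then becomes a distribution-matching problem:
compare a specimen's feature distributions against per-day reference
distributions and pick the day that matches best.

The package covers the full chain — synthetic tissue generation, segmentation,
morphometry, ensemble modeling, day inference, the traditional reference
datings, and concordance analysis — so the method can be developed and tested
end to end without clinical material.

## Feature ensembles and the Weibull cPDF model

Each tissue element contributes a feature vector: pores have area (µm²,
equivalently the radius of the equal-area disc), length (maximum Feret
diameter, a proxy for deviation from circularity), rim curvature (mean
absolute curvature, 1/µm) and rim tortuosity (perimeter over convex-hull
perimeter, dimensionless ≥ 1); vessels have mean diameter and segment length
between branch points (µm). For one specimen, all elements from its ~20
images form one ensemble per feature, and the cumulative distribution of a
feature is modeled by the three-parameter Weibull function

$$We(x) = 1 - \exp\!\left[-\left(\frac{x-b}{\lambda}\right)^{\gamma}\right],$$

where the location $b$ is the smallest attainable or detectable value of the
feature (set by biology and by the optical resolution at the given
magnification), the scale $\lambda$ stretches the distribution, and the shape
$\gamma$ controls whether the density piles up against the resolution limit
($\gamma < 1$) or has an interior mode ($\gamma > 1$).

**Location policy.** $b$ is *not* fitted by default. Estimating a location
jointly with scale and shape is notoriously unstable on skewed samples, and
physically $b$ is a property of the instrument/feature, not of the specimen.
`fit_weibull()` pins $b$ (policy `"fixed"`, default 0 in feature units, set it
to the resolution limit of your setup) and estimates $(\lambda, \gamma)$ by
maximum likelihood via the standard one-dimensional profile equation for the
shape; if the profile solve fails, a least-squares fit of the model cPDF to
the empirical step cPDF is used and flagged in the `method` column. An
explicit `"min_offset"` policy (location just below the sample minimum) is
available for exploration.

## Comparing distributions: the weighted two-sample KS test

All distribution comparisons use the two-sample Kolmogorov–Smirnov statistic
$D$, the sup-distance between the two weighted step cPDFs, evaluated exactly
over the union of support points. P-values come from the asymptotic
Kolmogorov distribution at the effective size $n_1 n_2/(n_1+n_2)$, where each
$n$ is the sample's weight sum. Weights matter because per-day reference
distributions are *pooled*: all patients sharing a (histology-labelled) cycle
day contribute their normalized histograms weighted by their effective
element counts, so a patient with more detected elements counts more. The
pooled step cPDF is carried as the concatenated, reweighted element values,
which reproduces the weighted-average histogram exactly on the shared bins.
Histogram axes are fixed per feature (24 bins spanning the pooled data up to
its 99th percentile) so that per-day histograms are directly comparable.

## Day inference

`score_sample()` compares a sample's pore-feature distributions to every
dictionary day and combines the per-feature KS p-values with equal weights
(arithmetic mean; a geometric-mean variant is available — the combining
algebra is a genuinely open choice and the arithmetic mean is the most
literal reading of "equal weights"). Blood-vessel features can be added via
`feature_set`, but the default is pores only.

The raw profile is then smoothed with a five-day top-hat window
(`tophat_convolve()`), encoding the prior that neighbouring secretory days
resemble each other, and normalized to sum one. At the boundaries of the day
range the window is truncated; the default treats the truncated window as a
plain convolution (sum), which turns an interior delta into a plateau of five
equal values and an edge delta into a shorter plateau. The alternative
(`edge = "mean"`, renormalizing by the actual window size) preserves a
uniform profile exactly but systematically drags near-edge peaks outward to
the range edge, which measurably hurts day recovery two to three days from
the boundary; the sum variant instead makes the two extreme days (15 and 28)
unreachable as argmax — their estimates land two days inward. We consider the
second artefact the lesser one (the extreme days are also the least
interesting clinically) and default to `edge = "sum"`.

`infer_day()` takes the argmax; exact ties are resolved deterministically by
the score-weighted centroid of the maximal plateau, rounded to the nearest
integer day. No sub-day interpolation is attempted — dating is reported in
whole days.

**Accuracy bookkeeping.** `day_confusion_matrix()` compares every pair of
dictionary days (mean KS p-value over features), smooths the matrix with a
3×3 Gaussian kernel and row-normalizes to a maximum of one, giving a relative
probability of assessing day $j$ when the truth is day $i$. The per-day ± error
is the half-width of the contiguous region around the diagonal where this
relative probability stays ≥ 0.5, reported separately toward each side. A
Gaussian kernel is used for the smoothing: a 3×3 Sobel kernel is a derivative
operator and cannot smooth, so it is not a meaningful option here.

## Traditional reference datings

* **Histology** is ingested as-is (consensus day plus asymmetric error); it is
  already expressed on the standard 28-day calendar by its own criteria.
* **Patient report** counts days from the reported first day of the last
  menses to the sampling date (inclusive) and renormalizes by the reported
  average cycle length. The reported cycle-length variance propagates through
  the local slope of the renormalization map.
* **Hormones**: a four-hormone serum panel (estradiol, progesterone, LH, FSH)
  is dated by minimizing $\chi^2(d) = \sum_h (x_h - \mu_h(d))^2 /
  (\sigma_{\mathrm{meas},h}^2 + \sigma_{\mathrm{ref},h}^2(d))$ over the days
  of a 30-day reference cycle anchored at the LH peak, with the ± error taken
  as the span of days within $\Delta\chi^2 \le 1$ of the minimum (the
  single-parameter confidence convention). Hormones with zero total variance
  on a day are excluded from that day's sum with a warning.
* **Ultrasound thickness** is carried through reports but never converted to
  a dating.

**Cycle renormalization.** Cycles that are not 28 days long are mapped onto
the standard calendar by rescaling the proliferative phase to 14 days while
holding the luteal phase fixed at 14 days: with ovulation assumed at
$O = L - 14$ for cycle length $L$, $d' = 14\,d/O$ for $d \le O$ and
$d' = 14 + (d - O)$ otherwise, rounded to two decimals. The fixed-luteal
piecewise-linear map is the standard convention; it is isolated in
`renormalize_day()` so an alternative can be substituted in one place. The
same map (with $L = 30$) converts the hormone reference's day grid to the
standard calendar.

## The synthetic tissue generator

The generator exists so that every stage has ground truth. It emulates three
layers of a dating study:

1. **Feature ensembles** (`default_trajectories()`, `sample_features()`):
   for each feature and secretory day, a Weibull parameter triple; samples are
   drawn by inverse transform, $x = b + \lambda(-\ln U)^{1/\gamma}$. The
   default parameter table is *synthetic*: no quantitative per-day parameter
   values are published for real tissue, so the table encodes the qualitative
   regimes that are described for the secretory phase — pore-area
   $\gamma < 1$ throughout with a mid-phase dip as pores merge; pore-length
   $\gamma > 1$ only in the peak-merger window (≈ days 20–22); rim curvature
   and tortuosity tracking the same merger narrative; vessel-diameter
   $\gamma > 1$ throughout with a dip near day 19 — while the scale
   parameters drift smoothly (pore area grows ≈ 20 %/day as pores merge).
   The magnitude of the per-day drift was calibrated once, at design time, so
   that adjacent days are statistically distinguishable at a few hundred
   elements per feature — the regime the dating pipeline is designed to
   operate in — and then frozen. Features of an element are drawn
   independently; real pores surely have correlated area/length/tortuosity,
   and the renderer reintroduces part of that correlation geometrically (see
   below).

2. **Scenes** (`render_image()`): an 800 µm × 800 µm region of interest at
   2 µm/px by default (400×400 px, single channel). Pores are rendered as
   darker blobs: an ellipse carrying the sampled area and max-Feret length
   (capped at a physical aspect ratio of 3.5 — the sampled length is
   otherwise unconstrained by the sampled area), rim-perturbed by a radial
   Fourier series whose amplitude is tuned to the sampled tortuosity by a
   two-step fixed-point calibration, then rescaled to the exact target area.
   Rendered curvature is therefore *emergent* (it follows from size and rim
   perturbation) rather than matched to its sampled value. Vessels are darker
   curvilinear bands of the sampled diameter along a smooth random-walk
   centerline. Placement is rejection sampling, largest pores first;
   pore–pore overlap is never allowed, while the pore–vessel clearance
   relaxes stepwise and vessels may ultimately pass beneath pores (pores are
   stamped opaquely last, so pore shapes stay intact). Gaussian background
   texture (sd 0.02) plus a light blur gives soft rims; an optional defocus
   quadrant (Gaussian blur, recorded in the truth in-focus mask) exercises
   focus gating. Scene truth stores every polygon and centerline in µm with
   the features *measured from the generated geometry*.

   Because the mean pore area grows through the phase, a fixed pore count per
   image would push the filling factor toward geometric infeasibility at late
   days; `pores_per_image()` scales the count to a target filling factor of
   6 % within bounds [15, 50].

3. **Cohorts** (`generate_cohort()`): per patient, a true day, a cycle length
   (integer N(28, 1.8²) clipped to 25–35), consistent last-menses/sampling
   dates with reporting noise (sd 1 day), a histology day drawn from a
   discrete kernel (P(0) = 0.6, P(±1) = 0.15, P(±2) = 0.05 — a ±1-day scatter
   scale), a hormone panel from the reference profile with noise scaled by
   the tabulated variance, an endometrial thickness (never used for dating),
   and either a direct feature table or rendered scenes. All randomness is
   seed-reproducible.

The shipped hormone reference (`hormone_reference()`) is likewise synthetic —
the assay manufacturers' tables are proprietary — with textbook shapes
(biphasic estradiol, sharp mid-cycle LH surge at day 16 of the 30-day
reference cycle, luteal progesterone plateau) and mild baseline drifts so no
two days share a mean vector. The χ² machinery is table-agnostic: any CSV
with columns `day, hormone, mean, variance` can be substituted.

**What passing tests do and do not show.** The generator produces clean,
well-separated, independently-drawn features on a uniform background. Success
on it demonstrates that the pipeline is *correct* (each stage recovers what
the previous stage encoded) — not that real endometrium carries this much
day-to-day signal, nor that the classical segmentation pipeline survives
uneven illumination, mucus, blood, or staining variation. Those questions
need clinical images.

## Segmentation: design and numerical choices

No segmentation algorithm is prescribed by the problem; the package uses a
deterministic classical pipeline, fully parameterized in
`segmentation_config()`:

* **Focus gating**: sliding-window (21 px) variance of the Laplacian
  response, thresholded at 0.15× the image's robust noise-level Laplacian
  variance (squared scaled MAD). Referencing the noise level — rather than a
  quantile of the local variances — keeps texture-only background in focus
  while defocused regions, whose high-frequency content is suppressed, fall
  below threshold. Morphological closing-then-opening (disc 9, border-padded)
  cleans the mask. A constant image has no focus evidence and yields an empty
  mask.
* **Candidate extraction**: union of an adaptive threshold (local mean over
  31 px + 0.1 offset, on the inverted image) and a global threshold (median
  background − 0.15); the global one catches the interiors of blobs larger
  than the adaptive window. Holes are filled; components labelled.
* **Pore/vessel classification** is per component, by shape: a component is a
  vessel if it is elongated (Feret²/area ≥ 6 — a band of length L and width w
  scores ≈ L/w) *and* its local width (2× distance transform along its
  skeleton) is nearly constant (CV < 0.4), or if it is extremely elongated
  (≥ 12) regardless; it must also carry a multiscale ridge (Hessian
  tubeness) response. Width constancy is the discriminating insight: strongly
  elongated pores exist, but their width varies along the axis, while vessels
  are bands of near-constant caliber.
* **Pores**: outer contours of pore-classified components, filtered by area
  (≥ 3 px² — the digitization floor, chosen so pores at the generator's
  20 µm² location survive at 2 µm/px — and ≤ 5000 px²), compactness
  (area/Feret² ≥ 0.12, just below the 3.5-aspect-ellipse value) and solidity
  (≥ 0.4, loose because merged and wiggly pores are real objects, not
  artefacts; merged pore candidates are deliberately *not* split). The
  reported area is the mean of the pixel count (which overestimates a dark
  blob by its blur halo) and the contour shoelace area (which undercuts the
  boundary pixels' outer halves); this half-pixel boundary correction is
  close to unbiased, which matters because the location parameter of the
  area ensemble sits near the digitization floor.
* **Vessels**: Zhang–Suen thinning of the vessel components; the skeleton is
  turned into a pixel graph (4-adjacency plus only those diagonal links not
  already carried by a shared 4-neighbour — this collapses the staircase
  patterns thinning leaves along diagonals), branch points are nodes of
  degree ≥ 3, and the segments between splits are the connected paths after
  branch-point removal, each at least 8 px long. Per-point width is 2× the
  distance-transform value along the centerline.
* A detection quality score (mean boundary gradient contrast) is attached but
  not used for filtering by default.

2X and 4X magnification sets are collated as separate partitions of a
specimen ensemble and never mixed: features are physical (µm-based) so the
axes agree, but the resolution limit — and hence the location parameter $b$ —
differs.

## Evaluation sizes

The test-suite and the acceptance script evaluate the pipeline at sizes
chosen to exercise the statistics meaningfully on one CPU: Weibull recovery
at n = 2000 over 50 replicates; the segmentation benchmark on 50-pore,
10-vessel scenes over 8–20 seeds; day recovery at 100 trials per day with 300
elements per feature against a dictionary pooled from 3 patients × 1000
elements per day; the image-to-dating study on a 40-patient cohort with four
images per patient and leave-one-out dictionaries labelled by (noisy)
histology. Leave-one-out is the honest mode: a patient never contributes to
the reference it is scored against.

## Known limitations

* The trajectory table and hormone reference are synthetic calibrations, not
  estimates of clinical values; absolute day-recovery rates transfer to real
  data only insofar as real ensembles separate as strongly.
* Features are sampled independently per element; real cross-feature
  correlation is only partially reintroduced by the renderer.
* The day grid is integer and the secretory range fixed at 15–28 by default;
  proliferative-phase dictionaries would need their own calibration.
* Overlapping fields among the images of one specimen are treated as
  independent samples; no de-duplication of elements seen twice is attempted.
* The two extreme dictionary days are structurally biased inward by the
  default top-hat edge handling (see above).
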