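# vped — virtual-pathology endometrial dating

`vped` estimates the menstrual-cycle day of an endometrium from magnified
images of its luminal surface. On such images the outlets of endometrial
glands appear as dark, roughly elliptical pores, and superficial blood
vessels as dark curvilinear bands. Through the secretory phase (standard
days 15–28) the *statistical ensembles* of their morphometric features —
pore area, length, rim curvature, rim tortuosity; vessel diameter and
segment length — evolve systematically, so dating can be posed as a
distribution-matching problem. The package is aimed at reproductive-medicine
researchers and image-analysis developers who want to build, calibrate and
stress-test this kind of dating pipeline without clinical material.

## The model in brief

For one specimen, every feature's cumulative distribution (cPDF) is modeled
by the three-parameter Weibull function

    We(x) = 1 − exp(−((x − b)/λ)^γ),

with location *b* (smallest attainable/detectable value), scale *λ*, and
shape *γ* (γ < 1: density piled against the resolution limit; γ > 1:
interior mode). A per-day reference dictionary pools the feature
distributions of all patients sharing a (histology-labelled) cycle day,
weighted by their element counts. A new specimen is dated by computing, for
each candidate day, the two-sample Kolmogorov–Smirnov p-value per pore
feature against that day's pooled distribution, combining the four p-values
with equal weights, smoothing the resulting day profile with a five-day
top-hat window, and taking the most probable day. Per-day ± errors come from
a KS confusion matrix between the dictionary days. Traditional reference
datings (χ² hormone dating on a 30-day LH-anchored reference, patient-report
day counting, histology pass-through — all renormalized to the standard
28-day calendar) and concordance statistics (Pearson and adjusted R,
regression, systematic-bias sign test) are included for comparison studies.

A synthetic tissue generator closes the loop: per-day Weibull parameter
trajectories → feature samples → rendered images with exact ground truth →
whole cohorts with patient reports, hormone panels and noisy histology. See
`vignette("vped-methods")` for the models, parameter semantics, and design
decisions.

## Worked example

Build a dictionary from a synthetic cohort, then date a fresh day-21 sample:

```r
library(vped)
library(dplyr)

co <- generate_cohort(42, noise = cohort_noise_zero(), seed = 11,
                      elements_per_sample = 1000)
labels <- co$patients |> transmute(patient, day = true_day)
dict <- build_dictionary(co$features, labels,
                         feature_set = pore_feature_names())
dict
#> <vped_dictionary> days 15-28 (14 days), features: pore_area, pore_length, pore_curvature, pore_tortuosity

sample <- sample_features(day = 21, n_elements = 300, seed = 42)
conf <- day_confusion_matrix(dict)
vped_date(sample, dict, confusion = conf)
#> # A tibble: 1 × 4
#>     day err_lo err_hi method
#> * <int>  <int>  <int> <chr>
#> 1    21      1      1 vped
```

The inferred day is 21 — the day the sample was generated for — with a
±1-day error band read off the dictionary's confusion matrix. The ensemble
model itself is available directly:

```r
fit_weibull(filter(sample, feature == "pore_area")$value, b = 20)
#> # A tibble: 1 × 6
#>       b lambda gamma method sup_distance     n
#>   <dbl>  <dbl> <dbl> <chr>         <dbl> <dbl>
#> 1    20   422. 0.510 mle          0.0317   300
```

i.e. the day-21 pore-area ensemble is strongly left-skewed (γ ≈ 0.51 < 1)
with scale ≈ 422 µm², and the fitted cPDF sits within sup-distance 0.032 of
the empirical one. `autoplot()` methods exist for empirical distributions,
day profiles, confusion matrices and method comparisons; `tidy()`/`glance()`
for fits and comparisons. The image pipeline is exercised the same way:
`generate_cohort(..., images = TRUE)` → `segment_cohort()` →
`loo_date_cohort()` dates every patient against a dictionary built from the
others.

A thin command-line wrapper for dating a feature CSV against a serialized
dictionary lives at `inst/cli/vped.R`.

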