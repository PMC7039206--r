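---
title: "Models and methods behind invquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind invquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invquant)
```

`invquant` re-implements the quantification stack used to characterize
intracellular nanovesicles (INVs) — the ~30-nm uncoated transport
vesicles marked by TPD54 — across seven assays. This vignette explains
each model, its assumptions, the tunable parameters, and the numerical
and design choices made where the procedure left them open. No empirical
number is stated here that the test suite or the acceptance script does
not itself compute.

## RUSH transport kinetics

A RUSH experiment releases a fluorescent cargo from the ER and follows
the fraction of total cell fluorescence at the Golgi over time. The
rising phase is modeled by the logistic

$$f(x) = y_0 + \frac{y_{max} - y_0}{1 + (x_{1/2}/x)^n},$$

fitted by least squares from the first frame to two frames past the
trace maximum (`fit_logistic()`). The model is undefined at $x = 0$ (its
right limit is $y_0$), so a $t = 0$ sample is excluded from the fit and
logged rather than offset. Initialization is $y_0$ = first value,
$y_{max}$ = window maximum, $x_{1/2}$ = first half-range crossing,
$n = 4$ with bounds $n \in (0, 50]$ — robust sigmoid defaults; the
original procedure does not state its starts. The post-peak decline is
an ordinary least-squares line $f(x) = a + bx$ from the trace maximum to
the last frame (`fit_tail_line()`).

Three half-times follow (`transport_halftimes()`):
$t_{1/2}(\mathrm{ER{\to}Golgi}) = x_{1/2}$;
$t_{1/2}(\mathrm{ER{\to}PM})$ is the time at which the tail line crosses
the logistic half-maximum value $(y_0 + y_{max})/2$; the Golgi transit
time is their difference. The source procedure's wording ("the
corresponding y value for $x_{1/2}$ was used") admits readings; the
crossing-of-the-half-maximum interpretation is adopted because it is the
only one that uses both the stated y value and the stated line fit. A
non-declining tail ($b \ge 0$) or a crossing before $x_{1/2}$ leaves the
ER-to-PM time flagged as undefined rather than fabricated.

## Rerouting and FRAP kinetics

Knocksideways rerouting traces are averages over ten 10×10-px
mitochondrial ROIs and several cytoplasmic ROIs (`roi_mean_traces()`).
Photobleaching is corrected by the simple-ratio method, formalized here
as a first-frame-anchored reference ratio,
$\mathrm{corr}(t) = y(t)\,r(t_0)/r(t)$ — the method is named but not
defined in the source; this form is a no-op for a constant reference and
leaves the first frame untouched. Rerouting onset is fitted with
$y(t) = y_0 + A\,(1 - e^{-(t-t_{event})/\tau})$ with free amplitude
sign, so rising mitochondrial and decaying cytoplasmic signals share one
model. The reported $\chi^2$ is the residual sum of squares divided by
$N - k$ (the original statistic is not defined).

FRAP traces are normalized as
$r = (F_{roi} - F_{bg})/(F_{cell} - F_{bg})$ — correcting for the
fluorescence destroyed by the bleach pulse — then scaled so the first
post-bleach frame is 0 and the mean of the first five pre-bleach frames
is 1. Whether the ratio uses whole-cell mean or integrated intensity is
immaterial for a fixed cell footprint; the mean is used. Recovery is
fitted with a double exponential
$y(t) = M[f(1-e^{-t/\tau_{fast}}) + (1-f)(1-e^{-t/\tau_{slow}})]$;
$\tau_{fast} \le \tau_{slow}$ is enforced by reordering after the fit,
which removes label switching without constraining the optimizer.
`t_half` solves $y(t) = M/2$ numerically. When the optimizer reports
singular convergence (the two components collapse onto a ridge, e.g.
when the true components are indistinguishable at the given noise), the
ridge solution is accepted with a `relaxed_convergence` flag; if no fit
is obtained at all, the function falls back to a single exponential with
an explicit flag.

## EM vesicle-capture morphometry

Scenes arrive as 5-column `object contour x y z` text (the
`model2point` export of manual IMOD segmentation). The 5-column dialect
is required because objects and contours must be distinguished; object
indices carry no semantics, so the reader demands an explicit
index-to-label mapping rather than assuming a layout for the deposited
archive. Coordinates stay in pixels until morphometry scales them to nm.

* **Diameter** — twice the mean polar radius of the contour about its
  point centroid. The centroid stands in for the undefined "vesicle
  center"; contours are near-circular and densely sampled, where the
  centroid and the true center coincide to first order.
* **Perimeter** — summed closed polyline length of all mitochondrial
  contours, in µm.
* **Abundance** — vesicle contours per µm of that perimeter.
* **Decorated fraction** — the fraction of the mitochondrial boundary
  within 15 nm of a vesicle outline. The primary implementation is
  exact: for each boundary segment, the parameter intervals lying inside
  a vesicle polygon or within 15 nm of one of its edges (capsule
  regions, solved as linear and quadratic inequalities) are unioned and
  measured analytically. The test-only reference is a 0.5-nm
  arc-length sampling of the boundary with pointwise distance tests —
  deliberately the raster-flavored computation the original analysis
  used ("an area … dilated by 15 nm"), with a ≤2% equivalence band
  between the two accepted as the raster/exact discrepancy.

Vesicles touching an image border are kept (the source is silent) and
the decorated fraction is monotone in the dilation radius, which the
suite checks as a property.

## STORM spot sizing

Reconstructed localization-count images are searched for local maxima
by topographic prominence (threshold: strictly greater than 5 counts,
matching the detection setting of the original pipeline). Prominence
follows the topographic definition — peak height above the highest
saddle to any higher peak, with the border treated as $-\infty$ so the
global maximum is always retained; an exhaustive flood-fill oracle in
the test suite defines correctness, since the external tool's exact
behavior is not normative. Plateau maxima report the plateau centroid.

Each detected coordinate seeds a least-squares fit of
$f(x, y) = z_0 + A\exp[-((x-x_0)^2/2\sigma_x^2 + (y-y_0)^2/2\sigma_y^2)]$
over a 41×41-px window, and the spot width is
$\mathrm{FWHM} = 2\sqrt{2\ln 2}\,\sigma_y \cdot \text{pixel size}$ —
$\sigma_y$ alone, as in the original reporting; a geometric-mean option
exists but defaults off. Fits with $\sigma < 0.2$ px (unidentifiable
from pixel-center samples) or $\sigma >$ window/2 (background
absorption) are excluded as non-converged, and only converged fits enter
the FWHM histogram and the density (spots per 10 µm², over a
user-supplied cell footprint; the original cell delimitation is not
stated). The default reconstruction pixel size is 16 nm and
config-overridable, as the original value is not printed.

## Flicker and dispersal metrics

The flicker metric takes a 50×50-px, 30-frame excerpt, divides each
frame by its own mean (removing gain and first-order bleaching — the
source does not say whether frames were bleach-corrected first, and this
normalization makes the question moot to first order), computes the
per-pixel temporal variance with the $n-1$ estimator, and reports the
mean of the 50×50 variance matrix. Excerpt placement is explicit or
seeded, never silently centered.

Golgi dispersal is the convex-hull area of thresholded trans-Golgi
marker coordinates divided by the cell area. The threshold (default:
95th intensity percentile) is a documented configuration step reported
alongside the metric, since the original value is unstated. With signal
points taken at pixel centers the hull of a fully filled convex mask is
smaller than the mask's pixel area by a half-pixel rim, so "dispersal =
1" holds only in the fine-resolution limit; the suite asserts > 0.95 on
a 100×100 mask.

## Screen statistics

The per-cell statistic is the mitochondrial intensity ratio
$F_{post}/F_{pre}$. Effect sizes versus the GFP control are differences
of group mean ratios with 95% bias-corrected and accelerated (BCa)
bootstrap intervals, re-implemented rather than delegated: $10^5$
resamples by default (the original count), bias term
$z_0 = \Phi^{-1}(\#\{\hat\theta^* < \hat\theta\}/B)$, acceleration from
jackknife skewness over the pooled leave-one-out statistics. Resampling
is stratified by trial when labels are present, respecting the
experimental structure, and values are sorted within strata first so the
interval is exactly invariant to row order. Zero-variance groups or a
one-sided resample distribution trigger a flagged percentile fallback.
A construct is a "hit" when the pooled interval excludes 0.

The many-to-one tests against GFP are implemented as a max-t permutation
test (Welch t per construct, null from permuting cell labels, each
p-value read off the family maximum). This deviates in method — not in
intent — from the named parametric test: it is exact for the small,
non-Normal per-trial samples of the screen and converges to the
parametric answer under exchangeability. Both per-trial and pooled
analyses are emitted, since the original four-level significance
coloring (hit in one, two, three trials, or pooled only) is a
presentation rule over those same numbers.

## The synthetic world

Every generator is a pure function of its parameters and a seed
(`synth_config()`), stores its ground truth beside the data, and
round-trips through the package's writers/readers. Noise models are
chosen to match typical fluorescence statistics, since the source states
none: additive Gaussian for traces (SD = `noise_sd` on the fraction
scale for RUSH, `noise_sd` × |amplitude| for a.u. traces, so SNR 10
means `noise_sd` = 0.1) and Poisson for count images and stacks. Other
stated-world defaults: vesicle diameters Normal(30, 9.4²) nm truncated
at one pixel radius; captured vesicles placed with boundary gaps drawn
uniformly below 15 nm and uncaptured ones ≥ 100 nm away; localization
spots σ = 24 nm on 16-nm pixels (a ~30-nm-class object under the
reported FWHM identity); screen tables with lognormal per-cell baselines
and ratio scatter (`cell_sd` = 0.25).

What the generators do **not** emulate: optics (no PSF beyond the single
Gaussian per spot), raw STORM frames, 3D EM volumes (profiles are 2D
sections, as in the assay), cell-to-cell heterogeneity beyond the
lognormal scatter, and correlated noise. A green synthetic test
establishes that the estimator inverts its own forward model at
realistic noise — not that the biological values are reproduced; the
deposited-data golden checks exist for that and require the archive
(they fail with instructions when it is absent, see
`tests/testthat/test-acceptance.R`).

One calibration note: the BCa coverage check follows its stated
construction (two Normal groups shifted by 0.5, n = 100 cells per
group), where the implementation measures ~95% coverage. On small
(n ≈ 75), lognormally scattered tables the same intervals measure ~93%
— the known finite-sample behavior of BCa on skewed data, not an
implementation artifact; the permutation tests are exact by
construction at any n.

## Numerical choices, degeneracies, limits

* All nonlinear fits use bounded `port` least squares with jittered
  restarts; every failure mode is a typed error or an explicit flag —
  nothing is silently imputed.
* Interval arithmetic in the decorated fraction merges closed intervals
  with exact endpoints; the only tolerance in the EM stage is the
  1e-300 guard against zero-length edges.
* The TIFF codec is a deliberate minimal baseline subset (uncompressed
  little/big-endian grayscale, 8/16-bit unsigned or 32-bit float,
  multi-page) written for this package because no TIFF reader exists in
  the supported dependency set; compressed or multi-sample files are
  rejected loudly.
* Times must be strictly increasing; duplicate timestamps are an error,
  missing values are dropped with a counted warning — the one documented
  deviation from strict-by-default parsing.
* RUSH traces peak where the logistic reaches 99% of its plateau before
  the linear decline begins; this reproduces the rise-then-fall shape
  without modeling PM delivery explicitly, and the 0.99 constant is the
  generator's definition of "peak", not a fitted quantity.
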