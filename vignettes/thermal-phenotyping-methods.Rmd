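---
title: "Methods: canopy-temperature phenotyping and logistic grain filling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy-temperature phenotyping and logistic grain filling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermofill)
```

## Overview

`thermofill` turns a thermal-phenotyping field protocol into a tested
pipeline: plot-level canopy temperature (CT) from calibrated temperature
rasters, spatial normalization against neighbouring plots, multi-season
classification of lines into cold/warm/mediate temperature types, and a
logistic model of thousand-grain-weight accumulation whose derived
parameters are related to CT by correlation panels and group contrasts.
Because the field measurements behind such studies are rarely published,
every stage is exercised on synthetic data with known ground truth; this
vignette records the models, the defaults, and the design decisions that
were genuinely open.

## CT extraction

A `thermal_frame` is a single-band matrix of temperatures in °C.
Atmospheric and emissivity correction are treated as already applied by
the acquisition software: no radiometric model is attempted, because
vendor tools perform this step and publish no model to reproduce.  Plot
regions are axis-aligned rectangles with 0-based, half-open pixel bounds
— hand-drawn field ROIs are irregular, but rectangles exercise the same
averaging logic and make region-disjointness testable.  The plot mean is
the plain arithmetic mean of unmasked, non-`NaN` pixels; no trimming,
since the mask replaces the manual exclusion of undesirable areas.  Soil
masking is a threshold rule (`apply_soil_mask`): soil radiates several
degrees hotter than a transpiring canopy at midday, so pixels above the
threshold are excluded, and a plot losing *all* its pixels is an error
naming the plot rather than a silent `NaN`.

Rasters are stored as single-strip uncompressed little-endian TIFFs with
IEEE-float samples, written by the package itself (`write_frame`):
32-bit float is the natural container for °C values, round-trips
bitwise for 32-bit inputs, and preserves `NaN` sensor dropouts.  Reading
uses `tiff::readTIFF`, which accepts this sample format; integer or
multi-band rasters are rejected as format errors.

## Neighbour normalization

For plot $p$ with neighbour set $N(p)$,
$\mathrm{rel}(p) = \mathrm{CT}(p) - \frac{1}{|N(p)|}\sum_{q \in N(p)}
\mathrm{CT}(q)$, computed per date.  Any additive effect shared by a
plot and its neighbours — a warmer year, a cloudier afternoon — cancels
exactly, which the tests assert to 1e-10 after shifting all CTs on a
date by arbitrary constants.

Two decisions here were open:

* **Adjacency geometry.** "Six neighbouring plots" does not pin down a
  geometry.  We use the hex-like set {E, W, N, S, NE, SW} on the
  planting grid, which is symmetric by construction and truncates at
  field edges.  Crucially the adjacency ships as *data* in
  `layout.yaml`, so any other geometry is a data change, not a code
  change.
* **Order of averaging.** Whether replicate plots are averaged before or
  after the spatial subtraction is not dictated by the method.  The
  default normalizes per plot and averages replicates afterwards,
  because the confounder being removed is spatial and acts on plots;
  the alternative (`order = "line"`) is exposed and coincides with the
  default on noiseless balanced fields.

Relative CT is not clipped: the −2 to 2 °C range often quoted for such
data is an observation, not a transform.

## Temperature-type classification

Per line and season, the ordinary least-squares slope of relative CT on
the day index summarises the trend, and the season mean summarises the
level.  A line is **cold-type** iff slope $< -\varepsilon$ *and* mean
$< 0$ in every season; **warm-type** iff slope $> +\varepsilon$ and mean
$> 0$ in every season; otherwise **mediate** — including the
characteristic case of a trend that flips sign between years.  Requiring
both conditions is the conservative reading of selection "by trends and
averages"; $\varepsilon$ defaults to 0.01 °C/day so that numerically
near-zero slopes never force a cold/warm call.  "Decreasing trend" could
also be read as monotonicity; we use slope sign with a tolerance, and
flag that as our reading.

## Logistic grain filling

Thousand-grain weight follows $y(t) = k/(1 + a e^{-bt})$ with $t = 0$ at
27 days after anthesis ($k$ g: ceiling weight; $b$ 1/day: steepness).
Fitting is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`)
started from a log-linearisation: with $k_0 = 1.05\max y$,
$\ln(k_0/y - 1)$ is regressed on $t$, giving $b_0$ from the slope and
$a_0$ from the intercept; a coarse multi-start grid is the fallback.  A
lower bound $k \ge 0.5 \max y$ keeps the optimiser in the model class.
$R^2 = 1 - SSE/SST$ is reported and fits are screened at $R^2 > 0.95$;
non-sigmoid data fail the screen rather than being accepted.

Derived parameters:
$C_0 = k/(1+a)$, $V_{max} = kb/4$ (the rate at the inflection
$t^* = \ln a / b$), $V_{mean} = kb/6$, and the end time $T$ solving
$y(T) = 0.96k$, i.e. $T = \ln(24a)/b$ since $100/96 - 1 = 1/24$.  The
printed form of the end-time formula in the field literature is
bracket-ambiguous; we implement the form consistent with the defining
96% statement and verify it against a root-finding oracle to 1e-8.  The
active filling period has no standard closed form; we define $D = 6/b$,
the unique duration making $V_{mean} = k/D$ consistent with
$V_{mean} = kb/6$, and flag it as an inference.  "Late grain
accumulation" is ambiguous between the weight reached at $T$ (which is
$0.96k$ by construction) and the remainder $k - y(T) = 0.04k$; both are
computed, the literal reading is the default (`y_definition`).

## Association reporting

Correlation panels are Pearson throughout (the reported quantities are
linear associations with parametric stars), with two-sided p-values from
the $t$ transform on $n-2$ df, pairwise-complete deletion, and stars at
p < 0.05/0.01/0.001.  Zero-variance or <3-pair cells are undefined
(`NA`), never 0.  No multiple-testing correction by default, matching
the per-cell star convention; Benjamini–Hochberg is available.  Group
contrasts use Welch's test because temperature-type groups can be as
small as two lines, making pooled variances indefensible; percent
difference is relative to the warm-type mean, and a compact letter
display (insert-and-absorb over the pairwise Welch matrix) supports bar
annotation.  Weather summaries report a rain window's total, the period
total, and the window's percent share at full precision and rounded to
the integer percent conventionally quoted.

## The synthetic generator

The generator defines the study conditions; it is the ground truth the
pipeline must recover.

* **Field**: 20 lines × 3 replicate plots on a 6 × 10 planting grid
  (12 px plots, 3 px soil gaps), two seasons with ambients 25 and
  26.5 °C — a +1.5 °C year-two offset that normalization must cancel.
  Soil images +8 °C above ambient.  Sensor noise is i.i.d. Gaussian,
  default sd 0.2 °C; within-line replicate variance is not asserted
  anywhere upstream, so it remains a parameter rather than a fixed
  value.  Planted types use ±0.8 °C offsets and ±0.1 °C/day slopes
  (mediate: slope sign flips between seasons, zero offset); 0.8 °C was
  chosen once as a mid-scale value inside the −2 to 2 °C relative-CT
  range such data occupy.
* **Filling**: true parameters drawn from k ∈ [35, 55] g, a ∈ [10, 30],
  b ∈ [0.15, 0.35] /day — ranges bracketing typical wheat fits —
  sampled on days 0, 2, 6, 8, 12, 16, 25 (a realistic seven-visit
  campaign), with 0.5 g measurement noise, truncated at zero because
  dry mass cannot be negative.
* **Traits**: linear-Gaussian construction, each trait loading on the
  standardised CT with independent residuals, so any target correlation
  in [−1, 1] is feasible and the implied covariance is positive
  semidefinite by construction.
* **Weather**: a deterministic 46-day fixture with a 13-day rain window
  totalling 339.3 mm inside a 539 mm period (63%).

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: spatial field trends (fertility or
moisture gradients that violate the exchangeable-neighbour assumption),
irregular hand-drawn ROIs, registration error between dates, non-Gaussian
sensor error, weather-driven day-to-day CT fluctuations beyond a linear
trend, and any biological coupling between a line's CT type and its true
filling parameters (the pipeline measures that coupling; the generator
plants it only through the trait correlations).

## Numerical choices and problem sizes

Determinism is absolute under a fixed seed: every stochastic stage draws
through an isolated seeded stream, and the pipeline manifest records MD5
hashes so reruns are verifiably byte-identical.  Identity checks
(Vmax vs the numeric maximum of V(t), T vs the 96% root) are asserted at
1e-8 over 1000 random draws; extraction is checked against a per-pixel
brute-force loop at 1e-10 and against noiseless ground truth at 1e-5 °C.
The test and acceptance workloads use 20-series adequacy runs,
200-series recovery runs, and 60-plot two-season fields — sizes chosen
to estimate medians and concordance stably while keeping the whole suite
fast to iterate on.

## Limitations

No spatial-trend surface correction (row–column or spline) is provided;
the neighbour subtraction is purely local.  No alternative growth
families (Richards, Gompertz, Weibull) and no pre-27-DAP early filling:
the model targets the middle and late filling stages only.  The
classifier's slope-sign reading of "trend" and the $D = 6/b$ and
$T$-formula inferences above are this package's resolutions of
ambiguities, exposed as defaults rather than hidden.
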