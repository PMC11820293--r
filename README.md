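# thermofill

Canopy-temperature (CT) phenotyping and grain-filling analysis for field
trials of wheat, built as a tested R pipeline over synthetic data with
known ground truth.

## The problem

Thermal-infrared imaging of a wheat nursery yields, per plot, a mean
canopy temperature. Raw CT confounds genotype with weather: a cloudier
afternoon or a warmer year shifts every plot. The classical fix is
spatial: subtract from each plot's CT the mean CT of its neighbouring
plots, leaving a *relative CT* on which genotypes can be compared across
dates and seasons. Lines whose relative CT consistently falls and stays
negative over the filling period in every season are *cold-type*; lines
that consistently rise and stay positive are *warm-type*; inconsistent
lines are *mediate-type*. Temperature type is then related to how grain
fills: the thousand-grain weight *y* (g) over days *t* since 27 days
after anthesis is modelled by the logistic curve

    y(t) = k / (1 + a e^(-b t)),

with filling rate V(t) = k a b e^(-b t) / (1 + a e^(-b t))², initial
weight C₀ = k/(1+a), maximum rate Vmax = kb/4, mean rate Vmean = kb/6,
active filling period D = 6/b, and filling end time T = ln(24a)/b (the
day the curve reaches 96% of its ceiling k). Fits are screened at
R² > 0.95. Trait–CT relationships are reported as Pearson panels with
significance stars (\*\*\* p<0.001, \*\* p<0.01, \* p<0.05) and
cold-vs-warm Welch contrasts with percent differences.

The package implements every stage — synthetic raster/series/trait/
weather generation, float32-TIFF plot extraction with soil masking,
six-neighbour normalization, two-season type classification, logistic
fitting with all derived parameters, and the correlation/contrast/
weather reporting — for researchers who want the method as runnable,
verifiable code rather than a manual image-software workflow.

## Worked example

The `analysis/` scripts run the whole study in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_extract_normalize.R
Rscript analysis/03_classify.R
Rscript analysis/04_fit_filling.R
Rscript analysis/05_associate.R
```

which prints (abridged):

```
Simulated: 10 frames (93x153 px), 60 plots, 20 filling series, 46-day weather record
Raw CT season offset 1.05 C per date on average; ... season imbalance -0.024 C
Classified 20 lines: 7 cold / 7 warm / 6 mediate.
Concordance with planted types: 100%.
Fitted 20 lines: all adequate = TRUE, min R^2 = 0.9980.
Median |relative error|: k 0.87%, b 2.99%.
CT vs Pn: r = -0.66** (n = 20).
Cold-type Pn +19.3% vs warm-type (Welch p = 0.00301).
Rain window days 17-29: 339.3 mm of 539 mm total = 63% of the filling period.
```

Read: the simulated season 2 is globally warmer (raw offset ~1.5 °C per
date before trend differences dilute the average), yet after neighbour
normalization the seasons are balanced to hundredths of a degree, and
every planted cold/warm/mediate label is recovered. All twenty logistic
fits clear the R² > 0.95 screen; the planted negative CT–photosynthesis
correlation surfaces as a starred negative cell; and the 13-day rain
window carries 63% of the period's rainfall. Stage tables land under
`results/run/`. The same pipeline is available in one call as
`run_all(run_config(out_dir))`, which also writes a seed/hash manifest.

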