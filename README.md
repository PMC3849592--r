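# fiberox

Per-myofiber quantification of oxidative damage and morphometry in
fluorescence images of skeletal muscle cross-sections.

Chronic limb ischemia in peripheral arterial disease (PAD) drives a
myopathy in which reactive-oxygen damage accumulates inside individual
gastrocnemius myofibers. `fiberox` implements the image-analysis and
statistics pipeline needed to study that process at the single-fiber
level: it segments myofibers from a sarcolemmal (wheat germ agglutinin)
membrane stain, measures background-corrected mean carbonyl and
4-hydroxy-2-nonenal (HNE) adduct signal per fiber in grayscale units
(gsu, 12-bit scale) together with the fiber's cross-sectional area (CSA,
µm²), stratifies each patient's fibers into damage-defined quartile
classes, and runs the cohort statistics a muscle-biopsy case–control study
needs. A synthetic cohort generator with full ground truth makes every
stage testable end to end.

It is intended for muscle physiologists and image-analysis engineers who
want a scriptable, validated alternative to interactive commercial tools
for this kind of morphometry.

## The measurement and the models

For fiber *i* of a specimen, the damage readout is the background-corrected
mean pixel intensity over the fiber interior,

    y_i = mean(I[fiber i]) − B,

where `B` is estimated per field and channel — for HNE as the median over
the extracellular/membrane compartment (HNE is absent from the
extracellular matrix), for carbonyl as the camera black level (the
extracellular matrix carries genuine carbonyl signal, so the extracellular
median would over-correct that marker). Specimen summaries are the mean
over *all* retained fibers pooled across fields (fiber-weighted, not
field-weighted). Negative corrected means are kept, preserving unbiased
group means.

Cohort analyses on the specimen summaries:

- **Group contrast** — ANCOVA `y ~ group + CAD + HTN` with least-squares
  adjusted means at the pooled covariate prevalences, plus percent
  differences under two conventions (relative to the larger mean, and
  relative to the control mean).
- **Clinical stage trend** — linear regression of PAD damage on the
  numeric Fontaine stage (2/3/4), CAD/HTN-adjusted.
- **Hemodynamics** — Pearson partial correlation of damage with the
  ankle-brachial index (ABI) given CAD/HTN, Fisher-z confidence interval.
- **Damage vs fiber size** — per patient and marker, fibers are split at
  the quartiles of the damage signal into classes Q1–Q4 (ties fall in the
  lower class) and class-mean CSA is modeled within patients
  (class + patient blocking); when the class effect is significant,
  least-squares contrasts compare Q4 against Q1–Q3.
- **Demographics** — χ² (no continuity correction) for binary variables,
  one-way F for continuous ones, flagging covariate candidates.

The synthetic generator tessellates each field into convex polygonal
fibers (capacity-controlled power diagram with Lloyd relaxation), leaves a
bright membrane rim between fibers, paints per-fiber damage values with
patient- and fiber-level variance, couples fiber CSA to fiber damage in
the PAD group, and emulates stage- and ABI-dependent damage — so the
programmed effects are known exactly and recovery can be verified.

## Worked example

Simulate one noise-free field, segment it, and measure the fibers:

```r
library(fiberox)

fc <- field_config(noise_model = "none", psf_sigma_px = 0)
sampler <- function(n) data.frame(carbonyl_gsu = 800, hne_gsu = 400,
                                  csa_um2 = exp(rnorm(n, log(5000), 0.25)))
fld <- generate_field(fc, sampler, seed = 7)
seg <- segment_fibers(fld$stack)
seg
#> label_map: 288 x 384 px, 21 fibers (19 regions excluded)

head(measure_field(fld$stack, seg, camera_black_gsu = 100)[
  , c("fiber_id", "csa_um2", "carbonyl_gsu", "hne_gsu")], 4)
#>   fiber_id csa_um2 carbonyl_gsu hne_gsu
#> 1        1 4285.84          800     400
#> 2        2 4405.83          800     400
#> 3        3 4186.13          800     400
#> 4        4 3099.46          800     400
```

The 40 painted fibers yield 21 interior fibers (19 border-truncated ones
are excluded from morphometry); the painted 800/400 gsu values are
recovered exactly after background correction, and matching against
ground truth gives precision = recall = 1.000 with a 2.6% median area
error.

Cohort level — simulate a 21-control / 34-PAD study and run the analyses:

```r
coh <- generate_cohort(cohort_config(seed = 42), render_images = FALSE)
meas <- truth_as_measurements(coh$fibers)
summ <- summarize_cohort(meas, coh$patients)
pad  <- summ[summ$group == "pad", ]

adjusted_group_comparison(summ, "carbonyl")
#> carbonyl: adjusted means control 489.2, PAD 722.4 (+32.3% vs larger, +47.7% vs control)
#>   group F(1,51) = 41.42, p = 4.2e-08; adjusted for: cad, htn

stage_trend(pad, "carbonyl")
#> carbonyl vs Fontaine stage: slope 101.0 per stage (SE 10.8), R^2 = 0.76, p = 2.1e-10 (n = 34)

abi_partial_correlation(pad, "carbonyl")
#> carbonyl vs ABI: partial r = -0.75, 95% CI [-0.87, -0.55], p = 6.7e-07 (n = 34)

qt <- quartile_table(meas, coh$patients)
quartile_repeated_measures(qt, "carbonyl", "pad")
#> CSA by carbonyl quartile class (pad): F(3,99) = 151.85, p = 6.6e-37
#>   class means (um^2): Q1 4548, Q2 4356, Q3 4180, Q4 3982
#>   Q1 - Q4: +566 um^2, p = 3.5e-37
#>   Q2 - Q4: +374 um^2, p = 3.8e-24
#>   Q3 - Q4: +198 um^2, p = 1.8e-10
```

PAD myofibers carry ~32% more carbonyl signal after CAD/HTN adjustment,
damage rises with Fontaine stage and falls with ABI, and within PAD
patients the most-damaged quartile of fibers (Q4) is ~570 µm² smaller
than the least-damaged (Q1) — the programmed study conditions, recovered
by the analysis.

The whole pipeline (simulate → segment → quantify → quartiles → stats)
runs from one config via `run_all(run_config(...))` or the CLI in
`inst/cli/fiberox`; see the vignette in `vignettes/` for the methods.

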