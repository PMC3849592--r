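---
title: "Quantifying oxidative damage in single myofibers: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying oxidative damage in single myofibers: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberox)
```

`fiberox` measures two forms of reactive-oxygen damage — hydrazide-reactive
protein carbonyl groups and the Michael adduct of 4-hydroxy-2-nonenal
(HNE) — inside individual myofibers of muscle cross-sections, together
with each fiber's cross-sectional area (CSA), and runs the cohort
statistics of a case–control biopsy study of peripheral arterial disease
(PAD). This vignette documents the measurement model, the synthetic-data
generator used for validation, the statistical procedures, and the design
choices made where the problem was genuinely open.

## The measurement model

Each microscopic field is a three-channel 12-bit image: a sarcolemmal
membrane label delineating fibers, a carbonyl channel and an HNE channel,
with intensities in grayscale units (gsu, 0–4095) and a known pixel size
(default 0.65 µm/px, typical of a 10× objective on a CCD camera of the
class used for muscle work; every simulated-image default in this package
is configurable).

**Segmentation** uses only the membrane channel: Gaussian smoothing
(default σ = 1 px), a threshold (Otsu by default, a fixed gsu value
optionally), morphological closing of the membrane mask (radius 1 px, to
bridge small rim gaps), then connected components of the mask complement.
Regions touching the image border are excluded — their CSA is truncated
and would bias morphometry downward — as are regions outside a plausible
fiber-size window (defaults 200–20,000 µm², bracketing adult human
myofiber CSA with wide margins). An optional marker-based watershed on the
distance map can split merged interiors on noisy membranes; it is off by
default because ridge-delineated convex fibers do not need it. The
algorithm assumes fibers are simply connected regions bounded by membrane
signal; it does no fiber typing and no fat/fibrosis classification.

**Quantification.** A fiber's damage readout is the mean pixel intensity
over its interior minus a per-field, per-channel background:

* HNE background: the median intensity over the pixels the segmentation
  classified as membrane/extracellular. HNE is confined to fiber
  interiors, so this compartment is signal-free and the median is an
  unbiased background estimate. (Using the membrane classification, not
  all unlabeled pixels, matters: unlabeled pixels also include the
  interiors of border-excluded fibers, which carry intracellular signal.)
* Carbonyl background: the camera black level. The extracellular matrix
  carries genuine carbonyl signal, so the extracellular median would
  subtract real biology from that marker; the documentation of
  `estimate_background()` warns about this and the pipeline default is a
  fixed black-level correction for carbonyl.

Whether to estimate background per field or globally is exposed in the
configuration; per field is the default since illumination and black
level can drift between acquisitions. Negative corrected means are kept
as-is: clamping at zero would bias group means upward. CSA is the
interior pixel count times the pixel area.

**Specimen summaries** pool all retained fibers of a specimen across its
fields with equal weight per fiber ("the mean of all myofibers"), rather
than averaging fields first; with unequal fibers per field the two
conventions differ, and a unit test pins the fiber-weighted one.

## Quartile-class analysis

For each patient and marker, the lower quartile, median and upper
quartile of the pooled fiber damage values define four classes: Q1 (at or
below the lower quartile), Q2 (above it, at or below the median), Q3
(above the median, at or below the upper quartile) and Q4 (above the
upper quartile). Ties fall in the lower class. Quartiles are computed by
linear interpolation between order statistics (R's type 7); the
convention is a parameter because boundary fibers change class under
other conventions. Fibers are pooled across fields before the quartiles
are taken, consistent with per-patient class definitions. Mean CSA per
class is the per-patient outcome; empty classes are recorded as missing,
not zero, so the repeated-measures model drops them.

## Cohort statistics

All cohort analyses operate on specimen summaries (one row per patient)
and adjust for coronary artery disease (CAD) and hypertension (HTN), the
two demographics that typically differ between PAD and control groups;
`demographics_table()` re-derives the covariate candidates for any given
cohort (χ² without continuity correction for binary variables, one-way F
for continuous ones).

* **Group contrast**: `outcome ~ group + CAD + HTN`, group tested by
  F-test against the covariate-only model; adjusted means are model
  predictions at the pooled covariate prevalences (the least-squares-means
  convention). Both the group-term F (1 numerator df) and the whole-model
  F (3 numerator df for 2 covariates) are reported, since summary
  statements about such cohorts appear in both parameterizations.
* **Percent difference**: two conventions are implemented and both are
  always reported — `vs_control` = (PAD − control)/control × 100, and
  `vs_larger` = (PAD − control)/max(control, PAD) × 100. For damage
  increases of the size seen in PAD cohorts the two differ materially
  (e.g. means of 486 vs 695 gsu are +30% of the larger mean but +43% of
  control); the package default is `vs_larger`, and the ambiguity is
  documented rather than resolved.
* **Stage trend**: damage regressed on the numeric Fontaine stage
  (2 = claudication, 3 = rest pain, 4 = tissue loss) plus covariates. A
  single-slope model is used — one R² per marker — rather than a
  stage-factor model; the reported R² is that of the fitted model.
* **ABI partial correlation**: residualize damage and the ankle-brachial
  index on the covariates, correlate the residuals. The confidence
  interval uses the Fisher z transform with SE = 1/sqrt(n − k − 3) for k
  covariates; the p-value uses t with n − k − 2 df. With no covariates
  this reduces exactly to the plain Pearson correlation.
* **Repeated-measures quartile model**: class-mean CSA modeled as
  class + patient (a within-subject ANOVA on up to four repeated values
  per patient; no covariance structure beyond the patient block is
  assumed, appropriate for four class means per subject). If the class
  effect is significant at α = 0.05, least-squares contrasts of Q4
  against Q1, Q2, Q3 follow, unadjusted by default to match raw pairwise
  reporting; Holm adjustment is a flag. Exactly flat class profiles are
  reported as F = 0, p = 1 rather than a 0/0 ratio.
* **Marker agreement**: plain Pearson correlation between specimen mean
  carbonyl and mean HNE across PAD specimens — a consistency check that
  two chemically independent damage labels tell the same story.

## The synthetic cohort generator

The generator exists so that every stage can be validated against known
truth. Its defaults are the study conditions of a 21-control / 34-PAD
gastrocnemius cohort: specimen-level carbonyl 486 ± 135 (control) vs
695 ± 132 gsu (PAD); HNE 261 ± 101 vs 436 ± 119 gsu; CSA 5,324 ± 1,371 vs
3,760 ± 1,546 µm²; Fontaine stages mixed 13:9:12 over stages 2:3:4; CAD
prevalence 23.8%/61.7% and HTN 57.1%/82.3%; ABI 0.94–1.34 in controls and
0.01–0.81 in PAD; 5–15 fields per specimen.

**Patient model.** PAD damage decomposes as group mean + stage effect +
ABI effect + patient random effect. The stage effect is linear in stage,
centered at the proportion-weighted mean stage so the group mean is
preserved; its per-marker defaults (137 gsu/stage carbonyl, 119
gsu/stage HNE) reproduce stage means near 552/707/827 gsu (carbonyl) and
310/454/548 gsu (HNE). ABI declines with stage (means 0.50/0.35/0.20,
within-stage SD 0.12), and the damage–ABI slope (−150 gsu per ABI unit)
acts on the within-stage ABI residual, so stage means are unaffected
while the damage–ABI correlation is negative both through and beyond the
stage pathway. The patient random-effect SD is derived by variance
decomposition: the target specimen-level SD minus the variance already
induced by stage and ABI, floored at 15% of the target — so simulated
specimen SDs match the configured ones. Patient effects of the two
markers share a latent factor (correlation 0.8), which, with the shared
stage effect, makes specimen-level marker agreement strong.

**Fiber model.** Within a specimen, a standard-normal latent damage
factor drives both markers (fiber-level correlation 0.7) with
within-specimen SDs of 150 gsu (carbonyl) and 120 gsu (HNE). These
within-specimen spreads are not identifiable from specimen-level
summaries; they are a modeling choice flagged here, sized so that fibers
within one section span a visibly wide damage range without saturating
the 12-bit scale. Fiber CSA couples to the fiber's carbonyl deviation
from the patient mean by `csa_damage_coupling` (default −1.5 µm²/gsu in
PAD, 0 in controls): the most-damaged fibers are the smallest, in PAD
only. For a normal damage distribution the implied Q4 − Q1 CSA gap is
2.54 × 150 × 1.5 ≈ 570 µm². True gsu values are rounded to integers at
draw time, as a 12-bit camera would digitize them, which makes noise-free
measurement and the TIFF round trip exact.

**Geometry.** Fields are tessellated into convex polygonal fibers by a
capacity-controlled power diagram computed directly on the pixel grid
(compiled kernel): random seeds, two Lloyd relaxations for even spacing,
then weight iterations that push each cell's realized pixel count toward
its target area (drawn from the fiber CSA model; the update uses
dArea/dweight ≈ 1.65, constant for hexagonal cells). Realized areas track
targets with a median relative error of roughly 5–10%, and the realized
interior pixel count × pixel area *is* the ground-truth CSA — one
consistent definition of truth that the measurement contract can recover
exactly. Cells are shrunk by the membrane width (default 3 px) to leave
an extracellular rim; fibers per field are set from the field area
divided by the patient's programmed mean CSA, so realized specimen means
match programmed ones.

**Painting and noise.** The membrane channel is bright on the rim;
carbonyl = camera black + per-fiber level inside fibers + an
extracellular carbonyl level (default 300 gsu) on the rim; HNE = camera
black + per-fiber level inside fibers only — the extracellular HNE equals
the camera black exactly when noise is off, mirroring the biology (ECM
damage is detected exclusively as carbonyl). An optional Gaussian PSF
blur (default σ 0.8 px) precedes noise; the noise model is Gaussian read
noise (default SD 25 gsu) optionally after Poisson shot noise — the
standard CCD model. Everything clamps to [0, 4095].

**What the generator does not emulate**: fatty infiltration, endomysial
fibrosis, target lesions, staining chemistry, uneven illumination,
chromatic misregistration, or non-convex fiber shapes. Passing tests
therefore demonstrate correctness of the measurement and statistics under
clean, convex, well-delineated histology — not robustness to every
real-world artifact; the watershed flag and fixed-threshold option are
the first knobs to reach for on harder material.

## Numerical and engineering choices

* Quartile boundary ties go to the lower class; the degenerate all-equal
  case puts every fiber in Q1.
* Constant covariates are dropped from models with a warning rather than
  producing singular fits; analyses whose preconditions a small cohort
  cannot meet (e.g. a partial correlation on three PAD patients) are
  reported as skipped by the pipeline instead of aborting the run.
* A constant membrane channel is an error ("no membrane structure");
  zero surviving fibers after filtering is a warning and an empty label
  map.
* Instance matching uses greedy one-to-one pairing by descending IoU with
  an IoU ≥ 0.5 match criterion — the standard instance-segmentation
  convention — and is invariant to label permutation.
* Images are written as multi-page 16-bit TIFFs (membrane, carbonyl, HNE)
  holding 12-bit data; label maps carry the membrane classification as a
  second binary page so background estimation survives a round trip
  through files.
* Determinism: a cohort is a pure function of its configuration and seed;
  the pipeline manifest records an MD5 hash per output file, and two runs
  with the same config and seed produce identical hashes.

Validation problem sizes, chosen to exercise the contracts at meaningful
statistical resolution: segmentation fidelity on ten 288 × 384 px
noise-free fields of ~40 fibers; parameter recovery over ten simulated
21/34-patient cohorts at the default study conditions (ground-truth
tables, no rasterization — rendering adds segmentation error that the
fidelity suite already bounds); null calibration of the trend and
quartile tests over 1000 replicates at the cohort's own n; and the
quartile-class oracle over 1000 random fiber sets including heavy ties.

## Known limitations

* The segmentation is a stand-in satisfying the measurement contract, not
  a reimplementation of any commercial partitioning procedure; on
  low-contrast or discontinuous membranes it will under-segment unless
  the watershed flag is enabled.
* The generator's ABI spread is narrower than real cohorts show, and ABI
  enters damage linearly; only the sign and approximate strength of the
  damage–ABI association should be read from simulations.
* Fontaine stage enters the trend model as a numeric score; ordinal
  treatments (isotonic or factor coding) are deliberately out of scope.
* The repeated-measures model treats the four class means as exchangeable
  within patient; with many missing classes (tiny specimens) its F-test
  degrees of freedom shrink accordingly.
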