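# cartbarrier

Quantification pipeline for nanoparticle-dependent assessment of articular
cartilage barrier function, aimed at researchers evaluating contrast-enhanced
MRI of cartilage and the accompanying safety assays (live/dead imaging,
transwell chemotaxis, cytokine panels, dose calibration).

Early cartilage disease is dominated by depletion of extracellular matrix
(glycosaminoglycans), which increases the tissue's permeability to small
nanoparticles long before structural damage is visible. Injecting
superparamagnetic iron oxide nanoparticles (SPIONs) into a joint and imaging
before and after therefore probes the cartilage *barrier*: the deeper the
particles permeate, the more the superficial cartilage darkens on
T2\*-weighted MRI. This package implements the measurement chain around that
idea as tested, reusable R code, driven end-to-end by a synthetic-data
module that generates every input with known ground truth.

## The core statistic

On a windowed (WL/WW = 420/821) sagittal slice, grey-scale intensity is
profiled along a line drawn perpendicular to the distal physis, from the
subchondral bone plate (distance 0) across the cartilage into the joint
cavity. The **peak** is the last intensity maximum just before the profile
drops off at the cartilage–joint cavity interface; the **half-peak** point
is where the profile, scanned from the peak back toward the bone, first
crosses half of the peak intensity (above the bone-side baseline). The
statistic is the peak-to-half-peak distance *d* (mm):

- per joint, *d*\_pre and *d*\_post (before/after SPION injection),
- the difference *d*\_pre − *d*\_post used in group comparisons
  (Kruskal–Wallis on ranks with Dunn's post-hoc),
- and the percentage 100·*d*\_post/*d*\_pre ("percent of pre"); lower values
  mean deeper particle permeation, i.e. a weaker barrier.

Around it the package provides:

| module | contents |
|---|---|
| synthetic data | seeded joint-slice phantoms with closed-form ground truth, agarose-well concentration series, two-channel 3-D cell stacks, exact-moments plate tables, calibration series |
| MRI profile | windowing, bilinear line profiles (with averaging width), peak/half-peak detection, percent-of-pre, well-ROI statistics, concentration-threshold detection |
| 3-D cell counting | single-scale scale-normalised Laplacian blob detection per channel (live ≈ 8 µm green, dead ≈ 6 µm red), manual-review edits, viability |
| chemotaxis | replicate averaging, percent migration vs the 100 %-migration wells, one-way ANOVA with pooled-MSE treatment-vs-control t contrasts and Holm–Šidák adjustment, summary-statistics ANOVA |
| biomarkers | replicate CV, multiplex QC gates (CV < 15 %, recovery 70–130 %, measurable range), PGE2 leave-one-out outlier rule (CV > 30 %), Kruskal–Wallis/Dunn |
| dosing | mean percent discrepancy of calibration series, filtration-loss dose adjustment, exposure concentrations, particle-size summaries |

## Worked example

```r
library(cartbarrier)

# a conditioned joint: 2 mm cartilage, permeation depth set so the
# ground-truth post/pre ratio is 0.60, MR-like noise at 5% of the peak
spec <- joint_phantom_spec(noise_sd = 39, seed = 42)
spec$permeation_depth <- permeation_for_ratio(spec, 0.60)  # 0.8 mm
ph <- generate_joint_phantom(spec)
m <- measure_barrier(ph$pre, ph$post, ph$line)
sprintf("pre %.3f post %.3f pct %.2f", m$pre_mm, m$post_mm, m$percent_of_pre)
#> "pre 0.954 post 0.554 pct 58.09"

# cohorts of 8 conditioned (ratio 0.60) and 9 unconditioned (0.87) joints
cond <- generate_joint_cohort(8, 0.60, joint_phantom_spec(noise_sd = 39), seed = 1)
unc  <- generate_joint_cohort(9, 0.87, joint_phantom_spec(noise_sd = 39), seed = 2)
compare_barrier_groups(cond, unc)
#> Barrier comparison (pre - post peak-to-half-peak differences)
#> Kruskal-Wallis: H = 12, p = 0.000532
#> Percent-of-pre by group [median (q1; q3)]:
#>   conditioned    57.18% (56.15%; 58.18%)
#>   unconditioned  89.16% (86.49%; 90.42%)
```

The measured pre distance is the ground-truth 1 mm up to sampling
resolution, the post/pre percentage recovers the generated 60 % ratio, and
the rank test separates the cohorts decisively.

The neutrophil-migration comparison can be reproduced directly from printed
group summaries (mean, SEM, n), without the raw plate:

```r
fig <- data.frame(group = c("C","CW","L","M","H"), n = c(10,5,5,5,5),
                  mean = c(10076,13390,12517,15666,20108),
                  sem  = c(1768,2350,2294,2623,2668))
anova_from_summary(fig, control = "C")
#> One-way ANOVA: F(4, 25) = 2.923, p = 0.04119
#> Holm-Sidak contrasts vs control group C :
#>  group      t    p_raw p_adjusted
#>     CW 1.0853 0.288139    0.49325
#>      L 0.7994 0.431583    0.49325
#>      M 1.8307 0.079094    0.21901
#>      H 3.2854 0.003012    0.01199
```

The administered dose has a significant overall effect (p = 0.041) and only
the highest dose differs from control after Holm–Šidák adjustment
(p = 0.012).

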