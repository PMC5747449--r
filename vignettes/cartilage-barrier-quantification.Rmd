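---
title: "Quantifying cartilage barrier function and nanoparticle safety assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cartilage barrier function and nanoparticle safety assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cartbarrier)
```

## Overview

`cartbarrier` implements the quantitative chain behind nanoparticle-dependent
cartilage barrier imaging: a grey-scale line-profile statistic on pre/post
contrast MRI, phantom-based detection of the minimum effective contrast
concentration, 3-D live/dead cell counting, transwell chemotaxis statistics,
biomarker assay quality control, and filtration-loss dose arithmetic. The
package is validated entirely on synthetic data whose ground truth is known
in closed form; this vignette records the models, the parameters that
matter, and the design decisions taken where the procedures admit several
reasonable readings.

## The barrier statistic

A calibrated slice (`image_slice`) is first normalised with its display
window: `clip((raw - (WL - WW/2)) / WW, 0, 1)`, with WL/WW fixed at 420/821
so intensities are comparable across imaging studies. An intensity profile
is sampled by bilinear interpolation along a user-supplied measurement line
running from the subchondral bone plate (distance 0) across the cartilage
into the joint cavity. The line carries two sampling parameters:

* `sampling_step` (mm) — the along-line sampling interval;
* `width_px` — the number of parallel one-pixel-spaced lines averaged
  perpendicular to the measurement direction, as in the line-width option
  of interactive profile tools. Averaging across width suppresses
  single-pixel noise without blurring the profile axis, which matters
  because the statistic below is localised along that axis.

**Peak.** The cartilage surface shows as the last intensity maximum before
the profile collapses into the (post-injection, hypointense) joint cavity.
Since "just prior to dropping off" is not an algorithm, we operationalise
it deterministically: scanning from the bone end, the peak is the last
sample attaining the running maximum before the smoothed profile falls
below `drop_fraction` (default 0.5) of that maximum — measured above the
profile's global minimum, so the rule is invariant under affine intensity
rescaling — for at least `min_run` (default 3) consecutive samples. A
candidate maximum only qualifies once its prominence reaches
`min_prominence` (default 0.5) of the profile's dynamic range; without this
gate, noise fluctuations in the near-zero bone region register as spurious
cliffs. A centred moving average of `smooth_width` samples (default 3) is
applied before detection and the peak value is reported from the smoothed
profile.

**Half-peak.** From the peak the profile is scanned back toward the bone
for the first crossing of half the peak value; the crossing is located by
linear interpolation between the bracketing samples. Two choices here were
genuinely open:

* *Search direction.* The joint-cavity side of the peak drops almost
  vertically at the interface, so a half-width measured there is degenerate
  (it would measure the interface sharpness, not the cartilage profile).
  The bone side is the informative direction and is the default; it is a
  visible argument, not a hidden convention.
* *Baseline.* Display windowing shifts intensities additively, so halving
  the raw peak value would make the statistic depend on the window offset.
  By default the half level is taken relative to the minimum smoothed value
  on the bone side of the peak (`baseline_offset = TRUE`), which makes the
  peak-to-half-peak distance exactly invariant under gain/offset changes
  (a tested property). `baseline_offset = FALSE` restores raw
  half-of-peak.
* *Ties.* A plateau lying exactly at the half level resolves to its
  peak-side edge (the first bracketing crossing encountered from the peak).

Per joint the pipeline reports the pre- and post-injection distances, their
difference, and `100 * post / pre` ("percent of pre"). Cohorts (conditioned,
i.e. matrix-depleted, versus unconditioned joints) are compared on the
pre−post differences with a tie-corrected Kruskal–Wallis test and Dunn's
pairwise z (two-sided; reported unadjusted and Bonferroni-adjusted, since
the post-hoc family here is a single pair and no adjustment convention is
canonical).

## The joint phantom and its ground truth

`joint_phantom_spec()` renders a 1-D profile model extruded across image
rows — the statistic itself is purely 1-D, so nothing is gained by
simulating 2-D anatomy. From the bone end: a signal-void bone plate (by
default at the window floor, so the windowed baseline is exactly zero), a
cartilage rise over `cartilage_thickness` (default 2 mm) that is either
linear or a Gaussian limb with scale `rise_sigma`, and joint fluid (bright
pre-injection, hypointense post-injection). Post-injection permeation is
modelled by truncating the rise at `permeation_depth` below the surface:
the darkened superficial zone merges with the hypointense fluid. This gives
closed-form ground truth:

* linear rise: distance = (T − d)/2, hence post/pre ratio = 1 − d/T;
* Gaussian limb: pre = σ√(2 ln 2), post = √(d² + 2σ² ln 2) − d.

`permeation_for_ratio()` inverts these, so cohorts with a prescribed
ground-truth ratio (0.60 for conditioned joints, 0.87 for unconditioned,
matching the reported study medians of ~59.6 % and ~87 %) can be generated
directly. Noise is additive Gaussian on the raw grey values, clipped to the
valid range — the simplest desk-scale stand-in for MR magnitude noise; the
generators are explicit stand-ins, not claims about any scanner's noise
model.

Default pixel spacing is 0.02 mm. This follows from an error budget, not
from acquisition physics: the peak position is resolved to about one
sample, so recovering a 0.87 ratio of ~1 mm distances to better than 2
percentage points requires sampling at a few hundredths of a millimetre.
Slices exported from a clinical viewer at display resolution are of this
order. Both scales of validation hold on the defaults: noise-free recovery
is within one pixel of the closed form, and at noise of 5 % of the peak
grey value the median recovered percent-of-pre across 200 simulated cohort
pairs stays within 2 percentage points of ground truth while the
Kruskal–Wallis comparison of 8-vs-9 joint cohorts rejects essentially
always.

## Concentration-threshold phantoms

`generate_phantom_series()` renders one slice per concentration: a
circular well (default 6 mm diameter, the nanoparticle solution) in a
uniform agarose surround. `detect_threshold_concentration()` implements
"at or above" semantics: the smallest concentration from which *every*
well is at least `k` (default 3) control SDs darker than the control
region. A single dark well followed by a brighter one does not qualify;
a flat series returns no threshold. On a step series darkening from
22.4 µg/mL the detector returns 22.4.

## 3-D live/dead counting

Cells are spheres at the scale given per channel (live/green ≈ 8 µm,
dead/red ≈ 6 µm). The detector is a single-scale, scale-normalised
Laplacian-of-Gaussian blob response with per-axis sigmas
`radius_scale * diameter / 2 / sqrt(3)` converted to voxels through the
voxel size (anisotropy is handled per axis). Local response maxima above a
threshold are reported; maxima closer than `min_center_separation`
(default 0.7) times the diameter are suppressed keeping the stronger
response. The reference tool for such counts is proprietary and its
response function unknown; a standard blob detector at the stated
diameters is the faithful open equivalent, and equivalence is asserted
only on synthetic ground truth. Its "render quality" display setting has
no detection analogue, so the default threshold is an Otsu split of the
positive response histogram — parameter-free and robust across the
amplitudes the generator produces. Channels are processed independently;
co-localised green/red signal is counted in both, matching how live/dead
channels are tallied in practice. `manual_review()` mirrors the
review-and-correct step, with an audit trail and errors on removals that
match nothing (including duplicate removals).

The stack generator places centres uniformly with a minimum separation
(rejection sampling with bounded retries; an over-packed volume is an
error) and renders solid spheres with a one-voxel anti-aliased shell —
keeping the closed-form ground truth while avoiding pure step edges. On
noise-free stacks detection is exact; at a signal-to-noise ratio of 10
with 50 spheres per channel precision and recall stay at or above 0.95.

## Transwell chemotaxis statistics

Technical replicates are averaged per well; migration is expressed relative
to the mean of the maximum-migration wells (bottom wells loaded directly
with the dosing cell suspension). Group comparison is a fixed-effects
one-way ANOVA followed by t contrasts of each treatment against the control
group using the pooled within-group mean square on its full N − k degrees
of freedom — the equal-variance form, which is what reproduces the
published comparison (the printed H-vs-C p of 0.012 is consistent with
pooled df = 25 and not with Welch df). The m = 4 contrasts are adjusted by
the Holm–Šidák step-down: order the raw p ascending and take the running
maximum of `1 - (1 - p_(i))^(m - i + 1)`, clipped to 1. All tests are
two-sided.

`anova_from_summary()` reconstructs the identical analysis from printed
(n, mean, SEM) per group — within-group sum of squares from
`(n-1) * (sem * sqrt(n))^2`, between-group from the means — an algebraic
identity with the raw-data ANOVA, tested to 1e-9 relative error. The plate
generator's exact-moments mode (draw, then affinely re-standardise to the
target mean/SD; replicate jitter is recentred so well means are exact)
turns that identity into an executable cross-check: a plate generated from
the printed summaries yields the same F, p and adjusted contrasts through
the raw-data route. Degenerate inputs are deliberate: constant data is an
error for the contrast ANOVA (zero variance everywhere), while the
plate-loading weight ANOVA — an overall F with no contrast structure —
reports F = 0 for identically loaded wells.

Under the complete null the omnibus F rejects at the nominal 5 % (empirical
rate within [0.035, 0.065] at 2000 simulations), and the gated family-wise
procedure (omnibus gate plus any adjusted contrast) is conservative — it
cannot exceed, and generally sits below, the omnibus rate, which is why the
package reports both.

## Biomarker quality control

The multiplex gate accepts a measurement only when it is inside the
measurable range, the associated quality control recovered between 70 % and
130 % (endpoints inclusive), and the replicate CV (100·SD/mean, sample SD)
is strictly below 15 % — a CV of exactly 15.0 % is rejected. Accepted
values are the replicate mean times the dilution factor; out-of-range
readings are recorded as censored, not zeroed, and stay out of rank tests.
The competitive-ELISA rule excludes outliers that push the CV strictly
above 30 %: the exclusion mechanism is not defined by the quoted rule, so
it is operationalised as leave-one-out CV minimisation — remove the single
replicate whose removal minimises the CV of the remainder, and exclude the
measurement if even that leaves the CV above 30 %. The rule is
deterministic, order-independent, auditable, and agrees with exhaustive
subset search whenever a single removal suffices (a tested property).

## Dose recalibration and sizing

Filtration loss is estimated as the mean per-pair percent discrepancy
`100 * (expected - observed) / expected` over a calibration dilution
series — pairwise then averaged, not pooled by mass, so each dilution
contributes equally and the estimate is scale-invariant per pair. Doses
are adjusted as `nominal * (1 - loss)`; applying the 44 % loss to a 40 µg
nominal sample gives 22.4 µg, and exposure concentrations are dose mass
over media volume reported to three significant figures (560 µg / 9 mL →
62.2 µg/mL), matching the reporting convention for the printed exposure
levels. Particle sizing is summarised as a fixed-bin histogram with
arithmetic mean and modal bin; the synthetic TEM sample draws log-normal
diameters (a conventional shape for nanoparticle size distributions) with
mean 12 nm, SD 3 nm, n = 172.

## Reproducibility, problem sizes, and limitations

Every generator takes an integer seed and restores the caller's RNG state;
identical seeds give bit-identical artifacts. The validation suite uses
200 simulated cohort pairs for the barrier statistic, 2000 null
simulations per test procedure, 100-dataset oracle sweeps for the
summary/raw ANOVA identity and half-peak localisation, and stacks of
50 spheres per channel in a 200×200×60 µm volume at 2 µm voxels — sizes
chosen so Monte-Carlo error is small relative to the tolerances being
asserted.

What passing these tests does *not* show: the phantoms have planar
geometry, ideal windowing, Gaussian noise and a sharp permeation boundary,
so they exercise the measurement chain, not anatomical variability,
partial-volume effects at curved interfaces, susceptibility artefacts, or
depth-dependent fluorescence attenuation in thick tissue (which the
counting module deliberately does not correct). Measurement-line placement
and slice selection are human steps and remain inputs. The detector
equivalence for cell counting is asserted against synthetic spheres, not
against any proprietary tool's output on real stacks.
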