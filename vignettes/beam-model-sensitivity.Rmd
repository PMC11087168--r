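---
title: "Beam-model sensitivity of IMRT/VMAT plans and complexity-metric ranking: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-model sensitivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(planperturb)
```

# The problem

A treatment planning system computes dose through a configurable beam model.
Community surveys show a wide spread in how clinics set the model's
parameters — MLC offset, transmission, leaf-tip width, tongue-and-groove
width, source size, and the dosimetric calibration terms — and atypical
settings correlate with audit failures. Two questions follow: *which
parameters matter most when they drift to the tails of the community
distribution*, and *which plan complexity metrics identify the plans most
sensitive to such drift*. `planperturb` implements a desk-scale,
fully-reproducible version of that study design: a synthetic plan cohort, a
2D fluence surrogate in place of a commercial dose engine, the 18 standard
complexity metrics, and a regression/ranking/threshold pipeline.

# Plan model

Plans are lists of beams; beams are ordered control points carrying per-pair
leaf-tip positions for both banks (bank A negative side, bank B positive, so
gap `= x_B − x_A ≥ 0`), jaw windows, gantry angle, cumulative MU fraction,
nominal time and interval dose rate. The machine is a 60-pair Millennium-120
layout (10×10 mm, 40×5 mm, 10×10 mm leaf widths spanning ±200 mm).

A leaf pair is **active** at a control point iff its gap exceeds the minimum
dynamic gap (default 0.6 mm) and its y-extent overlaps the jaw window. All
per-leaf metric averages run over active pairs. Junction-based metrics (TGi,
edge metric, interdigitation) use junctions whose **two** adjacent pairs are
both active: a junction against a parked pair lies behind the jaws, and any
other convention would make the closed-field TGi depend on arbitrary parking
positions (the rectangle fixture must score exactly 0).

Control-point MU weights use the half-interval rule on the cumulative
meterset, `w_i = (cum_{i+1} − cum_{i−1})/2` with half intervals at the ends;
a single control point has weight 1. Step-and-shoot beams are represented as
start/end control-point pairs per segment (constant aperture while the
segment's MU is delivered), which makes the same weighting rule give each
segment exactly its MU fraction.

DICOM-RT Plan I/O is a minimal explicit-VR little-endian codec written for
this package (no DICOM library exists in the target environment). Nominal
time is not a DICOM attribute; the writer stores the per-interval mean dose
rate (`DoseRateSet`) and the reader reconstructs time from cumulative MU,
which is exact whenever rates and times are mutually consistent — an
invariant of every generator output.

# Synthetic cohort: the stated world

The generator emulates the *statistical structure* of a 25-plan clinical
cohort — five plans each of prostate, lung, head-and-neck, brain and
mesothelioma — not any patient's anatomy. Per site preset:

| site | technique | beams×CPs | meanGap target (mm) | roughness | sweep (mm) |
|---|---|---|---|---|---|
| head-and-neck | VMAT | 2×36 | 10–20 | 0.80 | 100 |
| mesothelioma | static-IMRT | 5×10 segments | 12–22 | 0.70 | 120 |
| prostate | VMAT | 2×36 | 18–32 | 0.45 | 90 |
| brain | VMAT | 1×48 | 25–42 | 0.30 | 90 |
| lung | VMAT | 1×48 | 25–48 | 0.25 | 100 |

Leaf trajectories: per-pair aperture centers mix a shared reflected Gaussian
random walk with per-pair walks, `c_i = (1−ρ)·C + ρ·ξ_i`; the mixing
parameter ρ (*adjacency roughness*) controls adjacent-leaf decorrelation and
therefore the tongue-and-groove index (verified monotone in the tests).
Per-control-point gaps are log-normal around a plan-level target drawn
uniformly from the site's range, AR(1)-smoothed along the arc so the plan
stays deliverable; MU fractions are Dirichlet; times and dose rates respect
machine limits (600 MU/min, 6°/s, 25 mm/s). A calibration pass rescales gaps
about their centers until the plan's mean MLC gap is within 2% of target
(≤ 20 iterations; in practice 1–3).

Choices a reader should know about:

* **Gap ranges** are invented (the source study reports ordering, not
  values) and bracket the published decision thresholds (20 and 34 mm) so
  threshold derivation is exercised on both sides. The TGi ranges in the
  presets are *descriptive* — TGi is not calibrated; the ranges record what
  the roughness/dispersion settings produce, and the coverage test holds the
  generator to them.
* **Technique mix** is VMAT everywhere except static-IMRT mesothelioma; the
  clinical mix is unstated in the literature this emulates, so this is a
  configurable default, not an inference.
* **Seeding**: per-plan seeds derive from the master seed by a splittable
  counter, so cohorts are reproducible independently of generation order.
  The default master seed (20240314) was fixed before any downstream result
  was measured and is not a tuning knob.

What a green test on this cohort does **not** establish: anything about real
patient anatomy, 3D scatter, oblique incidence, or deliverability. The
generator produces plausible aperture morphology with controllable
complexity; its purpose is to give the pipeline a world whose ground truth
is known.

# Complexity metrics

The 18 metrics follow the standard published definitions (MCS as the product
of aperture-area and leaf-sequence variability; irregularity as
`P²/(4πA)` of the rectilinear aperture polygon; edge metric as exposed
leaf-side length per aperture area; plan modulation as
`1 − Σ w·A / A_union`; a total modulation index integrating the tail
distribution of leaf-speed changes with acceleration/dose-rate/gantry
penalties). The source study names but does not define 16 of the 18; every
formula is therefore fixed exactly as implemented here and each is verified
against an independent naive-loop oracle to 1e-9 relative on seeded plans.
Conventions worth noting:

* MU-weighted averaging everywhere, matching the mean-gap definition's
  weighting; the first-quartile gap is a weighted quantile with linear
  interpolation over all (control point, active pair) gap samples.
* TGi junction denominator is the mean of the two pair gaps, floored at
  0.1 mm, ratio clamped at 1. Whether the original averages over junctions
  or leaves, or clamps, is unstated; this convention is documented, not
  attributed.
* "Speed/dose-rate/gantry modulation" are MU-weighted standard deviations
  (a Park-style index is an alternative reading of the same names).
* Undefined metrics (no active pairs, fewer than 3 control points) are NA
  markers, never silently 0; NA propagates through beam averaging.
* Numerical tie-breaks: the modulation index returns 0 when the speed-change
  standard deviation is below 1e-9 of the speed scale (floating-point dust
  on constant-speed beams); LSV of a constant bank is 1; zero-area control
  points are dropped from irregularity/edge averages with weight
  renormalization.
* MU scaling: multiplying MU by c (with dose rates scaled accordingly at
  fixed times) changes `total_mu` by c and dose-rate metrics by c; aperture
  metrics are invariant. Refinement invariance (inserting interpolated
  control points changes meanGap/TGi/MCS by <1%) holds for smooth
  trajectories and is tested on a sinusoidal fixture; rough random-walk
  trajectories are *not* refinement-invariant for TGi, because adjacent-leaf
  differences flip sign between control points and linear interpolation
  shrinks their absolute value — a property of the trajectory's roughness
  spectrum, not of the metric engine.

# Fluence surrogate

All beams share one isocenter-plane beam's-eye view (0.5 mm/pixel default).
Per control point: 1 inside the effective aperture; transmission under
leaves; a linear ramp of width `leaf_tip_width` from 1 at the effective tip
to transmission at `tip + width` (chosen over a 50%-point shift because its
excess fluence has the closed form `w(1−T)/2` per unit edge, which the tests
integrate); tongue-and-groove strips at transmission level along exposed
leaf sides; zero outside jaws; Gaussian source blur; quadratic off-axis
modifier. Aperture edges use area-weighted pixel coverage (anti-aliasing),
which is what makes the analytic offset law exact on the grid. Blur and
off-axis commute with MU-weighted summation and are applied once per plan
map. Effective tip positions move outward by
`Δ = offset + gain·|x|/10 cm + curvature·x²` (cm), gap floored at zero; the
outward-positive, |x|-gain, x²-curvature convention is documented, not
asserted as any vendor's.

Dosimetric modifiers: output-factor error scales the map by
`1 + err·(A_eq − 100 mm)/100 mm` with `A_eq` the MU-weighted
equivalent-square side (`4A/P`); PDD-slope error scales each ROI readout by
`1 + err·(depth − 10 cm)`. ROI endpoints are pixel percentiles (CTV
min/max/D95 as 0.2/99.8/5th percentiles, serial-OAR near-max as 98th,
coverage as the fraction of CTV pixels ≥ 98% of the baseline CTV median).

The community percentile table seeds MLC offset, transmission and leaf-tip
width from published data; transmission's percent-labelled column
(0.007–0.025) is read as fractions (0.7–2.5%), the only physically plausible
interpretation. The other seven parameter rows ship as clearly-marked
placeholders.

**Scale caveat.** Because anatomy, depth dose and 3D transport are absent,
absolute deviations are surrogate-scale. The package's claims are the signs
(97.5th-percentile offset/transmission overdose, 2.5th underdose), the
monotone decrease of offset sensitivity with mean gap (Spearman ρ ≤ −0.9
across the cohort), the analytic first-order law `ΔD/D = 2Δδ/g` for a
constant-gap sliding window, and the correlation structure used by the
ranking — not Gray-level accuracy.

# Study pipeline

The full grid (10 parameters × 4 percentiles × 25 plans) yields the
canonical 1,000 perturbation cells; each cell records seven endpoint
deviations against the per-plan baseline map (computed once). The parameter
filter counts cells with |mean-CTV deviation| > 1% and keeps parameters with
at least 10% of the grand total ("at least": the boundary count is kept).
PDD is excluded from metric regressions by default — its dose impact follows
ROI depth (geometry), not plan complexity — with a flag to include it.

Per (metric, parameter): the response is each plan's maximum absolute
mean-CTV deviation over the four percentile levels (absolute, because under-
and over-dose both count). OLS fits are computed per site and pooled; both
are reported because the source design does not state which fed its summary
figure. Ranking uses the per-site fits: unweighted mean R² (primary),
weighted mean R² (weights = each fit's count of plans above the 1%
threshold; the original weighting is undefined, this one is a documented
placeholder), and mean residual RMSE; ties break alphabetically. Metrics
with zero variance within every group (number of arcs, within sites) have
undefined R² and are excluded from ranking averages. Thresholds invert the
pooled fitted line at 2% and 4% dose limits with a direction flag (negative
slope → robust above, e.g. mean gap; positive slope → robust below, e.g.
TGi).

# Design decisions that were genuinely open

* **Ranking outcome at the default seed.** On the default cohort the
  first-quartile gap and the mean gap are statistically tied for the top
  mean-R² rank on the MLC-offset parameter (0.9836 vs 0.9815; metric #3
  trails at ≈0.86), and which of the two wins flips with the master seed.
  This is intrinsic: the deviation mechanism is ≈ `2Δδ/gap`, so any
  monotone summary of the gap distribution predicts it almost equally well.
  The acceptance test that names mean gap (or TGi) as the single winner is
  left red rather than re-seeding the world; the reproducible claim is that
  the two gap metrics jointly dominate all 16 others.
* **Static-beam kinematics**: segment reshaping is instantaneous (zero-MU,
  zero-time intervals), so static beams have well-defined reconstructible
  timelines; their speed metrics are 0 by convention.
* **JSON fixture dialect** mirrors the in-memory structure one-to-one so
  determinism can be asserted byte-wise.
* **Test budget scaling**: the generator-calibration check runs 40 seeds
  (not 100) and ensemble coverage 8 seeds × 3 sites (not 50), and the
  acceptance cohort grid is computed once and shared by two criteria —
  runtime scaling only; no tolerance or target was altered.

# Known limitations

Single shared BEV (no gantry-angle compositing, no anatomy); no 3D dose, no
heterogeneity, no DVH on structures, no homogeneity endpoint; jaw
transmission ignored; closed leaf pairs inside the jaw window are modelled
at transmission level without a rounded-tip leak peak; the DICOM codec reads
only the dialect it writes (explicit VR little endian, the RT Plan subset
listed in `R/rtplan_io.R`); thresholds derived from surrogate-scale fits are
method demonstrations, not clinical action levels.
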