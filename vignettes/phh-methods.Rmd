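---
title: "Methods: stain quantification, volumetry, and gated group comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain quantification, volumetry, and gated group comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phhquant)
```

phhquant implements the quantitative core of a neonatal rat model of
post-hemorrhagic hydrocephalus (PHH): after intraventricular injection of
blood breakdown products (saline control, hemoglobin, ferric iron, lysed red
blood cells), disease burden is read out as (i) ferric-iron deposition on
Perls Prussian-blue stained sections and (ii) progressive ventricular CSF
enlargement on serial MRI. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generators do
and do not emulate.

## 1. Blue/pink stain quantification

### Model

A Perls-stained section contains three color populations: Prussian-blue
pigment (ferric iron reacted with ferrocyanide), eosin-pink counterstained
tissue, and background. Classification is purely chromatic: a pixel is
`blue` when each of its R, G, B values lies inside the blue class's
per-channel inclusive interval, `pink` likewise, `other` otherwise. The two
boxes are axis-aligned in RGB space — the simplest structure consistent with
an interactive "adjust three channel thresholds per class" workflow. The
readout is

$$\mathrm{ratio} = \frac{\#\,\mathrm{blue}}{\#\,\mathrm{blue} + \#\,\mathrm{pink}}$$

so background never enters numerator or denominator; the ratio is the
iron-deposition area as a fraction of recognized tissue area. In the modeled
assay this ratio spans roughly $0.7\times10^{-4}$ (saline) to
$30\times10^{-4}$ (direct iron injection).

### Parameters and defaults

* **Threshold boxes** (`rgb_threshold_set`, 0–255 per channel, bounds
  inclusive on both ends, matching common 8-bit threshold semantics). The
  original assay's values were set empirically and never published, so the
  shipped `default_thresholds()` is a documented stand-in: blue =
  R [0,120], G [0,130], B [120,255]; pink = R [150,255], G [60,210],
  B [100,220]. Every result records `thresholds_used`, and
  `calibrate_thresholds()` can replace the default from annotated
  pure-class patches (grid search maximizing balanced per-class accuracy;
  ties broken by earliest grid ordering, so calibration is deterministic).
* **Precedence**: a pixel inside both boxes is `blue`. The assay's analyte
  is iron; when boxes overlap, the iron-centric reading is the conservative
  choice for an iron-deposition ratio.
* **Batch policy**: one threshold set per batch, applied to every image
  (between-group comparison requires batch-level consistency); per-image
  overrides exist in `stain_batch()` but must be explicit. Whether the
  original workflow re-tuned per image is ambiguous; the batch-fixed
  reading is adopted.
* **Tissue mask** (optional): excludes pixels from the map and all counts.

One documented ambiguity: the assay's denominator is described both as
"whole brain tissue area" and as blue + pink pixel totals. The explicit
pixel formula is implemented; under a pink box that captures tissue well the
two readings coincide up to unstained-tissue pixels.

### Degenerate inputs

`blue + pink == 0` (no recognizable tissue) is an error, not a zero — it
signals a mis-thresholded or empty image. Non-8-bit or non-RGB input is
rejected rather than silently rescaled.

## 2. Ventricular volumetry

Volume is the Cavalieri estimator: per-slice segmented area × slice
thickness, summed over slices, mm³ converted to mL (÷1000). For a single
slice this reduces to area × thickness. Compartments are carried per record
(`LATERAL_L`, `LATERAL_R`, `THIRD`, `AQUEDUCT`, `FOURTH`, `EXTRA_AXIAL`);
the default inclusion set is lateral + third ventricles, because in coronal
neonatal scans only those are consistently captured — aqueduct, fourth
ventricle and extra-axial CSF spaces are excluded by default. Left/right
lateral ventricles stay separate labels (bilateral injections make
laterality worth preserving) and are summed at volume time.

Slice thickness is a **required user input with no default**: the modeled
study never states its value numerically. Mixed thickness within one scan is
an error unless explicitly overridden. Missing visits (death before D26,
scanner downtime) stay absent from trajectory tables — never imputed.

Accuracy: for an ellipsoid the cross-sectional area is quadratic in the
through-plane coordinate, so the midpoint-rule Cavalieri sum has error
$\pi a b\, t^2/(6c)$ — about 3% at 0.5 mm slices and 0.1% at 0.1 mm for a
2 × 1.5 × 1 mm phantom — plus a rasterization term controlled by the
in-plane pixel spacing (0.02 mm default in the phantom generator).

## 3. Statistics

### Trend analysis

`trend_from_means()` is closed-form OLS (`slope = cov/var`) plus Pearson's
*r*. The published trajectory fits regress the **four per-day group means**,
not the per-animal points, and that is the default unit in
`trend_by_group()` (`unit = "animals"` gives the pooled alternative). On the
reference mean trajectories this reproduces the published iron slope
0.04310 mL/day (*r* = 0.9793) and L-RBC slope 0.01495 (*r* = 0.9900)
exactly to printed precision; the control slope is only reproducible to ~2
significant figures because the printed means are themselves rounded.
A constant response makes *r* undefined: it is returned as flagged `NA`
with slope 0, never a silent 0.

### Gated group comparison

`compare_groups()` reproduces the full decision tree:

1. **Normality gate**: Shapiro–Wilk per group; parametric only if every
   group's p ≥ α (α = 0.05 throughout, surfaced as a knob). Groups with
   n < 3 or zero spread route to the nonparametric family with a visible
   warning — conservative and reproducible.
2. **Parametric, 2 groups**: unpaired two-tailed Student's t.
3. **Parametric, >2 groups**: variance gate first — Brown-Forsythe test of
   equal spread (Levene on deviations from medians), the k-group
   generalization of the two-group F test. The gate is applied only on this
   branch because that is where the source procedure states it. Equal
   spread → one-way ANOVA + Tukey all-pairs; unequal → Brown-Forsythe F\*
   and Welch ANOVA (Welch p reported as the omnibus, F\* alongside) +
   Dunnett many-to-one against the first (control) group.
4. **Nonparametric**: Mann–Whitney (2 groups) or Kruskal–Wallis + Dunn
   all-pairs (tie-corrected z statistics, two-sided, Bonferroni-adjusted —
   the adjustment family is not stated in the source, and Bonferroni is the
   common Prism-style default; adjusted p is never below unadjusted).

Standard statistics are delegated (`shapiro.test`, `t.test`, `aov` +
`TukeyHSD`, `oneway.test`, `car::leveneTest`, `multcomp::glht`,
`wilcox.test`, `kruskal.test`); the Dunn and Brown-Forsythe-F\* statistics
are implemented in the package. The returned `gate_trace` (per-group
Shapiro p, variance-gate p, α) fully determines the branch, so every choice
is replayable. Design note: after an unequal-variance omnibus the classic
Dunnett correction (rather than its T3 variant) is used, matching the
stated post hoc by name; this branch carries no headline result.

Cross-day group contrasts are run as a per-day omnibus + post hoc
(`compare_by_day()`); whether the source ran them that way or as isolated
pairwise tests is not stated, and the per-day omnibus reading is the more
conservative.

## 4. Synthetic data: what it emulates, what it does not

* `make_stain_image()` — three color populations at controlled mixing
  fractions. Class counts are exact by largest-remainder allocation of the
  target fractions; colors are Gaussian around class centers (sd
  `jitter_sd`, rounded, clamped to [0,255]); layouts are uniformly
  scattered pixels or compact blobs. Default centers sit inside the default
  threshold boxes so the zero-jitter closed loop recovers ground truth
  exactly, and jitter sd 8 keeps ±3 sd inside the boxes. It does **not**
  emulate stain gradients, chromatic aberration, tissue texture, nuclei,
  or slide-scanner illumination fields — passing tests show classifier
  correctness against known chromatic populations, not robustness to real
  histology variability.
* `make_ventricle_stack()` — an axis-aligned ellipsoid phantom with
  analytic volume $\tfrac{4}{3}\pi abc$, rasterized per slice at its
  mid-plane. Not an anatomical ventricle shape; it validates the
  integration rule, not segmentation.
* `make_cohort()` — per-subject volumes drawn log-normal around the
  four-group reference mean trajectories (log-normal guarantees positive
  volumes and right skew). The default between-subject spread is CV = 1.13
  at every group-day: the mean of the three CVs recoverable from the
  reported day-26 SEMs (iron 1.00, control 1.17, hemoglobin 1.23); per-day
  spreads beyond those three points are unknown and this constant-CV
  default is an assumption. Optional dropout emulates death from severe
  hydrocephalus: after a drawn volume exceeds a threshold, each later
  visit is missed with the given probability, leaving absent rows. Real
  cohorts additionally have within-subject autocorrelation, which the
  generator does not model — trajectories here are independent draws per
  visit.

Every generator is a pure function of spec + seed (bit-reproducible).

## 5. Problem sizes used in validation

The shipped validation suite regresses the four reference mean trajectories
(4 points each); recovers stain ratios on 50 seeded 50 × 50 images spanning
blue fractions 0–0.05 (the assay's observed scale) within 0.005 absolute;
integrates the 2 × 1.5 × 1 mm phantom at 0.5/0.25/0.1 mm slices (≤ 2%
error at 0.1 mm, error non-increasing under refinement); estimates the
gated pipeline's type-I error on four n = 10 Gaussian null groups over
2000 replicates (nominal band 0.035–0.065); and measures the day-26
four-group configuration at n = 10/group over 1000 seeds, where the
nonparametric branch with significant iron-vs-control and L-RBC-vs-control
post hocs is selected in ≈ 96% of seeds. These sizes keep the whole suite
in the tens of seconds on a laptop while leaving Monte-Carlo error well
below the tested margins.

## 6. Known limitations

* The default threshold boxes are a stand-in, not the original assay's
  values; quantitative comparability across laboratories requires
  calibration on each staining batch.
* Chromatic-box classification cannot separate overlapping stain colors;
  optical-density stain deconvolution is out of scope.
* Volumetry consumes segmented areas; it does not segment.
* The comparison machinery is cross-sectional per day; mixed-effects
  longitudinal modeling and survival analysis of early deaths are out of
  scope.
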