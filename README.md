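# phhquant

Quantitative analysis for a neonatal rat model of post-hemorrhagic
hydrocephalus (PHH). After intraventricular injection of blood breakdown
products — saline control, hemoglobin (Hb), ferric iron (Fe³⁺), or lysed red
blood cells (L-RBC) — disease burden is quantified two ways, and this
package implements both readouts plus the statistical machinery around
them:

* **Blue/pink stain quantification.** Pixels of a Perls Prussian-blue +
  eosin stained section are classified by axis-aligned RGB boxes into blue
  (ferric-iron pigment), pink (tissue) or other, and iron deposition is
  reported as the unitless ratio

  ratio = #blue / (#blue + #pink)

  so background never enters the denominator. Threshold boxes are
  serializable, recordable per result, and calibratable from annotated
  patches (`calibrate_thresholds()`).

* **Ventricular CSF volumetry.** The Cavalieri estimator
  V = Σ (slice area × slice thickness), in mL, over an explicit
  compartment-inclusion policy (lateral + third ventricles by default;
  aqueduct, fourth ventricle and extra-axial spaces excluded). Missing
  visits are preserved as absent, never imputed.

* **Trend + gated group comparison.** Closed-form OLS slope and Pearson *r*
  of per-day group-mean trajectories, and the full normality-gated test
  selection: Shapiro–Wilk per group, then Student's t / one-way ANOVA +
  Tukey / Brown-Forsythe & Welch ANOVA + Dunnett (after a Brown-Forsythe
  variance gate) / Mann–Whitney / Kruskal–Wallis + Dunn (Bonferroni),
  with the complete gate trace returned so every branch choice is
  replayable.

* **Synthetic data.** Seeded, bit-reproducible generators for stained
  sections with exact ground-truth class counts, ellipsoid ventricle
  phantoms with analytic volumes, and four-group longitudinal cohorts
  whose generating means are the reference group trajectories — so the
  whole pipeline is testable without slides or scans.

See `vignettes/phh-methods.Rmd` for the models, defaults and numerical
choices, and their rationale.

## Worked example

```r
library(phhquant)

# trend of the iron group's reference mean trajectory (D5/12/19/26)
m <- reference_cohort_means()
iron <- m[m$group == "iron", ]
trend_from_means(iron$day, iron$mean_volume_mL)
#> linear trend over 4 points: slope 0.0431 mL/day, intercept -0.2264 mL, Pearson r 0.9793

# stain quantification of a synthetic section with known truth
sim <- make_stain_image(stain_image_spec(width = 100, height = 100,
  blue_fraction = 0.003, pink_fraction = 0.95, jitter_sd = 8, seed = 42))
blue_pink_ratio(classify_pixels(sim$image), image_id = "synthetic_42")
#> blue/pink stain ratio: 0.00314795  (blue 30 / [blue 30 + pink 9500])
#>   image: synthetic_42
#>   thresholds: phhquant-default

# day-26 four-group comparison on a simulated cohort (n = 10/group)
coh <- make_cohort(cohort_spec(n_per_group = c(control = 10L, Hb = 10L,
  iron = 10L, `L-RBC` = 10L), seed = 1))
compare_by_day(coh, control = "control")$day_26
#> between-group comparison
#>   groups: control (n=10), Hb (n=10), iron (n=10), L-RBC (n=10)
#>   Shapiro-Wilk p: control 0.0841, Hb 0.00466, iron 0.0635, L-RBC 9.29e-06
#>   test chosen: KRUSKAL_WALLIS_DUNN
#>   omnibus p: 4.95e-07
#>   post hoc (adjusted p):
#>     control vs Hb                1
#>     control vs iron              2.656e-06
#>     control vs L-RBC             0.001553
#>     Hb vs iron                   0.0004509
#>     Hb vs L-RBC                  0.06225
#>     iron vs L-RBC                0.9758
```

The trend slope 0.0431 mL/day with *r* = 0.9793 says the iron group's mean
ventricular volume grows ~43 µL per day, almost perfectly linearly, over
postnatal days 5–26. The stain ratio 0.0031 is the fraction of recognized
tissue pixels carrying Prussian-blue pigment. The day-26 comparison routes
to Kruskal–Wallis + Dunn because two groups fail the Shapiro–Wilk gate, and
finds iron and L-RBC volumes significantly above control while Hb does not
differ from control — the qualitative signature of iron-driven
hydrocephalus.

A command-line wrapper over the same functions lives at
`inst/cli/phhquant.R` with subcommands `stain`, `volume`, `trend`,
`compare`, `simulate`, each writing a JSON run manifest (config, seed,
input digests).

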