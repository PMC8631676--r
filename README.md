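# ecglvh

Detecting echocardiographic left ventricular hypertrophy (LVH) from the
12-lead ECG.

Echocardiography is the workhorse reference test for LVH: LV mass is
computed from diastolic linear measurements with the cube formula
`LVM = 0.8·1.04·[(LVID + LVPWT + IVST)³ − LVID³] + 0.6` g, indexed to
Mosteller body surface area (`LVMI = LVM/BSA`), and called positive above
115 g/m² in men and 95 g/m² in women. ECG criteria are cheap proxies for
that call, but the classical ones (Sokolow-Lyon, Cornell, Dalfó, Cornell
voltage-duration product, Romhilt-Estes) trade sensitivity away for
specificity. This package is a toolkit for building and judging such
criteria:

* the **CHCM** (cardiac hypertrophy computer-based model), a three-node
  decision-tree criterion on automated ECG measurements — T-wave voltage
  in lead I (≤ 0.055 mV), and peak-to-peak QRS amplitude in aVL
  (> 1.235 mV) and aVF (> 0.178 mV) — with two positive phenotypes
  (repolarization-type and voltage-type LVH), shipped as a replaceable
  JSON tree spec;
* the full comparator criteria battery and the echo reference standard
  (BSA, LVM, LVMI, LVH severity, relative wall thickness, geometry);
* a from-scratch **cost-sensitive entropy-based tree inducer** of the
  kind that produces such criteria: midpoint-threshold information-gain
  splits with an MDL penalty, minimum-expected-cost leaf labeling, and
  global pessimistic-error pruning;
* **diagnostic evaluation**: confusion matrices, Se/Sp/PPV/NPV, exact
  (Clopper-Pearson) and Wilson intervals, prevalence/accuracy/NPV
  identities, and bit-exact reconstruction of a 2×2 table from published
  summary rates;
* a seeded **synthetic cohort generator** with sex-specific LV mass
  distributions, configurable LVH prevalence and class-conditional ECG
  effects, so the whole pipeline runs end to end without patient data.

Everything is tidyverse-shaped: cohorts are tibbles (one row per patient,
canonical columns and units in `cohort_schema()`), functions pipe, fitted
trees have `tidy()`/`glance()`/`autoplot()` methods.

## Worked example

```r
library(ecglvh)

cohort <- generate_cohort(cohort_config(n_patients = 500, seed = 2024))
evaluate_criteria(cohort, reference = "chcm") |>
  dplyr::select(criterion, delta_accuracy, accuracy,
                sensitivity, specificity)
#>   criterion delta_accuracy accuracy sensitivity specificity
#> 1 sokolow           -0.130    0.590       0.098       0.993
#> 2 cornell           -0.084    0.636       0.200       0.993
#> 3 dalfo              0.040    0.760       0.644       0.855
#> 4 vdp               -0.030    0.690       0.320       0.993
#> 5 romhilt            0.082    0.802       0.658       0.920
#> 6 chcm               0.000    0.720       0.636       0.789
```

On this synthetic cohort (46% LVH prevalence, echo-derived ground truth)
the pure voltage criteria show the textbook pattern — near-perfect
specificity, single-digit-to-30% sensitivity — while the CHCM and the
point-score criteria trade a little specificity for several-fold higher
sensitivity. Individual patients carry a full decision trace:

```r
chcm_classify(cohort[1, ])$path[[1]]
#>   feature        op    threshold observed result
#> 1 T_amp_I_mV     le       0.055   -0.0253 TRUE
#> 2 QRS_ppk_aVF_mV gt       0.178    1.25   TRUE
```

A flat or inverted T wave in lead I with preserved aVF voltage lands this
patient in the repolarization-type LVH leaf.

Published performance tables can be audited without patient-level data:

```r
reconstruct_cm(156, 0.474, 0.42, 0.829) |> metrics_from_cm()
# accuracy 0.635, ppv 0.689, npv 0.613 from an integer 2x2 table
implied_prevalence(0.743, 0.687, 0.538)   # 0.329
accuracy_from_rates(0.743, 0.687, 0.329)  # 0.705
```

See the methods vignette (`vignettes/ecglvh-methods.Rmd`) for the models,
parameter choices, and what synthetic-cohort results do and do not show.

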