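---
title: "Methods: ECG detection of echocardiographic LVH"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG detection of echocardiographic LVH}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecglvh)
```

## The problem

Left ventricular hypertrophy (LVH) is a strong predictor of cardiovascular
morbidity and mortality. The reference test in routine practice is
echocardiography: LV mass is computed from diastolic linear measurements,
indexed to body surface area, and compared to sex-specific limits. The ECG
is far cheaper and ubiquitous, but the classical ECG voltage criteria have
notoriously poor sensitivity. This package implements a complete pipeline
for studying that trade-off on tabular per-patient data: the
echocardiographic reference standard, a battery of classical ECG criteria,
a compact decision-tree ECG criterion (the CHCM), the cost-sensitive
entropy-based tree inducer that produces such criteria, diagnostic
performance evaluation with exact intervals, and a seeded synthetic cohort
generator so the whole pipeline is testable end to end without patient
data.

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe. A *cohort* is an ordinary tibble, one row per
patient, with the canonical column names and units given by
`cohort_schema()` (amplitudes mV, durations ms, dimensions cm, mass g,
LVMI g/m²).

## Echocardiographic reference standard

Ground truth is computed per patient from diastolic septal thickness
(IVST), internal diameter (LVID), posterior wall thickness (LVPWT), weight,
height and sex:

* body surface area: `sqrt(weight * height / 3600)` (Mosteller);
* LV mass by the cube formula:
  `0.8 * 1.04 * ((LVID + LVPWT + IVST)^3 - LVID^3) + 0.6` g;
* LVMI = LVM / BSA; LVH is positive strictly above 115 g/m² (men) or
  95 g/m² (women);
* relative wall thickness `2 * LVPWT / LVID` partitions geometry into
  normal, concentric remodeling, concentric and eccentric hypertrophy at
  RWT 0.42 (the boundary belongs to the low-RWT side);
* severity stages use bands anchored at the cutoffs. The published bands
  are printed as integer intervals (e.g. mild 116–131 g/m²), which leaves
  non-integer LVMI values such as 115.5 unclassified; we implement the
  bands as continuous half-open intervals — male mild (115, 131], moderate
  (131, 148], severe > 148; female (95, 108], (108, 121], > 121 — so the
  classification is total. "Above the cutoff" is strict; band upper edges
  are inclusive.

```{r}
tibble::tibble(sex = "male", IVST_cm = 1.34, LVID_cm = 4.77,
               LVPWT_cm = 1.33, weight_kg = 78.2, height_cm = 166.3) |>
  echo_ground_truth() |>
  dplyr::select(lvm_g, lvmi_g_per_m2, lvh_positive, severity, geometry)
```

## The ECG criteria battery

`score_criteria()` runs a registry of criteria; each can also be called
directly. Voltage thresholds are strict (`>`) as published;
Romhilt-Estes item comparisons use `>=`. S-wave amplitudes are magnitudes.

| criterion | rule |
|---|---|
| `sokolow` | R aVL > 1.1 mV |
| `cornell` | S V3 + R aVL > 2.8 mV (men) / > 2.0 mV (women) |
| `dalfo` | S V3 + R aVL > 1.6 mV (men) / > 1.4 mV (women) |
| `vdp` | (R aVL + S V3 [+ 0.6 mV in women]) × QRS duration > 244 mV·ms |
| `romhilt` | six-item point score, positive at ≥ 4 points |
| `chcm` | the packaged decision tree below |

Two Romhilt-Estes details deserve note. The published item list prints the
QRS-duration and intrinsicoid thresholds as "0.09 msec" and "0.05 msec";
these are second-to-millisecond typos and are implemented as 90 ms and
50 ms, the standard values. The 3-point voltage group (any limb-lead R or S
≥ 2.0 mV, R in V5/V6 ≥ 3.0 mV, S in V1/V2 ≥ 3.0 mV) is awarded at most
once regardless of how many of its clauses hold, so the score stays in
0–13. P terminal force is measured in V1 in Ashman units (1 unit = 1 mm
depth × 0.04 s) and stored as a unitless count to avoid convention errors.

## The CHCM decision tree

The CHCM calls echo-LVH from three automated ECG measurements, combining a
repolarization marker with voltage evidence:

```{r}
chcm_tree()
```

Published sources fix the three thresholds (T-wave voltage in lead I
≤ 0.055 mV; peak-to-peak QRS in aVL > 1.235 mV; peak-to-peak QRS in aVF
> 0.178 mV), the node count, the two positive phenotypes, and the roles of
the parameters (the aVF test suppresses misclassification of low-voltage
tracings; the aVL test detects high-voltage LVH), but not the full drawing
of the topology. The packaged tree is the unique four-level arrangement
consistent with those constraints: the T-wave branch guarded by the aVF
minimum yields the *repolarization* phenotype, the aVL branch the
*voltage* phenotype, and no single parameter can produce a positive call.
The tree ships as a JSON spec file (`load_tree()`/`save_tree()`), not hard
code, so an alternative topology is expressible without touching the
package. Leaf probabilities in the shipped spec are 1/0 because class
frequencies at the leaves were not published; the 50% leaf rule
(`positive` iff `p > 0.5`) is enforced structurally for every tree.

## The tree inducer

`train_tree()` is a from-scratch, interpretable, cost-sensitive inducer in
the classic entropy style for continuous features:

* **Splitting.** At each node every feature's candidate thresholds are the
  midpoints between consecutive distinct sorted values; the
  (feature, threshold) pair with maximal information gain splits the node.
  Ties go to the earlier column, then the smaller threshold, so builds are
  fully deterministic. Gain ratio is available by flag.
* **MDL correction** (default on). The gain of a continuous split is
  penalized by `log2(m)/n` for `m` candidate thresholds before comparison,
  and a node splits only if the penalized gain is positive. Without this
  term, exhaustive threshold search reliably finds spuriously
  "significant" splits in pure noise that confidence-based pruning cannot
  undo.
* **Stopping.** Pure nodes, nodes below `2 * min_cases_per_leaf` cases,
  zero (penalized) gain, or `max_depth`.
* **Cost-sensitive leaves.** With false-negative cost `c_fn` and
  false-positive cost `c_fp`, a leaf with `n+` positives and `n-`
  negatives stores `p = n+ c_fn / (n+ c_fn + n- c_fp)` and is labeled
  positive iff `p > 0.5`. This is exactly the minimum-expected-cost label,
  reduces to the empirical class frequency at equal costs, and keeps every
  induced tree consistent with the 50% leaf rule. The default cost ratio
  is 2:1 (false negatives dearer) — the direction is dictated by the
  screening use case, the magnitude is a package default and fully
  configurable, since only the direction is published.
* **Global pruning.** A bottom-up pass compares each subtree's pessimistic
  error (sum over leaves of `n * U(e, n)`, with `U` the one-sided binomial
  upper bound at confidence `pruning_confidence`, default 0.25) with that
  of collapsing to a single leaf, and collapses whenever the subtree is
  not strictly better. Error counts use the *majority class*, not the
  cost-weighted label: pruning therefore depends only on the data, and the
  cost matrix can only relabel leaves from negative to positive. This
  makes a useful property structural — raising the false-negative cost can
  never reduce training-set sensitivity — at the price that pruning does
  not account for asymmetric costs when estimating subtree value.

`split_cohort()` provides the seeded simple random 70/30-style partition
used to separate training from testing data.

## Diagnostic evaluation

`evaluate_criteria()` scores a cohort, compares each criterion with the
echo ground truth and reports accuracy (with CI), sensitivity,
specificity, PPV, NPV and the accuracy difference against a reference
criterion. Supporting primitives:

* `binomial_ci()`: Clopper-Pearson via beta quantiles (default; the exact
  interval) or Wilson score. For interior counts Clopper-Pearson is at
  least as wide as Wilson; at 0 or n successes the one-sided exact
  interval can be marginally narrower.
* `reconstruct_cm()` rebuilds an integer 2×2 table from (n, prevalence,
  Se, Sp), rounding half-away-from-zero in a fixed order (cases, then tp,
  then tn) so reconstructions are bit-exact and auditable.
* `implied_prevalence()`, `accuracy_from_rates()` and `npv_from_rates()`
  are the Bayes identities linking Se/Sp/PPV/NPV/prevalence/accuracy; they
  let one check a published performance table for internal consistency
  without patient-level data.
* Ratios with zero denominators are reported as absent (`NA` plus a
  reason), never coerced to 0 or 1.

```{r}
reconstruct_cm(156, 0.474, 0.42, 0.829) |> metrics_from_cm() |>
  dplyr::select(accuracy, sensitivity, specificity, ppv, npv)
```

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the criteria
assume, not ECG waveforms:

* **Echo.** A latent LVH mixture component is drawn per patient; echo
  dimensions and anthropometrics come from class-conditional truncated
  normals. The component distributions default to published
  case/control group statistics (control IVST 1.04 (0.19) cm, LVID
  4.38 (0.63) cm, LVPWT 1.04 (0.19) cm; LVH 1.34 (0.27), 4.77 (0.80),
  1.33 (0.24); weight and height analogous), with IVST–LVPWT correlation
  0.8 (both walls thicken together; the exact correlation is not
  published and is configurable).
* **Calibration.** Because the cube formula is nonlinear, the echo-derived
  LVH rate of a mixture is not its mixing weight. The generator estimates
  the per-component echo-positive rates by a seeded internal Monte Carlo
  and solves for the weight that makes the *echo-derived* prevalence hit
  the configured target (default 0.462). Unreachable targets warn and
  clip. The echo-derived class — not the latent component — is the ground
  truth used everywhere downstream.
* **ECG.** Features are drawn conditionally on the echo class: voltages
  shift up in LVH, T-wave amplitude in lead I shifts down (it may be
  negative; floor −1 mV), durations lengthen slightly. In aVL and aVF the
  R and S amplitudes are drawn as fractions of the lead's peak-to-peak
  amplitude, which guarantees the dominance invariant (peak-to-peak ≥
  each wave) while keeping a realistic low-voltage tail — the tail the
  CHCM's aVF guard exists for. `ecg_effect_scale = 0` removes all
  class-ECG association, giving a null cohort on which every criterion's
  Youden index is ~0. Uninformative `noise_*` columns emulate the bulk of
  an automated ECG export.
* **Planted labels.** `plant_tree_labels()` labels a cohort by a known
  tree plus independent label noise, enabling parameter-recovery
  experiments: at n = 2000 and 10% noise the learner (with
  `min_cases_per_leaf = 25`, a conventional minimum-leaf setting for
  noisy clinical data of this size) recovers exactly the three planted
  CHCM features with thresholds inside one inter-point gap of the planted
  ones.

What passing tests on these cohorts shows is that the *machinery* is
correct — formulas, thresholds, induction, pruning, metrics. It does not
show that any criterion attains its published accuracy on real patients:
the generator draws from idealized truncated normals, has no measurement
error model, no rhythm or conduction abnormalities, and only a scalar
correlation between walls.

## Numerical and design notes

* Sizes used by the shipped experiments: recovery n = 2000; null-pruning
  100 replicates of n = 200 with 3 noise features; cost-sensitivity 20
  cohorts of n = 300. These give stable statistics while keeping a full
  run in seconds to minutes on one core.
* Tie-breaks and degenerate inputs: constant features return "no split";
  empty branches inherit nothing (every generated split has two non-empty
  children by construction of midpoint thresholds); zero-denominator
  ratios are absent, not zero; duplicated patient ids, non-finite
  amplitudes, non-positive dimensions and unknown sex codes are rejected
  at validation with the field named.
* The half-open severity bands, the Romhilt-Estes unit fixes, the CHCM
  topology reconstruction and the cost-free pruning rule are the places
  where this package had to resolve ambiguity in its sources; each is
  flagged above in its own section.
* Limitations: no ROC/AUC analysis, no alternative LVMI indexations
  (height^2.7), no waveform-level simulation, no handling of missing
  values by design (records with gaps in required features are rejected,
  matching a complete-case regime).
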