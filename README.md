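# csieval — evaluating functional-sparing craniospinal irradiation plans

Craniospinal irradiation (CSI) cures most children with average-risk
medulloblastoma, but irradiating the whole brain and spine at 23.4 Gy in
13 fractions carries lifelong costs: neurocognitive decline from
hippocampal dose, endocrine dysfunction from the hypothalamic–pituitary
axis (HPA), hearing loss, alopecia, and spinal deformity from uneven
vertebral dose. Functional-sparing VMAT techniques carve dose away from
these structures — and the question a planning study must answer is what
that sparing buys (lower predicted complication probabilities) and what
it costs (coverage, robustness to setup error, deliverability).

`csieval` is the evaluation side of that question, for medical physicists
and planning-study authors. It implements, as tested R functions:

* **DVH and dosimetric indices** — exact bin-free cumulative DVHs;
  D<sub>x%</sub>, D<sub>cc</sub>, V<sub>xGy</sub>, mean/min/max;
  homogeneity index HI = (D₂% − D₉₈%)/D₅₀%; Paddick conformity index
  CI = V²<sub>t,ref</sub>/(V<sub>t</sub>·V<sub>ref</sub>); vertebral dose
  gradient D₂% − D₉₈%; goal-sheet evaluation.
* **Radiobiology** — EQD2 = D·(d + α/β)/(2 + α/β); gEUD = (Σ vᵢDᵢ^(1/n))ⁿ;
  the Lyman–Kutcher–Burman probit NTCP = Φ((D_eff − TD₅₀)/(m·TD₅₀)) for
  hippocampus (on EQD2 of D₄₀%, TD₅₀ = 14.88 Gy, m = 0.54, α/β = 2) and
  scalp (on gEUD with n = 0.14, TD₅₀ = 22 Gy); a multivariate parametric
  endocrine model in HPA dose, age and follow-up time; a logistic cochlear
  model in median dose (b₀ = −5.3, b₁ = 0.085); Niemierko EUD/TCP for the
  target.
* **Robustness** — the canonical 30-scenario rigid setup-error set
  (±2/3/5 mm, ±1/2°), DVH bands, and λ = (D_best − D_worst)/D_nominal·100%
  per magnitude group.
* **Plan complexity** — MU, control points, beam irregularity (PI),
  modulation complexity score (MCS), small aperture score (SAS10), mean
  field area, mean leaf gap, mean leaf travel, per beam / isocenter / plan.
* **Delivery QA** — global 2-D/3-D gamma analysis (3%/3 mm, 2%/2 mm),
  planned-vs-delivered ΔDVH, and delivery-log RMS mechanical errors.
* **A synthetic head-and-spine phantom** (`phantom_spec`, `generate_dose`,
  `generate_plan`, `generate_log`) whose sparing dips, vertebral gradient
  and plan modulation are controllable and seeded, so the entire pipeline
  runs end to end with no patient data.

See `vignettes/csi-plan-evaluation.Rmd` for the models, conventions and
their assumptions, and the limits of what the synthetic phantom emulates.

## Worked example

The radiobiological chain at published cohort-mean hippocampal doses —
D₄₀% of 24.0 Gy for a standard plan versus 12.7 Gy for a
functional-preservation plan, both in 13 fractions with α/β = 2:

```r
library(csieval)
scheme <- fractionation_scheme(n_fractions = 13, alpha_beta_Gy = 2)
d40 <- c(standard = 24.0, sparing = 12.7)
data.frame(D40_Gy   = d40,
           EQD2_Gy  = round(eqd2(d40, scheme), 2),
           NTCP_pct = round(100 * hippocampal_ntcp(d40, scheme), 1))
#>          D40_Gy EQD2_Gy NTCP_pct
#> standard   24.0   23.08     84.6
#> sparing    12.7    9.45     25.0
```

The sparing plan converts an 84.6% predicted probability of
neurocognitive impairment into 25.0%. The same chain runs on synthetic
dose distributions — here a coarse phantom with the default sparing
recipe, followed by a robustness study of the hippocampal D₄₀% under the
30-scenario setup-error set:

```r
ph   <- generate_phantom(phantom_spec(grid_shape = c(48, 48, 100),
                                      spacing_mm = c(4, 4, 4),
                                      spine_length_mm = 150, seed = 7))
dose <- generate_dose(ph, dose_recipe(mode = "functional_sparing"), seed = 7)
dvh  <- compute_dvh(dose, ph$structures$hippocampus)
dose_metric(dvh, "Dmean")   # 12.4 Gy: the recipe's sparing target, recovered
dose_metric(dvh, "D40%")    # 12.5 Gy

st <- robustness_study(dose, ph$structures,
                       metric_map = c(hippocampus = "D40%"),
                       isocenter_mm = ph$geometry$head_centre_mm)
st$summary[, c("group", "nominal", "band_width", "lambda_percent")]
#>  group nominal band_width lambda_percent
#>    ±1°    12.5      0.163           1.30
#>  ±2 mm    12.5      0.800           6.40
#>    ±2°    12.5      0.226           1.81
#>  ±3 mm    12.5      1.379          11.04
#>  ±5 mm    12.5      2.375          19.02
```

λ grows with shift magnitude because the sparing dips place steep dose
gradients at the hippocampus — the robustness price of sparing. A standard
(unspared) dose on the same phantom gives λ near zero in every group.

## The analysis workflow

`analysis/` holds the numbered study drivers, run from the repository
root in order:

| script | stage | writes |
| --- | --- | --- |
| `01_simulate_phantom.R` | 2 mm phantom, sparing + standard doses/plans/logs | `results/cohort/` (interchange files) |
| `02_dosimetry.R` | PTV/organ dose metrics, goal sheet | `results/02_*.csv` |
| `03_ntcp.R` | EQD2 and the four NTCP models | `results/03_ntcp.csv` |
| `04_robustness.R` | 30-scenario λ per structure/magnitude | `results/04_*.csv` |
| `05_complexity.R` | complexity metrics per isocenter group | `results/05_complexity.csv` |
| `06_delivery_qa.R` | log RMS, gamma, ΔDVH | `results/06_*.csv` |
| `07_cohort_report.R` | 4-patient cohort with paired statistics | `results/cohort_report/` |

Each script prints what it found; stage 7 wraps the whole study in
`run_pipeline()`, whose outputs are a pure function of the configuration
(reruns are byte-identical).

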