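---
title: "Methods: dosimetric, radiobiological and deliverability evaluation of craniospinal irradiation plans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CSI plan evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`csieval` evaluates volumetric modulated arc therapy (VMAT) craniospinal
irradiation (CSI) plans, with particular attention to functional-sparing
techniques that carve dose away from the hippocampus, the
hypothalamic–pituitary axis (HPA), the cochlea and the scalp while holding
target coverage and vertebral dose homogeneity. It covers five evaluation
layers — dose–volume metrics, normal-tissue complication probability (NTCP)
models, setup-uncertainty robustness, MLC plan-complexity metrics, and
planned-versus-delivered QA — plus a synthetic head-and-spine phantom
generator so the full pipeline runs, and is tested, without patient data.

The package evaluates plans; it does not create them. There is no inverse
optimization, no beam transport, and no CT/heterogeneity modelling.

# Dose model and DVH conventions

A `dose_grid` is a 3-D dose array with per-axis spacing and origin; axes are
(x = left–right, y = anterior–posterior, z = superior–inferior), voxel
centres at `origin + (index − 1) · spacing` (mm). Structures are boolean
masks voxelised by the voxel-centre-in-region rule.

Three conventions remove tolerance knobs from everything downstream:

* **Bin-free DVHs.** The cumulative DVH is the exact sorted vector of
  in-structure voxel doses; `D_x%` is a linearly interpolated order
  statistic (the smallest dose received by the hottest x% of the volume,
  the standard ICRU reading), and `D_cc` is the analogue on absolute
  volume. No fixed-width dose bins exist anywhere, so unit tests can be
  exact. Ties are resolved by a stable sort; this cannot change any metric.
* **Whole-voxel volumes.** `volume_cc` is the true-voxel count times the
  voxel volume. No partial-volume weighting — a documented limitation,
  visible mostly for structures a few voxels across (cochlea, pituitary).
* **No resampling for metrics.** Metrics are computed on the native grid.

The homogeneity index is `HI = (D2% − D98%)/D50%` and the Paddick
conformity index is `CI = covered² / (target · isodose)`. The vertebral
dose gradient is `D2% − D98%` over the vertebral mask. In the pipeline the
conformity/coverage isodose is taken at 95% of the prescription: the
synthetic dose plateaus exactly at the prescription inside the target, so
the prescription isodose itself is degenerate under calculation noise.

# Radiobiological models

All models are forward evaluations; nothing is fitted. Parameters ship in
`inst/extdata/ntcp_params.yaml`, keyed by organ.

**Fractionation.** The linear-quadratic equivalent dose in 2-Gy fractions
is `EQD2 = D · (d + α/β)/(2 + α/β)` with `d = D/n` the per-fraction dose.
With `d = 2 Gy` the conversion is the identity; the test suite checks the
closed form against a per-fraction BED summation at machine precision.

**gEUD.** `gEUD = (Σᵢ vᵢ Dᵢ^{1/n})ⁿ` over the differential dose
distribution. `n = 1` is the mean dose; small positive `n` weights the hot
end (serial organs); the tumor convention `n = 1/a` with `a < 0` weights
the cold end.

**LKB probit.** `NTCP = Φ((D_eff − TD50)/(m · TD50))`, with Φ the standard
normal CDF (computed through `pnorm`, i.e. the error function — no lookup
tables). Two organ instances:

* hippocampus (neurocognitive impairment): `D_eff = EQD2(D40%)` with
  TD50 = 14.88 Gy, m = 0.54, α/β = 2;
* scalp (acute grade-2 alopecia): `D_eff = gEUD(n = 0.14)` with
  TD50 = 22 Gy, m = 0.54.

**Endocrine dysfunction (HPA).** A multivariate parametric model in dose,
age and follow-up time: `φ = exp(−(const + β_age·age + β_age²·age² +
β_dose·dose))`, `NTCP = 1 − 1/(1 + (φ·t)^{1/γ})`, where the dose is the
mean of the hypothalamic and pituitary D50% values. Defaults: γ = 0.56,
const = 3.13, β_age = −0.106, β_age² = 0.007, β_dose = −0.049, t = 5
years. Age is age at treatment, in continuous years. `t = 0` gives
NTCP = 0 exactly.

**Hearing loss (cochlea).** Logistic in the median cochlear dose with
b₀ = −5.3, b₁ = 0.085.

**Target EUD/TCP.** EUD through `geud` with a tumor exponent `a`, and the
Niemierko logistic `TCP = 1/(1 + (TCD50/EUD)^{4γ₅₀})`. No validated
parameter set exists for pediatric medulloblastoma, so the function
refuses to run without explicit parameters; the registry ships an
*illustrative* set (a = −10, TCD50 = 30 Gy, γ₅₀ = 2) flagged as such.

**Cohort-mean caveat.** Published cohort tables report means of
per-patient NTCPs, while evaluating a model at cohort-mean inputs gives
the NTCP of the mean. Because the models are mildly nonlinear over a
tight cohort spread, the two differ by well under a percentage point at
the spreads involved; both paths are available (`run_pipeline` evaluates
per patient and then averages).

# Setup-uncertainty robustness

The canonical scenario set holds 18 translations (±2, ±3, ±5 mm on each
of the LR/AP/SI axes) and 12 rotations (±1°, ±2° in pitch, yaw, roll) —
30 scenarios in five magnitude groups of six.

A perturbed dose is the planned dose field rigidly transformed relative
to the structure frame and resampled trilinearly. This is the standard
isocenter-shift surrogate for a full perturbed recomputation; it ignores
dose changes from surface curvature and density, which is acceptable for
rank comparisons between plans but not for absolute perturbed dosimetry.
Design decisions, made once:

* rotations are intrinsic, applied roll → pitch → yaw about the cranial
  isocenter (pitch about LR, yaw about AP, roll about SI), all
  config-overridable through the scenario objects;
* the rotation centre is the cranial isocenter (the head centre in the
  phantom; a centroid in the analysis scripts), since no other centre is
  canonical for multi-isocentre CSI;
* voxels that sample outside the grid take the nearest-edge value (not
  zero), avoiding artificial cold spots at the grid boundary; structures
  whose sampled voxels fall outside the grid in more than 5% of voxels
  trigger a warning;
* the robustness index is `λ = (best − worst)/nominal × 100` with the
  extremes taken **within one magnitude group** (six scenarios), nominal
  excluded — matching per-magnitude reporting rows. Passing a different
  scenario list gives any alternative grouping, including all-30 extremes.

`robustness_study` samples the dose at the transformed coordinates of the
structure voxels instead of resampling the whole grid; this is exactly the
in-structure restriction of the full-grid transform (the tests assert
equality) and keeps a 30-scenario study on a 2 mm grid in seconds.

# Plan complexity

Control-point sequences carry two leaf banks (left ≤ right per pair), x
jaws, per-CP cumulative meterset, gantry angle and beam MU. Leaf pairs
with a gap at or below 1 mm count as closed (leaf-gap minima of 5 mm-leaf
MLCs are ~0.5–1 mm; config-exposed), and jaws clip gaps before any
area/gap computation. The leaf width defaults to 5 mm at isocenter.

The metric definitions follow the canonical forms of the VMAT
deliverability literature: beam irregularity per Du et al. (2014), the
modulation complexity score per McNiven et al. (2010) with the
adjacent-CP averaging of Masi et al. (2013) for VMAT, and the small
aperture score per Crowe et al. (2014):

* **PI** — per CP, aperture irregularity `AI = perimeter²/(4π·area)`,
  computed per connected run of open pairs and area-weighted (this keeps
  disjoint islands from cross-talking); MU-weighted over CPs, then over
  beams. The aperture perimeter is the MLC staircase: leaf-end steps plus
  side edges plus end caps. Note a geometric consequence: a rasterised
  disc's staircase perimeter converges to its Manhattan length `8r`, so
  its AI approaches `16/π² ≈ 1.62`, not 1 — the tests pin this limit. A
  square gives exactly `4/π`; AI ≥ 1 for any single-component aperture.
* **MCS** — per CP, the leaf-sequence variability per bank over the open
  pairs (`LSV`, 1 for aligned leaf ends; defined as 1 for a single open
  pair or zero positional range) multiplied across banks, and the
  aperture-area variability (`AAV`, aperture area over the beam's
  per-pair maximal openings); the beam MCS averages adjacent CP pairs
  weighted by segment MU. A static field fully open to its own maximum
  scores exactly 1.
* **SAS10** — MU-weighted fraction of open pairs with a gap under 10 mm.
* **MFA / MLG** — MU-weighted mean aperture area (cm²) and open-pair gap
  (cm).
* **MLT** — per beam, total leaf travel summed over CPs and averaged over
  all leaves (cm); aggregated MU-weighted at isocenter/plan scope. Whether
  plan-level MLT should be MU-weighted is not settled in the literature;
  MU-weighting was chosen for consistency with every other aggregate and
  is a one-line change.

Reports are emitted per beam, per isocenter group (cranial `iso1` versus
spinal `iso2`/`iso3`) and per plan.

# Planned-versus-delivered QA

**Gamma analysis** is global: dose differences are normalised to the
maximum of the reference distribution, and evaluated points below 10% of
that maximum are excluded (both conventions are standard QA practice and
config-exposed). The search minimises
`sqrt((Δd/ΔD)² + (Δr/DTA)²)` over a neighborhood of radius 3·DTA sampled
at DTA/10 steps with linear interpolation of the reference, visited in
order of increasing distance with early termination — deterministic, with
a bounded gap to the continuous optimum. Gamma is asymmetric in its
arguments; both directions are computable. Tightening the criteria can
only remove passing points, which the tests assert on every fixture.

**ΔDVH** is `delivered − planned` per structure/metric, exactly
antisymmetric under swapping inputs.

**Delivery logs** yield RMS errors over all leaves × CPs (MLC) and CPs
(gantry). The delivered dose itself is a *surrogate*: the MU-weighted mean
signed leaf-gap error, relative to the mean planned gap, scales the
planned dose as a global output factor. This captures the first-order
output effect of systematic gap errors and nothing spatial; it is a
stated limitation of the desk-scale pipeline, not an emulation of a Monte
Carlo reconstruction engine.

# The synthetic phantom and what it does (not) emulate

`phantom_spec`/`generate_phantom` build a pediatric-scale head sphere
(default radius 80 mm) with a cranial PTV (head minus a 10 mm margin),
paired hippocampi (~3 cc total), hypothalamus, pituitary, paired
cochleae, a 5 mm scalp shell, a spinal-canal cylinder (default 300 mm)
and a vertebral column abutting it posteriorly. No per-patient anatomy
statistics are published for the cohort this emulates, so the sizes are
plausible pediatric values, config-exposed and jittered (±1 mm SD) across
seeds; they are not claimed to match any cohort.

`generate_dose` composes, deterministically given (phantom, recipe, seed):

1. prescription dose inside the target envelope, a Gaussian penumbra
   (default σ = 6 mm) outside it, and a wide spinal dose bath;
2. a linear anterior–posterior ramp across the vertebrae whose amplitude
   is solved by 1-D root finding so the vertebral `D2% − D98%` equals the
   recipe's value (defaults 4.7 Gy sparing / 8.7 Gy standard, the spreads
   the two techniques produce);
3. in sparing mode, one anisotropic **super-Gaussian** well
   `exp(−u²/2)` (u the squared scaled radius, widths = structure
   semi-axes + 3 mm) per avoidance structure. A plain Gaussian tail
   proved too heavy: it dragged PTV D95 far below the 95% coverage level,
   whereas the super-Gaussian is flat over the structure and dies fast
   outside it. Because the wells enter linearly, their amplitudes come
   from solving the small linear system of well-means over the avoidance
   masks — the exact fixed point a per-well bisection would converge to,
   and it handles the overlapping hypothalamus/pituitary wells jointly;
4. additive Gaussian noise (default SD 0.05 Gy) emulating Monte Carlo
   calculation noise, then clipping at zero.

Default sparing targets are hippocampus 12.4, hypothalamus 14.7,
pituitary 15.4 and cochlea 21.4 Gy mean dose — the sparing levels the
technique is designed to reach. The standard mode applies no wells, so
interior organs sit at prescription.

What the phantom does **not** emulate: optimizer-shaped dose texture and
hot spots (the standard arm plateaus exactly at prescription, so its
near-maximum metrics are tighter than clinical plans), scalp-specific
sparing (the scalp dose is purely penumbral and identical between modes),
field junctions, couch/immobilisation dose, and any anatomy–plan coupling
(plans and doses are generated independently). Consequently, passing
tests demonstrate that the evaluation layers are correct and that the
direction of every technique contrast (sparing cuts functional-organ
NTCP, costs robustness at steep gradients, raises modulation) is
reproduced — they do not certify absolute cohort dosimetry, robustness
magnitudes or complexity means against clinical data.

# Numerical choices

* Trilinear interpolation is vectorised in-package and cross-checked in
  the tests against an independent loop implementation and the exactness
  property on trilinear polynomials; outside the grid it clamps to the
  nearest edge and reports the clamped fraction.
* All randomness flows through explicit integer seeds; RNG state is saved
  and restored around every draw, so library calls never perturb a
  session's RNG. Derived per-patient seeds stay below 2³¹.
* Problem sizes: the full phantom is 100×100×250 voxels at 2 mm (the
  resolution used for the headline robustness and recovery checks); unit
  tests run a 4 mm phantom, which keeps the whole suite around a minute
  while exercising identical code paths.
* Degenerate paired statistics (zero-variance differences) are flagged
  `degenerate` and report p = 1 (identical arms) or p = 0 (constant
  shift) instead of NaN. Wilcoxon signed-rank uses the normal
  approximation. No multiple-testing correction is applied across the
  report tables, matching how planning comparisons of this kind are
  conventionally reported; interpret single p-values accordingly.

# Known limitations

* Rigid-transform robustness ignores re-scatter and surface effects.
* The delivered-dose surrogate has no spatial resolution.
* Whole-voxel volumes bias small-structure metrics at coarse grids.
* NTCP parameter sets originate from adult or non-CSI cohorts; outputs
  are comparative, not absolute risks.
* The TCP parameter set is illustrative only.
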