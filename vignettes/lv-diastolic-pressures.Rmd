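---
title: "Non-invasive LV diastolic pressure estimation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive LV diastolic pressure estimation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvfill)
```

## The problem

Left-ventricular (LV) filling pressure is the central haemodynamic quantity
in the assessment of diastolic function and heart failure, but its direct
measurement requires catheterization. `lvfill` implements a non-invasive
estimation chain that produces the minimum LV pressure, the
pre-atrial-contraction (pre-A) pressure — a surrogate for mean left atrial
pressure — the end-diastolic pressure (EDP), the isovolumic relaxation time
constant $\tau$, and a patient-specific diastolic pressure *curve*, from
quantities an echo exam provides: a global longitudinal strain (GLS) trace,
a mitral inflow velocity trace, cuff systolic pressure, BMI, left atrial
reservoir strain (LARS) and LV volumes.

## The model

Three relations are combined.

**Relaxation (Weiss model).** During isovolumic relaxation LV pressure
decays exponentially, $P(t) = P_0 e^{-t/\tau}$. The decay is assumed to
start at a fixed fraction of systolic pressure, $P_0 = 0.65\,P_{sys}$, and
to last $0.85 \cdot IVRT$ down to the pressure at mitral valve opening
$P_{MVO}$, giving the estimator

$$\tau = \frac{0.85\,IVRT}{\ln(0.65\,P_{sys}) - \ln(P_{MVO})}.$$

**Minimum pressure regression.** Minimum LV pressure follows a
cohort-derived linear model,
$minP_{LV} = -6.885 + 0.025 P_{sys} + 0.243\,BMI - 0.097\,LARS +
0.158\,\tau$ (mmHg; $\tau$ in ms).

**Transmitral gradient (simplified Navier–Stokes).** The instantaneous
atrio-ventricular pressure difference is
$\Delta P = \tfrac{\rho}{2}\big(v_{MV}^2 + \tfrac{Q}{\Delta Q} v_{MV}^2\big)$,
with $v_{MV}$ the transmitral velocity, $Q = dV/dt$ the flow rate obtained
by differentiating the strain-derived volume trace, and $\Delta Q$ the flow
increment. Its early-diastolic maximum links the two pressures:
$preA = minP_{LV} + \max \Delta P_E$.

Because $P_{MVO} = preA + 5$ mmHg while $\tau$ (hence $minP_{LV}$, hence
$preA$) depends on $P_{MVO}$, the system is closed and is solved by
fixed-point iteration (`solve_coupled()`), sequentially updating
$P_{MVO} \to \tau \to minP_{LV} \to preA$. EDP adds the A-wave gradient
maximum and a passive-filling term to pre-A. Finally, a time-normalized
reference diastolic curve (built from annotated measured curves,
`build_reference()`) is re-anchored at six events — MVO, minimum $P_{LV}$,
peak E, A start, peak A, MVC — and mapped to the patient's event times
(`generate_patient_curve()`).

## Parameters that matter

| option | default | meaning |
|---|---|---|
| `tau_ivrt_factor` | 0.85 | decay fraction of IVRT (AVC precedes the decay onset) |
| `p0_fraction` | 0.65 | $P_0 / P_{sys}$, cohort-derived |
| `p_mvo_offset_mmHg` | 5 | $P_{MVO} - $ mean $P_{LA}$ |
| `rho_kg_m3` | 1060 | blood density |
| `dq_rule`, `dq_floor_frac` | `"onset"`, 0.05 | $\Delta Q$ convention and blow-up guard |
| `solver_tol_mmHg`, `solver_max_iter` | 0.01, 10 | fixed-point stopping rule |
| `smooth_window` | 3 | moving average before each differentiation |
| `orifice_cm2` | 4 | flow-to-velocity mapping when no Doppler trace is given |
| `passive_rise_mmHg` | 0 | passive-filling term of EDP (pluggable) |

All constants are surfaced in `lv_options()` and can be loaded from a JSON
config (`lv_options_from_json()`); every result JSON embeds the resolved
options for provenance. JSON was preferred over YAML so that the package
depends only on `jsonlite`.

## Design choices where the method is underdetermined

* **$\Delta Q$ convention.** "Change of flow rate" is ambiguous; the default
  takes $\Delta Q(t) = Q(t) - Q(\text{wave onset})$ per sample with a floor
  of 5% of the window's peak $|Q|$ (both $Q$ and $\Delta Q$ vanish at the
  onset). With this rule the wave-peak gradient is exactly
  $\rho v_{peak}^2$, since $Q/\Delta Q \to 1$. Per-wave fixed and
  per-sample difference rules are selectable.
* **Event rules.** AVC is taken as the first sample of the peak-shortening
  plateau of the GLS trace (a strain-rate zero crossing is selectable);
  MVO and A-start are flow-onset times; the minimum-pressure time is the
  maximum flow acceleration on the E upstroke; MVC is the cycle end.
* **Sub-sample onsets.** At a smooth wave onset the flow rises
  quadratically, so $\sqrt{Q}$ is linear in $t$; onsets are located by a
  linear fit to $\sqrt{Q}$ over the 0.5–5% rise band extrapolated to zero.
  A plain threshold crossing is biased by one to three samples — enough to
  bias $\tau$ by $\sim$1 ms through IVRT — while the fit is unbiased to
  well under half a sample and degrades gracefully under noise (the band
  widens above the estimated noise floor).
* **Noise-aware plateau tolerances.** Peak-negative-GLS is ill-posed under
  noise (the argmin wanders the isovolumic plateau); the plateau tolerance
  scales with a robust high-frequency noise estimate and collapses to a
  floating-point floor on clean traces.
* **Anchor pressures.** Peak-E pressure defaults to
  $preA - \tfrac{\rho}{2} v_E^2$ (convective-only gradient at the moment
  of zero flow acceleration); peak-A defaults to the midpoint of the
  A-start and MVC pressures. Offsets between anchors are blended linearly
  in normalized time, which preserves the reference shape and passes
  exactly through the anchors.
* **Solver.** Sequential updates with tolerance 0.01 mmHg (max absolute
  change across the four unknowns, $\tau$ in ms) and a cap of 10
  iterations; the map is a contraction over the physiological domain
  (derivative $\approx 0.158\,\tau^2 / (0.85\,IVRT \cdot P_{MVO}) < 1$). A
  second, unstable fixed point exists near the $P_{MVO} \to 0.65 P_{sys}$
  singularity; iterates approaching it raise a divergence error naming the
  inputs.

## The synthetic world

`simulate_patient()` builds one cycle on a uniform grid: half-cosine
ejection to ESV, an isovolumic plateau of duration IVRT, raised-cosine E
and A filling waves separated by diastasis. GLS mirrors the volume curve;
velocity is flow over an effective orifice area; the true pressure runs the
Weiss decay from $0.65 P_{sys}$ to $P_{MVO}$ over $0.85 \cdot IVRT$ and
then raised-cosine segments through the event anchors.

Self-consistency is built in at zero noise: IVRT inverts the $\tau$
estimator; $minP_{LV}$ follows the regression at the true $\tau$; the
E-peak velocity satisfies $preA = minP_{LV} + \rho v_E^2$ under the onset
$\Delta Q$ rule. Hence the full pipeline must recover the truth up to
discretization (one-sample timing error: $\lesssim 0.5$ ms in $\tau$,
$\lesssim 0.1$ mmHg in pressures at the 1 ms default grid) — this is what
the recovery tests establish, and *all* they establish. The generator's
default ranges (cuff pressure 100–160 mmHg, LARS 15–45%, $\tau$ 30–65 ms,
E gradient 1.5–5 mmHg, heart rate 55–65 bpm) describe a mixed clinical
cohort; pre-A is drawn as regression minimum plus E gradient so every draw
is self-consistent, and draws violating ranges or cycle timing are
rejected and redrawn. The effective orifice enlarges above 4 cm² (cap
6.5 cm²) when the stroke volume could not otherwise pass in the available
diastolic time; velocities and $Q/\Delta Q$ are area-invariant, so the
estimation targets are unchanged.

What the generator does **not** emulate: vendor-filtered speckle-tracking
(noise is independent per-sample Gaussian, which is brutal on second
derivatives at 1 kHz — hence the small test noise levels), beat-to-beat
variability, E/A fusion at high heart rates (a single-wave fixture covers
the degradation path instead), mitral stenosis or regurgitation, and any
LA/LV interaction beyond the anchor construction. A green recovery test
therefore validates internal consistency of the implementation, not
clinical accuracy; the published clinical agreement figures require
invasive data and are out of scope.

## Numerical notes

* Derivatives are central differences with one-sided ends, after a
  centred moving average (window 3); second derivatives are differentiated
  from the smoothed first derivative.
* Filling-wave peaks are detected on an extra-smoothed flow (window
  $\ge 5$) with a 60 ms minimum peak separation, so that noise spikes are
  not mistaken for filling waves; onset fits use the lightly smoothed
  flow.
* A minimum two-sample separation is enforced between consecutive events,
  keeping the earlier event fixed.
* Degenerate inputs error early with the offending quantity named:
  non-positive volumes, non-negative peak strain, $P_{MVO} \ge 0.65
  P_{sys}$, empty wave windows, zero-variance regressors.
* Reference curves resample each inter-event segment to 100 points by
  linear interpolation; averaging is pointwise in normalized time.

## Limitations

The regression coefficients and the 0.65/0.85/+5 constants are taken as
published; re-fitting them requires invasive data (a utility for synthetic
cohorts exists via `linfit()`). The passive-filling EDP term defaults to
zero and is exposed as a configuration hook. IVRT from strain uses the
peak-shortening surrogate for AVC; absolute IVRT accuracy on real data
depends on the upstream strain quality.
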