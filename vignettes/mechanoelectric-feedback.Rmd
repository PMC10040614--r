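---
title: "Mechanoelectric feedback in a closed-loop 0D heart: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanoelectric feedback in a closed-loop 0D heart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cardiomef` simulates the acute interplay between cardiac mechanics and
electrophysiology — mechanoelectric feedback (MEF) — in a biventricular,
closed-loop model small enough to run on a laptop. This vignette describes
the component models, the numerical scheme, the calibration of the default
parameter set, and what the surrogate can and cannot say about a real
(three-dimensional) heart.

## The component models

### Myocyte electrophysiology

Each wall patch carries one ventricular myocyte following the ten
Tusscher–Panfilov (2006) formulation: 12 Hodgkin–Huxley gates, intracellular
Na⁺/K⁺/Ca²⁺ handling with a subspace and sarcoplasmic reticulum, and the
usual current complement (I_Na, I_CaL, I_to, I_Kr, I_Ks, I_K1, pumps and
exchangers). The epicardial variant is the default for every patch; the
transmural assignment of the source model's cellular analyses is not
specified, so a single, configurable cell type keeps the wall homogeneous
(`cell_params("endo")`/`"mid"` switch the I_to/I_Ks presets). An external
current port accepts the pacing stimulus and the stretch-activated current.
In tissue, the depolarizing wavefront contributes a foot current that a
space-clamped cell lacks; the stimulus is therefore a rectangular 2 ms pulse
at roughly twice diastolic threshold (−36 A/F).

Activation times are detected as the interpolated upward 0 mV crossing and
repolarization as 90% of the return from peak toward the pre-stimulus
diastolic potential; the source work does not state its thresholds, so these
conventional choices are package definitions.

### Stretch-activated current and trigger calibration

The SAC current is the sigmoidal, weakly selective cation current
`I_SAC = G (V_m − E_SAC) / (1 + K e^{−α(λ−1)})` with reversal potential
E_SAC = −20 mV. The *trigger level* is the sustained fiber stretch that just
elicits an action potential in an isolated, paced-to-steady-state cell;
`calibrate_sac()` finds the minimal conductance G by bisection (relative
tolerance 10⁻³) such that a stretch step held for one cycle at the trigger
fires (peak V_m > 0 mV) while one scan step (1%) below stays under −40 mV.

The sigmoid shape parameters are configuration, not physical constants: the
published slope values make the channel nearly linear over λ ∈ [1, 1.15], so
a cell whose diastolic stretch sits a few percent below the trigger receives
a chronic depolarizing current, accommodates near −70 mV (sodium channels
inactivate) and can never fire — in a 0D model whose *entire* wall sits at
the same diastolic stretch this abolishes stretch-triggered excitation
altogether. The default steepness α = 30 (with K = 100) makes the channel
switch-like around the trigger so that only transient over-stretch — the
prestretch of late-activated patches — delivers a suprathreshold current
pulse. This is the single most consequential configuration decision in the
package and is revisited under "Limitations".

### Active tension

The cross-bridge model is the Land three-state scheme (unblocked →
pre-powerstroke W → post-powerstroke S, with troponin/tropomyosin gating by
CaTRPN and B) driven by the myocyte's calcium:

* `T_a = h(λ) · T_ref/r_s · ((ζ_s + 1) S + ζ_w W)`, floored at zero;
* length dependence through `h(λ)` (β₀) and through the calcium sensitivity
  `Ca₅₀(λ)` (β₁ < 0: stretch sensitizes, the cellular Frank–Starling
  effect);
* velocity dependence through the distortions
  `dζ/dt = A_eff λ̇ − c ζ`, which cut tension roughly 40% at ejection-speed
  shortening — this is why the MEF-ablation experiments that remove velocity
  dependence must retune `T_ref` down to 70 kPa to keep peak pressure
  comparable.

Coupling to electrophysiology is strictly one-way (calcium is read from the
cell; troponin buffering does not feed back on the ionic model). Kinetic
rates default to the cited human formulation with four organ-level
calibration overrides (see below). All rates are overridable through
`land_params()`.

### Passive wall and the multi-patch ventricle

Passive fiber stress comes from the orthotropic exponential strain energy
`Ψ = C/2 (e^Q − 1)` reduced to the fiber axis under incompressible uniaxial
kinematics (transverse stretch λ^{−1/2}, shears zero, transverse normal
stress eliminated by the thin-wall zero-traction condition), giving the
analytic Cauchy stress `σ = λ dΨ/dλ`.

Each ventricle is an independent thin-wall sphere whose midwall encloses the
cavity plus half the wall volume. The sphere's area is partitioned into
patches (12 LV including 4 septal, 6 RV by default) that must all carry the
same membrane tension `T_i = σ_i · V_wall,i / A_i`; a damped Newton solve
with exact area renormalization enforces `ΣA_i = A_m` to 10⁻¹² and tension
equalization to 10⁻¹⁰ relative (with a 10⁻³ kPa·cm absolute floor where the
common tension crosses zero). Fiber stretch is the in-plane area stretch
`λ_i = √(A_i/A_ref,i)`. Cavity pressure is `P = 2T/r`. Compared with the 3D
original this closure drops the direct LV–RV mechanical interaction,
torsion, transverse active stress and pericardial boundary conditions — the
septal patches simply live on the LV sphere.

Two stabilizing ingredients matter and are deliberate model content:

* **Wall viscosity.** A stress `η λ̇` (η = 1000 kPa·ms) inside the coupled
  equilibrium. Myocardium is viscoelastic, and in the patch system the
  viscosity is also what keeps the equal-tension redistribution well-posed
  under dyssynchronous activation: without it, tension-rise imbalances of a
  few percent drive patch areas into sub-millisecond exchange oscillations
  and, through the velocity dependence, into runaway mutual stretching.
* **Bounded, filtered stretch rate.** The backward-difference λ̇ fed to the
  distortion ODEs is clamped to ±10 /s (well above any physiological rate)
  and its patch-to-patch deviation from the ventricle-mean rate is smoothed
  with a 5 ms first-order filter. The mean (cavity-driven) component passes
  through unfiltered, so single-ventricle dynamics are untouched; the filter
  only removes the solver-scale redistribution noise whose amplitude grows
  like 1/Δt and which would otherwise masquerade as physical shortening
  velocity.

### Circulation

A 12-ODE closed loop: four linear-compliance vascular beds (systemic and
pulmonary arteries and veins), two time-varying-elastance atria (raised
cosine activation, right atrium at the cycle start, left 40 ms later), and
four valves obeying a two-term orifice law
`L dq/dt = ΔP − R_B q|q| − R_lin q` whose Bernoulli resistance blends
smoothly (0.01 mmHg window) between open and closed values according to the
flow direction and inertial memory. Total blood volume is conserved exactly
by construction (each flow enters two compartments with opposite signs);
runs hold it to ~10⁻¹² relative per beat.

## Numerical scheme

Mechanics steps of 0.2 ms advance the coupled system; within each step, in
order: (1) electrophysiology substeps at 0.02 ms (exponential Rush–Larsen
gate updates, forward concentrations) with tension substeps at 0.1 ms
(exponential updates — every cross-bridge state is linear in itself, so the
scheme is unconditionally stable); (2) a fixed-point iteration between the
circulation and the wall: the equilibrium solve provides cavity pressure and
its volume derivative (a local compliance, by a 0.02 mL finite difference),
the circulation substeps (0.1 ms, semi-implicit valve updates by an exact
scalar quadratic solve) integrate against that linearization, and the
linearization point is updated until the end-of-step pressure is
self-consistent to 10⁻⁶ relative (maximum 50 iterations; 2–4 typical).
Pressure–volume metrics use step-averaged valve flows, which keep the
stroke volume from the volume trace and the integrated aortic flow within
1%. Halving the mechanics step changes stroke volume by < 0.5% (tested).

The 0.2 ms mechanics step is smaller than the 1 ms typical of such loops
because the velocity dependence introduces a fast (≈2.5 ms) distortion time
constant into the wall–valve feedback; at 1 ms the staggered coupling
rings at end-ejection.

## Calibration of the defaults

The study conditions are fixed: 600 ms cycle, right-atrial activation at
cycle start, 40 ms inter-atrial delay, 130 ms atrioventricular delay,
simultaneous ventricular activation at baseline, up to ten beats to steady
state (convergence = beat-to-beat change of LV stroke volume, end-diastolic
volume and pressure all < 1%, the package's definition). The calibration
targets are the canine organ-scale values: LV end-diastolic volume 59.1 mL,
stroke volume 18.8 mL, peak pressure 111.2 mmHg, end-diastolic pressure
12.7 mmHg, isovolumetric contraction 68 ms, ejection 139 ms.

Because the original's tuned parameter tables are not available, the
calibration was redone at the organ level, in this order: wall geometry
(reference areas set so end-diastolic stretch ≈ 1.05–1.06; effective wall
volumes 34/13 mL) and passive scaling C = 8.8 kPa to pin the end-diastolic
pressure–volume point; `T_ref` = 136 kPa against systemic resistance for
stroke volume and peak pressure; venous volumes and atrial elastances for
the filling side. Four tension-kinetics values were moved from the cited
human defaults to meet the systolic timing at this heart rate — Ca₅₀ʳᵉᶠ
1.15 µM (from 0.805), tropomyosin cooperativity n_Tm 3.5 (from 2.2),
troponin-unblocking scale k_u 0.15 ms⁻¹ (from 1), and T_ref as above —
trading calcium sensitivity for a twitch whose rise and relaxation produce
the observed isovolumetric and ejection durations. The wall's required
effective tension (~74 kPa peak after velocity weakening) was chosen so that
the ablation experiments' retuned `T_ref` = 70 kPa is a genuine reduction,
as it must be for the reported stroke-volume drop. The shipped initial
compartment volumes are the converged steady state of this configuration, so
a fresh run settles in about three beats; the slow (~60-beat) venous
redistribution time constant would otherwise exhaust the ten-beat budget.

The LBBB activation map delays septal patches by 25–55% and LV free-wall
patches by 50–100% of a total spread, with the right ventricle at the sinus
AV delay. The spread (100 ms) and the CRT propagation spread (55 ms, paced
patches at a 120 ms device delay, no interventricular delay) are
configuration calibrated to the reported acute stroke volumes; the 0D
surrogate needs its own values because the equal-tension sphere translates a
given activation spread into more mechanical dyssynchrony than a 3D
continuum does.

## The synthetic drivers

`make_stretch()` (hold/step/ramp/sinusoid/quick-release, with exact analytic
rates), `make_calcium()` (the single-peak transient
`dia + amp (t/τ_p) e^{1−t/τ_p}`, peaking exactly at τ_p) and the fixture
registry (`make_fixture()`) stand in for what a tissue-scale model would
supply, so each module is testable in isolation. `disperse_activation()`
adds seed-deterministic uniform jitter (±25 ms default) to the activation
times: the heterogeneity that 3D geometry produces intrinsically has to be
injected here, and the jittered configuration is what makes the direction of
the MEF heterogeneity effects (stretch-spread shrinking, tension-spread
growing with MEF present) testable at all. Passing those directional tests
says the mechanisms act the right way; it does not make the 0D spread
magnitudes comparable to tissue values.

## Known limitations

* The LBBB/CRT/baseline ordering of maximal dP/dt does not reproduce: in
  the surrogate, prestretch-boosted late patches steepen the pressure rise
  under dyssynchrony, so LBBB's dP/dt is not depressed relative to baseline
  the way a 3D continuum (where the early free wall bulges outward) shows.
  Stroke-volume and peak-pressure orderings do reproduce.
* Everything transmural and regional is gone: no torsion, no LV–RV
  interaction through the septum, no pericardium, a single cell type.
* The trigger-level sweep produces premature excitation only at the 5%
  level (the paper's 3D stretch field, with its wider regional spread,
  begins firing at 7%); the directional statements — safety at 8–10%,
  monotonically advancing earliest activation — hold.
* Refractoriness is tested as "no regenerative upstroke after an early
  second stimulus" rather than a peak-voltage bound, since the plateau of
  this ionic model sits above 0 mV at the 50 ms coupling interval.
* The ionic formulation is checked against an independent stiff-solver
  integration and the published model's behavioural fingerprints (resting
  potential, APD rate dependence, calcium-transient range), not against a
  byte-level reference export.

## Problem sizes used by the tests

Single-cell work uses full-resolution 0.02 ms steps; coupled runs use the
18-patch heart for up to 10 beats and the 8-patch `mini-heart` fixture for
smoke tests; the ablation matrix runs its six configurations for exactly ten
beats each so that paired comparisons are made at a common beat. These sizes
are the package's defaults and are what the shipped acceptance script uses.
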