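---
title: "Modelling cerebral blood flow and mitochondrial metabolism during hypercapnia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebral blood flow and mitochondrial metabolism during hypercapnia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

Breathing CO₂-enriched air (hypercapnia) dilates cerebral vessels and raises
cerebral blood flow (CBF). Whether it also changes the brain's oxygen
consumption (CMRO₂) is disputed: non-invasive monitoring in adult volunteers
shows a rise in tissue oxygenation index (TOI) large enough that a
Fick-principle calculation implies CMRO₂ *falls*, while the near-infrared
cytochrome-c-oxidase signal ([oxCCO]) shows a large, slow *oxidation* of the
Cu~A~ centre. `brainco2` implements a forward dynamic model of the cerebral
circulation coupled to a reduced electron-transport-chain (ETC) model, two
candidate CO₂→metabolism pathways, a modified-Fick ΔCMRO₂ estimator and a
genetic-algorithm (GA) fitting pipeline, so that the two pathways can be
tested against CBF, TOI and [oxCCO] simultaneously:

* **substrate supply** (`supps` > 0): CO₂ throttles the delivery of reducing
  equivalents (NADH) to the chain, raising the NAD/NADH ratio;
* **ATP demand** (`uf`): CO₂ scales the rate of proton re-entry through ATP
  synthase, moving the proton motive force Δp.

## Model structure

Nine ODE states. Three are input filters: mean arterial pressure is smoothed
with time constant `tau_P`, and the normalized CO₂ excursion
$x = (\mathrm{PaCO_2} - \mathrm{PaCO_2}_n)/\Delta\mathrm{PaCO_2^{ref}}$
is low-pass filtered twice, with `tau_c` (vascular pathway, stimulus $c_1$)
and `tau_c2` (metabolic pathway, stimulus $c_2$). The normalization constant
is 15 mmHg (≈ 2 kPa), so a standard challenge drives $c \approx 1$ at
plateau and the gains `supps`/`uf` of magnitude ±0.05 read directly as ±5%
effects.

The vascular compartment is a lumped radius model: the target radius is
$r_\infty = r_n\,[1 + k_r \tanh(R_{autc}\,c_1 - R_{autp}(P/P_{an} - 1))]$,
relaxing with time constant `t_r`, and
$\mathrm{CBF} = \mathrm{CBF}_n (r/r_n)^4 (P - P_v)/(P_{an} - P_v)$
(Poiseuille-type radius dependence, linear pressure head). The `tanh` caps
dilation and constriction at ±`k_r`; `R_autc` is calibrated so the
small-signal CBF reactivity is 4% per mmHg PaCO₂, the value observed in the
volunteer recordings the model targets. Middle-cerebral-artery velocity
change (Vmca) is identified with percentage CBF change (constant insonated
cross-section).

The mitochondrial compartment tracks an NADH pool fraction, the redox
fractions of Cu~A~ and haem a₃, mitochondrial O₂ and Δp. Electron flux
passes through three lumped irreversible stages,

$$f_1 = k_1\,\mathrm{CuA_{ox}}\,\mathrm{NADH}\,e^{-\gamma_1 \delta},\quad
  f_2 = k_2\,\mathrm{CuA_{red}}\,\mathrm{a3_{ox}}\,e^{-\gamma_2 \delta},\quad
  f_3 = k_3\,\mathrm{a3_{red}}\,\frac{O_2}{O_2 + K_m}\,e^{-\gamma_3 \delta},$$

with $\delta = (\Delta p - \Delta p_n)/Z$, CMRO₂ $= f_3/4$ (4 e⁻ per O₂) and
NADH consumed at $f_1/2$ (2 e⁻ per NADH). Protons are pumped at
$p_1 f_1 + p_2 f_2 + p_3 f_3$ (defaults 4, 1, 1 per electron) and re-enter
through ATP synthase,
$L_{CV} = r_{CV}\, u_{\mathrm{eff}}\,(e^{(\Delta p - \Delta p_{CV0})/Z} - 1)$
(clamped at zero below $\Delta p_{CV0} = 90$ mV — no synthase reversal), and
a linear leak $k_{leak}\Delta p$. Substrate supply produces NADH at
$J_{prod} = k_{prod}\,u^{2 D_{NADH}}\,(1 - \mathrm{supps}\cdot c_2)\,
\mathrm{NAD}/(\mathrm{NAD} + K_N)$; demand scales as
$u_{\mathrm{eff}} = u (1 + \mathrm{uf}\cdot c_2)$ with the baseline demand
$u$ fixed at 1 and no demand→CBF coupling (`R_u = 0`). Oxygen enters from a
capillary pool whose dissolved concentration tracks the mean
arterio-venous saturation; TOI mixes arterial and venous saturations with an
arterial weight that by default follows the vessel radius (set
`avr_dynamic = 0` for fixed-ratio optics); [oxCCO] is
$\mathrm{cytox_{tot}}(\mathrm{CuA_{ox}} - \mathrm{CuA_{ox}}(0))$ in µM.

Modelling NADH as a dynamic pool (rather than a fixed NAD/NADH constant) is
what lets a supply restriction simultaneously raise NAD/NADH, oxidise Cu~A~
and lower steady-state flux — an algebraic ratio cannot reduce flux on its
own.

### Calibration

`bc_params()` solves all rate constants in closed form so that the baseline
steady state sits *exactly* on the nominal physiology: CBF 0.0083 s⁻¹
(≈ 50 ml·100 g⁻¹·min⁻¹), CMRO₂ 0.024 mM O₂ s⁻¹, Δp 145 mV, Cu~A~ 67%
oxidised, haem a₃ 10% reduced, NAD/NADH 9, mitochondrial O₂ 24 µM, arterial
saturation 0.98 at P_a 90 mmHg and PaCO₂ 5 kPa. The baseline proton influx
is split 75% synthase / 25% leak (`leak_frac_n`, a typical mitochondrial
coupling efficiency), which fixes `r_CV` and `k_leak`; the proton
capacitance `C_buf` is set so Δp relaxes with ≈ 5 s. Changing any nominal
value recalibrates everything, so every GA candidate is a self-consistent
model.

### Choosing the Δp-sensitivities

The sign constraints are structural: γ₂ > γ₁ ≥ 0 is required so that a
demand *reduction* (Δp rise) slows the Cu~A~→a₃ step more than the
NADH→Cu~A~ step and therefore *reduces* Cu~A~ oxidation. The magnitudes
needed a second constraint. At steady state the Cu~A~ redox shift obtainable
from a supply restriction is governed entirely by the $f_2$ relation: with
flux at a fraction $x$ of baseline, $\mathrm{CuA_{red}}$ scales as
$x\,e^{\gamma_2\delta}$, and $\delta$ itself follows from the proton balance
($\delta \approx Z \ln x / 1.65$ at the default synthase operating point).
Reproducing the observed behaviour — a ≈ 0.5–0.6 µM Cu~A~ oxidation (a
0.25–0.27 shift of a 67%-oxidised 2.2 µM pool) alongside only a 5–15% CMRO₂
reduction — therefore requires $\gamma_2 |\delta| / Z \approx 1.5$ at
$x \approx 0.9$, i.e. γ₂ ≈ 15. We set γ₁ = 2, γ₂ = 15, γ₃ = 0.5. With
smaller γ₂ the model can still produce all the right *signs* but the fitted
oxCCO response saturates well below the measured amplitude.

### Numerics

Integration uses `deSolve::lsoda` (stiff-capable, adaptive; rtol 1e-6, atol
1e-9) with the right-hand side compiled in C and the inputs supplied as
linearly interpolated forcings. A pure-R reference implementation of the
same equations is kept in `bc_derivs()` and the two are held to agreement by
a fixed-step RK4 oracle test (dt = 10 ms, ≤ 1e-4 relative). Steady states
are found by damped Newton iteration on the five metabolic states (the
filter states have closed-form fixed points), falling back to a long
relaxation integration, and must reach a maximum absolute derivative below
1e-9. The synthase clamp at $\Delta p_{CV0}$ and the floor on $u_\mathrm{eff}$
and supply at 0 are the only non-smooth elements; both sit far from all
trajectories explored by the fits.

## Signal conditioning and the Fick comparator

Monitoring signals are low-pass filtered (0.25 Hz, fifth-order Butterworth)
and resampled at 1 Hz, as in the volunteer study. The filter is applied
forward-backward (zero-phase): this analysis is offline, and a causal filter
would add a lag that the fitted time constants `tau_c`/`tau_c2` would then
absorb. Vmca is converted to ΔCBF% against the mean of the first 100 s
(pre-challenge) window; ETCO₂ in kPa becomes PaCO₂ in mmHg (×7.50062); NaN
gaps ≤ 5 s are linearly interpolated, longer gaps are an error.

The model-independent comparator inverts TOI under a static
arterial:venous ratio (AVR 0.25, the convention of the Fick-NIRS
literature; the true ratio drifting with vasodilation is a known limitation)
to get venous saturation, and forms
$\mathrm{CMRO_2^{rel}} = (1 + \Delta\mathrm{CBF}/100)\,
(S_aO_2 - S_vO_2)/(S_aO_2^0 - S_vO_2^0)$. When the model's own TOI is
generated with fixed-ratio optics this estimator recovers the model's CMRO₂
change exactly — the internal-consistency oracle in the test suite. Note
the estimator is *not* invariant to additive TOI offsets (an offset changes
numerator and baseline extraction by the same absolute amount, hence their
ratio); absolute TOI calibration matters.

## The synthetic challenge

The generator emulates the study protocol: 6% inspired CO₂ for 300 s
(onset 100 s, offset 400 s of a 600 s record) targeting a +2 kPa ETCO₂
rise, with a +5 mmHg MABP rise, constant SpO₂, and saturating ramps with a
20 s time constant. Descriptive observations are smooth ramps that attain
their plateaus at the challenge offset: ΔVmca +45%, ΔTOI +10 percentage
points, Δ[oxCCO] +0.58 µM with a 180 s response time (the metabolic delay),
TOI baseline 73.5%. The +10 TOI plateau was chosen jointly with the +45%
Vmca rise so the triple is internally consistent with a Fick CMRO₂ fall in
the 5–15% range — a smaller TOI rise would flip the Fick estimate positive
and contradict the phenomenon the pipeline is built to analyse; it is also
what the forward model itself produces at a 45% CBF rise. All plateaus are
configuration fields, not constants. Default noise is Gaussian, SD 2% of
each channel's dynamic range, i.i.d. per sample.

What the generator does *not* emulate: subject-level variability (it is a
group-mean emulation), physiological oscillations (respiratory/Mayer
waves), drifts, or coloured noise. Passing fits on these data therefore
demonstrate identifiability and the regimes' qualitative separation, not
robustness to every artefact of real recordings.

## Fitting

The cost is the mean absolute difference per target channel over the full
record (baseline included, which anchors absolute TOI/CBF levels), each
weighted by the reciprocal SD of the observed channel so the signals enter
on equal unit-free terms. Each regime frees exactly six parameters
(`supps` *or* `uf`, plus `R_autc`, `tau_c`, `tau_c2`, `P_an`, `CBF_n`) with
bounds ±0.5 on the gains, 1–60 s and 1–600 s on the time constants,
0.25–4× nominal on `R_autc`, 70–110 mmHg on `P_an` and 0.6–1.4× nominal on
`CBF_n`.

Optimization is a seeded real-coded GA (tournament selection, SBX
crossover 0.9, per-gene Gaussian mutation 0.1, elitism 2) run in unit-box
coordinates, warm-started at the unmodified model, and followed by a
bounded Nelder–Mead polish of the best candidate — a standard hybrid
global/local scheme that removes most run-to-run scatter. GA
hyperparameters are exposed in `ga_control()`; the shipped desk-scale
defaults are population 40 × 60 generations, and the repeat machinery
(`repeat_fits()`) defaults to 20 repeats with seeds `seed + i`, reporting
per-parameter means and SDs (the study-scale setting is 200 repeats). The
test suite and acceptance script use populations of 16–40 and 12–40
generations with 2–6 repeats; at these sizes a single fit takes tens of
seconds and parameter recovery on noiseless forward data is already exact
to three digits for the supply gain.

`P_an` and `CBF_n` are only weakly identified individually — their fitted
combinations keep the absolute baseline CBF and TOI at physiological
values, so their repeat SDs are large while the gains and time constants
are tight. This is expected, not a failure of the optimizer.

## What the pipeline concludes

`run_pipeline()` chains: data preparation → unoptimized simulation → ±0.05
sweeps of both gains → Fick estimate → both regimes × three target sets
({oxCCO}, {TOI, CBF}, {all three}) with repeats → a summary table and a
verdict. A regime "reconciles" the data if its all-signal fit matches the
observed oxCCO sign *and* its modelled CMRO₂ change agrees in sign with the
Fick estimate. On the synthetic challenge: the unmodified model yields a
tiny CMRO₂ *rise* while Fick says *fall*; the demand regime can match
either the oxCCO rise (with `uf` > 0, forcing CMRO₂ up) or the TOI/CBF pair
(with `uf` < 0, forcing oxCCO negative) but never both; only the supply
regime fits all three signals with a CMRO₂ fall. Plateau statistics are
means over the last 100 s of the challenge window against the 0–100 s
baseline.

## Known limitations

* The ETC is reduced to three lumped irreversible stages with exponential
  Δp-inhibition; Δψ and ΔpH are lumped into a single Δp state, and
  mitochondrial pH is not explicit.
* The purely flow-mediated oxCCO response of the unmodified model is much
  smaller than in richer models (mitochondrial O₂ sits ~50× above the
  oxidase K~m~), so CO₂-metabolism gains carry almost all of the fitted
  oxCCO signal.
* Group-mean fitting only; no per-subject inference, no uncertainty beyond
  repeat spread.
* The Fick comparator inherits the static-AVR assumption; with
  radius-dependent optics (the default) it systematically overstates the
  CMRO₂ fall, which is precisely the regime-discriminating behaviour under
  study.
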