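---
title: "Modelling sepsis progression and treatment with sepsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling sepsis progression and treatment with sepsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsim)
```

## What the package models

`sepsim` simulates a virtual adult patient acquiring a bacterial tissue
infection, mounting an acute inflammatory response, and — when the
inoculum is large enough — progressing through systemic inflammatory
response syndrome (SIRS) to sepsis and septic shock, with or without
treatment. Three coupled layers advance together on a 0.05 h grid:

1. an 18-state **acute inflammatory response (AIR)** ordinary differential
   equation system with a hysteretic toll-like-receptor (TLR) switch:
   pathogen at the infection site and in blood, local and systemic
   macrophage and neutrophil pools, an epithelial barrier, nitric-oxide
   synthases, four cytokines (TNF, IL-6, IL-10, IL-12) and a global
   tissue-integrity variable;
2. a reduced **lumped-parameter physiology**: three vascular–tissue
   compartment pairs with Starling fluid exchange and Patlak albumin
   transport, a common lymphatic return, a baroreflex-controlled
   hemodynamic block, renal output, an energy-deficit/lactate submodel and
   SIRS symptoms (fever, tachypnea, leukocytosis);
3. a **treatment layer**: two-compartment drug kinetics with an
   MIC-anchored antibiotic pharmacodynamic law and a sigmoidal vasopressor
   effect, plus crystalloid/colloid fluids and the two REFRESH
   resuscitation protocol arms.

Everything is deterministic; identical configurations reproduce identical
trajectories bit for bit.

## The inflammation core

All Hill interactions use three response shapes: the saturating
up-regulation $HU_1(x,n,h) = x^h / (1 + (x/n)^h)$, the bounded sigmoid
$HU_2(x,n,h) = x^h / (x^h + n^h)$ and its complement
$HD(x,n,h) = 1/(1 + (x/n)^h)$, so that $HU_2 + HD = 1$. Nitric oxide is
algebraic rather than differential:
$NO = iNOS\,(1 + k_{NOMA}(M_A + N_A)) + eNOS$, and the TLR switch obeys

$$R(t) = \begin{cases} 1 & P_T > P^+ \\ R(t^-) & P^- < P_T < P^+ \\
0 & P_T < P^- \end{cases}$$

with $P^+ = 2\times10^6$ and $P^- = 10^3$ — a hysteresis loop, so the
switch keeps its state between the thresholds.

### Transcription choices in the invasion equations

The published parameter table this model builds on is internally precise,
but the typeset invasion equations are ambiguous in several denominators
and factor pairings, and the rate constants impose hard structural limits:
the resting-pool replenishment fluxes cap sustained active macrophages at
0.25 and active neutrophils at 0.1 (in model units), and the background
blood-clearance slope (0.531/h) sits just below the nominal pathogen
growth rate (0.6/h). We resolved the ambiguous terms by requiring the
model to reproduce its own quantitative anchors — the critical inoculum
near $6.95\times10^6$ at $S_P = 0.6$ and graded severity outcomes — and
documented each choice:

* **Tissue growth** is logistic, written as net growth minus
  density-dependent mortality,
  $S_{net} P_T - S_P P_T^2/\kappa_{PT}$, so that an antibiotic-suppressed
  (negative) net rate still kills above the carrying capacity
  $\kappa_{PT}$ (default $3\times10^6$, a package-added parameter).
* **Translocation** of tissue pathogen into blood is gated by barrier
  loss: $\theta_P P_T \,(1 - B + b_B)/(1 + k_{PTB} B)$. An intact barrier
  admits only a small constitutive trickle ($b_B = 0.002$), which gives
  sub-threshold infections their transient low-grade bacteremia.
* **Barrier erosion** requires both TLR activation and a high local
  burden: $(k_{BR} + k_{BNT} P_T)\, R \, B \, HU_2(P_T, x_{BP}, h_{BP})$
  with $x_{BP} = 8.2\times10^6$ and $h_{BP} = 16$. The $4\times10^{-8}$
  coefficient only makes sense on pathogen count scales (on neutrophil
  counts of order $10^3$ it would be inert), and the saturating burden
  threshold is the package's explicit design choice: it is what creates a
  sharp, correctly oriented critical inoculum. Healing is suppressed by
  the burden relative to carrying capacity,
  $S_B (1-B) / (1 + k_{BPT} P_T/\kappa_{PT})$.
* **Blood-side neutrophil kill** uses the printed form
  $k_{PBNA} N_A\, HU_2(P_B, x_{PN}, 2)$.

With these choices the system is bistable in the initial tissue load: below
the separatrix the patient settles into a *colonised carrier* state
(tissue pathogen at carrying capacity, barrier intact, blood counts of
order 0.5 and a controlled, mild inflammatory tone), above it the barrier
collapses, bacteremia escapes the immune containment and grows without
bound. Because the blood growth term is linear there is no finite septic
fixed point; integration therefore caps blood pathogen at $10^{10}$ and
classifies such runs septic. Classification uses the blood count at a
500 h horizon against an elimination threshold of 20 (the two branches sit
at ~0.5 and ~$10^{10}$, so any threshold within two orders of magnitude
gives the same answer), and "control" of bacteremia means a declining
count or one persistently below a tenth of that threshold.

### What the printed system cannot do

Two behaviours of the source material are *not* reproducible under the
published rate constants, and the package does not pretend otherwise:

* cytokine storms are weak — sustained IL-6 tops out near 0.2–0.4, far
  below the half-max (0.85) of the tissue-damage equation, so the
  anatomical tissue-integrity state barely moves even in septic runs;
* sub-threshold severities still show a "storm-lite" (nitric oxide and
  IL-6 rise for every infected run), so the inflammation magnitudes are
  only weakly graded between mild and moderate infections.

Both facts shaped the physiology coupling below, and both are stated here
rather than hidden in tuning.

## Hybrid integration

The continuous states advance with an adaptive stiff integrator (`lsodar`,
relative tolerance $10^{-6}$, absolute tolerance $10^{-9}$ per state and
$10^{-3}$ for the two pathogen counts). The TLR switch is treated as
piecewise constant on the macro grid: threshold crossings are located by
root finding, integration continues to the next grid boundary, and the
hysteresis rule is applied there. For runs without time-varying drug
input the integrator covers long spans in single calls between crossings,
which is what keeps the bisection and the growth-rate scan fast; coupled
treatment runs step the full grid. States are clamped to their biological
domain (non-negative; $B \le 1$; $TI \in [TI_{min}, 1]$) at every
hand-off. Halving the macro step changes the critical load by well under
1%, and a fixed-step classical Runge–Kutta oracle at $dt = 10^{-3}$ h
agrees with the adaptive result to a relative $10^{-4}$ on all 18 states
over 48 h — both are tested.

## The reduced physiology

The baseline patient is the standard adult: blood volume 5 L (hematocrit
0.40), heart rate 72/min, stroke volume 70 mL, arterial pressures
114/73.5 mmHg (MAP 87), urine output 0.9 mL/min, lactate 1 mM, core
temperature 37 °C, respiration 16/min, WBC 7000/µL. Three vascular–tissue
pairs (muscle/skin 40%, gut 30%, other viscera 30%) hold 10 L of
interstitium against capillary/interstitial hydrostatic pressures of
25/−3 mmHg and albumin at 4.5/1.5 g/dL; plasma protein is taken
proportional to albumin and converted to colloid osmotic pressure with the
Landis–Pappenheimer cubic. At construction the per-pair endothelial
resistances, lymph baselines and diffusion capacities are solved exactly
so that filtration totals 4.0 L/day, lymph returns precisely what is
filtered, and transcapillary albumin flux balances its convective lymph
return. The baseline is therefore an *exact* fixed point: a 72 h
uninfected run drifts by strictly zero, and the conservation laws (fluid
and albumin, to $10^{-9}$ per step) hold by construction of the explicit
flux bookkeeping.

### Coupling to inflammation

The physiological layer consumes four inflammation outputs: tissue
integrity, nitric oxide, active neutrophils and IL-6. Because anatomical
tissue integrity barely moves (see above), the layer derives its damage
signal from integrity weighted by IL-6-driven endothelial activation —
glycocalyx degradation is cytokine-mediated, which is also the
biologically sensible reading:

$$d = 1 - TI\,\bigl(1 - w_6\, HU_2(IL6, x_6, 6)\bigr), \qquad
w_6 = 0.85,\; x_6 = 0.23.$$

Two first-order lags shape the time course: endothelial damage develops
over $\tau_{endo} = 32$ h (progressive glycocalyx shedding) and
NO-mediated vasoplegia over $\tau_{NO} = 26$ h (vascular smooth-muscle
adaptation). These lags are what turn the near-step inflammation signals
into the observed day-scale hemodynamic decline.

### Mechanisms and their constants

* **Endothelial dysfunction**: resistance and reflection coefficient fall
  linearly with damage, $R_1 = R_1^0 \max(0.05,\, 1 - 3.0\,d)$ and
  $\sigma = \sigma^0 \max(0.05,\, 1 - 2.4\,d)$. The leaked albumin erodes
  the osmotic gradient, which is the slow positive feedback that drives
  progressive hypovolemia.
* **Capillary pressure** follows volume exponentially,
  $P_c = 25\,e^{8(BV/BV_0 - 1)}$ mmHg: overfilling drains quickly (a
  500 mL bolus given to the leaky patient redistributes within the hour —
  fluid-refractory hypotension), depletion floors filtration.
* **Interstitial stiffening**: beyond 3.2 L of excess interstitial volume
  the tissue pressurises quadratically (the edema "safety factor"),
  restoring lymph return and letting accumulated resuscitation fluid
  finally hold intravascularly. This is what ends the fluid-liberal
  protocol mid-course rather than immediately or never.
* **Hemodynamics**: stroke volume follows preload with gain 0.9 (capped
  at +15%), pulse pressure scales as $(SV/SV_0)^3$, MAP $= CO \times
  SVR$. Nitric oxide depresses intrinsic vascular resistance through a
  sigmoidal Emax law ($E_{max} = 0.63$, EC50 $= 0.30$ above baseline NO,
  Hill 2). A first-order baroreflex (time constant 0.5 h) drives SVR
  (gain 4, cap +90%) and heart rate (gain 3, cap +33%) toward the MAP
  setpoint; from SIRS onset (first time two of the four criteria hold)
  the SVR gain is progressively inhibited, ramping to 95% over 44 h.
  The septic patient is accordingly hyperdynamic: pressure falls mainly
  through resistance, not output.
* **Renal output**: $UO = 0.9\,(MAP/87)^3 (BV/5)^2$ mL/min, clipped at
  zero and three times baseline; a constant volume-neutral intake of
  0.9 mL/min replaces baseline losses.
* **Metabolism**: an energy deficit accumulates at $0.5\,d$ per hour and
  recovers at $0.8\,E\,(1-d)$; lactate is produced at $1.55\,E$ and
  cleared at $0.12$ toward baseline. The untreated severe run crosses
  2 mM at about 20 h.
* **Symptoms**: fever and tachypnea are Emax responses in damage (maxima
  +3 °C and +16/min, half-max 0.12, exponent 1); WBC is baseline plus
  $8\times10^4$ per unit of active neutrophils.

All constants above were calibrated jointly against the untreated severe
timeline (systolic pressure below 100 mmHg near 26 h, MAP below 65 mmHg
near 45 h, lactate above 2 mM near 20 h, minimum SVR near 60% of
baseline) and the two protocol fluid totals; the achieved values are
computed by `scripts/acceptance.R` at run time, not quoted here.

## Drugs and fluids

Drug kinetics are linear two-compartment models advanced by an exact
matrix-exponential step, so mass balance holds to rounding error.
Piperacillin (the antibacterial component of the
piperacillin/tazobactam combination; tazobactam is assumed inert) uses
$CL = 4500/278$ L/h — which pins the area under the plasma curve for the
4.5 g dose at exactly 278 mg·h/L — with $V_1 = 8$ L, $V_2 = 18$ L,
$Q = 24$ L/h and an unbound fraction of 0.7. The antibiotic
pharmacodynamic law is

$$S_{net}(C_u) = S_{max} - (S_{max} - S_{min})
\frac{(C_u/MIC)^\gamma}{(C_u/MIC)^\gamma - S_{min}/S_{max}},$$

which is exactly zero at $C_u = MIC$ for *any* parameter values — the
property that removes the need for a separate EC50. Defaults tie
$S_{max}$ to the pathogen growth rate (0.6/h) with a maximal reduction
$S_{max} - S_{min} = 0.70$/h; the Hill exponent $\gamma = 10$ was
calibrated, together with the distribution volumes, so that the effect
stays within 5% of maximal for 3.0 h after a 4.5 g/30 min dose against a
MIC of 16 mg/L. (A low exponent of 2 gives only ≈2.3 h; the exponent is
the parameter the effect-window anchor actually constrains.) The net rate
replaces the pathogen growth rate in both the tissue and blood equations;
each substitution can be disabled in the scenario configuration.
Norepinephrine uses fast kinetics (effective half-life of minutes) and a
sigmoidal SVR effect ($E_{max} = 0.35$, EC50 2.5 µg/L) sized so that a
0.18 µg/kg/min infusion lifts the septic patient's MAP to the 65–70 mmHg
band without overshooting the systolic goal.

## The REFRESH protocols

The treatment scenarios chain three stages from a single untreated severe
run: a snapshot at 44 h (just before septic shock), a fluid challenge of
two 500 mL boluses at 44 and 44.5 h with observation to 46 h (the patient
qualifies when systolic pressure stays below 100 mmHg), and six protocol
hours from 46 h. Both arms start 4.5 g piperacillin over 30 min. The
control arm adds a 1000 mL bolus and reviews every 30 min: 500 mL when
SBP or MAP is below goal (90/65 mmHg), a further 500 mL on the hour when
urine output (trailing 30-min mean, against 0.625 mL/min, i.e.
0.5 mL/kg/h at 75 kg) is low, and termination to 75 mL/h maintenance once
both pressure goals are met. The experimental arm runs maintenance saline
at 1 mL/kg/h plus norepinephrine at 0.18 µg/kg/min, reviews hourly with
250 mL boluses for low urine output, and stops everything but maintenance
at goal. Protocol boluses are infused over 24 min and the initial control
bolus over 45 min, so reassessment happens shortly after an infusion
completes; an infusion ending exactly on a review boundary would be
assessed at its peak effect, which is an artefact of instantaneous-vitals
checks, not of the rules. Every review writes the vitals it saw and the
action it took to an audit log, and the suite cross-checks that each
administered bolus is justified by a logged threshold violation.

One treatment-timing result does not carry over from the source engine:
delaying treatment by 12 h multiplies blood bacteria by roughly three
orders of magnitude here, not by two-fold, because the septic branch
grows exponentially (~0.58/h net) with no finite septic fixed point. The
direction — delay leaves a sicker, more bacteremic patient — holds and is
what the tests assert.

## Serialization and reproducibility

Patient snapshots (full AIR, drug, physiology and infusion state) are
written as version-stamped, checksummed JSON with every double at 17
significant digits, which round-trips IEEE-754 exactly: resuming from a
snapshot reproduces the uninterrupted run to within $10^{-9}$ per
variable, and save–load–save is byte-identical. Parameter registries and
drug definitions round-trip through flat JSON the same way.

## Problem sizes and what the tests show

The test suite and acceptance script run the model at the study's own
scales: 500 h horizons for outcome classification, ~10 bisection runs for
the critical inoculum, a growth-rate grid of 0.40–0.90 in steps of 0.05,
48 h coupled severe runs and 6–8 h protocol runs; the whole suite
completes in well under a minute on one CPU. Passing tests demonstrate
internal consistency (conservation, oracle agreement, hysteresis,
serialization) and agreement with the handful of quantitative anchors the
model was calibrated against. They do not validate the model against
clinical data: the physiology is a deliberately small stand-in for a full
circuit-based engine, per-organ heterogeneity, coagulation, respiratory
involvement and thermoregulatory dynamics are out of scope, and the
severity grading of the inflammation layer is weaker than the biology it
caricatures.

```{r quick-demo, eval = FALSE}
# a 48 h untreated severe infection
sim <- run_scenario(scenario(severity = "Severe", t_end = 48))
print(sim)
plot(sim)

# the critical inoculum at the nominal growth rate
find_critical_load(S_P = 0.6)
```
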