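# sepsim

Whole-body simulation of sepsis progression and treatment in a virtual
patient.

Sepsis is a dysregulated host response to infection whose clinical course —
systemic inflammation, capillary leak, hypovolemia, vasoplegic hypotension,
hyperlactatemia, shock — unfolds over hours to days, and whose management
(fluids, vasopressors, antibiotics, and their timing) is still actively
debated. `sepsim` is a desk-scale simulator for exploring that course and
those treatment choices *in silico*. It is aimed at modellers and
computational physiologists who want an inspectable, fully deterministic
workbench rather than a monolithic physiology engine.

## The model in brief

Three layers advance together on a 0.05 h grid:

* **Acute inflammatory response (AIR).** An 18-state ODE system: pathogen
  at the infection site `P_T` and in blood `P_B`, local and systemic
  macrophage/neutrophil pools, an epithelial barrier `B`, NO synthases, the
  cytokines TNF, IL-6, IL-10, IL-12, and a tissue-integrity variable `TI`.
  A hysteretic toll-like-receptor switch `R` turns on above a pathogen
  burden `P⁺ = 2·10⁶`, off below `P⁻ = 10³`, and otherwise keeps its state;
  it gates barrier erosion and neutrophil recruitment. Nitric oxide is
  algebraic: `NO = iNOS·(1 + k_NOMA·(M_A + N_A)) + eNOS`. The system is
  bistable in the initial tissue load: below a critical inoculum the
  patient ends as a colonised carrier with bacteremia eliminated, above it
  the barrier collapses and blood bacteria escape immune containment.
  `find_critical_load()` locates the separatrix by bisection.

* **Reduced physiology.** Three vascular–tissue compartment pairs exchange
  fluid by Starling's law, `J_V = (ΔP_h − ΔCOP)/R₁`, with colloid osmotic
  pressure from the Landis–Pappenheimer cubic
  `COP = 2.1·C + 0.18·C² + 0.009·C³` and albumin moving by the Patlak
  convection–diffusion flux with Peclet number `Pe = J_V(1−σ)/PS`. A tuned
  lymphatic returns exactly what is filtered at baseline (4.0 L/day).
  Inflammation degrades the endothelium (resistance and reflection
  coefficient fall with a cytokine-weighted damage signal), a baroreflex
  defends MAP until its SVR gain is inhibited by sustained SIRS, and an
  energy-deficit submodel produces lactate.

* **Treatment.** Two-compartment drug kinetics (exact matrix-exponential
  steps); the antibiotic net-growth law
  `S_net = S_max − (S_max−S_min)·u/(u − S_min/S_max)`, `u = (C_u/MIC)^γ`,
  which is exactly zero at `C_u = MIC` for any parameters; a sigmoidal
  vasopressor effect on SVR; saline and albumin-colloid fluids; and the
  REFRESH resuscitation protocols (fluid-liberal control arm vs
  restricted-fluid + early-norepinephrine experimental arm) with audited
  30/60-minute reviews.

## Worked example

```r
library(sepsim)

# critical inoculum at the nominal pathogen growth rate
find_critical_load(S_P = 0.6)
#> Critical initial tissue load at S_P = 0.6: 6959000
#>   (bracket [6941000, 6977000], 10 runs)

# untreated severe infection, fully coupled, 48 h
sim <- run_scenario(scenario(severity = "Severe", t_end = 48))
print(sim)
#> Sepsis simulation: Severe infection, 0.0 .. 48.0 h (961 samples)
#>   final: P_B 1.62e+05, TI_eff 0.807, MAP 58.6, SBP 76.0,
#>   lactate 3.37 mM, cum fluid 0.00 L
```

The critical inoculum is the initial tissue bacterial load separating
self-resolving infection from septic escape — here ≈ 6.96·10⁶ CFU/mL. In
the severe run the virtual patient's systolic pressure crosses the
100 mmHg sepsis screening threshold at 25.2 h, lactate exceeds 2 mM at
20.3 h, MAP falls below the 65 mmHg shock threshold at 41.8 h, and
systemic vascular resistance bottoms out at 58.6% of baseline — the
textbook sequence of screening-positive sepsis progressing to vasoplegic
septic shock.

Treatment scenarios chain from a snapshot of that run:

```r
sc   <- scenario(severity = "Severe", t_end = 44)
base <- run_scenario(sc)                      # untreated to 44 h
pre  <- refresh_pretrial(base$snapshot, sc)   # 2 x 500 mL fluid challenge
pre$qualified                                 # TRUE: fluid-refractory
ctl  <- run_refresh(pre$snapshot, "control", sc)
ctl$snapshot$cum_fluid_ml / 1000              # cumulative fluid, litres
ctl$audit                                     # every protocol decision
```

A thin command-line front end is included at `inst/cli/sepsim.R`
(`run <scenario.json>`, `find-threshold --sp 0.6`, `resume <snapshot>`),
with an example scenario file under `inst/extdata/`.

## Scope and limitations

The physiology is a deliberate reduction of a circuit-based whole-body
engine: no per-organ damage heterogeneity, no coagulation or respiratory
involvement, no thermoregulation dynamics, and the published inflammation
rate constants cap immune-pool activation in ways that weaken the
severity grading of cytokine levels. The methods vignette
(`vignettes/sepsim-methods.Rmd`) documents the model equations, every
calibrated constant, the transcription decisions taken where the source
equations were ambiguous, and what the passing tests do and do not show.
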