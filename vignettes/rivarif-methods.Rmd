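---
title: "Modeling the rivaroxaban-rifampin interaction: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the rivaroxaban-rifampin interaction: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivarif)
```

## The problem

Rivaroxaban is eliminated by hepatic metabolism (CYP3A4 and
CYP-independent hydrolysis) and by renal excretion (mostly active P-gp/BCRP
tubular secretion, with a minor glomerular-filtration component). Rifampin
induces both CYP3A4 and P-gp, so co-medication lowers rivaroxaban exposure —
a thrombosis hazard in patients who need both an anticoagulant and an
antibiotic — and the induction builds up and washes out over days, so the
right dose changes over time. `rivarif` couples three submodels into one
ODE system so that dosing-regimen questions (how much during co-medication,
how to start, how to step down after withdrawal) can be answered by
simulation against a reference exposure window.

## Induction kinetics

Relative enzyme activity at each site follows a turnover model: zero-order
synthesis stimulated by the inducer through an Emax relationship and
first-order degradation,

$$\frac{dE_{t,i}}{dt} = K_{deg}\,E_0\,E_{max}
  \frac{f_{u,i}\,C_i}{EC_{50} f_{u,hep} + f_{u,i}\,C_i}
  + K_{deg}\,(E_0 - E_{t,i}), \qquad i \in \{\text{liver}, \text{renal}\}.$$

| parameter | default | units | meaning |
|---|---|---|---|
| `E0` | 1 | fold | baseline activity |
| `Emax` | 9 | fold | maximal induction (10-fold ceiling) |
| `EC50` | 0.8 | uM | half-maximal inducer concentration |
| `Kdeg` | 0.0096 | 1/h | degradation rate; half-life 72.2 h |
| `fu_hep` | 0.42 | – | unbound fraction in the hepatocyte assay, corrects `EC50` |
| `Kp_liver` | 0.27 | – | liver/plasma partition of the inducer |
| `fu_liver` | 0.609 | – | unbound fraction in liver |
| `mw_inducer` | 822.94 | g/mol | converts mg/L plasma levels to uM |

At constant inducer the equation is linear in $E_t$, relaxing exponentially
(rate $K_{deg}$) to $E_0(1 + E_{max}\cdot occ)$; the test suite verifies the
numerical trajectories against this closed form to 1e-9 relative accuracy.
P-gp induction is assumed to share the CYP3A4 parameters (both proteins are
PXR-regulated), as is standard for this interaction.

Two unit/siting choices were genuinely open:

* **Renal site concentration.** A partition coefficient is only available
  for liver. The renal site therefore uses the unpartitioned plasma
  concentration with `fu_renal_site = fu_liver` by default — the
  conservative choice, and configurable. Since plasma levels exceed
  `Kp_liver`-scaled liver levels, renal P-gp induces somewhat faster than
  hepatic CYP3A4 (steady-state activities ~4.7 vs ~3.6 under 600 mg qd).
* **Molar bridge.** `EC50` is molar while the PK states are mass-based;
  rifampin's molar mass 822.94 g/mol converts between them.

## Rifampin with autoinduction

A one-compartment oral model (`Ka` 0.58 1/h, `V` 0.33 L/kg, apparent values
with bioavailability absorbed; no explicit F) whose total clearance is
decomposed into renal, CYP3A4-hepatic and other-hepatic parts, the CYP3A4
part scaling with the hepatic activity:

$$CL(E_t) = CL_R + f_m E_{t,liver}(CL_t - CL_R) + (1-f_m)(CL_t - CL_R),$$

with `CL_t` 7.4 L/h, `CL_R` 1.5 L/h, `f_m` 0.2. At baseline this returns
`CL_t` exactly; at the 10-fold ceiling it reaches 18.02 L/h. Simulated
600 mg qd dosing shows the expected autoinduction signature: the daily
rifampin AUC falls from ~78 to ~59 mg·h/L within a week and then levels
off.

## Rivaroxaban disposition and its calibration

The previously published whole-body description of rivaroxaban is not
reproduced here; the package deliberately uses a reduced one-compartment
model with first-order absorption whose apparent clearance is partitioned by
elimination pathway:

$$CL(t) = CL_{total}\left[f_{cyp} E_{t,liver} + f_{other} +
  r\,(f_{pgp} E_{t,renal} + f_{gfr})\right],
  \qquad r = \mathrm{CrCL}/\mathrm{CrCL}_{ref}.$$

Defaults: `Ka_riv` 1.4 1/h, `V_riv` 50 L, `CL_total` 9.3 L/h, fractions
(0.35, 0.21, 0.38, 0.06), `CrCL_ref` 104 ml/min. The fractions and
`CL_total` are *calibration* choices, not literature measurements, fixed
once by requiring simultaneously that

1. uninduced 10 mg qd steady state for a median patient sits mid-window
   (simulated: Cmax ~148 ng/ml in 91–196; daily AUC ~1057 ng·h/ml in
   771.5–2118.2);
2. steady-state induced clearance under rifampin 600 mg qd is roughly
   tripled (simulated ~3.5-fold), consistent with a tripled daily dose
   (15 mg bid) being the regimen that restores in-window exposure while
   10 mg bid stays below the efficacy bound and 20 mg regimens breach the
   Cmax safety bound;
3. on day 2 of an initiation plan (10 mg qd day 1, 15 mg bid after) the
   partially induced clearance already keeps Cmax under 196 ng/ml, while on
   day 1 the uninduced 15 mg bid overshoots both bounds.

Constraint 3 is the binding one: it requires a large induction-sensitive
clearance fraction (`f_cyp + f_pgp` ≈ 0.73). With a smaller inducible share
(e.g. `f_cyp` 0.18, `f_pgp` 0.30) day-2 Cmax under 15 mg bid stays above
196 ng/ml and *no* day-1 reduction can fix it — the enzyme state is driven
by rifampin alone, so day-2 exposure is independent of the day-1
rivaroxaban dose. The chosen fractions keep rivaroxaban's qualitative
elimination pattern (hepatic ~56%, renal ~44%, active secretion the major
renal route) while satisfying all three requirements.

Renal function scales both renal pathways linearly in CrCL; protein binding
is absorbed into the apparent parameters. Between-patient variability is
not modeled (a six-patient basis cannot identify it); all simulations are
for a single deterministic patient, by default the reference case (64 y,
60.3 kg, male, CrCL 118 ml/min) on whom the regimen analyses are run.

## Numerical engine

The coupled six-state system (rifampin depot/central, rivaroxaban
depot/central, two activities) is integrated with fixed-step classical RK4.

* **Step size** `dt = 0.05` h. A step-halving audit (`halve_step_check()`)
  on the co-medication scenario changes rivaroxaban concentrations by
  < 1e-5 relative, far below the 0.1% acceptance bound; the error ratio
  under halving confirms order-4 convergence.
* **Dosing events** are instantaneous depot additions applied before the
  step that begins at the dose time; times are snapped to the grid with a
  warning beyond 1e-9 h. Same-time events are summed, so event order is
  irrelevant.
* **Initial conditions**: drug states 0 and activities `E0`, unless a
  warm-start state is supplied — withdrawal scenarios restart from the
  co-medication steady state, and a warm-started continuation is verified
  to equal one continuous simulation.
* **Degenerate inputs**: non-finite or negative states abort with the first
  bad time; doses at or beyond the horizon are rejected; empty regimens are
  valid and yield identically zero drug states.

Exposure metrics use the solver grid directly: Cmax as the max sampled
concentration, AUC by trapezoid, both per 24-h calendar day (for bid
regimens the daily AUC sums both intervals, because the reference window is
defined on a once-daily basis). Steady state is the first day whose AUC
changes by < 1% from the previous day, capped at day 21 (≈ 5 washout
half-lives) for regimen acceptance; under co-medication detection typically
fires near day 12, when the daily AUC is within ~2.5% of its day-21 value.

## Regimen searches

* `evaluate_comedication_grid()` simulates {2.5, 5, 10, 15, 20} mg × {qd,
  bid} from a cold start together with rifampin 600 mg qd (same clock time)
  and accepts a candidate iff its steady-state Cmax and daily AUC are
  in-window.
* `plan_initiation()` keeps the maintenance regimen from day 2 and returns
  the *largest* day-1 candidate (ties toward the higher single dose) whose
  day-1, day-2 and steady-state records are all in-window.
* `plan_withdrawal()` is a greedy per-day feasibility search: starting from
  the co-medication steady state with rifampin stopped, each day takes the
  lowest candidate daily dose that stays in-window given the carried-over
  drug and enzyme state. Greedy search is used because the target is stated
  only as "keep every day in the window"; with a fixed window and monotone
  de-induction the greedy schedule is non-increasing in daily dose. The two
  fixed strategies (immediate 10 mg qd; maintained 15 mg bid) are evaluated
  alongside: the first under-exposes on each of the first five days, the
  second crosses the bleeding-risk bound once de-induction completes — on
  day 8 under this calibration; the crossing day is reported rather than
  asserted because it is sensitive to the calibrated inducible fraction.

## Synthetic data and what validation shows

`cohort_spec()`/`synthetic_study()` emulate the structure of the clinical
series the analysis targets: six virtual patients drawn uniformly from the
characteristic ranges (age 36–71 y, weight 60–67 kg, CrCL 52–129 ml/min,
3 male/3 female), a canonical dosing history exercising pre-induction,
induction and washout phases (rivaroxaban 10 mg qd from day 1; rifampin
600 mg qd days 4–17), and sparse samples at 2, 4, 8, 12, 24 h post-dose on
days 1, 7, 14 and 19 with multiplicative lognormal residual error
(default CV 20%, a typical bioanalytical + model residual magnitude;
$\sigma = \sqrt{\ln(1+cv^2)}$). Everything is reproducible from the spec
seed, and the generator restores the caller's RNG state.

Because the observations are generated by the same model that predicts
them, fold-error validation here checks the *statistic and pipeline*, not
model correctness: with CV = 0 every fold error is exactly 1, and with
CV = 0.2 the predicted share of fold errors below 2 is
$2\Phi(\ln 2/\sigma) - 1 \approx 99.95\%$, which the Monte-Carlo check
reproduces. Real data would add model misspecification, inter-individual
variability and dosing-history uncertainty that synthetic self-validation
cannot surface.

## Problem sizes

The test suite and the acceptance script run deterministic scenarios at
`dt = 0.05` h: 22-day co-medication grids (10 candidates), 22-day
initiation searches (4 candidates), a 21-day warm-up plus 7 greedy days and
two 16-day fixed strategies for withdrawal, 12-day uninduced baselines, and
a 3-patient, 21-day synthetic study; Monte-Carlo residual checks use 10^4
draws. Module tests use shorter horizons (3–8 days) at `dt = 0.1` h where
closed forms or orderings, not absolute accuracy, are under test.

## Known limitations

* One-compartment victim disposition: no distribution phase, so the
  simulated Cmax shape is a calibration surrogate, not a mechanistic
  prediction; organ-level modeling, BCRP as a separate transporter and
  hepatic impairment are out of scope.
* Gut-wall P-gp/CYP3A4 induction (reduced oral bioavailability) is not
  modeled; only liver and kidney sites are induced.
* No inhibition components (the interaction modeled is purely inductive),
  no enterohepatic recirculation of rifampin, no nonlinear absorption.
* The exposure window is a percentile range, not an established
  concentration-effect cutoff; conclusions inherit that caveat.
* No inter-individual variability: regimen recommendations are for a single
  reference patient, and per-day window checks are deterministic.
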