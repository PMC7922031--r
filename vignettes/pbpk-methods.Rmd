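---
title: "Methods: a whole-body parent-metabolite PBPK model of carbamazepine with enzyme induction and DDI simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-body parent-metabolite PBPK with induction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model structure

`pbpkddi` simulates the pharmacokinetics of carbamazepine (CBZ) and its
active metabolite carbamazepine-10,11-epoxide (CBZ-E) in a whole-body
physiologically based (PBPK) framework, and uses the coupled model to
predict drug-drug interactions (DDIs) driven by CYP3A4/CYP2B6/EPHX1
induction, mechanism-based inactivation and competitive inhibition.

The body is represented by 14 perfusion-limited compartments (venous and
arterial blood, lung, liver, kidney, gut wall, adipose, muscle, skin, bone,
brain, heart, spleen, and a lumped rest compartment) connected by blood
flows, with portal drainage of gut wall and spleen into the liver. Every
drug adds 21 states (14 organ amounts, 4 lumen states, cumulative urine,
cumulative metabolized, cumulative formed-from-parent); each enzyme
expression site adds one state holding the enzyme amount relative to
baseline. Eliminated material is moved into sink states, never destroyed,
so total drug-equivalents are conserved identically — the mass-balance
tests check bookkeeping and integration consistency, not a tuned
tolerance.

### Distribution

Tissue:plasma partition coefficients use the neutral-species
Rodgers-Rowland composition equations,
`Kp = fu * (f_EW + f_IW + P f_NL + (0.3 P + 0.7) f_NP)` with `P = 10^logP`.
Both packaged compounds carry no pKa, so no ionization terms enter. For
adipose, `P` is replaced by the vegetable-oil:water coefficient through
`log Dvo = 1.115 logP - 1.35`; with octanol directly, a logP 2.0 compound
would receive an adipose Kp near 20 and a grossly inflated volume of
distribution. The blood:plasma ratio defaults to 1 (both compounds are
neutral with reported ratios near unity), so blood compartments carry
plasma-equivalent concentration; the ratio is an engine option.

### Absorption and formulations

The lumen has two segments (stomach, small intestine). Gastric emptying is
first order with half-time 15 min fasted and 60 min fed (options).
Solutions/suspensions enter the stomach dissolved. Solid forms release
drug with a Weibull profile parameterized by `t_50` (time to 50% released)
and a shape factor, with `f(lag + t_50) = 0.5` by construction
(ln 2 convention). Numerically, release is integrated as a hazard-rate
process — pooled release density over pooled survivor function across all
active dose events, applied to the tracked solid amounts — which is exact
for a single dose and for shape 1 under any event history, and keeps the
state dimension independent of the number of doses. Dissolution is capped
smoothly as the dissolved lumen concentration approaches the saturation
solubility (336 ug/mL in fasted intestinal fluid for CBZ), which makes
absorption of an 800 mg dose sublinear, as observed clinically.
Absorption flux is permeability x effective area (default 0.66 m^2) x
dissolved intestinal concentration. Dissolved lumen drug is eventually
absorbed completely (no colonic transit/fecal loss) — acceptable for these
two high-permeability compounds and a documented limitation. The packaged
Weibull parameters for immediate/extended-release tablets are package
defaults fitted to qualitative release behaviour, not literature values.

### Metabolism, excretion, and the parent-metabolite link

CBZ is cleared by five Michaelis-Menten pathways (`v = E k_cat S /
(K_m + S)`, unbound tissue concentration as `S`): CYP3A4 and CYP2C8 both
forming CBZ-E mole for mole, a second CYP3A4 route to hydroxylated
metabolites, CYP2B6, and UGT2B7 (k_cat derived as Vmax over microsomal
UGT2B7 content, 0.79/82.9 = 9.53e-3 1/min); plus an unspecific first-order
hepatic clearance (0.02 1/min on unbound liver drug) and renal filtration
with a GFR fraction of 0.03 (net of tubular reabsorption). CBZ-E is
cleared by EPHX1 as a linear specific clearance (`v = E_rel CL_spec S`,
CL_spec 0.01 1/min, E_rel the enzyme pool relative to baseline) and renal
filtration with GFR fraction 0.21. The epoxide model is independently
dosable, so it can be simulated as an administered compound or as a formed
metabolite. The two formation fluxes enter the metabolite's liver (or gut
wall) compartment directly and are additionally accumulated in a
formed-sink, which is what makes the formation-vs-consumption coupling
testable to 0.1%.

### Enzyme turnover, induction and inhibition

Each expression site evolves as
`dE/dt = k_deg E_0 f_ind - (k_deg + r_inact) E`. The synthesis multiplier
is an Emax model on the unbound tissue concentration of each inducer at
the enzyme's site, combined additively across inducers:
`f_ind = 1 + sum_i E_max,i C_u,i / (EC_50,i + C_u,i)`. Under a clamped
inducer concentration the pool converges to `E_0 f_ind` (tested against
the closed form within 0.5%). CBZ induces CYP3A4 (E_max 6.00), CYP2B6
(17.00) and EPHX1 (3.25), all with EC_50 20 uM — this autoinduction is
always active, so multiple dosing lowers CBZ exposure relative to the
superposition benchmark. Mechanism-based inactivation adds
`k_inact C_u / (K_I + C_u)` to the degradation rate; competitive
inhibition scales the apparent K_m by `1 + C_u/K_i` (and divides linear
clearances by the same factor). The exact induction-equation form and the
choice of unbound intracellular concentration as driver are declared
package contracts; they follow mechanistic convention where the source
material defers to its appendix.

Turnover half-lives default to 36 h (liver CYP3A4, CYP2C8, UGT2B7, EPHX1),
23 h (gut-wall CYP3A4) and 32 h (CYP2B6). Baseline tissue concentrations
(CYP3A4 in liver and gut wall, CYP2C8/CYP2B6 in liver, UGT2B7 in
liver/kidney/gut wall, EPHX1 in liver) are declared defaults standing in
for an expression database that is not reproduced here; both are
config-overridable and the expression *pattern*, not the absolute levels,
is what the structural tests pin down.

## Numerics

No stiff ODE solver package is available in the target environment, so the
package carries its own: a Rosenbrock(2,3) linearly implicit scheme (the
classic ode23s formula pair) with finite-difference Jacobian reused across
steps until a rejection or staleness (20 accepted steps), a numerically
estimated time-derivative term for the time-dependent release schedule,
adaptive step control on the embedded error estimate, and cubic Hermite
dense output. Dose administrations restart the solver with updated lumen
states. The scheme is L-stable, which the induction problem needs: the
system couples absorption dynamics (minutes) with enzyme turnover (days).

Default tolerances are rtol 1e-6, atol 1e-9 umol. An earlier design target
of rtol 1e-8 was measured to cost about 4x more steps with an order-2
method while changing trajectories by ~1e-5 relative; since every reported
quantity carries at most 3 significant digits and mass balance is exact by
construction, 1e-6 is the default and the analytic-oracle tests pass
tighter tolerances explicitly. States in `[-1000*atol, 0)` are read as 0
after each accepted step inside the engine (rate laws internally clamp
substrate concentrations at 0, so negative excursions are pure roundoff);
a state below that floor aborts with a diagnostic. Cmax is read off the
output grid, which carries at least 200 points per dosing interval by
default.

## Observables and evaluation statistics

Venous plasma concentration is the reported profile; saliva is `fu *`
plasma (1:4 for CBZ with fu 0.25); the urine observable is the cumulative
fraction of the molar dose excreted unchanged. AUC_last is the linear
trapezoid from dosing to the last sample; DDI AUC and Cmax ratios are
with-perpetrator over alone, both arms on identical victim sampling grids
re-zeroed to the victim's reference dose.

Model performance statistics follow the conventions of this modeling
field: MRD = 10^sqrt(mean(log10(pred/obs)^2)) for concentrations,
GMFE = 10^mean(|log10(pred/obs)|) for exposure metrics, and the fraction
of predictions within 2-fold (boundaries inclusive — a declared convention
so counts are reproducible). MRD >= GMFE on any pair set (Jensen), which
is tested as a property. DDI predictions are judged with
interaction-strength-dependent prediction-success limits: at observed
ratio R (folded to >= 1), the allowed fold-margin is
`L = (delta + 2(R-1))/R` with delta = 1.25, i.e. exactly 20% deviation at
no interaction, widening to 2-fold for strong interactions, symmetric
under joint reciprocals. Delta is exposed as an argument.

## Parameter estimation

The objective is the sum of squared log10 residuals between simulated and
observed concentrations (profiles span orders of magnitude; a linear-scale
objective would let peaks dominate troughs, and the induction signal lives
in the troughs). Optimization is Monte-Carlo multistart (uniform draws on
the transformed bounded space, seeded, first start at the incumbent model
value) followed by a Levenberg-Marquardt refinement written against the
residual vector with finite-difference Jacobians and box clipping.
Simulation failures inside the objective return a large penalty rather
than aborting the search. Fitting E_max jointly with its EC_50 from
single-arm data is refused by default — the two are not separately
identifiable there, and the source workflow fixed EC_50 from literature. A
one-at-a-time normalized AUC sensitivity utility is provided; it is a
plain relative-perturbation measure and is not claimed equivalent to any
particular vendor implementation.

## Synthetic data: what it emulates and what it does not

`generate_observed_dataset()` stands in for digitized clinical study
tables: it simulates the protocol as ground truth, samples the sparse
schedule, applies multiplicative lognormal residual noise (default
sigma 0.15 log10 units, a typical between-subject spread of digitized
concentration data), drops values below a limit of quantification, and
reports per-time mean and SD across subjects. It is seeded and
reproducible, and it does not disturb the caller's RNG stream. It does
*not* emulate inter-study heterogeneity in formulations or demographics,
digitization error structure of specific published figures, or real
between-subject parameter correlation — so a green recovery test
establishes that the estimation machinery inverts the model's own data,
not that the model is identifiable from any particular historical study.

## Design decisions on genuinely open points

- **Autoinduction direction benchmark.** The steady-state dosing-interval
  AUC under chronic dosing is compared against the single-dose AUC(0-inf):
  without induction these are equal by superposition, and autoinduction
  must push the steady-state value below it (measured ratio ~0.56 at
  400 mg bid). A naive comparison against the day-1 0-to-12 h AUC is not a
  valid induction test for this compound: with a ~38 h single-dose
  half-life, accumulation raises the day-14 interval AUC above the day-1
  partial AUC regardless of induction strength.
- **Perpetrator models ship as clearly marked synthetic stubs.** The
  interaction constants of erythromycin, alprazolam, simvastatin,
  bupropion and efavirenz live outside the packaged source material;
  inventing literature values would fabricate provenance. The stubs are
  schema-valid, load through `load_drug_config()`, and exercise every
  interaction mode; users supply real parameter sets as JSON configs.
- **Configs are JSON only** (the YAML parser is not a guaranteed
  dependency of the target environment).
- **Allometry**: organ volumes scale linearly with body weight, flows and
  GFR with the 0.75 power; composition fractions are intensive.

## Known limitations

Perfusion-limited tissues only (no permeability-limited organs); no P-gp
or other transporters; no colonic absorption window or fecal loss; mean
virtual individuals only (no population variability sampling); blood cells
are not an explicit binding compartment (B:P fixed near 1); the packaged
reference physiology is a single adult table, not an age/sex-resolved
database.
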