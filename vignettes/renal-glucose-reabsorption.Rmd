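---
title: "Modelling renal glucose reabsorption by SGLT1 and SGLT2"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling renal glucose reabsorption by SGLT1 and SGLT2}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sgltsim)
```

## The physiological picture

Plasma glucose is filtered freely at the glomerulus and, in health,
almost completely recovered along the proximal tubule. Two transporters
do the work: SGLT2, a low-affinity high-capacity pathway in the early
(convoluted) proximal tubule, and SGLT1, a high-affinity low-capacity
pathway in the late (straight) segment. Gliflozin drugs competitively
inhibit SGLT2 and produce therapeutic glucosuria; the interplay of
SGLT1 compensation and residual SGLT2 activity explains why even potent
inhibitors reduce total reabsorption far less than SGLT2's baseline
share would suggest.

`sgltsim` represents the proximal tubule as nine sequential well-mixed
compartments: PCT1–6 (SGLT2) followed by PST1–3 (SGLT1), draining into
a urinary bladder and a cumulative urine compartment. The division into
sub-segments matters because the luminal glucose concentration changes
substantially along the tubule — it is depleted by reabsorption and
concentrated by water removal — and the local concentration is what the
saturable kinetics respond to.

## Model equations and assumptions

**Flows.** Water reabsorption is modelled as a fixed decrement: luminal
flow out of sub-segment *i* is $(1 - 0.074\,i)\,\mathrm{GFR}$, i.e.
every sub-segment removes 7.4 % of GFR, leaving 33.4 % of filtered
water at the end of PST3 (about two thirds reabsorbed). The parameter
table from which the scheme is taken prints the final coefficient as
0.333 while the self-consistent decrement arithmetic gives
$1 - 9 \times 0.074 = 0.334$; we compute all nine flows from the
decrement ($Q_i = (1 - 0.074\,i)\,\mathrm{GFR}$) and accept the 0.001
rounding discrepancy against the printed last value.

**Reabsorption.** In sub-segment $j$ with luminal glucose $C_j$ and
luminal inhibitor $D_j$,

$$R_j = \frac{V_{max,j}\, C_j}{K_m \left(1 + D_j / K_i\right) + C_j},$$

the classical competitive-inhibition form: the drug scales the apparent
$K_m$ and leaves $V_{max}$ untouched. Capacity is distributed uniformly
($V_{max2}/6$ per PCT sub-segment, $V_{max1}/3$ per PST sub-segment).
With $D = 0$ the expression reduces bitwise to plain Michaelis–Menten
kinetics. Reabsorbed glucose is routed to cumulative accumulator
compartments (split by transporter) rather than back to plasma — the
model is built for conditions where plasma glucose is externally
controlled (clamps) or tightly regulated (normal glucose tolerance), so
there is no feedback of recovered glucose on the plasma level.

**Drug disposition in the nephron.** Only the unbound fraction of
circulating drug is filtered ($f_{up}\,\mathrm{GFR}\,C_{plasma}$); the
drug then travels the same compartments as glucose but is not
reabsorbed, so at steady state its luminal concentration rises
monotonically along the tubule as water is removed — by a factor of
about 2.8 from plasma ultrafiltrate to the final sub-segment. This
concentration-by-water-removal is why occupancy computed from luminal
drug exceeds occupancy computed from free plasma drug; the site of
competition is the lumen, so `occupancy_and_residual()` uses the
luminal PCT concentration by default and offers `basis = "plasma"` as
an alternative convention.

**Bladder.** The bladder is treated as a fixed-volume (0.2 L)
well-mixed compartment with a solute-only mass balance: solute enters
with the tubular outflow and leaves at $K_X \cdot C_{bladder}$ with the
measured urine outflow $K_X$. Volumetric inflow and outflow are not
balanced (urine flow is much smaller than end-tubule water flow because
the loop of Henle and distal nephron — not modelled — reabsorb most of
the remaining water); holding the solute volume at 0.2 L is the
simplest closure consistent with the fixed measured $K_X$. The bladder
time constant $V_X/K_X \approx 13$–20 min is the main transient between
tubular events and urine collection.

## The two solvers and their cross-check

`simulate_tubule()` integrates the full ODE system with `deSolve`'s
`lsoda` (stiff-capable), relative tolerance $10^{-8}$ and absolute
tolerance $10^{-10}$ mmol. Integration restarts at every forcing
discontinuity so clamp staircases are not smoothed. Negative states are
never clipped; the tolerances are chosen so that undershoot stays below
$10^{-6}$ and anything larger raises an error. Initial conditions are
the analytic steady state of the starting conditions (clamp studies
begin at established fasting equilibria), or empty compartments plus a
discarded 2-h burn-in for time-varying daily profiles.

`steady_state_profile()` solves the clamped problem exactly: segment by
segment, conservation (inflow = convective outflow + reabsorption)
gives the quadratic
$Q_j C^2 + (Q_j K_{app} + V_{max,j} - L_{in})\,C - L_{in} K_{app} = 0$
whose unique positive root is the luminal concentration; the drug
concentration is $f_{up}\,\mathrm{GFR}\,C_{plasma,drug}/Q_j$ in closed
form. Because the two solvers share no numerical machinery, their
agreement (within 0.1 % per segment across a wide glucose × drug grid,
enforced in the test suite) is a genuine cross-validation, and every
simulation is audited for glucose and drug mass conservation to
$10^{-6}$ relative error.

## Protocols

**Stepped hyperglycemic clamp (SHC).** `make_shc_protocol()` builds the
piecewise-constant glucose staircase. The canonical calibration design
escalates 100→350 mg/dL in 50 mg/dL increments over the "first 4 h",
which fixes the per-step duration at 40 min; it is user-overridable.
GFR and urine outflow are constant per step; when only per-arm ranges
are known we default to their midpoints.

**Daily glucose profile.** The loss-of-function experiments need a
realistic normoglycemic day. The published experiments used a mean
healthy profile whose numerical trace is not public, so
`synth_daily_glucose_profile()` generates a constrained synthetic
stand-in: a nocturnal plateau at 82 mg/dL, a daytime baseline at 86
mg/dL (logistic transitions at 06:30 and 22:30), and three post-meal
excursions at 07:00, 12:00 and 18:00 (0.5 h linear rise, 1 h
exponential decay), with excursion amplitudes rescaled analytically so
the time-weighted 24-h mean is exactly the requested 90 mg/dL and the
trace stays inside [80, 125] mg/dL (peaks ≈ 120 mg/dL). A seed jitters
meal times (±15 min) and relative amplitudes (±5 %) deterministically.
Quantities that depend on the supra-threshold excursions — above all
the glucosuria under partial SGLT2 loss — are therefore approximate
with respect to any particular real profile with the same constraints;
quantities dominated by the mean level (complete-knockout UGE, percent
reduction in reabsorption) are robust to the shape.

## Calibration

`calibrate_sglt()` estimates the transporter kinetics from per-step
clamp UGE tables covering four arms (healthy/T2DM × baseline/drug). The
parameterization follows the physiological reasoning used to build the
default sets: $V_{max1}$, $K_{m1}$, $K_{m2}$, $K_{i2}$ shared between
health and disease, $V_{max2}$ estimated for T2DM with the healthy
value expressed as a proportion of it. Starting points are the
literature anchors (14 and 126 mmol/h from a 10 %/90 % split of a 140
mmol/h total capacity, 1.8 and 4.9 mM affinities, 6 nM inhibitor
affinity) and optimization is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`) on log-parameters, with optional seeded
multi-start. Records whose achieved glucose deviates 25 % or more from
the group mean are excluded (`exclude_deviant_points()`), and the loss
only counts steps in the clinically relevant 100–400 mg/dL window —
above it, unmodelled hydrodynamic compensation distorts UGE.

Two forward models are available. The default treats each step as its
own clamped condition solved analytically ("quasi-steady" accounting):
steps are long (40 min) relative to tubular transit (minutes), the
objective stays smooth, and a full four-arm evaluation costs
microseconds. The `method = "ode"` path integrates each arm's full
staircase and accounts urine per collection window, including the
bladder washout lag; the test suite shows the two agree once steps are
long against the washout time constant. Synthetic data generation and
calibration share the forward model, so parameter-recovery studies are
internally consistent.

**Weighting.** Unit weights on gram residuals are the default. A
relative (observation-scaled) weighting is available and is the right
choice when the error model is multiplicative: the threshold-region
steps with small absolute UGE carry most of the information about the
affinities, and absolute weighting drowns them.

**What is identifiable.** Noise-free four-arm data identify all five
kinetic parameters essentially exactly (the recovery test demands 2 %).
Separating $V_{max1}$ from $V_{max2}$ requires both baseline and
drug arms — without SGLT2 perturbation only their sum is well
determined — and $K_{i2}$ is structurally non-identifiable without a
drug arm; `calibrate_sglt()` detects this, freezes $K_{i2}$ at its
starting value and flags it. At 5 % multiplicative noise the capacities
and affinities recover with median errors well under 15 % (20-seed
simulation study in the test suite), but $K_{i2}$ does not: at clinical
dapagliflozin exposure the luminal PCT concentration is 70–100 ×
$K_{i2}$, SGLT2 occupancy is ~99 %, and per-step UGE changes only ~3 %
per unit of $\ln K_{i2}$ — the information bound then puts the
achievable median error near 40 %. This is the same physics as the
residual-SGLT2-activity argument: once occupancy saturates, the data
say little about exactly how strong the binding is. Precise $K_{i2}$
estimation would need a low-dose arm with intermediate occupancy.

A similar identifiability caveat applies to the two-compartment PK
module: from a single noisy day-profile of total plasma concentration,
clearance and the concentration-time course are well determined, but
the distribution parameters (absorption rate, central/peripheral
volumes, inter-compartmental clearance) trade off along near-flat
likelihood directions. The tests assert what the data support.

## Synthetic data

`synth_shc_uge_dataset()` emulates the calibration study's design:
four arms, ten glucose targets (100–550 mg/dL), achieved glucose
jittered within ±5 % of target, per-step GFR drawn uniformly from the
printed per-arm ranges, and multiplicative lognormal noise (unit mean,
specified CV) on UGE — positive, right-skewed errors being the natural
choice for excretion data. The drug arms use a constant total plasma
concentration of 245 nM (100 ng/mL), a realistic clamp-average exposure
for 10 mg once-daily dapagliflozin. The generator reproduces the
statistical structure the calibration assumes; it does not attempt
inter-subject variability, within-step PK decline, assay censoring, or
the hydrodynamic UGE inflation seen above 400 mg/dL — so passing
recovery tests demonstrate correctness of the estimation machinery, not
robustness to every feature of real trial data.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run desk-scale problems:
24-h daily simulations on a 0.05 h output grid with a 2-h burn-in,
clamp simulations on a 0.02 h grid, a 6 × 4 glucose × drug grid for the
oracle-equivalence check, and 20 seeds × 5 optimizer starts for the
noisy recovery study. Each individual simulation completes in well
under a minute on one CPU.

## Known limitations

- Plasma glucose is a forcing, never a state: no glucose–insulin
  homeostasis, so free-living predictions require an external glucose
  model.
- No distal-tubule or collecting-duct transport, and no hydrodynamic
  (urine-volume) response to luminal glucose — predictions above
  ~400 mg/dL plasma glucose systematically understate UGE under strong
  inhibition.
- Intestinal SGLT1 effects of dual inhibitors are out of scope; the
  $V_{max1}$-scaling scans cover only the renal consequences of reduced
  SGLT1 activity.
- The dapagliflozin-like day-profile shipped for demonstrations
  (`synthetic_dapagliflozin_profile()`) is a labelled synthetic
  stand-in, not observed data, and is never used for quantitative
  claims.
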