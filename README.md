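# sgltsim

Mechanistic simulation of renal glucose reabsorption by the
sodium–glucose cotransporters SGLT1 and SGLT2 along the human proximal
tubule, with competitive inhibition by SGLT2 inhibitors (gliflozins).

The package is aimed at quantitative pharmacologists and physiologists
who want to reason about questions such as: how is reabsorption split
between SGLT2 (low affinity, high capacity, early proximal tubule) and
SGLT1 (high affinity, low capacity, late proximal tubule)? Why do potent
SGLT2 inhibitors suppress reabsorption by only 30–50 % in the clinic
despite near-complete target engagement? How much glucosuria does a
partial loss-of-function SGLT2 mutation cause in an otherwise healthy
person?

## The model

Glomerular filtrate flows through nine well-mixed sub-segments — six
proximal convoluted tubule (PCT1–6, carrying SGLT2) and three proximal
straight tubule (PST1–3, carrying SGLT1) — then a urinary bladder and a
urine collection compartment. Luminal flow out of sub-segment *i* is
(1 − 0.074·i)·GFR: each sub-segment removes the same water fraction, so
about two thirds of filtered water is gone by the end of the proximal
tubule. In each sub-segment glucose is reabsorbed by a Michaelis–Menten
process, competitively inhibited by the luminal (filtered, unbound)
drug:

    R_j = Vmax_j · C_glu,j / ( Km · (1 + C_drug,j / Ki) + C_glu,j )

with capacity split uniformly (Vmax2/6 per PCT sub-segment, Vmax1/3 per
PST sub-segment). Reabsorbed glucose goes to an accumulator, never back
to plasma: plasma glucose is always an external forcing (clamped or a
daily profile). Default kinetics: Vmax1 = 20 mmol/h, Vmax2 = 93.5
(healthy) / 110 (T2DM) mmol/h, Km1 = 0.5 mM, Km2 = 4 mM; dapagliflozin
Ki2 = 0.3 nM, Ki1 = 400 nM, fup = 0.07.

Two solvers share this model: a stiff ODE integrator (deSolve) for
arbitrary time-varying protocols, and an exact segment-by-segment
quadratic steady-state solver for clamped conditions, which doubles as
an independent oracle for the integrator.

## Worked example

Steady state of a healthy subject clamped at 100 mg/dL plasma glucose
(GFR 6.5 L/h):

```r
library(sgltsim)
geom <- build_geometry(sglt_physiology(gfr_l_per_h = 6.5),
                       sglt_transporters("healthy"))
steady_state_profile(geom, glucose_mgdl = 100)
#> <sglt_steady_state> glucose 100 mg/dL, GFR 6.5 L/h, drug 0 nM
#>   filtered 36.08 mmol/h | SGLT2 33.39 | SGLT1 2.672 | UGE 0.01714 mmol/h
```

Of 36 mmol/h filtered glucose, SGLT2 reabsorbs 33.4 and SGLT1 2.7
mmol/h — a 93 %/7 % split, operating at 36 % and 13 % of their
capacities — and almost nothing (0.017 mmol/h ≈ 0.07 g/day) escapes to
urine: reabsorption is essentially complete at normoglycemia.

Loss-of-function scan for SGLT2 under a synthetic normoglycemic day
(80–125 mg/dL, time-weighted mean 90 mg/dL, GFR 7.4 L/h):

```r
prof <- synth_daily_glucose_profile(seed = 1)
loss_of_function_scan("sglt2", c(0, 0.5, 1), prof, gfr_l_per_h = 7.4)
#>   fraction  uge_g reabsorbed_mmol reduction_pct
#> 1      0    0.163            886.          0
#> 2      0.5  4.17             864.          2.51
#> 3      1   78.5              451.         49.1
```

Halving SGLT2 capacity produces ~4 g/day of glucosuria; complete loss
produces ~79 g/day, yet total reabsorption falls by only ~49 % because
SGLT1 compensates downstream.

A command-line interface wraps the same functions
(`system.file("cli", "sgltsim.R", package = "sgltsim")`):

```sh
Rscript inst/cli/sgltsim.R steady-state --subject healthy --glucose 100 --gfr 6.5 --out results/
Rscript inst/cli/sgltsim.R lof-scan --transporter sglt2 --fractions 0,0.5,0.75,0.875,1.0 --out results/
```

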