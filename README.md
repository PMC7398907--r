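# atrazfba

Constraint-based simulation of atrazine biodegradation by
*Paenarthrobacter aurescens* TC1 — and, more generally, a compact R
toolkit for flux balance analysis (FBA), flux variability analysis (FVA),
time-stepped dynamic growth/degradation simulation, and model-driven media
design on genome-scale metabolic models.

## The problem

Atrazine is a persistent triazine herbicide. *P. aurescens* TC1 dismantles
it hydrolytically — TrzN converts atrazine to hydroxyatrazine, AtzB and AtzC
strip the side chains, the triazine ring leaves as cyanuric acid — and,
unlike most degraders, catabolizes the released ethylamine and
isopropylamine, so atrazine serves as a sole carbon **and** nitrogen source.
Degradation scales with the degrader population, which makes *media design*
a bioremediation strategy: find supplements that grow more biomass and you
accelerate degradation without touching the genome. This package provides
the in-silico side of that workflow for modelers and environmental
microbiologists.

## What it computes

Given a stoichiometric matrix $S_{m\times n}$ and flux bounds, FBA solves

$$\max_v\; c^\top v \quad \text{s.t.}\quad S v = 0,\;\; lb \le v \le ub,$$

where the objective flux $\mu$ (h⁻¹) of a biomass pseudo-reaction proxies
growth rate and media enter as exchange-reaction uptake bounds. On top of
that core the package offers:

* **I/O** — SBML Level 3 + fbc (with a ModelSEED-style legacy fallback) and
  plain TSV model/media tables (`read_sbml()`, `read_model_tables()`,
  `read_media()`).
* **Curation audits** — elemental/charge balance, blocked-exchange
  (energy-loop) audit, carbon/nitrogen requirement check, directionality
  report.
* **FBA / FVA** — `solve_fba()`, `run_fva()`, `degradation_capacity()`,
  with broom-style `tidy()`/`glance()` and an internal, oracle-tested
  simplex backend.
* **Dynamics** — `simulate_timecourse()`: finite substrate pools (default
  50 units), a per-cell uptake cap (default 1 unit/tick), pools updated from
  realized fluxes, biomass updated from μ, stop at stall.
* **Media design** — `supplement_screen()` + `classify_supplements()`
  (high/moderate/low vs the screen maximum), `gradient_scan()` surfaces,
  and `equimolar_nitrogen_dose()` for nitrogen-matched in vitro media.
* **The atrazine pathway** — `build_atrazine_pathway()` as a fully balanced,
  injectable reaction set; `bioavailable_cn()` for the 5 C / 2 N
  catabolizable share of each atrazine molecule.
* **Fixtures** — analytic toy models (`make_toy_model()`), the 11-ion
  minimal mineral medium (`make_mmm_media()`), and a seeded generator of
  provably mass-balanced random networks for property tests.

## Worked example

Inject the atrazine pathway into the toy host that can catabolize the
alkylamines, and grow on atrazine as the sole C/N source:

```r
library(atrazfba)

toy <- inject_pathway(make_toy_model("TOY-2"), build_atrazine_pathway())
med <- media(c(EX_atz = 1, EX_h2o = 1000, EX_h = 1000, EX_pi = 10))

solve_fba(toy, med)
#> <pa_fba> status: optimal, objective (BIOMASS): 0.833333 h^-1

degradation_capacity(toy, med, "EX_atz")
#> # A tibble: 1 × 4
#>   exchange min_uptake max_uptake objective_value
#>   <chr>         <dbl>      <dbl>           <dbl>
#> 1 EX_atz        1.000          1           0.833
```

μ = 5/6 is the closed-form carbon-limited optimum: each atrazine yields 5
usable carbons against 6 per glucose equivalent, and at the optimum the
1-unit atrazine uptake is stoichiometrically forced (FVA min = max). A
single-supplement screen ranks glucose far above ammonium — extra nitrogen
is pointless because deaminated atrazine nitrogen already covers the demand:

```r
classify_supplements(supplement_screen(toy, med, c("EX_glc", "EX_nh4")))
#> # A tibble: 2 × 5
#>   exchange    mu carbon nitrogen class
#> 1 EX_glc   4          6        0 high
#> 2 EX_nh4   0.833      0        1 low
```

The dynamic simulation on TOY-1 (pools of 50, cap 1, one starting cell)
doubles biomass every tick while the cap binds and converts all 50 glucose
units at yield 1, ending at biomass 51:

```r
traj <- simulate_timecourse(make_toy_model("TOY-1"),
                            dynamic_config(c(EX_glc = 50, EX_nh4 = 50)))
tidy(traj)
#> # A tibble: 7 × 5
#>    time biomass    mu EX_glc EX_nh4
#> 1     0       1     1     50   50
#> 2     1       2     1     49   49.5
#> 3     2       4     1     47   48.5
#> # … biomass reaches 51 when glucose runs out
autoplot(traj)
```

Nitrogen-matched dosing for in vitro validation — the L-histidine
concentration carrying the same molar nitrogen as 30 mg/l atrazine:

```r
equimolar_nitrogen_dose(compound("C8H14ClN5", mw = 215.68, conc = 30),
                        compound("C6H9N3O2",  mw = 155.15))
#> # A tibble: 1 × 2
#>    dose dose_exact
#> 1    36       36.0
```

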