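---
title: "Constraint-based modeling of atrazine biodegradation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based modeling of atrazine biodegradation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atrazfba)
```

## The modeling problem

*Paenarthrobacter aurescens* TC1 degrades the herbicide atrazine through a
three-step hydrolytic pathway (TrzN, AtzB, AtzC) and, unusually among known
degraders, catabolizes the released alkylamines — so atrazine can serve as
its sole carbon *and* nitrogen source. Because degradation activity scales
with the degrader population, media design is a bioremediation lever: a
supplement that grows more biomass degrades more atrazine without any strain
engineering. This package implements the constraint-based machinery for that
analysis: flux balance analysis (FBA) and flux variability analysis (FVA) on
a genome-scale metabolic model, a time-stepped dynamic simulation of growth
and substrate depletion, supplement screening and uptake-gradient scans,
curation audits, and the equimolar-nitrogen dose arithmetic used to design
matched in vitro media.

## The model and its assumptions

A metabolic network with $m$ metabolites and $n$ reactions is a
stoichiometric matrix $S_{m \times n}$. FBA assumes pseudo-steady state for
internal metabolites, $S v = 0$, bounds every flux ($lb \le v \le ub$, in
mmol gDW$^{-1}$ h$^{-1}$), and maximizes the flux $\mu$ of a biomass
pseudo-reaction as a proxy for growth rate (h$^{-1}$):

$$\max_v \; c^\top v \quad \text{s.t.}\quad S v = 0,\; lb \le v \le ub .$$

Media enter only through exchange-reaction bounds: an exchange written
`met_e ->` carries uptake as negative flux, so a medium maps exchange ids to
uptake magnitudes and `apply_media()` sets lower bounds to `-uptake`,
closing every unlisted exchange. Species flagged as SBML boundary species
are carried in $S$ but excluded from the steady-state constraint (the toy
fixtures' biomass product is such a sink).

Only the objective value of an FBA solution is well-defined; internal fluxes
at a degenerate optimum are not unique. All contract-level statements
therefore concern $\mu$ and FVA ranges: `run_fva()` fixes biomass at (a
fraction of) its optimum and minimizes/maximizes each flux, and
`degradation_capacity()` reports the resulting uptake range of a target
exchange — the model's estimate of degradation rate at optimal growth.

## The linear-programming layer

All analyses funnel through one internal interface (`lp_maximize()`):
maximize $c^\top v$ subject to $S v = 0$ and box bounds. A presolve pins
zero-width variables (closed exchanges), drops vacuous rows, and reduces the
equality system to an independent row set; the reduced program is solved by
a dense two-phase primal simplex written for this package, with upper bounds
as explicit slack rows and Bland's rule throughout. Metabolic LPs are highly
degenerate, and Bland's rule trades speed for a termination guarantee — an
acceptable trade at the problem sizes used here (tens to a few thousand
reactions). The feasibility tolerance defaults to $10^{-9}$ and is reported
in every solution; tests compare the solver against an independent
brute-force vertex-enumeration oracle on all networks with at most eight
reactions (agreement to $10^{-6}$).

Default bounds where a file states none are $-1000/1000$ for reversible and
$0/1000$ for irreversible reactions, the field's convention; this also keeps
every program bounded. ATP maintenance, when a model declares such a
reaction, is a fixed lower bound on that reaction and is taken as given from
the model file.

## Dynamic growth and degradation simulation

`simulate_timecourse()` iterates FBA over discrete time ticks under four
assumptions: (1) finite starting pools of media components; (2) a per-cell
uptake cap — each tick, the uptake bound of a pooled exchange is
$\min(\text{cap},\; \text{pool}/(X\,\Delta t))$, so a cell takes at most the
cap and the population can never overdraw the pool; (3) pools update from
realized exchange fluxes, $\text{pool} \leftarrow \text{pool} + v_{ex} X
\Delta t$, with secretion accumulating and available for later
re-consumption (ammonium released by atrazine degradation is the canonical
example); (4) biomass updates as $X \leftarrow X (1 + \mu \Delta t)$
(forward Euler; an exponential update is available as a config option). The
run stops when the relative biomass increase falls below `stall_tol`
(default $10^{-6}$) — the operational reading of "no further increase in
biomass" — or at `max_cycles`.

Defaults mirror the study protocol: pools of 50 units per media component, a
cap of 1 unit per biomass unit per tick, one starting cell, $\Delta t = 1$
h. The "units" are deliberately dimensionless; mapping to mmol or mg/l is a
caller-level scale factor, not something the simulator guesses. On TOY-1
these defaults give a hand-checkable trace: biomass doubles each tick while
the cap binds (1, 2, 4, 8, 16, 32), glucose falls 50, 49, 47, 43, 35, 19, 0,
and the endpoint equals $X_0 + Y S_0 = 51$ at yield $Y = 1$ — the
discretization error of the final partial tick is zero here because the pool
bound hands the LP exactly the remaining glucose.

## The atrazine pathway encoding

`build_atrazine_pathway()` encodes the hydrolytic route as a balanced,
injectable reaction set:

* TrzN: atrazine + H2O → hydroxyatrazine + Cl⁻ + H⁺
* AtzB: hydroxyatrazine + H2O → N-isopropylammelide + ethylamine
* AtzC: N-isopropylammelide + H2O → cyanuric acid + isopropylamine
* lumped ethylamine catabolism → acetaldehyde + NH4⁺
* lumped isopropylamine catabolism → L-alanine

Design choices worth stating explicitly. The ring is not cleaved in TC1, so
cyanuric acid is exported and accumulates mole-for-mole with atrazine
consumed; of atrazine's 8 C and 5 N, the catabolizable share is 5 C and 2 N
(`bioavailable_cn()`). Deaminated nitrogen leaves as NH4⁺ and chloride as
dissociated Cl⁻ + H⁺, which fixes charge balance. The amine catabolism
steps are multi-enzyme routes in vivo; they are lumped to single reactions
here because only their net stoichiometry matters for flux balance. Lumping
forces a bookkeeping decision for redox: the reactions are written
cofactor-neutral, with reducing equivalents leaving as molecular hydrogen
through a dedicated exchange. This is a deliberate abstraction — the real
electron acceptors are unresolved cofactors — and it keeps every pathway
reaction elementally and charge balanced, so the injected model still passes
`audit_model_balance()`. Water and protons are consumed stoichiometrically
and must be supplied as non-limiting media entries in simulations; the
11-ion mineral medium of `make_mmm_media()` deliberately contains exactly
the published ion list and nothing else, so the fixtures pass water
explicitly.

`inject_pathway()` adds the reactions plus any species the host lacks.
Whether atrazine then supports growth depends on the host's downstream
catabolism: TOY-2 (acetaldehyde assimilation, alanine deamination,
gluconeogenesis) grows at the closed-form carbon-limited optimum of
$\mu = \tfrac{5}{6}$ per unit atrazine uptake; TOY-1, which lacks amine
catabolism, gains nothing.

## Curation audits

Three audits mirror standard reconstruction-refinement steps. The balance
audit parses Hill-style formulas (wildcards R/X/* route a reaction to a
*skipped* list rather than a violation; charge is checked only when all
participants carry charges) and tallies $\sum_j S_{ij} \cdot
\text{atoms}_i$ per element with exact integer-like arithmetic. The
blocked-exchange audit closes every exchange in both directions and
maximizes biomass (plus an optional ATP probe); any flux above $10^{-6}$
reveals a futile, energy-generating loop. The nutrient-requirement audit
verifies that growth needs both a carbon and a nitrogen source by deleting
each class from the medium. Directionality handling is report-only:
reversible reactions whose reverse direction is unused at the optimum are
listed, never auto-flipped — directionality curation is a judgment call.

## Media design analyses

`supplement_screen()` adds one candidate exchange at a time to a base
medium and records $\mu$; because an extra uptake allowance only relaxes
the LP, a supplement can never reduce the optimum, which the tests assert
for every candidate. One shared supplement bound (default 10) keeps the
ranking comparable when no per-candidate table is supplied.
`classify_supplements()` labels candidates relative to the screen maximum:
**high** at $\ge 66\%$, **low** below $25\%$, **moderate** between. These
cutoffs are a package decision — the study reports the labels but not the
thresholds — chosen so the published example values (11.3, 7.4 and 1.4
h$^{-1}$ against a 13 h$^{-1}$ screen top) classify as high, moderate and
low; the classification is scale-invariant. `gradient_scan()` sweeps two
uptake bounds over grids and returns the $\mu$ surface, which LP
monotonicity makes non-decreasing along each axis.

`equimolar_nitrogen_dose()` implements the in vitro design arithmetic: the
concentration of a supplement delivering the same molar nitrogen as a
reference solution,
$\text{dose} = \frac{c_{ref}}{MW_{ref}} \cdot \frac{N_{ref}}{N_{tgt}} \cdot
MW_{tgt}$. Against 30 mg/l atrazine (MW 215.68, 5 N) this gives 35.97 →
36 mg/l for L-histidine and 37.2 → 37 mg/l for ammonium chloride. Doses are
reported rounded (integers for solids, one decimal for the liquid amines,
matching how such protocols print them) alongside the exact value; the
published concentrations are internally rounded to about 1%, so exact
agreement at full precision is not expected for every compound.

## Synthetic fixtures: what they do and do not show

The generator module makes the whole pipeline testable without any
downloaded reconstruction. TOY-1/TOY-2 have closed-form optima (documented
above), and `make_random_balanced_model()` builds seeded linear pathways
over a synthetic pseudo-element with formulas `E<k>`, so elemental balance
is provable by construction and closing the single exchange provably
removes all flux. These fixtures validate the solver, the audits, the
dynamics and the screening logic exactly — but they are desk-scale, single
pathway, and chemically trivial. They do not probe the numerical behavior of
a 2,541-reaction reconstruction, alternate-optima structure in a real
network, or real biomass compositions; reproducing published genome-scale
numbers (network statistics, the 123-supplement screen values) requires the
reconstruction's own SBML and media files, which the reader supplies
(`read_sbml()`, and `IRZ1179_SBML` for the test hook).

## Numerical choices and limitations

Tolerances: LP feasibility $10^{-9}$; audit and growth thresholds $10^{-6}$;
the FVA biomass floor is backed off by $10 \times$ the LP tolerance to avoid
knife-edge infeasibility. Ties in the screen ranking are left in sorted
order; degenerate fluxes are documented as non-contractual. Degenerate
inputs (empty media, exhausted pools, zero-candidate screens, wildcard
formulas) all have defined behavior exercised in the tests. Known
limitations: no Michaelis–Menten kinetics in the dynamic loop (deliberate —
uptake is capped, not rate-modeled), no parsimonious FBA or knockout
analysis, no thermodynamic direction assignment, and no multi-supplement
combinatorial optimization.
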