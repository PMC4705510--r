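---
title: "Model and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucosim)
```

mucosim simulates a mucosal immune response as three coupled scales on a
two-dimensional grid: stochastic cell agents (the cellular scale), cytokine
concentration fields evolved by diffusion and evaporation (the
intercellular scale), and a per-cell kinetic model of CD4+ T cell
differentiation (the intracellular scale). This vignette documents the
model equations, the default parameters and why they were chosen, the
numerical methods, and the limits of what the simulated scenarios can
claim.

## The spatial scale: grid, compartments and value layers

Space is a `width` x `height` grid of unit cells. Agents carry continuous
positions; the grid cell containing an agent is `floor(position)`.
Optional rectangular compartments (lumen, epithelium, lamina propria,
lymph node, blood) partition the grid; an agent bounces off its
compartment's walls unless its type is listed as `permeable`, in which
case it bounces off the outer grid boundary only and is reassigned to the
compartment it lands in. Reflection is the exact triangle-wave fold of
the candidate position into `[lo, hi)`, so a single step of any length
stays in bounds.

Each cytokine is a *value layer*: a scalar field `v` over the grid updated
synchronously each step by

```
v_n(c) = ce * ( v_{n-1}(c) + cd' * sum_{u in N(c)} ( v_{n-1}(u) - v_{n-1}(c) ) )
```

where `ce` is the evaporation (retention) constant, `N(c)` the von Neumann
(4) or Moore (8) neighbourhood, and `cd'` the effective diffusion weight.
Two details matter numerically:

* **Normalization.** In the literal (`mode = "raw"`) rule a point source
  with `cd = 0.6` and four neighbours loses `4 * 0.6 = 2.4` times its own
  value in one step and goes negative. The default `mode = "normalized"`
  uses `cd' = cd / |N|`, which is the standard stable explicit stencil:
  the update is then a convex combination of the centre and its
  neighbours for any `ce, cd` in `[0, 1]`, so non-negative fields stay
  non-negative without clamping. Raw mode is retained for comparison,
  with `clamp_nonnegative = TRUE` (the default) flooring the result at
  zero.
* **Boundaries.** `zero_flux` (default) makes an out-of-bounds neighbour
  mirror the centre value, contributing exactly zero difference; `torus`
  wraps indices. On a torus the pairwise differences cancel, so total
  mass obeys `sum(v_n) = ce * sum(v_{n-1})` exactly — an identity the
  test suite checks to 1e-9 relative, alongside a brute-force per-cell
  reference implementation agreeing to 1e-12 on random fields.

Defaults `ce = 0.98`, `cd = 0.6` are the reference study conditions: slow
evaporation keeps cytokine trails alive for tens of cycles, while the
normalized `0.6` spreads a deposit to its neighbours within a few cycles.

## The cellular scale: agents and transition rules

Agents live in one data frame: type, state, continuous position,
compartment, alive flag, movement speed, and optional chemotaxis settings.
Movement is a bounded random walk: each cycle a living agent draws a
direction uniformly on `[0, 2*pi)` and a speed uniformly on
`[0, speed_max]` (default `speed_max = 1` cell side). With chemotaxis
weight `w > 0` the direction is the renormalized blend
`(1 - w) * u + w * g_hat` of the random unit vector `u` and the local
layer gradient direction `g_hat` (central differences).

Two interaction rules are built in, following the qualitative biology of
dendritic-cell-mediated CD4+ T cell priming:

* **Dendritic-cell contact.** An immature dendritic cell sharing a grid
  cell with an infectious bacterium becomes an *effector* DC and releases
  IL-6 and IL-12 at that cell; with a tolerogenic bacterium it becomes a
  *tolerogenic* DC and releases TGF-beta. The release concentration is 70
  (relative units) with `"set"` semantics by default, i.e. the cell's
  concentration is set to the secreting cell's level rather than
  accumulated; `"add"` and `"set_max"` are available. When both bacterial
  subtypes co-occupy the cell the effector conversion wins by default
  (`dc_tie_break`). Differentiated DCs keep secreting every cycle while
  alive (`secretion_recurs = TRUE`), modelling sustained presentation; a
  single release at the conversion event can be configured instead.
* **Naive T cell differentiation.** A naive CD4+ T cell reads the local
  IL-12, TGF-beta and IL-6 concentrations, runs the intracellular model
  below, classifies the resulting output cytokines into Th1 / Th17 /
  Treg / still-naive, and on commitment releases its marker cytokine
  (IFN-gamma, IL-17 or IL-10) at its grid cell — by default at the
  ODE-predicted concentration, optionally at a fixed value.
  Differentiation is irreversible.

Other cell types (epithelial cells, macrophages, neutrophils, B cells,
`generic`) are driven by declarative `transition_rule()`s: a trigger
(contact with a type/state, or a local cytokine exceeding a threshold), a
firing probability, a target state and optional secretions. Rules are
evaluated in configured order and the first matching rule gets one chance
to fire.

**Order independence within a cycle.** Agents update in a uniformly
shuffled order, but every agent senses the *phase-start* snapshot: all
secretions are buffered and applied at the end of the update phase, and
cohabitant queries see the cycle-start states. Consequently a co-located
T cell senses a DC's deposit only after it has diffused for at least one
step — the update order cannot change what anyone senses, which is what
makes runs reproducible under a shuffled schedule.

## The intracellular scale: reduced differentiation kinetics

The full differentiation programme of a CD4+ T cell involves dozens of
species; for coupling into a tissue simulation it is replaced by a reduced
input--output-equivalent network with 9 species, 9 reactions and 6 ODEs.
The three inputs IL-12, TGF-beta, IL-6 are held constant during one
per-cell solve; three phenotype activities and three output cytokines
evolve as

```
dA_Th1 /dt = ka1 * IL12                      - kd * A_Th1
dA_Th17/dt = ka2 * TGFb * IL6 / scale        - kd * A_Th17
dA_Treg/dt = ka3 * TGFb / (1 + IL6 / Ki)     - kd * A_Treg
dIFNg  /dt = ks1 * A_Th1
dIL17  /dt = ks2 * A_Th17
dIL10  /dt = ks3 * A_Treg
```

These are the simplest rate laws realizing the canonical rules: IL-12
alone drives Th1; TGF-beta alone drives Treg; TGF-beta *with* IL-6 drives
Th17 while IL-6 suppresses Treg induction. The linear Th1 branch has the
closed form

```
A_Th1(T) = (ka1 * c / kd) * (1 - exp(-kd * T))
IFNg(T)  = ks1 * (ka1 * c / kd) * (T - (1 - exp(-kd * T)) / kd)
```

used as an independent test oracle (agreement required to 1e-6 relative;
a hand-written fixed-step RK4 and, where available, `deSolve::lsoda`
cross-check the full nonlinear system).

Default parameters (`kinetic_params()`): `ka* = 0.01`, `kd = 0.1`,
`ks* = 0.1`, `Ki = 1`, horizon `T = 50`, positivity threshold
`theta_out = 1e-3`. The rates are an own calibration, not a fit: they are
chosen so that a saturating input of 70 produces output concentrations of
order 10 within one horizon, keeping deposited marker cytokines on the
same scale as DC secretions. `bilinear_scale = 10` calibrates the Th17
drive: because IL-6 and IL-12 are co-released by the same effector DCs,
the Th17 condition `TGFb * IL6 / scale > IL12` is only attainable in
mixed-secretion regions if the scale is smaller than the release
concentration; a scale at or above 70 would suppress Th17 everywhere
except the pure-input corner and defeat the model's central qualitative
behaviour. `theta_out = 1e-3` keeps far-field diffusion tails from
committing T cells while letting any genuine local stimulation exceed the
threshold within one horizon.

```{r corners}
service <- ode_service(build_reduced_model())
classify <- function(i) classify_outputs(
  solve_for_cell(service, i)[c("IFNg", "IL17", "IL10")])
classify(c(IL12 = 70, TGFb = 0, IL6 = 0))   # Th1
classify(c(IL12 = 0, TGFb = 70, IL6 = 0))   # Treg
classify(c(IL12 = 0, TGFb = 70, IL6 = 70))  # Th17
classify(c(IL12 = 0, TGFb = 0, IL6 = 0))    # naive
```

**Integration.** Each solve runs the package's embedded Dormand–Prince
5(4) adaptive Runge–Kutta integrator (compiled, step-size control on a
scaled RMS error norm) at `rtol = 1e-10`, `atol = 1e-14` from an all-zero
state. The tight tolerances cost little — the system is 6-dimensional and
non-stiff — and keep the reduced and inflated models (below) within 1e-9
relative of each other. `deSolve` is deliberately *not* used in the hot
path: a tissue-scale run makes on the order of 10^4 service calls per
cycle, and per-call setup overhead of a general-purpose solver dominates
at this size; it remains a test-side oracle.

**Model inflation.** `inflate_model()` pads the reduced model with
decoupled first-order-decay species and inert constants up to a target
size — the reference BM scenario uses (108 species, 46 reactions, 60
ODEs) — to emulate the *cost* of integrating a comprehensive network
while provably preserving the input–output map (the padding states start
at zero and stay there).

**Solver instances, memoization, surrogates.** `ode_service()` manages
solver instances by strategy: `singleton` (one shared instance,
reinitialized each call), `per_cell` (one persistent instance per agent)
and `pool` (round-robin checkout). Every strategy reinitializes the state
from the calling cell's inputs, so all three are bitwise-equivalent in
output and differ only in memory and instantiation cost, which the cost
metrics expose. Because the integration is a deterministic function of
the input triple, results are memoized per unique input by default — in
the reference runs most naive T cells sit in zero-cytokine regions, so a
few hundred integrations serve ~10^4 calls. A `surrogate` function can
replace the integrator entirely (a hook for learned input–output maps).

## Scale coupling and the engine

A configuration (`scenario_config()`) plus a master seed fully determines
every output artifact. Each cycle has three phases: (a) movement and
layer diffusion (order configurable), (b) agent updates with buffered
deposits, (c) reporting. Every scale has a *simulation frequency*
`f in (0, 1]`: a scale executes on cycles that are multiples of
`round(1/f)`, starting at cycle 0, so `f = 0.1` gives exactly 10
intracellular executions per 100 cycles. The estimated per-cycle cost of
a hybrid schedule is the frequency-weighted sum `sum_i f_i * c_i` of
measured mean per-execution costs (`estimate_cycle_cost()`).

Randomness is split into named streams (placement, movement, shuffle,
rules), each a separately seeded Mersenne–Twister state derived from the
master seed, so consuming one stream (e.g. longer movement histories)
never perturbs another.

Four reference presets share one biology — a 100 x 100 grid, 500
infectious + 500 tolerogenic bacteria, 2,000 naive T cells, 2,000
immature DCs, six cytokine layers: **RM** (reduced model, singleton
solver), **BM** (model inflated to 108/46/60), **MS** (one solver
instance per T cell) and **DF** (intracellular frequency 0.1).

## What the scenarios do and do not emulate

The populations are placed uniformly at random and all concentrations are
in relative units; none of the rates are fitted to measurements. The
scenarios reproduce *qualitative, structural* behaviour: effector and
regulatory phenotypes emerge in spatially distinct neighbourhoods seeded
by which bacterial subtype a DC happened to meet, Th17 cells appear where
effector and tolerogenic secretion fields overlap, and lowering the
intracellular frequency trades temporal resolution of commitment for
cost. They do **not** emulate real tissue architecture (no crypt
geometry, no epithelial barrier dynamics by default), cell division,
death or recruitment (populations are conserved unless `death_prob` is
set), receptor-level signalling, or calibrated time/concentration units —
a cycle is an abstract tick, not a wall-clock interval. Quantitative
population fractions depend on the own-calibrated kinetic constants
(notably `bilinear_scale` and `theta_out`): with the defaults, Th17
counts are small relative to Th1 and Treg because three-cytokine overlap
regions are rare under uniform placement, and how dominant Th17 becomes
is sensitive to the positivity threshold. Conclusions should therefore be
drawn from ordering and presence/absence effects, from exact structural
identities (instance counts, execution ratios, mass scaling), and from
seed-averaged trends — not from absolute numbers.

## Reproducibility

Identical configurations and seeds give byte-identical counts tables and
snapshots; the CLI writes a `manifest.json` with the package version,
seed, cycle count and an MD5 of the serialized configuration. All
end-to-end quantities in `scripts/acceptance.R` (repository root) are
recomputed from a `--seed` argument at run time.
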