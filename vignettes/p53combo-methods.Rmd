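---
title: "Model and methods behind p53combo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind p53combo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53combo)
```

## The scientific question

More than half of human cancers retain wild-type p53 but suppress its
signalling through other lesions in the pathway — most prominently
overexpression of the phosphatase Wip1 or reduced expression of the
phosphatase PTEN. Within the model implemented here, both alterations make
cells completely resistant to radiation-induced apoptosis, so radiation
monotherapy cannot work; combining fractionated irradiation with a small-
molecule Mdm2 inhibitor (a nutlin-class drug) can restore the apoptotic
response. `p53combo` simulates single cells of three phenotypes — normal
(nominal parameters), *Wip1-cancer* (fivefold increased Wip1 transcription)
and *PTEN-cancer* (fivefold reduced PTEN transcription) — under combined
schedules, and screens schedules by how selectively they kill cancer cells
while sparing normal tissue.

## The reaction network

The model is a single declarative table of 32 species and 66 reactions
(`network_definition()`, shipped as `inst/extdata/p53_network.tsv`) compiled
into both engines, so the ODE approximation and the stochastic process can
never drift apart. Its architecture:

* **Damage sensing.** Irradiation of dose $D$ Gy creates $35 D$
  double-strand-break lesions (Poisson-distributed in the stochastic
  engine). Lesions are repaired by a saturable (Michaelis–Menten) repair
  flux, so large damage loads persist for days while small ones clear
  within a fraction of a cycle. Lesions activate ATM through a sharp
  (Hill-2) gate.
* **The p53 core.** p53 is synthesized constitutively and degraded mainly
  by nuclear Mdm2. Active ATM phosphorylates p53 at Ser15 into the
  *arrester* form (the transcription factor for Mdm2, Wip1 and p21) and
  further into the *killer* form (the transcription factor for PTEN).
  Wip1 dephosphorylates active ATM, the arrester and the killer. All
  phospho/dephospho cycles are Michaelis–Menten and operate near
  saturation; this zero-order ultrasensitivity is what turns the delayed
  Wip1 negative feedback into a relaxation oscillator with a period of
  about 7 h under persistent damage, matching the damage-driven p53
  pulsing seen in single cells.
* **The pro-survival arm.** PI3K converts PIP2 to PIP3; PTEN reverses
  this. PIP3 drives AKT phosphorylation through a second zero-order cycle
  (a sharp switch), and phospho-AKT drives the nuclear import of Mdm2.
  Killer-driven PTEN accumulation therefore closes a slow positive
  feedback: killer → PTEN → low PIP3 → AKT off → nuclear Mdm2 falls → p53
  pools and killer rise further. PTEN's long protein half-life (~11 h)
  makes this the apoptotic *timer*: repeated supercritical irradiation
  ratchets PTEN up over two to three cycles before the switch flips,
  which is why a 1.3 Gy/day schedule kills the deterministic normal cell
  in its third cycle while 0.8 Gy/day does not.
* **Commitment.** The killer form activates caspase through a steep
  (Hill-4) gate with a fast positive feedback; crossing the caspase
  threshold (5000 copies) is the apoptosis commitment, treated as
  absorbing in both engines even though the state keeps evolving.
* **Gene states.** Each p53 target gene is a pair of promoter-state
  species (two alleles, on/off). The stochastic engine keeps them
  discrete — promoter noise and the Poisson lesion count are the dominant
  intrinsic-noise sources — while the ODE engine treats them as occupancy
  fractions. The Wip1 and PTEN promoters respond quadratically to their
  transcription factor (p53 binds DNA as a tetramer), which sharpens the
  feedback loops.
* **Pharmacokinetics.** Oral dosing fills a depot that liberates to blood
  at $d_{r1} = 1/h$ and is eliminated at $d_{r2} = 0.25/h$, giving the
  two-exponential (Bateman) curve with its peak about 2 h after
  administration; drip infusion approaches its equilibrium with
  relaxation time $1/d_{r2} = 4$ h. Doses are expressed in IC$_{50}$
  units: the association/dissociation constants of inhibitor–Mdm2 binding
  are chosen so the equilibrium bound fraction is
  $F = \mathrm{INH_B}/(1+\mathrm{INH_B})$, i.e. a blood level of one
  IC$_{50}$ inactivates half of nuclear Mdm2. Translocation into the cell
  and binding are lumped into one association step; phenotype specificity
  enters as a divisor on the association constant of normal cells
  (equivalent to a reduced effective dose).

### Provenance of the parameter values

The network is a *reconstruction*: the published architecture is followed
and every constant stated in the primary literature is pinned (the Wip1 and
PTEN transcription coefficients $s_1 = 0.1$ and $s_2 = 0.03$ mRNA/s, the PK
constants, the IC$_{50}$ binding normalization, the fivefold phenotype
multipliers, the threefold irradiation ratio and the 1/3/10 uptake
specificities). The remaining rate constants were calibrated once, as a
package design decision, to reproduce the reference behaviour of the
published model family: a stable resting state; third-cycle apoptosis of
normal cells at 1.3 Gy/day on a 24-h cycle with 0.8 Gy/day subcritical;
complete resistance of both cancer phenotypes to 10 Gy/day with ~7-h
killer oscillations; and inhibitor-induced sensitization with the ordering
IR_crit(normal) < IR_crit(PTEN-cancer) < IR_crit(Wip1-cancer). After this
qualitative backbone was reached the parameter set was frozen; it is not
adjusted to any downstream result.

Known quantitative departures from the reference values, with this
parameter set: the 6-day 18-h-cycle monotherapy critical dose is
0.97 Gy/day rather than about 0.8; the most cytotoxic 6-day cycle length
is 12 h rather than 18 h; the inhibitor sensitizes normal and
PTEN-cancer cells more strongly than the reference (combination critical
doses near 0.3 Gy/day at 10 IC$_{50}$ rather than 0.61 and 1.6); and
Wip1-cancer cells have no finite combination critical dose at the
reference 10 IC$_{50}$ dose, becoming sensitizable only in a narrow
low-dose window (around 2-5 IC$_{50}$) that the screening step discovers.
Dose responses can be non-monotone near phenotype boundaries; the
bisection pre-scan reports such windows instead of hiding them. These
are limitations of reconstructing the network without its original rate
constants, and they are reported as-is.

## Engines

**Deterministic.** `simulate_ode()` integrates the mass-action /
Michaelis–Menten ODE system with `deSolve::lsoda` (default `rtol 1e-6`,
`atol 1e-2` on copy-number scales). Irradiations and oral doses are
impulsive state updates through the integrator's event mechanism;
integration restarts at each event, and an event scheduled at a sample
time is applied before the sample is recorded. Internally all rates are
per second (transcription rates are quoted in mRNA/s); every user-facing
time is in hours, converted in one place.

**Stochastic.** `ssa_run()` simulates the same network as a
time-continuous Markov process with an exact Gillespie loop written in
C++, using a dependency graph for partial propensity updates. Two
accelerations:

* *Species scaling*: abundant species (proteins) are counted in units of
  $\Omega$ copies (default $\Omega = 30$); a reaction moving any scaled
  species has its propensity divided by $\Omega$ and advances those
  species by one unit. Lesions, mRNAs and promoter states stay exact.
  The scheme preserves the deterministic limit exactly and amplifies only
  the shot noise of the scaled (abundant) species, whose own noise is
  dominated by low-copy upstream fluctuations; a distributional test on a
  gene-switch fixture (`test-stochastic_engine.R`) enforces that
  commitment-time distributions with and without scaling agree.
* *Early termination*: commitment is absorbing, so committed runs stop.

The depot/blood inhibitor pair is macroscopic; between stochastic jumps it
is advanced by its exact linear-ODE propagator, and jump waiting times are
capped at 60 s so propensities see the slowly varying blood level. Each
cell runs on its own counter-derived xoshiro256++ stream: ensembles are a
pure function of (network, protocol, root seed), and enlarging an ensemble
never reshuffles earlier cells.

## Critical doses and the two-step screen

`find_ir_crit()` bisects the minimal irradiation dose per day (IR_crit) at
which the deterministic trajectory commits within the protocol horizon,
after a coarse 8-point pre-scan of the bracket (default [0, 10] Gy/day)
that detects and warns about non-monotone dose responses rather than
silently bisecting across them; resistance at the top of the bracket is
reported as an unbounded critical dose.

`screen_protocols()` implements the two-step selection. Step one computes,
for every oral catalog protocol and every inhibitor dose on a grid, the
ratio IR_crit(normal)/IR_crit(cancer) — normal cells carrying the
specificity-reduced association constant — and selects the dose maximizing
the ratio (ties toward the lower dose; multimodality is warned).
Step two verifies the selected dose stochastically: cancer cells receive
the scanned irradiation dose over $[0.8, 1.5] \times$ IR_crit(cancer) for
7 cycles, normal cells one third of it, and a protocol is *plausible* at
the first scanned dose (IR_opt) where at least 95% of cancer cells and at
most 10% of normal cells commit. `minimize_inhibitor_dose()` then walks
the dose grid downward to the smallest still-plausible dose.

## Protocols

A protocol is `cycle_h` (12/18/24/36 h between irradiations), `n_cycles`,
the irradiation dose *per day* (converted to the per-event dose
`dose_per_day * cycle_h/24` at scheduling time, since every reported
critical dose is per day), and the inhibitor timing offsets within each
cycle (at most one administration per 12/18-h cycle, two per 24/36-h
cycle). The catalog (`protocol_catalog()`) holds ten oral 6-day protocols
normalized to 20 IC$_{50}$ per day plus one drip protocol. Three timings
are fixed as published — 24 h/(6, 18), 36 h/(6, 30) and 36 h/(0, 24) —
while the remaining seven are reconstructions with evenly spaced or
irradiation-aligned defaults, flagged `reconstructed` and overridable; the
per-administration dose of 18/36-h cycles (15 IC$_{50}$) follows from
holding the daily dose at exactly 20 IC$_{50}$.

## Numerical choices and degenerate inputs

* Commitment times are linearly interpolated at the caspase threshold
  crossing; the committed flag is latched (`cummax`).
* Oscillation periods are the median inter-peak interval of local maxima
  above a 20%-of-range level, requiring at least three peaks; flat series
  return `NA`.
* Bisection tolerance defaults to 0.01 Gy/day; coarser tolerances are
  used deliberately in the large screening runs (stated per run).
* The ODE integrator may undershoot zero between events; the compiled
  right-hand side clamps negative inputs to zero before evaluating rate
  laws (all of which are non-negative for non-negative states).
* Missing rate constants, dangling species references, negative doses,
  invalid cycle lengths and over-limit administration counts all fail
  loudly at construction; there are no silent defaults.

## What the tests do and do not show

The test suite validates the engines against independent oracles (the
Bateman closed form, the Poisson stationary law of a birth–death fixture,
enumeration of event schedules, hand-coded rate laws) and the model
against the calibrated reference behaviours above. All synthetic inputs —
fixtures and the model itself — describe an idealized, homogeneous cell
population with intrinsic noise only: no extrinsic (cell-to-cell
parameter) heterogeneity, no cell-cycle structure, no tumor growth or
selection, and no inhibitor toxicity. Passing tests therefore demonstrate
the correctness and reproducibility of the simulation and screening
machinery, not clinical validity of any schedule.

## Problem sizes used by the shipped analyses

The packaged tests and the acceptance script use 6-day (and 7-cycle
verification) horizons, 100-cell stochastic ensembles, a six-point
inhibitor-dose grid and 0.1 Gy/day bisection tolerance for the full
catalog screens, and 1000-cell ensembles nowhere; these sizes are the
package's fast configuration, chosen so a complete run finishes on one
CPU in minutes while keeping binomial confidence intervals honest (they
are always reported). The reference configuration of every function
(1000 cells, 0.5-IC$_{50}$ dose grid, 15-point IR scans, 0.01-Gy/day
tolerance) is the documented default.
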