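# p53combo

Simulation and in-silico optimization of combination protocols that pair
fractionated radiotherapy with an Mdm2 inhibitor (a nutlin-class drug),
built on a stochastic/deterministic model of the p53 regulatory network.

## The problem

Many cancers keep wild-type p53 but disable its signalling elsewhere in
the pathway: overexpression of the phosphatase **Wip1** or reduced
expression of the phosphatase **PTEN** both render cells resistant to
radiation-induced apoptosis, so radiotherapy alone cannot eliminate them.
An Mdm2 inhibitor frees p53 from degradation and can restore the apoptotic
response — but only when timed against the irradiation cycle, because the
damage-driven p53 system pulses with a period of about 7 h.

`p53combo` is for computational biologists who want to simulate single
cells of three phenotypes — normal, Wip1-cancer (5× Wip1 transcription)
and PTEN-cancer (5× reduced PTEN transcription) — under arbitrary
irradiation + dosing schedules and rank schedules by how selectively they
kill cancer cells.

## The model in brief

A single declarative reaction network (32 species, 66 reactions; shipped
as `inst/extdata/p53_network.tsv`) drives both engines:

* ODE approximation (`simulate_ode`, via deSolve) with impulsive
  irradiation/dosing events;
* exact Gillespie simulation (`ssa_run`, C++) with a species-scaling
  acceleration for abundant proteins and discrete promoter states and
  Poisson lesion counts as the intrinsic-noise sources.

Irradiation of dose `D` Gy creates `35·D` DNA double-strand breaks, which
activate ATM; ATM phosphorylates p53 into an *arrester* form (driving
Mdm2, Wip1, p21) and a *killer* form (driving PTEN). Wip1 closes the
negative feedback that makes p53 pulse; PTEN closes the slow positive
feedback (PTEN ⊣ PIP3 → AKT → nuclear Mdm2 ⊣ p53) that commits the cell:
when persistent killer signalling accumulates enough PTEN, AKT switches
off, nuclear Mdm2 collapses, the killer level escalates and caspase
crosses the commitment threshold. One-compartment pharmacokinetics
(liberation 1/h, elimination 0.25/h) converts oral or drip dosing into a
blood level `INH_B` in IC50 units; the inhibitor-bound fraction of Mdm2
is `F = INH_B / (1 + INH_B)`.

Key quantities:

* `IR_crit` — minimal irradiation dose per day (found by bisection) at
  which the deterministic cell commits to apoptosis under a protocol;
* the two-step screen (`screen_protocols`): maximize
  `IR_crit(normal)/IR_crit(cancer)` over the inhibitor dose, then verify
  stochastically that ≥95% of cancer cells and ≤10% of normal cells
  (receiving one third of the irradiation and a specificity-reduced
  inhibitor uptake) commit — a *plausible* protocol — and minimize the
  inhibitor dose (`minimize_inhibitor_dose`).

The network is a calibrated reconstruction of the published model family;
see the methods vignette (`vignettes/p53combo-methods.Rmd`) for what is
pinned from the literature, what was calibrated, and the known
quantitative departures.

## Worked example

```r
library(p53combo)

net  <- apply_phenotype(build_network(), cell_phenotype("normal"))
rest <- resting_state(net)

## the 24-h cycle combination protocol: 10 IC50 at 6 h and 18 h after
## each irradiation, 6 days
prot <- with_inh_dose(protocol_catalog("24h_6_18"), 10)

find_ir_crit(net, prot, state = rest, tol = 0.02)
#> IR_crit(normal, 24h_6_18) = 0.2778 Gy/day  [0.2604, 0.2778]

## stochastic ensemble just above the published reference dose
f <- apoptotic_fraction(net, with_ir_dose(prot, 0.72),
                        n_cells = 100, seed = 1, state0 = rest)
f
#> apoptotic fraction (normal, 24h_6_18): 100/100 = 1.000  [0.964, 1.000] (95% CI, 144 h)
```

The bisection output says the deterministic normal cell commits to
apoptosis for any dose above ≈0.27 Gy/day under this schedule (bracket
width = requested tolerance); the ensemble line reports the committed
cell count, the exact binomial 95% confidence interval, and the horizon.
Under the same schedule the first apoptotic dose of a PTEN-cancer cell is
only slightly higher (with a warning about a non-monotone response
window around 1.3 Gy/day), while a Wip1-cancer cell is not sensitized at
this inhibitor dose at all — it only becomes killable in a narrow
low-dose window that the screen discovers — the phenotype ordering and
dose dependence that motivate the two-step screen.

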