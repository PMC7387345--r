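## Shared fixtures: reduced networks for engine checks and cached
## phenotype-specific networks / resting states for the p53 model (computed
## once per test run).

## linear birth-death network: 0 -> A (kb), A -> 0 (kd*A); stationary law
## is Poisson(kb/kd). `scalable` toggles the species-scaling path.
birth_death_network <- function(kb = 60, kd = 0.02, scalable = FALSE) {
  def <- list(
    species = data.frame(name = "A", role = "protein", init = 0,
                         scalable = scalable, stringsAsFactors = FALSE),
    reactions = rbind(
      data.frame(id = "birth", k = "kb", fac = 1, rate = "", hill = "",
                 reactants = "", products = "A:1", pk = FALSE),
      data.frame(id = "death", k = "kd", fac = 1, rate = "A:1", hill = "",
                 reactants = "A:1", products = "", pk = FALSE)))
  build_network(c(kb = kb, kd = kd), def)
}

## dimerization fixture: A + A -> B, mass action
dimer_network <- function(k = 1e-3) {
  def <- list(
    species = data.frame(name = c("A", "B"), role = "protein",
                         init = c(10, 0), scalable = FALSE,
                         stringsAsFactors = FALSE),
    reactions = data.frame(id = "dimer", k = "k", fac = 1, rate = "A:2",
                           hill = "", reactants = "A:2", products = "B:1",
                           pk = FALSE))
  build_network(c(k = k), def)
}

zero_protocol <- function(days = 6) make_protocol(24, days, 0, mode = "none")

## two-state gene driving an abundant readout protein named Casp, so the
## engine's commitment latch applies: commitment times are dominated by the
## discrete gene-switching noise, the regime the scaling acceleration must
## preserve.
gene_switch_network <- function(k_sw = 1 / 1800, k_b = 4, k_d = 1e-3,
                                thresh = 2000) {
  def <- list(
    species = data.frame(name = c("G_off", "G_on", "Casp"),
                         role = c("DNA-state", "DNA-state", "protein"),
                         init = c(1, 0, 0),
                         scalable = c(FALSE, FALSE, TRUE),
                         stringsAsFactors = FALSE),
    reactions = rbind(
      data.frame(id = "g_on", k = "k_sw", fac = 1, rate = "G_off:1",
                 hill = "", reactants = "G_off:1", products = "G_on:1",
                 pk = FALSE),
      data.frame(id = "g_off", k = "k_sw", fac = 1, rate = "G_on:1",
                 hill = "", reactants = "G_on:1", products = "G_off:1",
                 pk = FALSE),
      data.frame(id = "birth", k = "k_b", fac = 1, rate = "G_on:1",
                 hill = "", reactants = "", products = "Casp:1", pk = FALSE),
      data.frame(id = "death", k = "k_d", fac = 1, rate = "Casp:1",
                 hill = "", reactants = "Casp:1", products = "", pk = FALSE)))
  build_network(c(k_sw = k_sw, k_b = k_b, k_d = k_d, casp_thresh = thresh),
                def)
}

## caches (one evaluation per test session)
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, expr, .fixture_cache)
  get(key, .fixture_cache)
}

phenotype_network <- function(label = "normal", specificity = 1) {
  cached(paste0("net_", label, "_", specificity),
         apply_phenotype(build_network(),
                         cell_phenotype(label,
                                        uptake_specificity = specificity)))
}

phenotype_rest <- function(label = "normal", specificity = 1) {
  cached(paste0("rest_", label, "_", specificity),
         resting_state(phenotype_network(label, specificity)))
}

fig3_protocol <- function(n_cycles = 6) {
  with_inh_dose(protocol_catalog("24h_6_18", n_cycles = n_cycles), 10)
}
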