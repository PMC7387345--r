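test_that("nominal network carries the published transcription rates", {
  net <- build_network()
  expect_equal(unname(net$params[["s_1"]]), 0.1)
  expect_equal(unname(net$params[["s_2"]]), 0.03)
  expect_equal(unname(net$params[["d_r1"]]), 1 / 3600)
  expect_equal(unname(net$params[["d_r2"]]), 0.25 / 3600)
})

test_that("network validation fails loudly", {
  pars <- default_parameters()
  p2 <- pars[setdiff(names(pars), "s_1")]
  expect_error(build_network(p2), "s_1")

  def <- network_definition()
  def$reactions$rate[def$reactions$id == "wip1_tx"] <- "NoSuchSpecies:1"
  expect_error(build_network(pars, def), "NoSuchSpecies")

  pars_bad <- pars
  pars_bad[["k_atm"]] <- -1
  expect_error(build_network(pars_bad), "negative")
})

test_that("TSV definition round-trips and matches the checked-in file", {
  net <- build_network()
  tmp <- tempfile(fileext = ".tsv")
  write_network_tsv(net, tmp)
  back <- read_network_tsv(tmp)
  expect_equal(back$species, net$species)
  expect_equal(back$reactions, net$reactions)
  expect_equal(back$params, net$params)
  rebuilt <- build_network(back$params, back)
  expect_equal(rebuilt$stoich, net$stoich)

  shipped <- read_network_tsv(
    system.file("extdata", "p53_network.tsv", package = "p53combo"))
  expect_equal(shipped$species, net$species)
  expect_equal(shipped$reactions, net$reactions)
  expect_equal(shipped$params, net$params)
})

test_that("phenotype specialization is multiplicative and invertible", {
  net <- build_network()
  w <- apply_phenotype(net, cell_phenotype("wip1_cancer"))
  expect_equal(unname(w$params[["s_1"]]), 0.5)   # fivefold above nominal
  expect_equal(unname(w$params[["s_2"]]), 0.03)

  p <- apply_phenotype(net, cell_phenotype("pten_cancer"))
  expect_equal(unname(p$params[["s_2"]]), 0.006) # fivefold below nominal
  expect_equal(unname(p$params[["s_1"]]), 0.1)

  n <- apply_phenotype(net, cell_phenotype("normal"))
  expect_equal(n$params, net$params)             # identity

  n10 <- apply_phenotype(net, cell_phenotype("normal",
                                             uptake_specificity = 10))
  expect_equal(unname(n10$params[["ka_inh"]]),
               unname(net$params[["ka_inh"]]) / 10)
  expect_equal(unname(p$params[["ka_inh"]]),
               unname(net$params[["ka_inh"]]))   # cancer keeps nominal ka

  back <- apply_phenotype(w, cell_phenotype("custom", 1 / 5, 1))
  expect_equal(back$params[["s_1"]], net$params[["s_1"]])

  expect_error(cell_phenotype("custom", -1, 1), "positive")
  expect_error(cell_phenotype("normal", 2, 1), "unit multipliers")
})

test_that("deterministic fluxes match hand-coded rate laws", {
  net <- build_network()
  st <- initial_state(net)
  st[c("p53", "p53A", "p53K", "ATMa", "Wip1", "Mdm2n", "DNAdam", "INHb")] <-
    c(8000, 3000, 1200, 5000, 9000, 4000, 40, 2.5)
  fl <- deterministic_rates(net, st)
  names(fl) <- net$reactions$id
  p <- net$params

  ## mass action with modifier: Mdm2-mediated killer degradation
  expect_equal(fl[["p53k_mdm2"]], p[["g_mdm_k"]] * 1200 * 4000,
               ignore_attr = TRUE)
  ## saturating repair
  expect_equal(fl[["repair"]], p[["v_rep"]] * 40 / (p[["K_rep"]] + 40),
               ignore_attr = TRUE)
  ## MM phosphorylation driven by active ATM
  expect_equal(fl[["p53_phos"]],
               p[["k_ph1"]] * 5000 * 8000 / (p[["Km_p53"]] + 8000),
               ignore_attr = TRUE)
  ## inhibitor association with the blood level
  expect_equal(fl[["inh_bind"]], p[["ka_inh"]] * 4000 * 2.5,
               ignore_attr = TRUE)

  ## mass-action linearity: doubling a reactant doubles that flux
  st2 <- st
  st2[["p53K"]] <- 2 * st[["p53K"]]
  fl2 <- deterministic_rates(net, st2)
  names(fl2) <- net$reactions$id
  expect_equal(fl2[["p53k_mdm2"]], 2 * fl[["p53k_mdm2"]],
               ignore_attr = TRUE)

  ## all-zero state: only zero-order syntheses fire
  z <- deterministic_rates(net, stats::setNames(rep(0, nrow(net$species)),
                                                net$species$name))
  names(z) <- net$reactions$id
  expect_gt(z[["p53_syn"]], 0)
  expect_gt(z[["proc_syn"]], 0)
  expect_equal(sum(z[setdiff(names(z), c("p53_syn", "proc_syn",
                                         "pk_drip"))]), 0)
  expect_error(deterministic_rates(net, st - 1e5), "negative")
})

test_that("stochastic propensities respect counts and combinatorics", {
  net <- build_network()
  st <- round(initial_state(net))
  pr <- stochastic_propensities(net, st)
  names(pr) <- net$reactions$id
  expect_true(all(pr >= 0))
  expect_equal(pr[["repair"]], 0, ignore_attr = TRUE)      # no lesions
  expect_equal(pr[["inh_bind"]], 0, ignore_attr = TRUE)    # no inhibitor

  expect_error(stochastic_propensities(net, st + 0.5), "non-integer")

  ## dimerization needs two copies
  dn <- dimer_network()
  expect_equal(stochastic_propensities(dn, c(A = 1, B = 0)), 0)
  expect_equal(stochastic_propensities(dn, c(A = 2, B = 0)), 1e-3 * 2 * 1)
  ## large copy number: combinatoric and mass-action forms converge
  for (N in c(10, 100, 1000)) {
    a <- stochastic_propensities(dn, c(A = N, B = 0))
    f <- deterministic_rates(dn, c(A = N, B = 0))
    expect_lt(abs(a - f) / f, 1.5 / N)  # (A*(A-1) vs A^2)
  }
})

test_that("phosphoform conversions conserve total amounts", {
  net <- build_network()
  S <- net$stoich
  conv <- list(
    c("p53_phos", "p53a_deph", "p53a_wip1", "p53a_phos2", "p53k_deph",
      "p53k_wip1"),
    c("atm_act", "atm_deact", "atm_wip1"),
    c("pip_phos", "pip_deph", "pip_deph0"),
    c("akt_phos", "akt_deph"),
    c("inh_bind", "inh_unbind"))
  sets <- list(c("p53", "p53A", "p53K"), c("ATMi", "ATMa"),
               c("PIP2", "PIP3"), c("AKT", "AKTp"), c("Mdm2n", "Mdm2nI"))
  for (i in seq_along(conv))
    expect_true(all(colSums(S[sets[[i]], conv[[i]], drop = FALSE]) == 0),
                info = paste("set", i))
})

test_that("the untreated deterministic system rests at its fixed point", {
  net <- phenotype_network("normal")
  tr <- simulate_ode(net, zero_protocol(2))
  expect_true(is.na(tr$apoptosis_time_h))
  ## the tabulated initial amounts are a rounded snapshot of the fixed
  ## point, so allow a small relaxation transient
  first <- tr$state[1, ]
  last <- tr$state[nrow(tr$state), ]
  expect_lt(max(abs(last - first) / pmax(first, 1)), 0.03)
  ## and the reached state is genuinely stationary
  mid <- tr$state[nrow(tr$state) - 12, ]
  expect_lt(max(abs(last - mid) / pmax(last, 1)), 1e-4)
})
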