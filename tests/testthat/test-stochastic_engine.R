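test_that("runs are a pure function of (network, protocol, seed, cell)", {
  net <- phenotype_network("normal")
  p <- with_ir_dose(fig3_protocol(2), 1)
  a <- ssa_run(net, p, seed = 7, cell = 3, sample_dt_h = 6)
  b <- ssa_run(net, p, seed = 7, cell = 3, sample_dt_h = 6)
  expect_identical(a$final_state, b$final_state)
  expect_identical(a$commit_time_h, b$commit_time_h)
  expect_identical(a$state, b$state)
  c <- ssa_run(net, p, seed = 8, cell = 3)
  expect_false(identical(a$final_state, c$final_state))
})

test_that("birth-death fixture reaches its Poisson stationary law", {
  ## kb/kd = 100; mean and variance of the stationary law are both 100
  net <- birth_death_network(kb = 2, kd = 0.02)
  p <- zero_protocol(3)
  vals <- unlist(lapply(1:40, function(i) {
    r <- ssa_run(net, p, horizon_h = 72, seed = 11, cell = i, omega = 1,
                 sample_dt_h = 4)
    r$state[r$time_h > 12, "A"]       # discard burn-in
  }))
  expect_equal(mean(vals), 100, tolerance = 0.05)
  expect_equal(var(vals), 100, tolerance = 0.35)
})

test_that("species scaling preserves commitment-time distributions", {
  ## scaled (omega = 10) vs exact (omega = 1) runs of the gene-switch
  ## fixture: the distribution of threshold-crossing (commitment) times is
  ## set by the discrete gene, which the scaling leaves exact, so a
  ## two-sample KS test must not reject
  net <- gene_switch_network()
  p <- zero_protocol(2)
  commit_times <- function(omega, cells)
    vapply(cells, function(i) {
      r <- ssa_run(net, p, horizon_h = 48, seed = 13, cell = i,
                   omega = omega)
      ifelse(r$committed, r$commit_time_h, 48)
    }, numeric(1))
  x <- commit_times(1, 1:100)
  y <- commit_times(10, 101:200)
  expect_true(all(x < 48) && all(y < 48))
  ks <- suppressWarnings(stats::ks.test(x, y))
  expect_gt(ks$p.value, 0.01)
})

test_that("untreated ensembles stay alive and fractions are reproducible", {
  net <- phenotype_network("normal")
  f <- apoptotic_fraction(net, zero_protocol(6), n_cells = 8, seed = 2,
                          state0 = phenotype_rest("normal"))
  expect_equal(f$n_apoptotic, 0)
  expect_equal(f$ci[1], 0)

  p <- with_ir_dose(fig3_protocol(6), 0.9)
  f1 <- apoptotic_fraction(net, p, n_cells = 6, seed = 4)
  f2 <- apoptotic_fraction(net, p, n_cells = 6, seed = 4)
  expect_identical(f1$fraction, f2$fraction)
  expect_identical(f1$commit_times_h, f2$commit_times_h)

  ## single cell gives a 0/1 fraction
  f3 <- apoptotic_fraction(net, p, n_cells = 1, seed = 4)
  expect_true(f3$fraction %in% c(0, 1))
})

test_that("the apoptotic fraction is monotone in the horizon", {
  net <- phenotype_network("normal")
  p <- with_ir_dose(fig3_protocol(6), 0.72)
  f6 <- apoptotic_fraction(net, p, n_cells = 10, seed = 9,
                           state0 = phenotype_rest("normal"))
  ## same seeds, shorter horizon: commitment can only be lost, not gained
  f3 <- apoptotic_fraction(net, p, horizon_h = 72, n_cells = 10, seed = 9,
                           state0 = phenotype_rest("normal"))
  expect_lte(f3$fraction, f6$fraction)
  expect_equal(sum(f6$per_day), f6$n_apoptotic)
})

test_that("stochastic and deterministic engines agree on clear-cut cases", {
  ## well above the deterministic critical dose the stochastic fraction
  ## approaches one; cancer cells resistant in the ODE stay resistant
  net <- phenotype_network("normal")
  p <- with_ir_dose(fig3_protocol(6), 1.5)
  f <- apoptotic_fraction(net, p, n_cells = 10, seed = 1,
                          state0 = phenotype_rest("normal"))
  expect_equal(f$fraction, 1)

  netw <- phenotype_network("wip1_cancer")
  pm <- make_protocol(24, 3, 10, mode = "none")
  fw <- apoptotic_fraction(netw, pm, n_cells = 6, seed = 1,
                           state0 = phenotype_rest("wip1_cancer"))
  expect_lte(fw$fraction, 0.2)
})
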