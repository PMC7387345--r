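test_that("zero-dose trajectories stay at rest and untreated cells survive", {
  net <- phenotype_network("normal")
  tr <- simulate_ode(net, zero_protocol(2), state = phenotype_rest("normal"))
  expect_true(is.na(apoptosis_time(tr)))
  expect_false(any(tr$committed))
  rng <- apply(tr$state, 2, function(x) diff(range(x)))
  expect_lt(max(rng / pmax(tr$state[1, ], 1)), 1e-3)
})

test_that("integration is insensitive to a tenfold tolerance refinement", {
  net <- phenotype_network("normal")
  p <- make_protocol(24, 1, 2, mode = "none")
  a <- simulate_ode(net, p, state = phenotype_rest("normal"), rtol = 1e-6)
  b <- simulate_ode(net, p, state = phenotype_rest("normal"), rtol = 1e-7,
                    atol = 1e-3)
  expect_lt(max(abs(a$state - b$state) / pmax(b$state, 1)), 1e-3)
})

test_that("irradiation events inject lesions impulsively", {
  net <- phenotype_network("normal")
  p <- make_protocol(24, 2, 2, mode = "none")
  tr <- simulate_ode(net, p, state = phenotype_rest("normal"),
                     sample_dt_h = 0.5)
  i0 <- which(tr$time_h == 0)
  ## 2 Gy/day * 35 lesions/Gy; the sample at an event time is post-impulse
  expect_equal(max(tr$state[tail(i0, 1), "DNAdam"]), 70, tolerance = 1e-6)
  i24 <- which(tr$time_h == 24)
  expect_gt(max(tr$state[i24, "DNAdam"]), 60)
})

test_that("the committed flag latches and the commitment time interpolates", {
  net <- phenotype_network("normal")
  p <- make_protocol(24, 3, 5, mode = "none")
  tr <- simulate_ode(net, p, state = phenotype_rest("normal"))
  t_ap <- apoptosis_time(tr)
  expect_true(is.finite(t_ap))
  expect_lte(t_ap, 72)
  ## absorbing: once committed, always committed
  expect_true(all(diff(tr$committed) >= 0))
  expect_true(all(tr$committed[tr$time_h > t_ap + 0.5]))
})

test_that("critical-dose bisection brackets and orders correctly", {
  net <- phenotype_network("normal")
  rest <- phenotype_rest("normal")
  p <- make_protocol(24, 3, mode = "none")
  ic <- find_ir_crit(net, p, state = rest, tol = 0.05, n_scan = 6)
  expect_true(is.finite(ic$ir_crit))
  expect_lt(ic$lo, ic$ir_crit)
  expect_lte(ic$ir_crit, ic$hi)
  expect_lte(ic$hi - ic$lo, 0.05)

  ## monotone response above the critical dose: higher dose commits no later
  t1 <- apoptosis_time(simulate_ode(net, with_ir_dose(p, ic$ir_crit + 0.1),
                                    state = rest))
  t2 <- apoptosis_time(simulate_ode(net, with_ir_dose(p, ic$ir_crit + 1.5),
                                    state = rest))
  expect_true(is.finite(t1) && is.finite(t2))
  expect_lte(t2, t1 + 1e-6)

  ## resistant phenotype reports an unbounded critical dose
  icw <- find_ir_crit(phenotype_network("wip1_cancer"), p,
                      state = phenotype_rest("wip1_cancer"), n_scan = 0)
  expect_identical(icw$ir_crit, Inf)
})

test_that("oscillation periods are measured from inter-peak intervals", {
  ## synthetic trajectory with a known period
  tt <- seq(0, 100, by = 0.25)
  mk <- function(x) structure(list(time_h = tt,
                                   state = cbind(p53K = x),
                                   committed = rep(FALSE, length(tt)),
                                   apoptosis_time_h = NA),
                              class = "trajectory")
  osc <- mk(1000 + 900 * sin(2 * pi * tt / 7))
  expect_equal(oscillation_period(osc, "p53K"), 7, tolerance = 0.05)
  flat <- mk(rep(1000, length(tt)))
  expect_true(is.na(oscillation_period(flat, "p53K")))
  two_peaks <- mk(1000 + 900 * sin(2 * pi * pmin(tt, 15) / 10))
  expect_true(is.na(oscillation_period(two_peaks, "p53K")))
})
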