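test_that("a single oral dose follows the Bateman curve", {
  pk <- pk_parameters()            # d_r1 = 1/h, d_r2 = 0.25/h
  ev <- data.frame(time_h = 0, dose = 10)
  tt <- seq(0, 24, by = 0.25)
  bateman <- 10 * 1 / (1 - 0.25) * (exp(-0.25 * tt) - exp(-1 * tt))
  expect_equal(blood_level(ev, pk, tt), bateman, tolerance = 1e-12)

  ## the blood level never reaches the administered dose (elimination)
  expect_lt(max(bateman), 10)

  expect_equal(blood_level(NULL, pk, tt), rep(0, length(tt)))
  expect_error(blood_level(data.frame(time_h = 0, dose = -1), pk, 1),
               "negative")
})

test_that("oral blood level is linear and superposable in the doses", {
  pk <- pk_parameters()
  tt <- seq(0, 48, by = 0.5)
  e1 <- data.frame(time_h = 0, dose = 10)
  e2 <- data.frame(time_h = 18, dose = 15)
  both <- rbind(e1, e2)
  expect_equal(blood_level(both, pk, tt),
               blood_level(e1, pk, tt) + blood_level(e2, pk, tt))
  expect_equal(blood_level(transform(both, dose = 2 * dose), pk, tt),
               2 * blood_level(both, pk, tt))
})

test_that("oral peak is about 2 h and matches the numeric argmax", {
  pk <- pk_parameters()
  tp <- peak_time(pk)
  expect_equal(tp, log(4) / 0.75)
  expect_equal(tp, 1.848, tolerance = 1e-3)

  tt <- seq(0, 12, by = 0.001)
  lv <- blood_level(data.frame(time_h = 0, dose = 1), pk, tt)
  expect_lt(abs(tt[which.max(lv)] - tp), 0.002)

  expect_equal(peak_time(pk_parameters(2, 1)), log(2))
  expect_error(peak_time(pk_parameters(mode = "drip")), "drip")
  expect_error(pk_parameters(0.2, 0.25, "oral"), "d_r1 > d_r2")
})

test_that("drip relaxes to equilibrium with time constant 1/d_r2 = 4 h", {
  pk <- pk_parameters(mode = "drip")
  expect_equal(drip_relaxation_time(pk), 4)
  eq <- 20 / 24 / 0.25            # daily dose / 24 / d_r2
  ev <- data.frame(time_h = 0, dose = 20)
  t95 <- drip_relaxation_time(pk, 0.05)
  expect_equal(blood_level(ev, pk, t95), 0.95 * eq, tolerance = 1e-9)
  expect_equal(blood_level(ev, pk, 200), eq, tolerance = 1e-6)

  ## equal daily dose: oral peaks exceed the drip equilibrium
  oral <- pk_parameters()
  peak <- blood_level(data.frame(time_h = 0, dose = 10), oral,
                      peak_time(oral))
  expect_gt(peak, eq)
})

test_that("bound fraction is the IC50-normalized binding isotherm", {
  expect_equal(bound_fraction(0), 0)
  expect_equal(bound_fraction(1), 0.5)    # 1 IC50 binds half of Mdm2
  expect_equal(bound_fraction(9), 0.9)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(bound_fraction(x)) > 0))
  expect_true(all(bound_fraction(x) < 1))
  expect_error(bound_fraction(-0.1), "non-negative")
})

test_that("the ODE engine reproduces the closed-form pharmacokinetics", {
  ## zero irradiation, so the network stays at rest and only the PK states
  ## move; the jointly integrated depot/blood pair must match the Bateman
  ## superposition
  net <- phenotype_network("normal")
  prot <- with_ir_dose(fig3_protocol(n_cycles = 2), 0)
  tr <- simulate_ode(net, prot, sample_dt_h = 0.5)
  pk <- pk_parameters()
  ev <- event_schedule(prot)
  ev <- data.frame(time_h = ev$time_h[ev$kind == "dose_inhibitor"],
                   dose = ev$magnitude[ev$kind == "dose_inhibitor"])
  expect_equal(tr$state[, "INHb"], blood_level(ev, pk, tr$time_h),
               tolerance = 1e-3, ignore_attr = TRUE)
})
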