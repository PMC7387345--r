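synthetic_curve <- function(dose, ratio) {
  structure(data.frame(dose = dose, ir_crit_cancer = 1, ir_crit_normal = ratio,
                       ratio = ratio),
            class = c("ratio_curve", "data.frame"))
}

test_that("the optimal inhibitor dose is the (tie-broken) ratio argmax", {
  d <- seq(0, 10, by = 0.5)
  uni <- synthetic_curve(d, exp(-(d - 4)^2 / 4))
  expect_equal(optimal_inhibitor_dose(uni), 4)

  plateau <- synthetic_curve(0:5, c(0, 1, 2, 2, 2, 1))
  expect_equal(optimal_inhibitor_dose(plateau), 2)   # lowest on the plateau

  multi <- synthetic_curve(0:6, c(0, 2, 0.5, 0.2, 1.5, 0.4, 0))
  expect_warning(dm <- optimal_inhibitor_dose(multi), "multimodal")
  expect_equal(dm, 1)

  expect_error(optimal_inhibitor_dose(synthetic_curve(0:3, rep(0, 4))),
               "zero")

  ## argmax equals an exhaustive scan on random unimodal-ish curves
  set.seed(42)
  for (i in 1:20) {
    r <- abs(stats::rnorm(15))
    cv <- synthetic_curve(seq_len(15), r)
    expect_equal(suppressWarnings(optimal_inhibitor_dose(cv)),
                 cv$dose[which.max(r)],
                 info = paste("rep", i))
  }
})

test_that("ratio curves are zero at zero dose for resistant phenotypes", {
  prot <- protocol_catalog("24h_6_18", n_cycles = 6)
  rc <- ratio_curve(prot, "pten_cancer", specificity = 10, dose_grid = 0,
                    tol = 0.1, n_scan = 0)
  expect_equal(rc$ratio[rc$dose == 0], 0)
  expect_identical(rc$ir_crit_cancer[1], Inf)
  expect_true(is.finite(rc$ir_crit_normal[1]))  # normal cells are not
})

test_that("verification logs the reduced normal-cell exposures", {
  prot <- protocol_catalog("24h_6_18", n_cycles = 6)
  v <- verify_protocol(prot, "pten_cancer", inh_dose = 10,
                       specificity = 10, n_cells = 4, seed = 3, n_ir = 2,
                       tol = 0.1, scan_all = TRUE)
  expect_equal(v$scan$ir_normal, v$scan$ir_cancer / 3)
  expect_equal(unique(v$scan$inh_dose_normal_effective), 1)   # 10 / 10
  expect_true(all(v$scan$ir_cancer >= 0.8 * v$ir_crit_cancer - 1e-9))
  expect_true(all(v$scan$ir_cancer <= 1.5 * v$ir_crit_cancer + 1e-9))
  ok_rows <- !is.na(v$scan$frac_cancer)   # cancer runs may be skipped
  expect_true(all(v$scan$cancer_lo[ok_rows] <= v$scan$frac_cancer[ok_rows] &
                  v$scan$frac_cancer[ok_rows] <= v$scan$cancer_hi[ok_rows]))
})

test_that("dose minimization requires a plausible starting point", {
  prot <- protocol_catalog("24h_6_18", n_cycles = 6)
  ## impossible threshold makes any protocol implausible
  expect_error(
    minimize_inhibitor_dose(prot, "pten_cancer", start_dose = 10,
                            specificity = 10, n_cells = 2, seed = 1,
                            n_ir = 1, tol = 0.1, cancer_min = 1.01),
    "not plausible")
})
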