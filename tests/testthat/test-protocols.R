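test_that("protocol validation enforces the cycle/administration rules", {
  expect_error(make_protocol(20, 6, 1), "cycle_h")
  expect_error(make_protocol(24, 0, 1), "positive integer")
  expect_error(make_protocol(24, 6, -1), "non-negative")
  expect_error(make_protocol(24, 6, 1, offsets_h = c(0, 6, 12),
                             inh_dose = 10), "at most 2")
  expect_error(make_protocol(12, 12, 1, offsets_h = c(0, 6),
                             inh_dose = 10), "at most 1")
  expect_error(make_protocol(24, 6, 1, offsets_h = 24, inh_dose = 10),
               "\\[0, cycle_h\\)")
  ## the two published example protocols construct cleanly
  p1 <- make_protocol(24, 6, 1, offsets_h = c(6, 18), inh_dose = 10)
  expect_equal(p1$offsets_h, c(6, 18))
  p2 <- make_protocol(36, 4, 1, offsets_h = c(6, 30), inh_dose = 15)
  expect_equal(protocol_duration(p2), 144)
})

test_that("event schedules enumerate irradiations and dosings", {
  p <- make_protocol(24, 6, 2, offsets_h = c(6, 18), inh_dose = 10)
  ev <- event_schedule(p)
  ir <- ev[ev$kind == "irradiate", ]
  expect_equal(ir$time_h, seq(0, 120, by = 24))
  expect_equal(unique(ir$magnitude), 2)       # 2 Gy/day at 24-h cycles
  inh <- ev[ev$kind == "dose_inhibitor", ]
  expect_equal(nrow(inh), 12)
  expect_false(is.unsorted(ev$time_h))

  ## direct enumeration oracle: 7 cycles of 36 h, offsets (0, 24)
  p36 <- make_protocol(36, 7, 2.4, offsets_h = c(0, 24), inh_dose = 15)
  ev36 <- event_schedule(p36)
  starts <- 36 * (0:6)
  expect_equal(ev36$time_h[ev36$kind == "dose_inhibitor"],
               sort(c(starts, starts + 24)))
  ## per-event dose scales with cycle length at fixed Gy/day
  expect_equal(unique(ev36$magnitude[ev36$kind == "irradiate"]),
               2.4 * 36 / 24)

  ## monotherapy has no inhibitor events; drip has one infusion-on event
  evm <- event_schedule(make_protocol(24, 6, 1, mode = "none"))
  expect_true(all(evm$kind == "irradiate"))
  evd <- event_schedule(make_protocol(24, 6, 1, inh_dose = 20,
                                      mode = "drip"))
  expect_equal(sum(evd$kind == "infusion_on"), 1)

  ## identical protocols give identical schedules
  expect_identical(ev, event_schedule(make_protocol(24, 6, 2,
                                                    offsets_h = c(6, 18),
                                                    inh_dose = 10)))
  expect_error(event_schedule(make_protocol(24, 6, mode = "none")),
               "no irradiation dose")
})

test_that("the catalog holds 10 oral protocols plus drip at 20 IC50/day", {
  cat6 <- protocol_catalog()
  expect_length(cat6, 11)
  expect_equal(sum(vapply(cat6, function(p) p$mode == "oral", logical(1))),
               10)
  expect_equal(cat6$drip$mode, "drip")

  ## the three published timings are fixed
  expect_equal(protocol_catalog("24h_6_18")$offsets_h, c(6, 18))
  expect_equal(protocol_catalog("36h_6_30")$offsets_h, c(6, 30))
  expect_equal(protocol_catalog("36h_0_24")$offsets_h, c(0, 24))
  expect_error(protocol_catalog("24h_6_18", offsets = list(`24h_6_18` = 3)),
               "fixed")
  expect_error(protocol_catalog("nope"), "unknown")

  ## every oral entry delivers 20 IC50 per day, whatever the cycle length
  for (p in cat6) {
    if (p$mode != "oral") next
    daily <- p$inh_dose * length(p$offsets_h) * 24 / p$cycle_h
    expect_equal(daily, 20, info = p$name)
    ## and 6 days' worth of cycles
    expect_equal(protocol_duration(p), 144, info = p$name)
  }

  ## reconstructed (unpublished) timings are flagged and overridable
  expect_true(attr(protocol_catalog("12h_6"), "reconstructed"))
  expect_false(attr(protocol_catalog("24h_6_18"), "reconstructed"))
  p <- protocol_catalog("12h_6", offsets = list(`12h_6` = 3))
  expect_equal(p$offsets_h, 3)
})
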