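one_comp <- list(list(weight = 1,
                      channels = list(GFP = c(3, 0.3), mCherry = c(6, 0.3))))

two_comp <- list(
  list(weight = 0.3, channels = list(GFP = c(2, 0.3), mCherry = c(6, 0.3))),
  list(weight = 0.7, channels = list(GFP = c(6, 0.3), mCherry = c(6, 0.3))))

test_that("event simulation respects weights, counts and seeds", {
  ev <- simulate_flow_events(one_comp, 100, seed = 1)
  expect_identical(nrow(ev), 100L)
  expect_true(all(attr(ev, "component") == 1L))
  expect_true(all(unlist(ev) > 0)) # log-normal intensities are positive

  ev2 <- simulate_flow_events(two_comp, 1e5, seed = 2)
  frac1 <- mean(attr(ev2, "component") == 1L)
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(frac1 - 0.3), 3 * se)
  expect_identical(ev2, simulate_flow_events(two_comp, 1e5, seed = 2))

  expect_error(simulate_flow_events(list(), 10, seed = 1),
               class = "liposcreen_input_error")
  expect_error(simulate_flow_events(one_comp, 0, seed = 1),
               class = "liposcreen_input_error")
  bad <- two_comp
  bad[[1]]$weight <- 0.5
  expect_error(simulate_flow_events(bad, 10, seed = 1), "sum to 1",
               class = "liposcreen_input_error")
})

test_that("gate fractions: bounds, conjunctions and transform invariance", {
  ev <- simulate_flow_events(two_comp, 2e4, seed = 3)
  expect_identical(gate_fraction(ev, gate_spec(gate_above("GFP", 0))), 1)
  expect_error(gate_fraction(ev[0, ], gate_spec(gate_above("GFP", 0))),
               class = "liposcreen_input_error")
  expect_error(gate_fraction(ev, gate_spec(gate_above("Keima", 1))),
               "Keima", class = "liposcreen_input_error")
  # invariance under a monotone transform applied to channel and threshold
  thr <- 50
  f_raw <- gate_fraction(ev, gate_spec(gate_below("GFP", thr)))
  f_log <- gate_fraction(ev, gate_spec(gate_below("GFP", log10(thr + 1),
                                                  transform = "log10")))
  expect_identical(f_raw, f_log)
  # partition of gate space sums to 1
  f_above <- gate_fraction(ev, gate_spec(gate_above("GFP", thr)))
  expect_equal(f_raw + f_above, 1)
})

test_that("lipophagy-positive fraction recovers the quenched component", {
  ev <- simulate_flow_events(two_comp, 1e5, seed = 4)
  # component 1 is GFP-quenched / mCherry-retained; cut between the modes
  frac <- lipophagy_positive_fraction(ev, gfp_cut = exp(4),
                                      mcherry_cut = exp(4))
  truth <- mean(attr(ev, "component") == 1L)
  expect_lt(abs(frac - truth), 0.01)
  # all GFP-high events -> 0
  hi <- simulate_flow_events(list(list(weight = 1,
    channels = list(GFP = c(8, 0.2), mCherry = c(6, 0.2)))), 1e4, seed = 5)
  expect_identical(lipophagy_positive_fraction(hi, exp(4), exp(4)), 0)
  # mCherry-negative debris never counted regardless of GFP
  debris <- simulate_flow_events(list(list(weight = 1,
    channels = list(GFP = c(0, 0.2), mCherry = c(0, 0.2)))), 1e4, seed = 6)
  expect_identical(lipophagy_positive_fraction(debris, exp(4), exp(4)), 0)
})

test_that("surface positivity is thresholded on the negative control", {
  ctrl_mix <- list(list(weight = 1, channels = list(LAMP1 = c(2, 0.5))))
  ctrl <- simulate_flow_events(ctrl_mix, 2e4, seed = 7)
  same <- simulate_flow_events(ctrl_mix, 2e4, seed = 8)
  f_null <- surface_positive_fraction(same, ctrl, "LAMP1", percentile = 99)
  expect_lt(abs(f_null - 0.01), 0.005)
  shifted <- simulate_flow_events(list(list(weight = 1,
    channels = list(LAMP1 = c(7, 0.3)))), 1e4, seed = 9)
  expect_gt(surface_positive_fraction(shifted, ctrl, "LAMP1"), 0.99)
  # percentile 100: strictly above the control max; higher percentile
  # never increases the fraction
  f100 <- surface_positive_fraction(same, ctrl, "LAMP1", percentile = 100)
  expect_lte(f100, f_null)
  expect_error(surface_positive_fraction(same[0, ], ctrl, "LAMP1"),
               class = "liposcreen_input_error")
  expect_error(surface_positive_fraction(same, ctrl, "CD63"),
               class = "liposcreen_input_error")
})

test_that("flow events round-trip through CSV", {
  ev <- simulate_flow_events(two_comp, 50, seed = 10)
  path <- withr::local_tempfile(fileext = ".csv")
  write_flow_csv(ev, path)
  back <- read_flow_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ev), tolerance = 1e-12,
               ignore_attr = TRUE)
})
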