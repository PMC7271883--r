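test_that("canopy temperature follows the linear profile", {
  pr <- thermal_profile(t0 = 20, lapse = 0.1)
  expect_equal(temperature_at_height(pr, 0), 20)
  expect_equal(temperature_at_height(pr, 50), 25)
  flat <- thermal_profile(t0 = 20, lapse = 0)
  expect_equal(temperature_at_height(flat, c(0, 60, 120)), rep(20, 3))
  expect_error(temperature_at_height(pr, 130), "range")
})

test_that("respiration chain reproduces the per-attack cost and Q10 scaling", {
  met <- metabolic_model()
  # independent chain: 25.70 ul O2/h x 0.0200832 J/ul / 60 min x 0.5 min
  anchor <- 25.70 * 0.0200832 / 60 * 0.5
  expect_equal(respiration_energy(met, 25, 0.5, "active"), anchor,
               tolerance = 1e-12)
  expect_lt(abs(anchor - 0.0043), 2e-6)                # ~4.3 mJ
  expect_equal(respiration_energy(met, 25, 0, "active"), 0)
  expect_equal(respiration_energy(met, 35, 0.5, "active"), 2 * anchor,
               tolerance = 1e-12)                      # Q10 = 2 doubling
  expect_equal(metabolic_rate(met, 18, "resting"),
               0.5 * metabolic_rate(met, 18, "active"), tolerance = 1e-12)
  expect_error(respiration_energy(met, 25, -1), ">= 0")
})

test_that("expected grasshopper payoff multiplies success, assimilation and energy content", {
  expect_equal(expected_grasshopper_payoff(), 0.25 * 0.8 * 33.81)
  expect_equal(expected_grasshopper_payoff(), 6.762, tolerance = 1e-12)
  expect_equal(expected_grasshopper_payoff(energetics_params(s = 1, assim = 1)),
               33.81)
  expect_equal(expected_grasshopper_payoff(energetics_params(E_g = 0)), 0)
})

test_that("net attack outcomes: grasshopper positive, woodlouse strictly negative", {
  p <- energetics_params(); met <- metabolic_model()
  out <- net_attack_outcomes(p, met, 25)
  # independent plug-in arithmetic
  ra <- 25.70 * 0.0200832 / 60
  g_hand <- 0.25 * (0.8 * 33.81 - ra * 20.5) - 0.75 * ra * 0.5
  expect_equal(out$grasshopper_net, g_hand, tolerance = 1e-12)
  expect_equal(out$grasshopper_net, 6.715, tolerance = 1e-3)
  expect_equal(out$woodlouse_net, -ra * 0.5, tolerance = 1e-12)
  # multiplier scaling (supplementary high-cost regime)
  out1000 <- net_attack_outcomes(energetics_params(m = 1000), met, 25)
  expect_equal(out1000$woodlouse_net, 1000 * out$woodlouse_net,
               tolerance = 1e-12)
  # signs across the field temperature range
  for (temp in seq(10, 40, by = 5)) {
    o <- net_attack_outcomes(p, met, temp)
    expect_gt(o$grasshopper_net, 0)
    expect_lt(o$woodlouse_net, 0)
  }
})

test_that("daily gain decomposes exactly and responds to parameters as expected", {
  doms <- simulation_domains()
  g <- daily_net_gain_profile(doms, heights = seq(0, 120, by = 5))
  expect_equal(g$gain_J_per_day,
               g$component_payoff - g$component_attack_cost - g$component_resting,
               tolerance = 1e-9)
  # no encounters: only resting costs remain, decreasing with height when
  # the canopy warms with height
  g0 <- daily_net_gain_profile(doms, p = energetics_params(E_day = 1e-12),
                               heights = seq(0, 120, by = 10))
  expect_equal(g0$gain_J_per_day, -g0$component_resting, tolerance = 1e-6)
  expect_true(all(diff(g0$gain_J_per_day) < 0))
  # increasing the woodlouse cost multiplier weakly decreases gain everywhere
  hs <- seq(0, 120, by = 10)
  g1 <- daily_net_gain_profile(doms, energetics_params(m = 1), heights = hs)
  g10 <- daily_net_gain_profile(doms, energetics_params(m = 10), heights = hs)
  g100 <- daily_net_gain_profile(doms, energetics_params(m = 100), heights = hs)
  expect_true(all(g10$gain_J_per_day <= g1$gain_J_per_day + 1e-12))
  expect_true(all(g100$gain_J_per_day <= g10$gain_J_per_day + 1e-12))
  # flat thermal profile and no encounters: gain constant in height
  gf <- daily_net_gain_profile(doms, p = energetics_params(E_day = 1e-12),
                               profile = thermal_profile(lapse = 0),
                               heights = hs)
  expect_lt(diff(range(gf$gain_J_per_day)), 1e-6)
  expect_error(daily_net_gain_profile(doms, heights = numeric(0)), "empty")
})
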