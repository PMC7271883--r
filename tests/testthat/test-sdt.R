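test_that("detection probabilities follow the equal-variance pooled-cue model", {
  dp <- detection_probs(2.5, 1.25, 1)
  expect_equal(dp$hit, pnorm(1.25), tolerance = 1e-12)
  expect_equal(dp$false_alarm, pnorm(-1.25), tolerance = 1e-12)
  expect_equal(round(dp$hit, 4), 0.8944)
  expect_equal(round(dp$false_alarm, 4), 0.1056)
  # always attack
  expect_equal(detection_probs(2.5, -Inf, 3), list(hit = 1, false_alarm = 1))
  # four looks double the effective separation of one look
  d4 <- detection_probs(2.5, 0.5, 4)
  expect_equal(d4$hit, pnorm(2 * (2.5 - 0.5)), tolerance = 1e-12)
})

test_that("strategy value: immediate attack vs assessed attack accounting", {
  pars <- sdt_params(payoff_G = 6.762, cost_W = 0.0043)
  # attack on sight at pi = 0.5
  expect_equal(strategy_value(-Inf, 1, 0.5, pars),
               0.5 * 6.762 - 0.5 * 0.0043, tolerance = 1e-12)
  expect_equal(strategy_value(-Inf, 1, 0.5, pars), 3.3789, tolerance = 1e-4)
  # assessed strategies carry the per-look retention factor and look costs
  v1 <- strategy_value(1.25, 1, 0.5, pars)
  dp1 <- detection_probs(2.5, 1.25, 1)
  expect_equal(v1, 0.75 * (0.5 * dp1$hit * 6.762 - 0.5 * dp1$false_alarm * 0.0043),
               tolerance = 1e-12)
  v2 <- strategy_value(1.25, 2, 0.5, pars)
  dp2 <- detection_probs(2.5, 1.25, 2)
  expect_equal(v2, 0.75^2 * (0.5 * dp2$hit * 6.762 - 0.5 * dp2$false_alarm * 0.0043) -
                 pars$look_cost, tolerance = 1e-12)
  # each extra look multiplies retention by (1 - p_loss) = 0.75
  expect_equal((1 - pars$p_loss)^2 / (1 - pars$p_loss)^1, 0.75)
  # no grasshoppers: attacking everything only incurs costs
  expect_lt(strategy_value(-Inf, 1, 0, pars), 0)
  # never attacking is worth nothing
  expect_equal(strategy_value(Inf, 1, 0.3, pars), 0)
})

test_that("optimizer: always-attack at defaults, selective under extreme costs, never without payoff", {
  pars <- sdt_params()
  for (pg in seq(0.05, 0.95, by = 0.15)) {
    s <- optimize_strategy(pg, pars)
    expect_equal(s$label, "always_attack")
    expect_equal(s$looks, 1L)
  }
  s1000 <- optimize_strategy(0.1, sdt_params(m = 1000))
  expect_equal(s1000$label, "selective")
  expect_equal(optimize_strategy(0.5, sdt_params(payoff_G = 0))$label,
               "never_attack")
})

test_that("optimizer output is optimal and responds monotonically to parameters", {
  set.seed(77)
  for (i in 1:10) {
    pars <- sdt_params(d_prime = runif(1, 0.5, 4), p_loss = runif(1, 0, 0.5),
                       payoff_G = runif(1, 2, 10),
                       cost_W = runif(1, 0.001, 0.01),
                       m = sample(c(1, 10, 100, 1000), 1))
    pg <- runif(1, 0.01, 0.99)
    s <- optimize_strategy(pg, pars)
    expect_gte(s$expected_value + 1e-12, strategy_value(-Inf, 1, pg, pars))
    expect_gte(s$expected_value + 1e-12, 0)  # never-attack benchmark
  }
  # optimal value non-increasing in the cost multiplier
  vals_m <- sapply(c(1, 10, 100, 1000, 10000), function(m)
    optimize_strategy(0.2, sdt_params(m = m))$expected_value)
  expect_true(all(diff(vals_m) <= 1e-12))
  # and non-decreasing in discriminability and in pi_G
  vals_d <- sapply(c(0.5, 1.5, 2.5, 3.5), function(d)
    optimize_strategy(0.2, sdt_params(d_prime = d, m = 1000))$expected_value)
  expect_true(all(diff(vals_d) >= -1e-12))
  vals_p <- sapply(seq(0.1, 0.9, by = 0.2), function(pg)
    optimize_strategy(pg, sdt_params(m = 1000))$expected_value)
  expect_true(all(diff(vals_p) >= -1e-12))
})

test_that("with free, riskless looks information never hurts", {
  pars <- sdt_params(p_loss = 0, look_cost = 0, m = 1000)
  vals <- sapply(1:5, function(n) {
    cs <- seq(-4, pars$d_prime + 4, by = 0.05)
    max(sapply(cs, strategy_value, n = n, pi_G = 0.2, params = pars))
  })
  expect_true(all(diff(vals) >= -1e-12))
})

test_that("perch optimum ignores woodlice at baseline cost but shifts up at x1000", {
  doms <- simulation_domains()
  hs <- seq(0, 120, by = 2)
  o0 <- optimize_perch(doms, heights = hs, woodlice_present = FALSE)
  o1 <- optimize_perch(doms, heights = hs, woodlice_present = TRUE)
  expect_equal(o1$z_star, o0$z_star)
  expect_equal(o1$strategy$label, "always_attack")
  # without woodlice every height prescribes attacking on sight
  expect_true(all(o0$table$label == "always_attack"))
  o1000 <- optimize_perch(doms, sdt_params(m = 1000), heights = hs)
  expect_gt(o1000$z_star, o1$z_star)
})
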