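test_that("fit_domain returns sample moments (normal) and method-of-moments (gamma)", {
  d <- fit_domain(c(50, 70), species = "MEFE")
  expect_equal(d$mu, 60)
  expect_equal(d$sigma, sqrt(200))  # n-1 denominator

  # sample with mean 5 and sd 5: shape = (5/5)^2 = 1, rate = 5/25 = 0.2
  g <- fit_domain(c(0, 5, 10), species = "ONAS", family = "gamma")
  expect_equal(g$shape, 1)
  expect_equal(g$rate, 0.2)
  # moment pair consistent with the natural parameters
  expect_equal(g$mu, g$shape / g$rate, tolerance = 1e-9)
  expect_equal(g$sigma, sqrt(g$shape) / g$rate, tolerance = 1e-9)

  expect_error(fit_domain(60, species = "PIMI"), "insufficient")
  expect_error(fit_domain(c(30, 30, 30), "ONAS", "gamma"), "degenerate")
  expect_error(fit_domain(c(30, 30, 30), "PIMI", "normal"), "degenerate")
  expect_error(fit_domain(c(-1, 5), "PIMI"), "finite")
})

test_that("gamma method-of-moments fit recovers parameters from large samples", {
  set.seed(404)
  z <- rgamma(10000, shape = 1, rate = 0.2)
  g <- fit_domain(z, "ONAS", "gamma")
  expect_lt(abs(g$shape - 1) / 1, 0.05)
  expect_lt(abs(g$rate - 0.2) / 0.2, 0.05)
})

test_that("domain_density evaluates the fitted family", {
  nd <- habitat_domain("PIMI", "normal", mu = 60, sigma = 28)
  expect_equal(domain_density(nd, 60), 1 / (28 * sqrt(2 * pi)),
               tolerance = 1e-9)
  expect_equal(domain_density(nd, 60), 0.014248, tolerance = 1e-4)
  gd <- habitat_domain("ONAS", "gamma", shape = 1, rate = 0.2)
  expect_equal(domain_density(gd, 0), 0.2)
  expect_error(domain_density(nd, -1), ">= 0")
  # mass below ground is excluded: integral over [0, 200] ~ 0.984
  int <- integrate(function(z) domain_density(nd, z), 0, 200)$value
  expect_equal(int, pnorm(200, 60, 28) - pnorm(0, 60, 28), tolerance = 1e-6)
  expect_equal(round(int, 3), 0.984)
})

test_that("attack rate matches the closed form and is symmetric", {
  a <- habitat_domain("PIMI", "normal", mu = 60, sigma = 10)
  self <- pairwise_attack_rate(a, a)
  expect_equal(self$attack_rate_density, 1 / (2 * 10 * sqrt(pi)),
               tolerance = 1e-6)
  expect_equal(round(self$closed_form, 6), 0.028209)

  b <- habitat_domain("MEFE", "normal", mu = 69, sigma = 28)
  ab <- pairwise_attack_rate(a, b)
  ba <- pairwise_attack_rate(b, a)
  expect_equal(ab$attack_rate_density, ba$attack_rate_density,
               tolerance = 1e-10)
  expect_equal(ab$quadrature, ab$closed_form, tolerance = 1e-6)

  # disjoint supports: overlap vanishes
  lo <- habitat_domain("x", "normal", mu = 5, sigma = 1)
  hi <- habitat_domain("y", "normal", mu = 115, sigma = 1)
  expect_lt(pairwise_attack_rate(lo, hi)$attack_rate_density, 1e-12)
})

test_that("attack rate scales as 1/s when both sds are scaled and means coincide", {
  for (s in c(2, 5)) {
    a1 <- habitat_domain("a", "normal", mu = 60, sigma = 8)
    b1 <- habitat_domain("b", "normal", mu = 60, sigma = 6)
    a2 <- habitat_domain("a", "normal", mu = 60, sigma = 8 * s)
    b2 <- habitat_domain("b", "normal", mu = 60, sigma = 6 * s)
    r1 <- pairwise_attack_rate(a1, b1)$closed_form
    r2 <- pairwise_attack_rate(a2, b2)$closed_form
    expect_equal(r2, r1 / s, tolerance = 1e-9)
  }
})

test_that("encounter composition behaves across heights", {
  g <- habitat_domain("MEFE", "normal", mu = 69, sigma = 10)
  w <- habitat_domain("ONAS", "gamma", shape = 1, rate = 0.2)
  # symmetric case
  expect_equal(encounter_composition(50, g, g), 0.5)
  # woodlice absent
  expect_equal(encounter_composition(30, g, NULL), 1)
  # near the ground the gamma dominates the mid-canopy normal
  expect_lt(encounter_composition(0, g, w), 1e-6)
  # monotone where the density ratio is monotone
  pis <- encounter_composition(seq(0, 69, by = 1), g, w)
  expect_true(all(diff(pis) > 0))
  # undefined when both densities vanish
  far <- habitat_domain("MEFE", "normal", mu = 500, sigma = 1)
  mode_up <- habitat_domain("ONAS", "gamma", shape = 2, rate = 0.5)
  expect_error(encounter_composition(0, far, mode_up), "undefined")
})

test_that("observation and domain CSV round-trips preserve content", {
  obs <- tiny_obs()
  f <- tempfile(fileext = ".csv")
  write_observations(obs, f)
  back <- read_observations(f)
  expect_equal(back$z_cm, obs$z_cm)
  expect_equal(back$species, obs$species)

  doms <- simulation_domains()
  fd <- tempfile(fileext = ".csv")
  write_domains(doms, fd)
  back <- read_domains(fd)
  expect_equal(back$PIMI$mu, doms$spider$mu)
  expect_equal(back$ONAS$rate, doms$woodlouse$rate, tolerance = 1e-12)
  expect_equal(back$ONAS$family, "gamma")

  bad <- obs; bad$z_cm[1] <- -2
  fb <- tempfile(fileext = ".csv")
  write_observations(bad, fb)
  expect_error(read_observations(fb), "finite")
})
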