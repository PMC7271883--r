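test_that("cage summaries average heights and carry overlap-based attack rates", {
  obs <- tiny_obs(zg = c(50, 70), zs = c(40, 80))
  sm <- summarize_cages(obs)
  expect_equal(sm$L_MEFE, 60)
  expect_equal(sm$L_PIMI, 60)
  # attack rate equals the overlap of the per-cage fits, computed
  # independently from the sample moments
  dg <- habitat_domain("MEFE", "normal", mu = 60, sigma = sd(c(50, 70)))
  ds <- habitat_domain("PIMI", "normal", mu = 60, sigma = sd(c(40, 80)))
  expect_equal(sm$A, pairwise_attack_rate(ds, dg)$quadrature,
               tolerance = 1e-10)
  expect_equal(sm$A_closed,
               dnorm(0, 0, sqrt(sd(c(50, 70))^2 + sd(c(40, 80))^2)),
               tolerance = 1e-10)
})

test_that("cages without both focal species are excluded with a warning", {
  obs <- rbind(tiny_obs(cage = "C1"),
               within(tiny_obs(cage = "C2"), {
                 species[species == "PIMI"] <- "MEFE"
               }))
  expect_warning(sm <- summarize_cages(obs), "C2")
  expect_equal(sm$cage_id, "C1")
})

test_that("height model recovers true effects and nulls", {
  # effects present
  sim <- simulate_experiment(synth_config(), seed = 21)
  fit <- quiet_fit(fit_height_model(sim$cages, chains = 2, n_iter = 1500,
                                    seed = 2))
  ci_w <- credible_interval(fit, "bW[2]")
  ci_tw <- credible_interval(fit, "bTW[2]")
  expect_lt(ci_w[1], 16.5); expect_gt(ci_w[2], 16.5)
  expect_lt(ci_tw[1], -19.3); expect_gt(ci_tw[2], -19.3)
  # grasshopper effects are null and their CIs say so
  ci_gw <- credible_interval(fit, "bW[1]")
  expect_lt(ci_gw[1], 0); expect_gt(ci_gw[2], 0)
  # all-null generator: spider woodlouse CI covers 0 too
  sim0 <- simulate_experiment(synth_config(b_PIMI_W = 0, b_PIMI_TW = 0),
                              seed = 22)
  fit0 <- quiet_fit(fit_height_model(sim0$cages, chains = 2, n_iter = 1500,
                                     seed = 2))
  ci0 <- credible_interval(fit0, "bW[2]")
  expect_lt(ci0[1], 0); expect_gt(ci0[2], 0)
})

test_that("prior-only sampling reproduces the printed prior centres", {
  pf <- quiet_fit(fit_height_model(NULL, chains = 2, n_iter = 3000,
                                   seed = 8, sample_prior = TRUE))
  s <- pf$summary
  get <- function(p, col) s[s$parameter == p, col]
  # medians/means at the prior centres within Monte-Carlo error
  expect_lt(abs(get("a[1]", "mean") - 69), 3)
  expect_lt(abs(get("a[2]", "mean") - 60), 8)
  expect_lt(abs(get("bT[1]", "mean") - (-0.13)), 3)
  # informative spider warming prior: mean within one prior sd of -12.7
  expect_lt(abs(get("bT[2]", "mean") - (-12.7)), 9.4)
  expect_lt(abs(get("bT[2]", "sd") - 9.4), 2)
  expect_lt(abs(get("bW[2]", "mean")), 8)  # diffuse Normal(0, 100)
})

test_that("dropping the interaction on no-interaction data leaves the woodlouse effect", {
  sim <- simulate_experiment(synth_config(b_PIMI_TW = 0), seed = 23)
  f1 <- quiet_fit(fit_height_model(sim$cages, chains = 2, n_iter = 1500,
                                   seed = 3))
  f2 <- quiet_fit(fit_height_model(sim$cages, chains = 2, n_iter = 1500,
                                   seed = 3, include_interaction = FALSE))
  m1 <- coef(f1)["bW[2]"]
  m2 <- coef(f2)["bW[2]"]
  expect_lt(abs(m1 - m2), 2)  # within Monte-Carlo/structural error (cm)
})

test_that("survival model: null recovery and boundary data", {
  sim <- simulate_experiment(synth_config(surv_beta_A = 0), seed = 31)
  fit <- quiet_fit(fit_survival_model(sim$cages, chains = 2, n_iter = 1500,
                                      seed = 4))
  ci <- credible_interval(fit, "bA")
  expect_lt(ci[1], 0); expect_gt(ci[2], 0)
  # all cages at full survival: fit runs and implies a high survival rate
  full <- sim$cages
  full$survivors <- full$stocked
  ffull <- quiet_fit(fit_survival_model(full, chains = 2, n_iter = 1500,
                                        seed = 4))
  expect_gt(plogis(coef(ffull)["alpha"]), 0.7)
})

test_that("posterior summaries carry convergence diagnostics", {
  sim <- simulate_experiment(synth_config(), seed = 41)
  fit <- quiet_fit(fit_survival_model(sim$cages, chains = 2, n_iter = 1000,
                                      seed = 5))
  expect_true(all(c("mean", "sd", "q2.5", "q97.5", "rhat", "ess") %in%
                    names(fit$summary)))
  expect_true(is.logical(fit$converged))
  expect_true(all(fit$summary$q2.5 <= fit$summary$q97.5))
  expect_true(all(fit$summary$ess > 0))
})
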