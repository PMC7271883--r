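# Shared fixtures and independent oracles used across test files.

# tiny observation table: one cage, two records per focal species
tiny_obs <- function(zg = c(50, 70), zs = c(40, 80), cage = "C1") {
  data.frame(
    cage_id = cage, block = "B1", year = 2015, woodlice = 0, warmed = 0,
    species = rep(c("MEFE", "PIMI"), c(length(zg), length(zs))),
    time_min = 420, x_cm = NA_real_, y_cm = NA_real_,
    z_cm = c(zg, zs), behavior = "", substrate = "")
}

# independent brute-force optimum of the signal-detection strategy value:
# exhaustive enumeration over a 10x finer criterion grid plus local golden
# refinement, computed directly from the closed-form value expression.
brute_force_sdt_optimum <- function(pi_G, pars) {
  val <- function(cc, n) {
    (1 - pars$p_loss)^n *
      (pi_G * pnorm(sqrt(n) * (pars$d_prime - cc)) * pars$payoff_G -
         (1 - pi_G) * pnorm(-sqrt(n) * cc) * pars$m * pars$cost_W) -
      (n - 1) * pars$look_cost
  }
  best <- max(0, pi_G * pars$payoff_G - (1 - pi_G) * pars$m * pars$cost_W)
  cs <- seq(-4, pars$d_prime + 4, by = 0.005)
  for (n in seq_len(pars$max_looks)) {
    v <- val(cs, n)
    i <- which.max(v)
    o <- optimize(function(cc) val(cc, n),
                  interval = c(cs[max(1, i - 1)], cs[min(length(cs), i + 1)]),
                  maximum = TRUE, tol = 1e-10)
    best <- max(best, v[i], o$objective)
  }
  best
}

# quiet model fits (convergence flags are exercised separately)
quiet_fit <- function(expr) suppressWarnings(expr)
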