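# Signal detection theory combined with habitat-domain encounter
# composition: optimal attack criterion, number of assessment looks, and
# perch height.

#' Signal-detection parameters
#'
#' Single-look cues are unit-variance normal with mean 0 for a woodlouse and
#' \code{d_prime} for a grasshopper (equal-variance model); pooling
#' \code{n} looks gives effective separation \code{d_prime * sqrt(n)}.
#' A spider that withholds its attack to assess the item risks losing the
#' opportunity with probability \code{p_loss} per look; attacking on sight
#' (the always-attack policy) carries no such risk.  Each look beyond the
#' first additionally costs one attack-time of active respiration
#' (\code{look_cost}).
#'
#' @param d_prime Discriminability of grasshopper vs woodlouse cues.
#' @param p_loss Probability of losing the prey item per assessment look.
#' @param max_looks Maximum number of looks considered.
#' @param payoff_G Expected net energy from attacking a grasshopper (J).
#' @param cost_W Magnitude of the energetic cost of attacking a woodlouse
#'   (J, before the multiplier).
#' @param m Woodlouse attack-cost multiplier.
#' @param look_cost Respiration cost of each look beyond the first (J).
#' @return Object of class \code{"sdt_params"}.
#' @export
sdt_params <- function(d_prime = 2.5, p_loss = 0.25, max_looks = 5,
                       payoff_G = 6.762, cost_W = 0.0043, m = 1,
                       look_cost = cost_W) {
  stopifnot(d_prime >= 0, p_loss >= 0, p_loss < 1, max_looks >= 1,
            cost_W >= 0, m > 0, look_cost >= 0)
  structure(list(d_prime = d_prime, p_loss = p_loss,
                 max_looks = as.integer(max_looks),
                 payoff_G = payoff_G, cost_W = cost_W, m = m,
                 look_cost = look_cost),
            class = "sdt_params")
}

#' Hit and false-alarm probabilities after n looks
#'
#' Pooling \code{n} unit-variance looks and applying criterion \code{c} (in
#' single-look cue units) gives
#' \code{hit = pnorm(sqrt(n) * (d_prime - c))} and
#' \code{false_alarm = pnorm(-sqrt(n) * c)}.  \code{c = -Inf} is the
#' always-attack policy (both probabilities 1), \code{c = Inf} never
#' attacks.
#'
#' @param d_prime Discriminability.
#' @param c Criterion (cue units; \code{-Inf}/\code{Inf} allowed).
#' @param n Number of looks (\code{>= 1}).
#' @return List with elements \code{hit} and \code{false_alarm}.
#' @export
detection_probs <- function(d_prime, c, n = 1) {
  stopifnot(n >= 1)
  if (is.infinite(c)) {
    p <- if (c < 0) 1 else 0
    return(list(hit = p, false_alarm = p))
  }
  list(hit = stats::pnorm(sqrt(n) * (d_prime - c)),
       false_alarm = stats::pnorm(-sqrt(n) * c))
}

#' Expected value of an attack strategy
#'
#' For an item that is a grasshopper with probability \code{pi_G}:
#' attacking on sight (\code{c = -Inf}) yields
#' \code{pi_G * payoff_G - (1 - pi_G) * m * cost_W}.  A selective strategy
#' (finite criterion, \code{n} looks) retains the item with probability
#' \code{(1 - p_loss)^n} while assessing, then attacks according to the
#' pooled-cue criterion, and pays \code{(n - 1) * look_cost} of assessment
#' respiration:
#' \deqn{V = (1-p_{loss})^n [\pi_G h \cdot payoff_G -
#'   (1-\pi_G) f \cdot m \cdot cost_W] - (n-1)\, look\_cost.}
#' Never attacking (\code{c = Inf}) is worth 0.
#'
#' @param c Criterion (\code{-Inf} = always attack, \code{Inf} = never).
#' @param n Number of looks.
#' @param pi_G Probability the item is a grasshopper.
#' @param params An \code{"sdt_params"}.
#' @return Expected value in J per encountered item.
#' @export
strategy_value <- function(c, n, pi_G, params) {
  stopifnot(inherits(params, "sdt_params"), pi_G >= 0, pi_G <= 1, n >= 1)
  if (is.infinite(c) && c > 0) return(0)
  if (is.infinite(c)) {
    return(pi_G * params$payoff_G - (1 - pi_G) * params$m * params$cost_W)
  }
  dp <- detection_probs(params$d_prime, c, n)
  (1 - params$p_loss)^n *
    (pi_G * dp$hit * params$payoff_G -
       (1 - pi_G) * dp$false_alarm * params$m * params$cost_W) -
    (n - 1) * params$look_cost
}

new_strategy <- function(criterion, looks, value, label) {
  structure(list(criterion = criterion, looks = as.integer(looks),
                 expected_value = value, label = label),
            class = "sdt_strategy")
}

#' @export
print.sdt_strategy <- function(x, ...) {
  cat(sprintf("SDT strategy: %s (criterion %s, looks %d), expected value %.4f J\n",
              x$label,
              if (is.infinite(x$criterion)) as.character(x$criterion)
              else sprintf("%.3f", x$criterion),
              x$looks, x$expected_value))
  invisible(x)
}

#' Optimise the attack strategy at a given encounter composition
#'
#' Grid search over criteria \code{c} in \code{{-Inf}} united with
#' \code{[-4, d_prime + 4]} in steps of 0.05 and looks
#' \code{n = 1, ..., max_looks}, followed by a local continuous refinement
#' of the criterion around the best grid point.  Ties are broken towards
#' smaller \code{n}, then smaller \code{|c|}.  The strategy is labelled
#' \code{"always_attack"} when the unconditional-attack value is within
#' 1e-12 of the optimum, \code{"never_attack"} when nothing beats not
#' attacking, otherwise \code{"selective"}.
#'
#' @param pi_G Probability an encountered item is a grasshopper.
#' @param params An \code{"sdt_params"}.
#' @return An \code{"sdt_strategy"}.
#' @export
optimize_strategy <- function(pi_G, params = sdt_params()) {
  stopifnot(pi_G >= 0, pi_G <= 1)
  step <- 0.05
  cs <- seq(-4, params$d_prime + 4, by = step)
  best <- list(c = -Inf, n = 1L,
               v = strategy_value(-Inf, 1, pi_G, params))
  better <- function(v, c, n, cur) {
    v > cur$v + 1e-12 ||
      (abs(v - cur$v) <= 1e-12 &&
         (n < cur$n || (n == cur$n && abs(c) < abs(cur$c))))
  }
  for (n in seq_len(params$max_looks)) {
    vals <- vapply(cs, strategy_value, numeric(1),
                   n = n, pi_G = pi_G, params = params)
    i <- which.max(vals)
    # local refinement of the criterion around the best grid point
    lo <- max(cs[1], cs[i] - step)
    hi <- min(cs[length(cs)], cs[i] + step)
    opt <- stats::optimize(function(cc) strategy_value(cc, n, pi_G, params),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-10)
    cand_c <- if (opt$objective > vals[i]) opt$maximum else cs[i]
    cand_v <- max(opt$objective, vals[i])
    if (better(cand_v, cand_c, n, best)) best <- list(c = cand_c, n = n, v = cand_v)
  }
  v_always <- strategy_value(-Inf, 1, pi_G, params)
  if (v_always >= best$v - 1e-12) {
    new_strategy(-Inf, 1L, v_always, "always_attack")
  } else if (best$v <= 1e-12) {
    new_strategy(Inf, 1L, 0, "never_attack")
  } else {
    new_strategy(best$c, best$n, best$v, "selective")
  }
}

#' Optimise perch height jointly with the attack strategy
#'
#' For every height on the grid the encounter composition
#' \eqn{\pi_G(z)} is computed from the habitat domains (using the spider's
#' own domain width as the local reach when \code{domains$spider} is
#' supplied), the attack strategy is optimised at the local temperature
#' (payoff and costs re-evaluated through the metabolic model), and the
#' expected daily net gain under that strategy is evaluated.  Returns the
#' gain-maximising height (ties towards the lower height) together with the
#' full height table.
#'
#' @param domains Named list of habitat domains (\code{grasshopper},
#'   optionally \code{woodlouse}, \code{spider}).
#' @param sdt An \code{"sdt_params"} (its \code{payoff_G}, \code{cost_W} and
#'   \code{look_cost} are recomputed per height from the energetics inputs;
#'   \code{d_prime}, \code{p_loss}, \code{max_looks} and \code{m} are used
#'   as given).
#' @param p An \code{"energetics_params"}.
#' @param met A \code{"metabolic_model"}.
#' @param profile A \code{"thermal_profile"}.
#' @param heights Height grid (cm).
#' @param woodlice_present Are woodlice present?
#' @return Object of class \code{"perch_optimum"}: list with \code{z_star},
#'   \code{strategy} (at \code{z_star}), \code{gain} (J/day at
#'   \code{z_star}) and \code{table} (per-height data frame with columns
#'   \code{z_cm}, \code{pi_G}, \code{criterion}, \code{looks}, \code{label},
#'   \code{value_J}, \code{gain_J_per_day}).
#' @export
optimize_perch <- function(domains, sdt = sdt_params(),
                           p = energetics_params(),
                           met = metabolic_model(),
                           profile = thermal_profile(),
                           heights = 0:120,
                           woodlice_present = TRUE) {
  if (length(heights) == 0) stop("empty height grid")
  wdom <- if (woodlice_present) domains$woodlouse else NULL
  predator_sd <- if (!is.null(domains$spider)) domains$spider$sigma else 0
  lam <- encounter_rates(domains, p, heights)
  lam_w <- if (woodlice_present) lam$woodlouse else rep(0, length(heights))
  pi_g <- encounter_composition(heights, domains$grasshopper, wdom,
                                predator_sd = predator_sd)
  temp <- temperature_at_height(profile, heights)
  att_min_g <- p$s * (p$t_a + p$t_h) + (1 - p$s) * p$t_a

  rows <- vector("list", length(heights))
  for (i in seq_along(heights)) {
    out <- net_attack_outcomes(p_no_mult(p), met, temp[i])
    pars_i <- sdt_params(d_prime = sdt$d_prime, p_loss = sdt$p_loss,
                         max_looks = sdt$max_looks,
                         payoff_G = out$grasshopper_net,
                         cost_W = -out$woodlouse_net, m = sdt$m,
                         look_cost = -out$woodlouse_net)
    strat <- optimize_strategy(pi_g[i], pars_i)
    lam_tot <- lam$grasshopper[i] + lam_w[i]
    dp <- detection_probs(sdt$d_prime, strat$criterion, strat$looks)
    ret <- if (is.infinite(strat$criterion)) 1
           else (1 - sdt$p_loss)^strat$looks
    act_min <- lam_tot *
      (ret * (pi_g[i] * dp$hit * att_min_g +
              (1 - pi_g[i]) * dp$false_alarm * p$t_a) +
       (strat$looks - 1) * p$t_a)
    rr <- metabolic_rate(met, temp[i], "resting")
    gain <- lam_tot * strat$expected_value - rr * (1440 - act_min)
    rows[[i]] <- data.frame(
      z_cm = heights[i], pi_G = pi_g[i],
      criterion = strat$criterion, looks = strat$looks,
      label = strat$label, value_J = strat$expected_value,
      gain_J_per_day = gain)
  }
  tab <- do.call(rbind, rows)
  best <- which.max(tab$gain_J_per_day)  # which.max takes the first maximum
  z_star <- tab$z_cm[best]
  strat <- new_strategy(tab$criterion[best], tab$looks[best],
                        tab$value_J[best], tab$label[best])
  structure(list(z_star = z_star, strategy = strat,
                 gain = tab$gain_J_per_day[best], table = tab),
            class = "perch_optimum")
}

# energetics params with the woodlouse multiplier stripped: the SDT layer
# applies its own multiplier through sdt_params$m.
p_no_mult <- function(p) {
  energetics_params(E_g = p$E_g, t_h = p$t_h, t_a = p$t_a, s = p$s,
                    assim = p$assim, E_day = p$E_day,
                    hunting_hours = p$hunting_hours, m = 1)
}

#' @export
print.perch_optimum <- function(x, ...) {
  cat(sprintf("Optimal perch: %.0f cm, gain %.3f J/day\n", x$z_star, x$gain))
  print(x$strategy)
  invisible(x)
}

#' Smallest woodlouse-cost multiplier that alters the optimum
#'
#' Scans the supplied multipliers in ascending order and returns the
#' smallest at which, relative to the multiplier-1 baseline, either the
#' optimal perch height shifts by more than one grid step or the optimal
#' strategy at the optimal perch is no longer always-attack.  Returns
#' \code{NA} ("none") when no multiplier in the list alters the optimum.
#'
#' @param domains Habitat domains as in [optimize_perch()].
#' @param sdt,p,met,profile,heights As in [optimize_perch()].
#' @param decades Ascending multipliers to scan.
#' @return The smallest altering multiplier, or \code{NA}.
#' @export
cost_multiplier_threshold <- function(domains, sdt = sdt_params(),
                                      p = energetics_params(),
                                      met = metabolic_model(),
                                      profile = thermal_profile(),
                                      heights = 0:120,
                                      decades = c(1, 10, 100, 1000, 10000)) {
  if (length(decades) == 0) stop("empty multiplier list")
  if (is.unsorted(decades)) stop("multipliers must be sorted ascending")
  step <- if (length(heights) > 1) min(diff(sort(heights))) else 1
  base_sdt <- modify_m(sdt, 1)
  base <- optimize_perch(domains, base_sdt, p, met, profile, heights,
                         woodlice_present = TRUE)
  for (d in decades) {
    opt <- if (d == 1) base
           else optimize_perch(domains, modify_m(sdt, d), p, met, profile,
                               heights, woodlice_present = TRUE)
    if (abs(opt$z_star - base$z_star) > step ||
        opt$strategy$label != "always_attack")
      return(d)
  }
  NA_real_
}

modify_m <- function(sdt, m) {
  sdt_params(d_prime = sdt$d_prime, p_loss = sdt$p_loss,
             max_looks = sdt$max_looks, payoff_G = sdt$payoff_G,
             cost_W = sdt$cost_W, m = m, look_cost = sdt$look_cost)
}
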