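# Temperature-dependent foraging energetics for a sit-and-wait spider.

#' Energetic parameters of the foraging model
#'
#' Defaults follow the parameter table of the cage-experiment system:
#' grasshopper body energy content 33.81 J, spider handling time 20 min,
#' attack time 0.5 min, attack success rate 0.25, assimilation efficiency
#' 0.8, 0.8 prey encounters per day, an 8-h daily hunting period, and a
#' woodlouse attack-cost multiplier of 1 (raised in sensitivity scans).
#'
#' @param E_g Grasshopper body energy content (J).
#' @param t_h Handling time of a successful grasshopper attack (min).
#' @param t_a Attack time (min), assumed equal for grasshoppers and woodlice.
#' @param s Attack success rate (fraction).
#' @param assim Assimilation efficiency (fraction).
#' @param E_day Expected prey encounters per day at the domain mode.
#' @param hunting_hours Daily hunting period (h).
#' @param m Woodlouse attack-cost multiplier (dimensionless).
#' @return Object of class \code{"energetics_params"}.
#' @export
energetics_params <- function(E_g = 33.81, t_h = 20, t_a = 0.5, s = 0.25,
                              assim = 0.8, E_day = 0.8, hunting_hours = 8,
                              m = 1) {
  stopifnot(E_g >= 0, t_h > 0, t_a > 0, s > 0, s <= 1,
            assim > 0, assim <= 1, E_day >= 0, hunting_hours > 0, m > 0)
  structure(list(E_g = E_g, t_h = t_h, t_a = t_a, s = s, assim = assim,
                 E_day = E_day, hunting_hours = hunting_hours, m = m),
            class = "energetics_params")
}

#' Canopy thermal profile
#'
#' Air temperature increases linearly with canopy height during a summer
#' day: \code{T(z) = T0 + lapse * z}, with a default gradient of
#' 0.1 degC per cm.
#'
#' @param t0 Ground temperature (degC).
#' @param lapse Temperature increase per cm of height (degC/cm, \code{>= 0}).
#' @return Object of class \code{"thermal_profile"}.
#' @export
thermal_profile <- function(t0 = 20, lapse = 0.1) {
  stopifnot(lapse >= 0)
  structure(list(t0 = t0, lapse = lapse), class = "thermal_profile")
}

#' Temperature at a canopy height
#'
#' @param profile A \code{"thermal_profile"}.
#' @param z Height(s) in cm within \code{[0, 120]}.
#' @return Temperature(s) in degC.
#' @export
temperature_at_height <- function(profile, z) {
  stopifnot(inherits(profile, "thermal_profile"))
  if (any(z < 0 | z > 120)) stop("height out of range [0, 120] cm")
  profile$t0 + profile$lapse * z
}

#' Metabolic model of the spider
#'
#' Respiration is converted to energy through the oxycalorific equivalent
#' (0.0200832 J per microlitre O2).  The active metabolic rate is anchored
#' at 25.70 ul O2/h at 25 degC -- equivalently 8.6 mJ/min, the rate that
#' makes a 0.5-min attack cost ~4.3 mJ -- and scales with temperature as
#' Q10 = 2.  The resting rate is a fixed fraction (default 0.5) of the
#' active rate at every temperature.  The respiration quotient (0.7) is
#' carried for converting user-supplied CO2-based respirometry to O2 units;
#' the default chain is already in O2 units.
#'
#' @param oxycal Oxycalorific equivalent (J per ul O2).
#' @param rq Respiration quotient (CO2 produced / O2 consumed).
#' @param active_o2_25 Active O2 consumption at 25 degC (ul O2/h).
#' @param rest_frac Resting rate as a fraction of the active rate.
#' @param q10 Q10 temperature coefficient.
#' @return Object of class \code{"metabolic_model"}.
#' @export
metabolic_model <- function(oxycal = 0.0200832, rq = 0.7,
                            active_o2_25 = 25.70, rest_frac = 0.5,
                            q10 = 2) {
  stopifnot(oxycal > 0, rq > 0, active_o2_25 > 0, rest_frac > 0, q10 > 0)
  structure(list(oxycal = oxycal, rq = rq, active_o2_25 = active_o2_25,
                 rest_frac = rest_frac, q10 = q10),
            class = "metabolic_model")
}

#' Metabolic rate at a temperature
#'
#' @param met A \code{"metabolic_model"}.
#' @param temp_c Temperature (degC).
#' @param state \code{"active"} or \code{"resting"}.
#' @return Rate in J per minute.
#' @export
metabolic_rate <- function(met, temp_c, state = c("active", "resting")) {
  stopifnot(inherits(met, "metabolic_model"))
  state <- match.arg(state)
  rate <- met$active_o2_25 / 60 * met$oxycal * met$q10^((temp_c - 25) / 10)
  if (state == "resting") rate <- rate * met$rest_frac
  rate
}

#' Respiration energy over a duration
#'
#' @param met A \code{"metabolic_model"}.
#' @param temp_c Temperature (degC).
#' @param duration_min Duration (min, \code{>= 0}).
#' @param state \code{"active"} or \code{"resting"}.
#' @return Energy in J.
#' @examples
#' respiration_energy(metabolic_model(), 25, 0.5, "active")  # ~4.3 mJ
#' @export
respiration_energy <- function(met, temp_c, duration_min,
                               state = c("active", "resting")) {
  if (any(duration_min < 0)) stop("duration must be >= 0")
  metabolic_rate(met, temp_c, match.arg(state)) * duration_min
}

#' Expected assimilated payoff of a grasshopper encounter
#'
#' Gross expected assimilated energy per encounter,
#' \code{s * assim * E_g}; with the default parameters
#' 0.25 x 0.8 x 33.81 = 6.762 J.  Respiration during the attack and
#' handling is accounted separately by [net_attack_outcomes()].
#'
#' @param p An \code{"energetics_params"}.
#' @return Energy in J.
#' @export
expected_grasshopper_payoff <- function(p = energetics_params()) {
  stopifnot(inherits(p, "energetics_params"))
  p$s * p$assim * p$E_g
}

#' Net energy outcomes of attacking each prey type
#'
#' Grasshopper attacks succeed with probability \code{s}; a success yields
#' the assimilated body energy minus active metabolism over the attack plus
#' handling time, a failure costs active metabolism over the attack time:
#' \deqn{g = s[\epsilon E_g - r_a(T)(t_a + t_h)] - (1-s) r_a(T) t_a.}
#' A woodlouse is never consumed, so its net outcome is the attack cost
#' only, \eqn{-m\, r_a(T)\, t_a} (strictly negative).
#'
#' @param p An \code{"energetics_params"}.
#' @param met A \code{"metabolic_model"}.
#' @param temp_c Temperature (degC).
#' @return List with elements \code{grasshopper_net} and
#'   \code{woodlouse_net} (J per encounter).
#' @export
net_attack_outcomes <- function(p = energetics_params(),
                                met = metabolic_model(), temp_c = 25) {
  ra <- metabolic_rate(met, temp_c, "active")
  list(
    grasshopper_net = p$s * (p$assim * p$E_g - ra * (p$t_a + p$t_h)) -
      (1 - p$s) * ra * p$t_a,
    woodlouse_net = -p$m * ra * p$t_a
  )
}

# Height-resolved encounter rates (per day). Weights are prey densities at
# the perch when no predator domain is supplied, or predator-domain overlap
# weights when one is; both are normalised so the best grasshopper height
# receives E_day encounters per day.
encounter_rates <- function(domains, p, heights, z_max = 120) {
  predator_sd <- if (!is.null(domains$spider)) domains$spider$sigma else 0
  grid <- seq(0, z_max, by = 1)
  wg_grid <- overlap_weight(domains$grasshopper, grid, predator_sd, z_max)
  norm <- p$E_day / max(wg_grid)
  lam_g <- norm * overlap_weight(domains$grasshopper, heights, predator_sd, z_max)
  lam_w <- if (!is.null(domains$woodlouse))
    norm * overlap_weight(domains$woodlouse, heights, predator_sd, z_max)
  else rep(0, length(heights))
  list(grasshopper = lam_g, woodlouse = lam_w, predator_sd = predator_sd)
}

#' Daily net energy gain across canopy heights
#'
#' For a spider hunting at perch height z the expected daily net gain is
#' \deqn{G(z) = \lambda_G(z) g(T(z)) + \lambda_W(z) w(T(z)) - r_r(T(z))
#'   (1440 - t_{act}(z)),}
#' where \eqn{\lambda_i(z)} are height-resolved encounter rates (per day),
#' \eqn{g} and \eqn{w} the net attack outcomes of [net_attack_outcomes()],
#' \eqn{r_r} the resting metabolic rate, and \eqn{t_{act}} the expected
#' minutes per day spent in attacks and handling; all remaining time is
#' spent at the perch height's resting rate.  Encounter rates are
#' normalised so that the best grasshopper height yields \code{p$E_day}
#' encounters per day, with the same constant for woodlice (equal-density
#' assumption).  When \code{domains$spider} is present, encounter weights
#' are domain-overlap weights around the perch; otherwise prey densities at
#' the perch itself.
#'
#' @param domains Named list with \code{grasshopper}, optionally
#'   \code{woodlouse} and \code{spider} \code{"habitat_domain"}s.
#' @param p An \code{"energetics_params"}.
#' @param met A \code{"metabolic_model"}.
#' @param profile A \code{"thermal_profile"}.
#' @param heights Height grid (cm) within \code{[0, 120]}.
#' @param woodlice_present Include the woodlouse attack-cost term?
#' @return A data frame of class \code{"net_gain_profile"} with columns
#'   \code{z_cm}, \code{gain_J_per_day}, \code{component_payoff},
#'   \code{component_attack_cost}, \code{component_resting}.
#' @export
daily_net_gain_profile <- function(domains, p = energetics_params(),
                                   met = metabolic_model(),
                                   profile = thermal_profile(),
                                   heights = 0:120,
                                   woodlice_present = TRUE) {
  if (length(heights) == 0) stop("empty height grid")
  if (any(heights < 0 | heights > 120)) stop("heights out of range [0, 120]")
  lam <- encounter_rates(domains, p, heights)
  lam_w <- if (woodlice_present) lam$woodlouse else rep(0, length(heights))
  temp <- temperature_at_height(profile, heights)
  ra <- metabolic_rate(met, temp, "active")
  rr <- ra * met$rest_frac
  payoff <- lam$grasshopper * p$s * p$assim * p$E_g
  att_min_g <- p$s * (p$t_a + p$t_h) + (1 - p$s) * p$t_a
  active_min <- lam$grasshopper * att_min_g + lam_w * p$t_a
  attack_cost <- lam$grasshopper * att_min_g * ra + lam_w * p$t_a * ra * p$m
  resting <- rr * (1440 - active_min)
  out <- data.frame(
    z_cm = heights,
    gain_J_per_day = payoff - attack_cost - resting,
    component_payoff = payoff,
    component_attack_cost = attack_cost,
    component_resting = resting
  )
  class(out) <- c("net_gain_profile", "data.frame")
  attr(out, "woodlice_present") <- woodlice_present
  out
}

#' @export
plot.net_gain_profile <- function(x, ...) {
  plot(x$z_cm, x$gain_J_per_day, type = "l",
       xlab = "Perch height (cm)", ylab = "Net energy gain (J/day)", ...)
  invisible(x)
}
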