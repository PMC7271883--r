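# Individual-based simulation of spider perch height.

#' Configuration of the perch-movement simulation
#'
#' Spiders start at a random canopy height and each hour either hold their
#' perch or move.  Moves are triggered by a baseline per-hour probability
#' (0.1 for a sit-and-wait predator, 0.8 for an active hunter), by
#' encounters with woodlice, and optionally by failed attacks on
#' grasshoppers.  Woodlouse encounters happen during the dawn and dusk
#' hours when woodlice forage aboveground (outside the daytime observation
#' window), with hourly probability \code{encounters_per_day} times the
#' woodlouse encounter weight at the spider's height divided by the number
#' of active hours; the encounter weight is the overlap of the woodlouse
#' domain with the spider's local vertical reach (sd \code{predator_sd}),
#' normalised to its canopy maximum -- the same habitat-domain encounter
#' law the energetics and signal-detection models use.  A woodlouse-
#' triggered move is directed upward, away from the ground-dwelling
#' woodlouse; baseline and failed-attack moves take a random direction.
#' Every move draws a magnitude \code{|Normal(step_mean, step_sd)|} and is
#' clamped to the canopy interval.
#'
#' @param mode \code{"sitwait"} (baseline move probability 0.1) or
#'   \code{"active"} (0.8); overridden by \code{p_move_base} if supplied.
#' @param p_move_base Baseline per-hour movement probability.
#' @param step_mean,step_sd Mean and sd (cm) of the step-magnitude draw.
#' @param canopy Height interval (cm), default \code{c(0, 100)}.
#' @param hours Simulated hours per replicate.
#' @param replicates Number of replicate spiders.
#' @param seed Master seed; per-replicate substreams are derived from it.
#' @param woodlice_present Simulate woodlouse encounters?
#' @param respond_to_failed_attacks Also move after failing to capture a
#'   grasshopper?
#' @param detection_threshold Realised height changes at or below this (cm)
#'   count as non-movements.
#' @param encounters_per_day Expected prey encounters per day at the
#'   best height.
#' @param woodlouse_active_hours Hours of day when woodlice forage
#'   aboveground (dawn and dusk, outside the observation window).
#' @param observation_window Hours of day of the empirical observation
#'   window, default 07:00--19:00.
#' @param hunting_hours Hours of day of the spider's 8-h hunting period
#'   (used by the failed-attack variant).
#' @param start_hour Hour of day at simulation step 1.
#' @param predator_sd Sd (cm) of the spider's local vertical reach used in
#'   encounter weights; 0 uses prey point densities instead.
#' @param woodlouse_domain,grasshopper_domain Habitat domains used for
#'   encounter weights (defaults: the pooled [simulation_domains()]).
#' @param attack_success Probability a grasshopper attack succeeds (a
#'   failure triggers a move in the failed-attack variant).
#' @return Object of class \code{"ibm_config"}.
#' @export
ibm_config <- function(mode = c("sitwait", "active"),
                       p_move_base = NULL,
                       step_mean = 10.5, step_sd = 14.5,
                       canopy = c(0, 100), hours = 50, replicates = 100,
                       seed = 1L,
                       woodlice_present = TRUE,
                       respond_to_failed_attacks = FALSE,
                       detection_threshold = 0.5,
                       encounters_per_day = 0.8,
                       woodlouse_active_hours = c(4, 5, 6, 19, 20, 21),
                       observation_window = c(7, 19),
                       hunting_hours = 9:16,
                       start_hour = 7,
                       predator_sd = 28,
                       woodlouse_domain = NULL,
                       grasshopper_domain = NULL,
                       attack_success = 0.25) {
  mode <- match.arg(mode)
  if (is.null(p_move_base))
    p_move_base <- if (mode == "sitwait") 0.1 else 0.8
  stopifnot(p_move_base >= 0, p_move_base <= 1, hours >= 1,
            canopy[1] < canopy[2], replicates >= 1,
            detection_threshold >= 0, predator_sd >= 0,
            attack_success > 0, attack_success <= 1)
  doms <- simulation_domains()
  if (is.null(woodlouse_domain)) woodlouse_domain <- doms$woodlouse
  if (is.null(grasshopper_domain)) grasshopper_domain <- doms$grasshopper
  structure(list(
    mode = mode, p_move_base = p_move_base,
    step_mean = step_mean, step_sd = step_sd, canopy = canopy,
    hours = as.integer(hours), replicates = as.integer(replicates),
    seed = as.integer(seed),
    woodlice_present = woodlice_present,
    respond_to_failed_attacks = respond_to_failed_attacks,
    detection_threshold = detection_threshold,
    encounters_per_day = encounters_per_day,
    woodlouse_active_hours = woodlouse_active_hours,
    observation_window = observation_window,
    hunting_hours = hunting_hours,
    start_hour = start_hour,
    predator_sd = predator_sd,
    woodlouse_domain = woodlouse_domain,
    grasshopper_domain = grasshopper_domain,
    attack_success = attack_success), class = "ibm_config")
}

# Precompute encounter-weight interpolators (normalised to their canopy
# maximum) so the hourly step stays cheap.
ibm_weights <- function(config) {
  grid <- seq(config$canopy[1], config$canopy[2], by = 0.5)
  ww <- overlap_weight(config$woodlouse_domain, grid, config$predator_sd)
  wg <- overlap_weight(config$grasshopper_domain, grid, config$predator_sd)
  list(woodlouse = stats::approxfun(grid, ww / max(ww), rule = 2),
       grasshopper = stats::approxfun(grid, wg / max(wg), rule = 2))
}

woodlouse_encounter_prob <- function(config, h, weights = NULL) {
  w <- if (is.null(weights)) {
    ww <- overlap_weight(config$woodlouse_domain,
                         seq(config$canopy[1], config$canopy[2], by = 0.5),
                         config$predator_sd)
    overlap_weight(config$woodlouse_domain, h, config$predator_sd) / max(ww)
  } else weights$woodlouse(h)
  min(1, config$encounters_per_day * w / length(config$woodlouse_active_hours))
}

grasshopper_encounter_prob <- function(config, h, weights = NULL) {
  w <- if (is.null(weights)) {
    wg <- overlap_weight(config$grasshopper_domain,
                         seq(config$canopy[1], config$canopy[2], by = 0.5),
                         config$predator_sd)
    overlap_weight(config$grasshopper_domain, h, config$predator_sd) / max(wg)
  } else weights$grasshopper(h)
  min(1, config$encounters_per_day * w / length(config$hunting_hours))
}

#' One hourly step of the perch-movement model
#'
#' The trigger checks run in order: woodlouse encounter (dawn/dusk active
#' hours only, when woodlice are present), baseline movement, then --
#' in the failed-attack variant -- a failed grasshopper attack during
#' hunting hours.  A woodlouse-triggered move is directed upward; other
#' moves take a random sign.  The new height is clamped to the canopy; a
#' clamped move whose realised displacement does not exceed the detection
#' threshold is logged \code{"clamped_null"}.
#'
#' @param height Current height (cm), within the canopy interval.
#' @param hour_of_day Hour of day (0--23).
#' @param config An \code{"ibm_config"}.
#' @param weights Optional precomputed encounter-weight functions (internal
#'   use; computed from the domains when omitted).
#' @return List with elements \code{height} (new height) and \code{event}
#'   (one of \code{"none"}, \code{"baseline_move"},
#'   \code{"woodlouse_encounter_move"}, \code{"failed_attack_move"},
#'   \code{"clamped_null"}).
#' @export
ibm_step <- function(height, hour_of_day, config, weights = NULL) {
  stopifnot(height >= config$canopy[1], height <= config$canopy[2])
  # encounter and baseline uniforms are always consumed so that paired
  # runs (same seed, woodlice toggled) share their random streams
  u_enc <- stats::runif(1)
  u_base <- stats::runif(1)
  event <- "none"
  if (config$woodlice_present &&
      hour_of_day %in% config$woodlouse_active_hours &&
      u_enc < woodlouse_encounter_prob(config, height, weights)) {
    event <- "woodlouse_encounter_move"
  } else if (u_base < config$p_move_base) {
    event <- "baseline_move"
  } else if (config$respond_to_failed_attacks &&
             hour_of_day %in% config$hunting_hours &&
             stats::runif(1) < grasshopper_encounter_prob(config, height, weights) &&
             stats::runif(1) < 1 - config$attack_success) {
    event <- "failed_attack_move"
  }
  if (event == "none") return(list(height = height, event = "none"))
  dir <- if (event == "woodlouse_encounter_move") 1
         else sample(c(-1, 1), 1)
  disp <- dir * abs(stats::rnorm(1, config$step_mean, config$step_sd))
  new_h <- min(max(height + disp, config$canopy[1]), config$canopy[2])
  clamped <- (new_h != height + disp)
  if (clamped && abs(new_h - height) <= config$detection_threshold)
    event <- "clamped_null"
  list(height = new_h, event = event)
}

#' Run the perch-movement simulation
#'
#' Runs \code{config$replicates} independent spiders for \code{config$hours}
#' hourly steps.  Initial heights are uniform on the canopy interval.  The
#' ensemble is deterministic given the master seed: each replicate runs on
#' its own substream seed derived from it.  Running the same master seed
#' with woodlice toggled pairs the replicates (identical starting heights
#' and shared baseline draws), which sharpens with/without contrasts.
#'
#' @param config An \code{"ibm_config"}.
#' @return Object of class \code{"ibm_ensemble"}: list with \code{heights}
#'   (matrix, replicates x (hours + 1), column 1 the initial height),
#'   \code{events} (matrix, replicates x hours) and \code{config}.
#' @export
run_ibm <- function(config = ibm_config()) {
  stopifnot(inherits(config, "ibm_config"))
  if (is.null(config$seed)) stop("configuration error: rng seed not set")
  weights <- ibm_weights(config)
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$replicates)
  H <- matrix(NA_real_, config$replicates, config$hours + 1)
  E <- matrix(NA_character_, config$replicates, config$hours)
  for (r in seq_len(config$replicates)) {
    set.seed(rep_seeds[r])
    h <- stats::runif(1, config$canopy[1], config$canopy[2])
    H[r, 1] <- h
    for (t in seq_len(config$hours)) {
      hod <- (config$start_hour + t - 1) %% 24
      st <- ibm_step(h, hod, config, weights)
      h <- st$height
      H[r, t + 1] <- h
      E[r, t] <- st$event
    }
  }
  structure(list(heights = H, events = E, config = config),
            class = "ibm_ensemble")
}

#' Summarise a perch-movement ensemble
#'
#' Realised movement probability is the fraction of hourly steps whose
#' realised height change exceeds the detection threshold; the mean step is
#' the mean realised absolute height change over all steps, zeros included.
#' Statistics are computed over all simulated hours (\code{$all}) and over
#' the steps falling in the daytime observation window
#' (\code{$observation}) -- the window in which the empirical movement
#' rates were recorded, and therefore the one to compare against them.
#'
#' @param object An \code{"ibm_ensemble"}.
#' @param ... Unused.
#' @return Object of class \code{"ibm_summary"}: list with elements
#'   \code{all} and \code{observation}, each containing
#'   \code{realized_move_probability}, \code{mean_step}, \code{sd_step} and
#'   \code{n_effective_steps}; plus \code{hourly_mean} and \code{hourly_sd}
#'   (mean and sd height across replicates at each hour) and
#'   \code{final10_mean} (per-replicate mean height over the final 10
#'   hours).
#' @export
summary.ibm_ensemble <- function(object, ...) {
  cfg <- object$config
  if (nrow(object$heights) == 0) stop("empty ensemble")
  dh <- abs(object$heights[, -1, drop = FALSE] -
              object$heights[, -ncol(object$heights), drop = FALSE])
  hod <- (cfg$start_hour + seq_len(cfg$hours) - 1) %% 24
  in_window <- hod >= cfg$observation_window[1] & hod < cfg$observation_window[2]
  stat <- function(d) {
    moved <- d > cfg$detection_threshold
    list(realized_move_probability = mean(moved),
         mean_step = mean(d),
         sd_step = stats::sd(as.numeric(d)),
         n_effective_steps = sum(moved))
  }
  nH <- ncol(object$heights)
  final10 <- rowMeans(object$heights[, seq(max(2, nH - 9), nH), drop = FALSE])
  structure(list(
    all = stat(dh),
    observation = stat(dh[, in_window, drop = FALSE]),
    hourly_mean = colMeans(object$heights),
    hourly_sd = apply(object$heights, 2, stats::sd),
    final10_mean = final10,
    config = cfg), class = "ibm_summary")
}

#' @export
print.ibm_summary <- function(x, ...) {
  cat(sprintf("IBM ensemble (%s, woodlice %s): %d replicates\n",
              x$config$mode,
              if (x$config$woodlice_present) "present" else "absent",
              x$config$replicates))
  cat(sprintf("  all hours:   move probability %.3f, mean step %.2f cm (sd %.2f)\n",
              x$all$realized_move_probability, x$all$mean_step, x$all$sd_step))
  cat(sprintf("  obs. window: move probability %.3f, mean step %.2f cm (sd %.2f)\n",
              x$observation$realized_move_probability,
              x$observation$mean_step, x$observation$sd_step))
  invisible(x)
}

#' @export
plot.ibm_ensemble <- function(x, ...) {
  hrs <- 0:x$config$hours
  mh <- colMeans(x$heights)
  sdh <- apply(x$heights, 2, stats::sd)
  plot(hrs, mh, type = "n", ylim = x$config$canopy,
       xlab = "Hour", ylab = "Height (cm)", ...)
  for (r in seq_len(min(nrow(x$heights), 100)))
    lines(hrs, x$heights[r, ], col = grDevices::grey(0.85))
  lines(hrs, mh, lwd = 2)
  lines(hrs, mh + sdh, lty = 2)
  lines(hrs, mh - sdh, lty = 2)
  invisible(x)
}
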