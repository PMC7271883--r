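# Synthetic cage-experiment data with the statistical structure the
# analysis assumes.

#' Configuration of the synthetic cage experiment
#'
#' Emulates the field design: blocks nested in years (2015, 2017, 2018),
#' woodlouse-addition treatments in all years, a factorial heat-lamp
#' (warming) treatment in 2018 only, half-hourly positions from 07:00 to
#' 19:00 (25 time points), and binomial survival of the grasshoppers
#' stocked per cage (2 in 2015/2017, 3 in 2018).  Baseline heights and
#' within-cage spreads are 69 +/- 10 cm for grasshoppers and 60 +/- 28 cm
#' for spiders; the default true treatment effects on spider height are a
#' +16.5 cm woodlouse effect and a -19.3 cm woodlouse x warming
#' interaction, with null grasshopper effects.
#'
#' @param years Calendar years.
#' @param blocks_per_year Number of blocks in each year.
#' @param mu_MEFE,mu_PIMI Baseline mean heights (cm).
#' @param sd_MEFE,sd_PIMI Within-cage height sds (cm).
#' @param b_PIMI_W,b_PIMI_T,b_PIMI_TW Spider treatment effects (cm).
#' @param b_MEFE_W,b_MEFE_T,b_MEFE_TW Grasshopper treatment effects (cm).
#' @param year_sd,block_sd Random-intercept sds (cm), length-2 vectors
#'   \code{c(MEFE, PIMI)}.
#' @param woodlouse_shape,woodlouse_rate Woodlouse gamma domain parameters.
#' @param surv_alpha,surv_beta_A Survival-model intercept and attack-rate
#'   slope on the logit scale (slope in cm, i.e. per 1/cm of attack rate).
#' @param stocked_by_year Grasshoppers stocked per cage in each year.
#' @param times_min Observation times (minutes since midnight).
#' @param n_grasshoppers,n_woodlice Animals per cage.
#' @param woodlouse_detect_p Probability a given woodlouse is visible at a
#'   given check (woodlice are rarely seen in daytime).
#' @param height_resolution Heights are recorded to this resolution (cm).
#' @return Object of class \code{"synth_config"}.
#' @export
synth_config <- function(years = c(2015, 2017, 2018),
                         blocks_per_year = c(5, 8, 7),
                         mu_MEFE = 69, mu_PIMI = 60,
                         sd_MEFE = 10, sd_PIMI = 28,
                         b_PIMI_W = 16.5, b_PIMI_T = 0, b_PIMI_TW = -19.3,
                         b_MEFE_W = 0, b_MEFE_T = 0, b_MEFE_TW = 0,
                         year_sd = c(3, 6), block_sd = c(3, 6),
                         woodlouse_shape = 1, woodlouse_rate = 0.2,
                         surv_alpha = 1.5, surv_beta_A = -10,
                         stocked_by_year = c(2, 2, 3),
                         times_min = seq(7 * 60, 19 * 60, by = 30),
                         n_grasshoppers = NULL, n_woodlice = 6,
                         woodlouse_detect_p = 0.02,
                         height_resolution = 0.5) {
  stopifnot(length(blocks_per_year) == length(years),
            length(stocked_by_year) == length(years),
            sd_MEFE > 0, sd_PIMI > 0, all(year_sd >= 0), all(block_sd >= 0),
            woodlouse_shape > 0, woodlouse_rate > 0)
  structure(list(
    years = years, blocks_per_year = blocks_per_year,
    mu_MEFE = mu_MEFE, mu_PIMI = mu_PIMI,
    sd_MEFE = sd_MEFE, sd_PIMI = sd_PIMI,
    b_PIMI_W = b_PIMI_W, b_PIMI_T = b_PIMI_T, b_PIMI_TW = b_PIMI_TW,
    b_MEFE_W = b_MEFE_W, b_MEFE_T = b_MEFE_T, b_MEFE_TW = b_MEFE_TW,
    year_sd = year_sd, block_sd = block_sd,
    woodlouse_shape = woodlouse_shape, woodlouse_rate = woodlouse_rate,
    surv_alpha = surv_alpha, surv_beta_A = surv_beta_A,
    stocked_by_year = stocked_by_year, times_min = times_min,
    n_grasshoppers = n_grasshoppers, n_woodlice = n_woodlice,
    woodlouse_detect_p = woodlouse_detect_p,
    height_resolution = height_resolution), class = "synth_config")
}

# cage design table: per year, each block holds one cage per treatment
# combination run that year (W in all years; warming factorial in 2018).
cage_design <- function(config) {
  rows <- list()
  for (k in seq_along(config$years)) {
    yr <- config$years[k]
    treats <- if (yr >= 2018) expand.grid(W = 0:1, T = 0:1)
              else data.frame(W = 0:1, T = 0)
    for (b in seq_len(config$blocks_per_year[k])) {
      for (j in seq_len(nrow(treats))) {
        rows[[length(rows) + 1]] <- data.frame(
          cage_id = sprintf("%d_B%02d_W%dT%d", yr, b, treats$W[j], treats$T[j]),
          block = sprintf("%d_B%02d", yr, b),
          year = yr, woodlice = treats$W[j], warmed = treats$T[j],
          stocked = config$stocked_by_year[k])
      }
    }
  }
  do.call(rbind, rows)
}

round_to <- function(x, res) round(x / res) * res

# truncated-at-zero normal draw (redraw on negative)
rtnorm0 <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x < 0)) {
    bad <- x < 0
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  x
}

#' Generate a synthetic behavioural observation table
#'
#' Draws cage-level mean heights from the linear treatment predictor plus
#' year and block-in-year random intercepts, then per-time-point heights
#' from the within-cage distributions: normal truncated at the ground for
#' spiders and grasshoppers, gamma for woodlice with sparse daytime
#' detectability.  Heights are recorded to 0.5 cm.  Deterministic given the
#' seed.
#'
#' @param config A \code{"synth_config"}.
#' @param seed Integer seed.
#' @return Observation data frame (schema of [read_observations()]).
#' @export
generate_observations <- function(config = synth_config(), seed = 1L) {
  set.seed(seed)
  cages <- cage_design(config)
  yr_re <- matrix(stats::rnorm(2 * length(config$years), 0,
                               rep(config$year_sd, each = length(config$years))),
                  ncol = 2)  # [year, species]; col 1 MEFE, col 2 PIMI
  blocks <- unique(cages$block)
  bl_re <- matrix(stats::rnorm(2 * length(blocks), 0,
                               rep(config$block_sd, each = length(blocks))),
                  ncol = 2)
  rownames(bl_re) <- blocks
  nt <- length(config$times_min)
  out <- vector("list", nrow(cages))
  for (i in seq_len(nrow(cages))) {
    cg <- cages[i, ]
    k <- match(cg$year, config$years)
    W <- cg$woodlice; Tt <- cg$warmed
    mu_g <- config$mu_MEFE + yr_re[k, 1] + bl_re[cg$block, 1] +
      config$b_MEFE_T * Tt + config$b_MEFE_W * W + config$b_MEFE_TW * Tt * W
    mu_s <- config$mu_PIMI + yr_re[k, 2] + bl_re[cg$block, 2] +
      config$b_PIMI_T * Tt + config$b_PIMI_W * W + config$b_PIMI_TW * Tt * W
    ng <- if (is.null(config$n_grasshoppers)) cg$stocked else config$n_grasshoppers
    recs <- list()
    # one spider per cage
    recs$spider <- data.frame(
      species = "PIMI", time_min = config$times_min,
      z_cm = round_to(rtnorm0(nt, mu_s, config$sd_PIMI),
                      config$height_resolution))
    recs$grass <- data.frame(
      species = "MEFE", time_min = rep(config$times_min, ng),
      z_cm = round_to(rtnorm0(nt * ng, mu_g, config$sd_MEFE),
                      config$height_resolution))
    if (W == 1) {
      seen <- stats::runif(nt * config$n_woodlice) < config$woodlouse_detect_p
      nsee <- sum(seen)
      if (nsee > 0) {
        recs$wood <- data.frame(
          species = "ONAS",
          time_min = rep(config$times_min, config$n_woodlice)[seen],
          z_cm = round_to(stats::rgamma(nsee, config$woodlouse_shape,
                                        config$woodlouse_rate),
                          config$height_resolution))
      }
    }
    recs <- do.call(rbind, recs)
    recs$cage_id <- cg$cage_id; recs$block <- cg$block; recs$year <- cg$year
    recs$woodlice <- W; recs$warmed <- Tt
    recs$x_cm <- NA_real_; recs$y_cm <- NA_real_
    recs$behavior <- ""; recs$substrate <- ""
    out[[i]] <- recs
  }
  obs <- do.call(rbind, out)
  rownames(obs) <- NULL
  obs[, c("cage_id", "block", "year", "woodlice", "warmed", "species",
          "time_min", "x_cm", "y_cm", "z_cm", "behavior", "substrate")]
}

#' Generate synthetic end-of-season survival counts
#'
#' Survivors per cage are drawn from
#' \code{Binomial(stocked, plogis(surv_alpha + surv_beta_A * A))}, with
#' \code{A} the cage's overlap-based attack rate.
#'
#' @param summaries Cage-summary data frame (from [summarize_cages()]) with
#'   columns \code{cage_id}, \code{year} and \code{A}.
#' @param config A \code{"synth_config"}.
#' @param seed Integer seed.
#' @return Data frame with columns \code{cage_id}, \code{stocked},
#'   \code{survivors}.
#' @export
generate_survival <- function(summaries, config = synth_config(), seed = 1L) {
  set.seed(seed)
  stocked <- config$stocked_by_year[match(summaries$year, config$years)]
  p <- stats::plogis(config$surv_alpha + config$surv_beta_A * summaries$A)
  data.frame(cage_id = summaries$cage_id, stocked = stocked,
             survivors = stats::rbinom(nrow(summaries), stocked, p))
}

#' Simulate a full synthetic cage experiment
#'
#' Convenience wrapper: generates observations, summarises cages (per-cage
#' mean heights and attack rates) and draws survival.
#'
#' @param config A \code{"synth_config"}.
#' @param seed Integer seed (observations use \code{seed}, survival
#'   \code{seed + 1}).
#' @return List with elements \code{observations} and \code{cages} (cage
#'   summary including \code{survivors} and \code{stocked}).
#' @export
simulate_experiment <- function(config = synth_config(), seed = 1L) {
  obs <- generate_observations(config, seed)
  cages <- summarize_cages(obs)
  surv <- generate_survival(cages, config, seed + 1L)
  cages$stocked <- surv$stocked[match(cages$cage_id, surv$cage_id)]
  cages$survivors <- surv$survivors[match(cages$cage_id, surv$cage_id)]
  list(observations = obs, cages = cages)
}
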