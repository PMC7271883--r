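# Plain-text interchange formats for observations and fitted domains.

#' Read a behavioural observation table
#'
#' Reads a CSV with header
#' \code{cage_id,block,year,woodlice,warmed,species,time_min,x_cm,y_cm,z_cm,behavior,substrate}
#' (booleans coded 0/1; \code{x_cm}/\code{y_cm} may be empty) and validates
#' the basic record invariants: heights non-negative, times within a day,
#' species codes among PIMI/MEFE/ONAS.
#'
#' @param file Path to the CSV file.
#' @return A data frame of observation records.
#' @export
read_observations <- function(file) {
  obs <- utils::read.csv(file, stringsAsFactors = FALSE)
  needed <- c("cage_id", "block", "year", "woodlice", "warmed", "species",
              "time_min", "z_cm")
  missing <- setdiff(needed, names(obs))
  if (length(missing))
    stop("observation file lacks columns: ", paste(missing, collapse = ", "))
  validate_observations(obs)
  obs
}

validate_observations <- function(obs) {
  if (any(!is.finite(obs$z_cm)) || any(obs$z_cm < 0))
    stop("invalid records: heights must be finite and >= 0")
  if (any(obs$time_min < 0 | obs$time_min >= 1440))
    stop("invalid records: time_min must lie in [0, 1440)")
  bad <- setdiff(unique(obs$species), c("PIMI", "MEFE", "ONAS"))
  if (length(bad))
    stop("invalid records: unknown species code(s) ", paste(bad, collapse = ", "))
  invisible(obs)
}

#' Write observation records to CSV
#'
#' @param obs Observation data frame (see [read_observations()] for the schema).
#' @param file Output path.
#' @export
write_observations <- function(obs, file) {
  utils::write.csv(obs, file, row.names = FALSE, quote = FALSE, na = "")
}

#' Write fitted habitat domains to CSV
#'
#' Columns: \code{species,family,mu,sigma,shape,rate,n_obs}.
#'
#' @param domains A list of \code{"habitat_domain"} objects.
#' @param file Output path.
#' @export
write_domains <- function(domains, file) {
  if (inherits(domains, "habitat_domain")) domains <- list(domains)
  df <- do.call(rbind, lapply(domains, function(d)
    data.frame(species = d$species, family = d$family, mu = d$mu,
               sigma = d$sigma, shape = d$shape, rate = d$rate,
               n_obs = d$n_obs)))
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE, na = "")
}

#' Read fitted habitat domains from CSV
#'
#' @param file Path to a CSV written by [write_domains()].
#' @return A named list of \code{"habitat_domain"} objects (names are
#'   species codes).
#' @export
read_domains <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    if (r$family == "gamma") {
      habitat_domain(r$species, "gamma", shape = r$shape, rate = r$rate,
                     n_obs = r$n_obs)
    } else {
      habitat_domain(r$species, "normal", mu = r$mu, sigma = r$sigma,
                     n_obs = r$n_obs)
    }
  })
  names(out) <- df$species
  out
}
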