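#' Convert buoyant weight to dry skeletal weight
#'
#' Hydrostatic weighing: a submerged aragonite skeleton of dry mass
#' \eqn{W_d} has buoyant weight \eqn{W_b = W_d (1 - \rho_{sw}/\rho_{arag})},
#' so \eqn{W_d = W_b / (1 - \rho_{sw}/\rho_{arag})}. Defaults are the
#' conventional seawater (1.023 g cm^-3) and aragonite (2.93 g cm^-3)
#' densities.
#'
#' @param buoyant buoyant weight, g (non-negative).
#' @param seawater_density,aragonite_density g cm^-3; seawater must be
#'   strictly below aragonite.
#' @return dry weight, g.
#' @export
buoyant_to_dry_weight <- function(buoyant, seawater_density = 1.023,
                                  aragonite_density = 2.93) {
  if (seawater_density <= 0 || seawater_density >= aragonite_density)
    stop("need 0 < seawater density < aragonite density")
  if (any(buoyant < 0)) stop("buoyant weight must be non-negative")
  buoyant / (1 - seawater_density / aragonite_density)
}

#' @rdname buoyant_to_dry_weight
#' @param dry dry skeletal weight, g.
#' @export
dry_to_buoyant_weight <- function(dry, seawater_density = 1.023,
                                  aragonite_density = 2.93) {
  if (seawater_density <= 0 || seawater_density >= aragonite_density)
    stop("need 0 < seawater density < aragonite density")
  dry * (1 - seawater_density / aragonite_density)
}

#' Season of a growth interval
#'
#' Assigns each interval an upwelling-cycle label from its midpoint date:
#' midpoints in the non-upwelling months (default March-September) are
#' \code{"non_upwelling"}, the rest \code{"upwelling"}; intervals longer
#' than \code{annual_cutoff} years span both seasons and are labelled
#' \code{"annual"}. The month mapping is configurable because the seasonal
#' labelling conventions differ among regional studies; the default labels
#' the higher-calcification months non-upwelling.
#'
#' @param start,end interval \code{Date}s.
#' @param non_upwelling_months integer months of the non-upwelling season.
#' @param annual_cutoff interval length (years) above which the label is
#'   \code{"annual"} (default 0.75).
#' @return character label.
#' @export
season_of_interval <- function(start, end, non_upwelling_months = 3:9,
                               annual_cutoff = 0.75) {
  dt <- as.numeric(end - start) / 365.25
  if (dt <= 0) stop("interval must have positive length")
  if (dt > annual_cutoff) return("annual")
  mid <- start + as.numeric(end - start) / 2
  m <- as.integer(format(mid, "%m"))
  if (m %in% non_upwelling_months) "non_upwelling" else "upwelling"
}

#' Calcification rate over one growth interval
#'
#' The change in dry weight between two measurements, standardised by the
#' mean planar surface area over the interval and by its length:
#' \eqn{rate = \Delta W_d / \bar{A} / \Delta t} in g CaCO3 cm^-2 yr^-1.
#'
#' @param w_start,w_end dry weights, g.
#' @param area_start,area_end planar areas, cm^2 (positive).
#' @param dt_years interval length in years (positive).
#' @return rate, g CaCO3 cm^-2 yr^-1.
#' @export
interval_calcification_rate <- function(w_start, w_end, area_start, area_end,
                                        dt_years) {
  if (any(dt_years <= 0)) stop("interval length must be positive")
  mean_area <- (area_start + area_end) / 2
  if (any(mean_area <= 0)) stop("mean planar area must be positive")
  (w_end - w_start) / mean_area / dt_years
}

#' Per-interval calcification estimates from an out-plant table
#'
#' Converts each coral's consecutive buoyant-weight observations into
#' interval calcification rates: buoyant weights are inverted to dry
#' weights, interval rates computed with
#' \code{\link{interval_calcification_rate}}, and each interval assigned a
#' season label via \code{\link{season_of_interval}}.
#'
#' @param outplants out-plant data.frame (see \code{\link{read_outplants}}).
#' @param lib rate library (supplies the weighing densities).
#' @param non_upwelling_months months defining the non-upwelling season.
#' @return data.frame: coral_id, site, gulf, start, end, season, dt_years,
#'   rate.
#' @export
outplant_calcification <- function(outplants, lib = default_rate_library(),
                                   non_upwelling_months = 3:9) {
  sw <- lib$densities$seawater_weighing
  ar <- lib$densities$aragonite
  res <- list()
  for (id in unique(outplants$coral_id)) {
    rec <- outplants[outplants$coral_id == id, , drop = FALSE]
    rec <- rec[order(rec$date), , drop = FALSE]
    dry <- buoyant_to_dry_weight(rec$buoyant_weight_g, sw, ar)
    n <- nrow(rec)
    for (j in seq_len(n - 1L)) {
      dt <- as.numeric(rec$date[j + 1L] - rec$date[j]) / 365.25
      res[[length(res) + 1L]] <- data.frame(
        coral_id = id, site = rec$site[1L], gulf = rec$gulf[1L],
        start = rec$date[j], end = rec$date[j + 1L],
        season = season_of_interval(rec$date[j], rec$date[j + 1L],
                                    non_upwelling_months),
        dt_years = dt,
        rate = interval_calcification_rate(dry[j], dry[j + 1L],
                                           rec$planar_area_cm2[j],
                                           rec$planar_area_cm2[j + 1L], dt),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

#' Aggregate calcification estimates
#'
#' Arithmetic mean and standard error of interval rates by grouping
#' columns (e.g. \code{"gulf"} or \code{c("gulf", "season")}). A group with
#' a single estimate reports \code{se = 0} and \code{se_defined = FALSE}.
#' Gulf-level annual means are the values fed to gross production.
#'
#' @param estimates data.frame from \code{\link{outplant_calcification}}.
#' @param by character vector of grouping column names.
#' @return data.frame with the grouping columns, \code{mean}, \code{se},
#'   \code{n}, \code{se_defined}.
#' @export
aggregate_rates <- function(estimates, by = "gulf") {
  if (nrow(estimates) == 0L) stop("no estimates to aggregate")
  if (!all(by %in% names(estimates)))
    stop("unknown grouping column(s): ",
         paste(setdiff(by, names(estimates)), collapse = ", "))
  key <- do.call(paste, c(estimates[by], sep = "\r"))
  uk <- unique(key)
  grp <- estimates[match(uk, key), by, drop = FALSE]
  stat <- t(vapply(uk, function(k) {
    r <- estimates$rate[key == k]
    n <- length(r)
    c(mean = mean(r),
      se = if (n > 1L) stats::sd(r) / sqrt(n) else 0,
      n = n)
  }, numeric(3)))
  res <- cbind(grp, as.data.frame(stat))
  res$se_defined <- res$n > 1L
  rownames(res) <- NULL
  res
}
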