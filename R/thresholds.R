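#' Fit a coral-cover threshold model
#'
#' Linear mixed-effects model of a budget response (net production or
#' accretion potential) on coral cover (in percent, 0-100) and gulf, with
#' site as a random intercept — the structure used to derive gulf-level
#' cover thresholds. Fitting uses \code{nlme::lme}; when the site variance
#' is degenerate (e.g. noiseless synthetic data) the model reduces to
#' ordinary least squares on the same fixed effects. Prediction is affine
#' in cover; thresholds use fixed effects only (population-level).
#'
#' @param budget budget data.frame (one row per transect) with columns
#'   \code{coral_cover_pct}, \code{gulf}, \code{site}, and the response.
#' @param response response column name, e.g. \code{"net"} or
#'   \code{"rap_mm_yr"}.
#' @return object of class \code{cover_model}: list with \code{response},
#'   \code{intercept} (reference gulf), \code{gulf_offset} (named, 0 for
#'   the reference), \code{cover_slope} (response units per percent
#'   cover), \code{site_sd} (random-intercept SD, 0 under the OLS
#'   fallback), \code{slope_se}, and the underlying \code{fit}.
#' @export
fit_cover_model <- function(budget, response = "net") {
  if (!response %in% names(budget))
    stop("response column '", response, "' not in budget table")
  d <- data.frame(y = budget[[response]],
                  cover = budget$coral_cover_pct,
                  gulf = factor(budget$gulf),
                  site = factor(budget$site))
  if (length(unique(d$cover)) < 2L)
    stop("coral cover is constant; threshold model is rank-deficient")
  multi_gulf <- nlevels(d$gulf) > 1L
  fixed <- if (multi_gulf) y ~ cover + gulf else y ~ cover
  fit <- tryCatch(
    nlme::lme(fixed, random = ~ 1 | site, data = d, method = "REML"),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- stats::lm(fixed, data = d)
    cf <- stats::coef(fit)
    site_sd <- 0
    slope_se <- summary(fit)$coefficients["cover", "Std. Error"]
  } else {
    cf <- nlme::fixef(fit)
    vc <- nlme::VarCorr(fit)
    site_sd <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    if (!is.finite(site_sd)) site_sd <- 0
    slope_se <- summary(fit)$tTable["cover", "Std.Error"]
  }
  offs <- stats::setNames(rep(0, nlevels(d$gulf)), levels(d$gulf))
  if (multi_gulf) {
    for (g in levels(d$gulf)[-1L]) {
      nm <- paste0("gulf", g)
      if (nm %in% names(cf)) offs[g] <- cf[[nm]]
    }
  }
  structure(list(response = response,
                 intercept = unname(cf[["(Intercept)"]]),
                 gulf_offset = offs,
                 cover_slope = unname(cf[["cover"]]),
                 slope_se = unname(slope_se),
                 site_sd = site_sd,
                 fit = fit),
            class = "cover_model")
}

#' Predict from a cover model
#'
#' Population-level (fixed-effects) prediction:
#' intercept + gulf offset + slope x cover.
#'
#' @param model a \code{cover_model}.
#' @param gulf gulf label; must be known to the model (any label is
#'   accepted for single-gulf models, with zero offset).
#' @param cover_pct coral cover in percent.
#' @return predicted response.
#' @export
predict_cover_model <- function(model, gulf, cover_pct) {
  off <- if (gulf %in% names(model$gulf_offset))
    model$gulf_offset[[gulf]] else 0
  model$intercept + off + model$cover_slope * cover_pct
}

#' Solve for the coral-cover threshold reaching a target response
#'
#' Inverts the affine cover model: the cover (percent) at which the
#' predicted response equals \code{target}. Thresholds above 100\% cover
#' are flagged \code{unattainable} — present-day production cannot reach
#' the target even at full coral cover.
#'
#' @param model a \code{cover_model}.
#' @param gulf gulf label.
#' @param target target response value (e.g. 0 for a net-positive budget,
#'   or a sea-level-rise rate in mm yr^-1 for an accretion model).
#' @return list with \code{required_cover_pct} and \code{unattainable}.
#' @export
solve_cover_threshold <- function(model, gulf, target) {
  if (model$cover_slope == 0)
    stop("cover slope is zero; threshold undefined")
  off <- if (gulf %in% names(model$gulf_offset))
    model$gulf_offset[[gulf]] else 0
  cover <- (target - model$intercept - off) / model$cover_slope
  list(required_cover_pct = cover, unattainable = cover > 100)
}

#' Ordinary least-squares tide-gauge trend
#'
#' Slope of monthly relative sea level (mm) on decimal year, missing
#' months simply omitted (no interpolation) — the standard treatment of
#' PSMSL monthly series.
#'
#' @param series data.frame with \code{year} and \code{level_mm}.
#' @param min_months minimum non-missing months required (default 24).
#' @param se if TRUE, return a list with the trend and its OLS standard
#'   error instead of the bare slope.
#' @return trend in mm yr^-1 (or \code{list(trend, se)}).
#' @export
tide_gauge_trend <- function(series, min_months = 24L, se = FALSE) {
  ok <- is.finite(series$level_mm)
  if (sum(ok) < min_months)
    stop("need at least ", min_months, " non-missing months, have ", sum(ok))
  fit <- stats::lm(level_mm ~ year, data = series[ok, , drop = FALSE])
  slope <- unname(stats::coef(fit)[["year"]])
  if (!se) return(slope)
  list(trend = slope,
       se = summary(fit)$coefficients["year", "Std. Error"])
}

#' Localize a global sea-level-rise projection
#'
#' Scales a global projected rate by the ratio of the locally observed
#' trend to the global observed trend:
#' \code{local = global_rate x local_obs / global_obs}. With the Balboa
#' trend of 1.4 mm yr^-1 and the 20th-century global-mean 1.7 mm yr^-1
#' the factor is ~0.82.
#'
#' @param global_rate projected global rate, mm yr^-1.
#' @param local_obs locally observed trend, mm yr^-1.
#' @param global_obs globally observed trend, mm yr^-1 (default 1.7).
#' @return localized rate, mm yr^-1.
#' @export
localize_projection <- function(global_rate, local_obs, global_obs = 1.7) {
  if (global_obs <= 0) stop("global observed trend must be positive")
  global_rate * local_obs / global_obs
}

#' Standard sea-level scenarios
#'
#' The three IPCC representative concentration pathways with their global
#' end-of-century rise rates (RCP 2.6: 4, RCP 4.5: 7, RCP 8.5: 15 mm
#' yr^-1) localized to the observed trend, plus the "current" scenario at
#' the observed local rate itself.
#'
#' @param local_obs observed local trend, mm yr^-1.
#' @param global_obs observed global trend, mm yr^-1 (default 1.7).
#' @return data.frame with \code{label, global_rate, local_rate}.
#' @export
sea_level_scenarios <- function(local_obs, global_obs = 1.7) {
  glob <- c(current = NA, RCP2.6 = 4, RCP4.5 = 7, RCP8.5 = 15)
  data.frame(label = names(glob), global_rate = unname(glob),
             local_rate = c(local_obs,
                            localize_projection(glob[-1], local_obs,
                                                global_obs)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Threshold / keep-up report over scenarios
#'
#' For each gulf and scenario: the coral cover required for the accretion
#' potential to match the scenario's local rise rate, the observed cover,
#' and the keep-up verdict at the observed cover (inclusive boundary).
#'
#' @param model a \code{cover_model} fitted with an accretion response
#'   (mm yr^-1).
#' @param scenarios data.frame as from \code{\link{sea_level_scenarios}}.
#' @param observed_cover named vector of observed coral cover (percent)
#'   per gulf.
#' @return data.frame: gulf, scenario, local_rate, required_cover_pct,
#'   observed_cover_pct, verdict, unattainable.
#' @export
scenario_report <- function(model, scenarios, observed_cover) {
  out <- list()
  if (nrow(scenarios) == 0L || length(observed_cover) == 0L)
    return(data.frame(gulf = character(), scenario = character(),
                      local_rate = numeric(),
                      required_cover_pct = numeric(),
                      observed_cover_pct = numeric(),
                      verdict = character(), unattainable = logical(),
                      stringsAsFactors = FALSE))
  for (g in names(observed_cover)) {
    for (i in seq_len(nrow(scenarios))) {
      thr <- solve_cover_threshold(model, g, scenarios$local_rate[i])
      pred <- predict_cover_model(model, g, observed_cover[[g]])
      out[[length(out) + 1L]] <- data.frame(
        gulf = g, scenario = scenarios$label[i],
        local_rate = scenarios$local_rate[i],
        required_cover_pct = thr$required_cover_pct,
        observed_cover_pct = observed_cover[[g]],
        verdict = classify_keepup(pred, scenarios$local_rate[i]),
        unattainable = thr$unattainable, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
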