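#' Default per-gulf, per-period benthic cover means
#'
#' Mean category proportions (probability vectors) used by the survey
#' generator, calibrated so transect-mean total coral cover follows the
#' observed trajectories: 81\% declining to 75\% in the Gulf of Panama and
#' 51\% to 39\% in the Gulf of Chiriqui over the five 2016-2018 surveys,
#' with thick algal turfs declining in the GoP (as urchins increase) and
#' dead substrate expanding in the GoC as coral is lost. Pocillopora
#' carries almost all coral cover; massive taxa total 2\%.
#'
#' @param periods ordered period labels (default the five study surveys).
#' @return list \code{gulf -> period -> named probability vector}.
#' @export
default_cover_means <- function(periods = default_periods()) {
  v <- function(Poc, CCA, fine, thick, ma, rub, df, sand)
    c(Pocillopora = Poc, Porites = 1, Pavona = 0.5, Gardineroseris = 0.5,
      CCA = CCA, fine_turf = fine, thick_turf = thick, macroalgae = ma,
      rubble = rub, dead_framework = df, sand = sand) / 100
  gop <- list(v(79, 2, 2, 6, 2, 3, 2, 2),
              v(77.5, 2, 3, 5, 2, 3, 3.5, 2),
              v(76, 2, 4, 4.5, 2, 3, 4.5, 2),
              v(74.5, 2, 5, 4, 2, 3, 5.5, 2),
              v(73, 2, 6, 3, 2, 3, 7, 2))
  goc <- list(v(49, 4, 10, 10, 5, 7, 8, 5),
              v(46, 4, 11, 11, 5, 8, 8, 5),
              v(43, 4, 12, 11.5, 5, 8, 9.5, 5),
              v(40, 4, 12.5, 12, 5, 9, 10.5, 5),
              v(37, 4, 13, 13, 5, 10, 11, 5))
  names(gop) <- names(goc) <- periods
  list(GoP = gop, GoC = goc)
}

#' @rdname synth_config
#' @export
default_periods <- function() {
  c("spring-2016", "autumn-2016", "spring-2017", "autumn-2017",
    "spring-2018")
}

#' Configuration for the synthetic survey generator
#'
#' Bundles every quantity the generator treats as ground truth. Defaults
#' reproduce the study design: three sites per gulf, six 100-point
#' transects per site and period, five survey periods, seasonal
#' Pocillopora calcification truths of 3.1 (non-upwelling) and 2.0
#' (upwelling) g CaCO3 cm^-2 yr^-1 in the GoP and 2.9 / 2.3 in the GoC,
#' urchin densities rising 0.5 to 1.7 ind m^-2 (GoP) and 0.4 to 4.9
#' (GoC), core compaction around 0.62, and a 1.4 mm yr^-1 tide-gauge
#' trend.
#'
#' @param seed integer; one global seed drives independent sub-streams for
#'   each data channel.
#' @param n_sites_per_gulf,n_transects survey design sizes.
#' @param periods ordered survey labels.
#' @param cover_means per-gulf, per-period category probability vectors.
#' @param true_calcification per-gulf named seasonal rates,
#'   g CaCO3 cm^-2 yr^-1.
#' @param urchin_traj per-gulf urchin densities by period, ind m^-2.
#' @param fish_density per-species densities, ind m^-2 (surveyed only in
#'   the final period, as in the field campaign).
#' @param n_corals_per_site out-plants per calcification station.
#' @param outplant_dates measurement dates (two 6-month seasons then one
#'   annual interval).
#' @param compaction_mean,compaction_sd core compaction fraction
#'   distribution.
#' @param sediment_mm_yr per-site sediment contribution to accretion.
#' @param slr_trend tide-gauge trend, mm yr^-1.
#' @param tide_years,tide_start length and start of the monthly series.
#' @param noise list of channel noise scales: \code{weight_sd} (g, per
#'   weight increment), \code{area_sd} (cm^2, between corals),
#'   \code{tide_sd} (mm), \code{tide_seasonal_amp} (mm),
#'   \code{tide_missing} (fraction of months missing).
#' @return validated configuration list of class \code{synth_config}.
#' @export
synth_config <- function(seed = 1L,
                         n_sites_per_gulf = 3L,
                         n_transects = 6L,
                         periods = default_periods(),
                         cover_means = default_cover_means(periods),
                         true_calcification = list(
                           GoP = c(non_upwelling = 3.1, upwelling = 2.0),
                           GoC = c(non_upwelling = 2.9, upwelling = 2.3)),
                         urchin_traj = list(
                           GoP = seq(0.5, 1.7, length.out = length(periods)),
                           GoC = seq(0.4, 4.9, length.out = length(periods))),
                         fish_density = c(Scarus_ghobban = 0.02,
                                          Scarus_rubroviolaceus = 0.005,
                                          Arothron_meleagris = 0.002),
                         n_corals_per_site = 20L,
                         outplant_dates = as.Date(c("2016-03-15",
                                                    "2016-09-15",
                                                    "2017-03-15",
                                                    "2018-03-15")),
                         compaction_mean = 0.62,
                         compaction_sd = 0.05,
                         sediment_mm_yr = 0.4,
                         slr_trend = 1.4,
                         tide_years = 50L,
                         tide_start = 1968,
                         noise = list()) {
  noise_def <- list(weight_sd = 3, area_sd = 5, tide_sd = 25,
                    tide_seasonal_amp = 60, tide_missing = 0.02)
  noise_def[names(noise)] <- noise
  cfg <- list(seed = as.integer(seed), n_sites_per_gulf = n_sites_per_gulf,
              n_transects = n_transects, periods = periods,
              cover_means = cover_means,
              true_calcification = true_calcification,
              urchin_traj = urchin_traj, fish_density = fish_density,
              n_corals_per_site = n_corals_per_site,
              outplant_dates = outplant_dates,
              compaction_mean = compaction_mean,
              compaction_sd = compaction_sd,
              sediment_mm_yr = sediment_mm_yr, slr_trend = slr_trend,
              tide_years = tide_years, tide_start = tide_start,
              noise = noise_def)
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
}

#' @rdname synth_config
#' @param cfg configuration to validate.
#' @export
validate_synth_config <- function(cfg) {
  for (g in c("GoP", "GoC")) {
    if (!g %in% names(cfg$cover_means)) stop("cover_means missing gulf ", g)
    for (p in cfg$periods) {
      pr <- cfg$cover_means[[g]][[p]]
      if (is.null(pr)) stop("cover_means missing period ", p, " for ", g)
      if (any(pr < 0)) stop("negative cover mean in ", g, "/", p)
      if (abs(sum(pr) - 1) > 1e-9)
        stop("cover means for ", g, "/", p, " sum to ", sum(pr), ", not 1")
      if (!all(names(pr) %in% benthic_categories()$all))
        stop("unknown category in cover means for ", g, "/", p)
    }
    if (any(cfg$urchin_traj[[g]] < 0)) stop("negative urchin density")
    if (any(cfg$true_calcification[[g]] < 0)) stop("negative calcification")
  }
  if (any(diff(as.numeric(cfg$outplant_dates)) <= 0))
    stop("out-plant dates must be strictly increasing")
  if (any(cfg$fish_density < 0)) stop("negative fish density")
  if (cfg$compaction_sd < 0 || any(unlist(cfg$noise) < 0))
    stop("noise scales must be non-negative")
  if (cfg$compaction_mean < 0 || cfg$compaction_mean > 1)
    stop("compaction mean must lie in [0, 1]")
  cfg
}

.site_names <- function(cfg, gulf) {
  paste0(gulf, "-S", seq_len(cfg$n_sites_per_gulf))
}

#' Generate point-intercept survey rows
#'
#' For each site, period and transect, draws the 100 point counts from a
#' multinomial over the configured gulf/period category means. Fully
#' deterministic given the config seed.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param points points per transect (default 100).
#' @return survey data.frame (passes
#'   \code{\link{validate_benthic_survey}}).
#' @export
gen_benthic_transects <- function(cfg, points = 100L) {
  set.seed(.substream_seed(cfg$seed, 1L))
  rows <- list()
  for (g in c("GoP", "GoC")) {
    for (s in .site_names(cfg, g)) {
      for (p in cfg$periods) {
        pr <- cfg$cover_means[[g]][[p]]
        for (t in seq_len(cfg$n_transects)) {
          cnt <- as.integer(stats::rmultinom(1L, points, pr))
          rows[[length(rows) + 1L]] <- data.frame(
            site = s, gulf = g, period = p,
            transect_id = paste0("T", t),
            category = names(pr), count = cnt, stringsAsFactors = FALSE)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate coral out-plant weight/area series
#'
#' Per coral: a fixed planar area, an initial dry weight, and dry-weight
#' increments of (true seasonal rate x area x interval length) plus
#' Gaussian noise; weights are emitted as buoyant weights through the
#' hydrostatic relation so the calcification module must invert it. The
#' final (annual) interval grows at the mean of the two seasonal rates.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param lib rate library (weighing densities for the emission step).
#' @return out-plant data.frame (passes \code{\link{read_outplants}}
#'   validation when round-tripped).
#' @export
gen_outplant_series <- function(cfg, lib = default_rate_library()) {
  set.seed(.substream_seed(cfg$seed, 2L))
  sw <- lib$densities$seawater_weighing
  ar <- lib$densities$aragonite
  dates <- cfg$outplant_dates
  nd <- length(dates)
  rows <- list()
  for (g in c("GoP", "GoC")) {
    tc <- cfg$true_calcification[[g]]
    for (s in .site_names(cfg, g)) {
      for (k in seq_len(cfg$n_corals_per_site)) {
        id <- paste0(s, "-C", k)
        area <- max(5, stats::rnorm(1, 30, cfg$noise$area_sd))
        dry <- numeric(nd)
        dry[1] <- max(5, stats::rnorm(1, 20, 2))
        for (j in seq_len(nd - 1L)) {
          dt <- as.numeric(dates[j + 1L] - dates[j]) / 365.25
          season <- season_of_interval(dates[j], dates[j + 1L])
          rate <- if (season == "annual") mean(tc) else tc[[season]]
          inc <- rate * area * dt + stats::rnorm(1, 0, cfg$noise$weight_sd)
          dry[j + 1L] <- dry[j] + max(inc, -0.5 * dry[j])
        }
        rows[[length(rows) + 1L]] <- data.frame(
          coral_id = id, site = s, gulf = g, date = dates,
          buoyant_weight_g = dry_to_buoyant_weight(dry, sw, ar),
          planar_area_cm2 = area, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate urchin and fish belt-transect densities
#'
#' Urchin densities follow the configured per-gulf trajectory with
#' Poisson counting noise over a 25 m^2 belt; fish are surveyed only in
#' the final period (100 m^2 belts) with Poisson noise around the
#' configured species densities, matching the field design in which fish
#' surveys were done once and extrapolated.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return grazer data.frame (long; passes \code{\link{read_grazers}}
#'   validation when round-tripped).
#' @export
gen_grazer_densities <- function(cfg) {
  set.seed(.substream_seed(cfg$seed, 3L))
  rows <- list()
  fish_period <- cfg$periods[length(cfg$periods)]
  for (g in c("GoP", "GoC")) {
    for (s in .site_names(cfg, g)) {
      for (pi in seq_along(cfg$periods)) {
        p <- cfg$periods[pi]
        lam <- cfg$urchin_traj[[g]][pi]
        for (t in seq_len(cfg$n_transects)) {
          rows[[length(rows) + 1L]] <- data.frame(
            transect_id = paste0("T", t), site = s, gulf = g, period = p,
            taxon = "Diadema_mexicanum",
            density_ind_m2 = stats::rpois(1L, lam * 25) / 25,
            stringsAsFactors = FALSE)
          if (p == fish_period) {
            for (sp in names(cfg$fish_density)) {
              rows[[length(rows) + 1L]] <- data.frame(
                transect_id = paste0("T", t), site = s, gulf = g,
                period = p, taxon = sp,
                density_ind_m2 =
                  stats::rpois(1L, cfg$fish_density[[sp]] * 100) / 100,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate per-site core compaction summaries
#'
#' Compaction fractions are Gaussian draws around the configured mean,
#' clamped to (0, 1]; porosity is one minus compaction by construction,
#' and each site carries the configured sediment contribution.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return core data.frame with \code{site, compaction_fraction,
#'   sediment_mm_yr, porosity}.
#' @export
gen_cores <- function(cfg) {
  set.seed(.substream_seed(cfg$seed, 4L))
  sites <- c(.site_names(cfg, "GoP"), .site_names(cfg, "GoC"))
  cx <- pmin(pmax(stats::rnorm(length(sites), cfg$compaction_mean,
                               cfg$compaction_sd), 0.01), 1)
  data.frame(site = sites, compaction_fraction = cx,
             sediment_mm_yr = cfg$sediment_mm_yr, porosity = 1 - cx,
             stringsAsFactors = FALSE)
}

#' Generate a monthly tide-gauge series
#'
#' Monthly levels are intercept + trend x elapsed years + an annual
#' harmonic + Gaussian noise, with a configured fraction of months missing
#' (kept as NA, as after parsing a sentinel-flagged PSMSL file).
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return data.frame with \code{year} (decimal) and \code{level_mm}.
#' @export
gen_tide_gauge <- function(cfg) {
  set.seed(.substream_seed(cfg$seed, 5L))
  months <- seq_len(12L * cfg$tide_years)
  year <- cfg$tide_start + (months - 0.5) / 12
  frac <- ((months - 0.5) / 12) %% 1
  level <- 6900 + cfg$slr_trend * (year - cfg$tide_start) +
    cfg$noise$tide_seasonal_amp * sin(2 * pi * frac) +
    stats::rnorm(length(months), 0, cfg$noise$tide_sd)
  miss <- stats::runif(length(months)) < cfg$noise$tide_missing
  level[miss] <- NA_real_
  data.frame(year = year, level_mm = level)
}

#' Write a tide-gauge series in PSMSL-style monthly text
#'
#' @param series data.frame with \code{year} and \code{level_mm} (NA =
#'   missing month).
#' @param path output path.
#' @param sentinel value written for missing months (default -99999).
#' @return \code{path}, invisibly.
#' @export
write_tide_gauge <- function(series, path, sentinel = -99999) {
  lev <- ifelse(is.na(series$level_mm), sentinel,
                round(series$level_mm))
  writeLines(sprintf(" %.4f; %6d; 0; 000", series$year, as.integer(lev)),
             path)
  invisible(path)
}

#' Generate the complete synthetic dataset
#'
#' All five data channels from one config (and hence one seed): survey,
#' out-plants, grazers, cores, and tide gauge.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return named list of data.frames.
#' @export
synth_dataset <- function(cfg = synth_config()) {
  list(survey = gen_benthic_transects(cfg),
       outplants = gen_outplant_series(cfg),
       grazers = gen_grazer_densities(cfg),
       cores = gen_cores(cfg),
       tide = gen_tide_gauge(cfg))
}

#' Write the synthetic dataset to a directory
#'
#' Emits the exact on-disk formats the readers expect: \code{survey.csv},
#' \code{outplants.csv}, \code{grazers.csv}, \code{cores.csv} and
#' \code{tide.txt} (PSMSL-style).
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param dir output directory (created if needed).
#' @return invisible named vector of file paths.
#' @export
write_synth_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- synth_dataset(cfg)
  paths <- c(survey = file.path(dir, "survey.csv"),
             outplants = file.path(dir, "outplants.csv"),
             grazers = file.path(dir, "grazers.csv"),
             cores = file.path(dir, "cores.csv"),
             tide = file.path(dir, "tide.txt"))
  utils::write.csv(d$survey, paths["survey"], row.names = FALSE)
  utils::write.csv(d$outplants, paths["outplants"], row.names = FALSE)
  utils::write.csv(d$grazers, paths["grazers"], row.names = FALSE)
  utils::write.csv(d$cores[, c("site", "compaction_fraction",
                               "sediment_mm_yr")],
                   paths["cores"], row.names = FALSE)
  write_tide_gauge(d$tide, paths["tide"])
  invisible(paths)
}
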