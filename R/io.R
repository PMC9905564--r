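#' Benthic category vocabulary
#'
#' The closed vocabulary of point-intercept categories: the four recorded
#' coral taxa, crustose coralline algae, and the non-calcifying substrate
#' classes.
#'
#' @return list with elements \code{coral} (taxon names) and \code{all}
#'   (full vocabulary).
#' @export
benthic_categories <- function() {
  coral <- c("Pocillopora", "Porites", "Pavona", "Gardineroseris")
  list(coral = coral,
       all = c(coral, "CCA", "fine_turf", "thick_turf", "macroalgae",
               "rubble", "dead_framework", "sand"))
}

#' Read a point-intercept benthic survey
#'
#' Expects CSV columns \code{site, gulf, period, transect_id, category,
#' count}. Every row is validated: gulf in \{GoP, GoC\}, category in the
#' closed vocabulary, counts non-negative integers, and the counts of each
#' (site, period, transect_id) must sum to \code{points} (the survey design
#' records one benthic category under each of 100 marks per 25-m transect).
#'
#' @param path CSV file path.
#' @param points declared points per transect (default 100).
#' @return data.frame of validated survey rows.
#' @export
read_benthic_survey <- function(path, points = 100L) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_benthic_survey(df, points = points)
}

#' Validate a benthic survey table
#'
#' @param df survey data.frame (see \code{\link{read_benthic_survey}}).
#' @param points declared points per transect.
#' @return the validated data.frame.
#' @export
validate_benthic_survey <- function(df, points = 100L) {
  need <- c("site", "gulf", "period", "transect_id", "category", "count")
  if (!all(need %in% names(df)))
    stop("survey table must have columns: ", paste(need, collapse = ", "))
  bad <- which(!df$gulf %in% c("GoP", "GoC"))
  if (length(bad))
    stop("row ", bad[1], ": unknown gulf '", df$gulf[bad[1]], "'")
  vocab <- benthic_categories()$all
  bad <- which(!df$category %in% vocab)
  if (length(bad))
    stop("row ", bad[1], ": unknown benthic category '",
         df$category[bad[1]], "'")
  bad <- which(!is.finite(df$count) | df$count < 0 |
                 df$count != round(df$count))
  if (length(bad))
    stop("row ", bad[1], ": count must be a non-negative integer")
  key <- interaction(df$site, df$period, df$transect_id, drop = TRUE)
  tot <- tapply(df$count, key, sum)
  off <- which(tot != points)
  if (length(off))
    stop("transect ", names(tot)[off[1]], " has ", tot[off[1]],
         " points, expected ", points)
  df
}

#' Read coral out-plant buoyant-weight records
#'
#' CSV columns: \code{coral_id, site, gulf, date (YYYY-MM-DD),
#' buoyant_weight_g, planar_area_cm2}. Dates must be strictly increasing and
#' weights/areas strictly positive within each coral.
#'
#' @param path CSV file path.
#' @return data.frame with \code{date} parsed to \code{Date}.
#' @export
read_outplants <- function(path) {
  if (!file.exists(path)) stop("out-plant file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("coral_id", "site", "gulf", "date",
            "buoyant_weight_g", "planar_area_cm2")
  if (!all(need %in% names(df)))
    stop("out-plant table must have columns: ", paste(need, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparsable out-plant date")
  if (any(df$buoyant_weight_g <= 0) || any(df$planar_area_cm2 <= 0))
    stop("out-plant weights and areas must be strictly positive")
  for (id in unique(df$coral_id)) {
    d <- df$date[df$coral_id == id]
    if (is.unsorted(d, strictly = TRUE))
      stop("dates for coral ", id, " are not strictly increasing")
    if (length(d) < 2L)
      stop("coral ", id, " has fewer than 2 observations")
  }
  df
}

#' Read grazer (urchin and fish) belt-transect densities
#'
#' CSV columns: \code{transect_id, site, gulf, period, taxon,
#' density_ind_m2}. Taxa are free-form but the budget model recognises
#' \code{Diadema_mexicanum}, the parrotfish species named in the rate
#' library, and \code{Arothron_meleagris}.
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_grazers <- function(path) {
  if (!file.exists(path)) stop("grazer file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transect_id", "site", "gulf", "period", "taxon", "density_ind_m2")
  if (!all(need %in% names(df)))
    stop("grazer table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(df$density_ind_m2) | df$density_ind_m2 < 0))
    stop("grazer densities must be non-negative")
  df
}

#' Read per-site reef-core summaries
#'
#' CSV columns: \code{site, compaction_fraction, sediment_mm_yr}. The
#' compaction fraction is the core-averaged solid fraction below the open
#' surface framework (top 2 m excluded before summarising); porosity is its
#' complement.
#'
#' @param path CSV file path.
#' @return data.frame with an added \code{porosity} column.
#' @export
read_cores <- function(path) {
  if (!file.exists(path)) stop("core file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "compaction_fraction", "sediment_mm_yr")
  if (!all(need %in% names(df)))
    stop("core table must have columns: ", paste(need, collapse = ", "))
  if (any(df$compaction_fraction < 0 | df$compaction_fraction > 1))
    stop("compaction fractions must lie in [0, 1]")
  if (any(df$sediment_mm_yr < 0)) stop("sediment rates must be non-negative")
  df$porosity <- 1 - df$compaction_fraction
  df
}

#' Read a PSMSL-style monthly tide-gauge series
#'
#' Parses the monthly relative-sea-level text format: semicolon-separated
#' fields \code{decimal_year; level_mm; days_missing; flag}, one line per
#' month, with the sentinel \code{-99999} marking a missing month. Missing
#' months are kept in the series with \code{level_mm = NA}, never zero.
#'
#' @param path text file path.
#' @param sentinel missing-value sentinel (default -99999).
#' @return data.frame with columns \code{year} (decimal) and \code{level_mm}.
#' @export
read_tide_gauge <- function(path, sentinel = -99999) {
  if (!file.exists(path)) stop("tide-gauge file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, ";", fixed = TRUE)
  if (any(vapply(parts, length, 0L) < 2L))
    stop("unparsable tide-gauge line: '",
         lines[which(vapply(parts, length, 0L) < 2L)[1]], "'")
  year <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  level <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(year) || anyNA(level))
    stop("unparsable numeric field in tide-gauge file")
  if (is.unsorted(year, strictly = TRUE))
    stop("tide-gauge months are not strictly increasing (duplicate or ",
         "out-of-order month)")
  level[level == sentinel] <- NA_real_
  data.frame(year = year, level_mm = level)
}

#' Write / read the per-transect budget table
#'
#' One row per transect with gross production, the six bioerosion
#' components, total bioerosion, net production and accretion potential.
#' Values are written with fixed 6-decimal formatting so a rewrite of the
#' same results is byte-identical.
#'
#' @param results budget data.frame (see \code{\link{reef_budget}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_budget_table <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) sprintf("%.6f", x))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_budget_table
#' @export
read_budget_table <- function(path) {
  if (!file.exists(path)) stop("budget file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
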