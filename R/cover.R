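#' Default benthic category-to-component mapping
#'
#' Maps point-intercept categories onto the substrate components entering
#' the bioerosion equations. Live coral (L) is the union of coral taxa;
#' thick algal turf (T) its own category; "dead substrate" (D), grazed and
#' bored by urchins and macroborers, comprises dead framework plus
#' fine algal turfs (turf-veneered bare carbonate); rubble (RC) enters only
#' the boring-sponge term, and standing dead framework (FC) is the
#' framework component of that term. Sand and fleshy macroalgae take part
#' in no erosive term.
#'
#' @return named list of category vectors.
#' @export
default_category_map <- function() {
  list(live      = benthic_categories()$coral,
       thick_turf = "thick_turf",
       dead      = c("dead_framework", "fine_turf"),
       rubble    = "rubble",
       framework = "dead_framework")
}

#' Summarise a survey into per-transect cover profiles
#'
#' Converts validated point counts into proportional covers: one row per
#' transect with a fraction column per benthic category plus the derived
#' substrate components \code{L} (live coral), \code{T_turf} (thick turf),
#' \code{D_dead} (dead substrate), \code{RC} (rubble), \code{FC} (standing
#' framework) and \code{coral_cover_pct}. Fractions sum to 1 per transect.
#'
#' @param survey validated survey data.frame.
#' @param points points per transect used for the survey (default 100).
#' @param map category mapping, see \code{\link{default_category_map}}.
#' @return wide data.frame, one row per (site, period, transect).
#' @export
cover_profiles <- function(survey, points = 100L, map = default_category_map()) {
  vocab <- benthic_categories()$all
  key <- paste(survey$site, survey$period, survey$transect_id, sep = "\r")
  ids <- !duplicated(key)
  prof <- data.frame(site = survey$site[ids], gulf = survey$gulf[ids],
                     period = survey$period[ids],
                     transect_id = survey$transect_id[ids],
                     stringsAsFactors = FALSE)
  ukey <- key[ids]
  for (cat in vocab) {
    sel <- survey$category == cat
    cnt <- tapply(survey$count[sel], key[sel], sum)
    prof[[cat]] <- as.numeric(cnt[ukey])
    prof[[cat]][is.na(prof[[cat]])] <- 0
    prof[[cat]] <- prof[[cat]] / points
  }
  rowsum_cat <- function(cats) {
    if (length(cats) == 1L) prof[[cats]] else rowSums(prof[, cats, drop = FALSE])
  }
  prof$L <- rowsum_cat(map$live)
  prof$T_turf <- rowsum_cat(map$thick_turf)
  prof$D_dead <- rowsum_cat(map$dead)
  prof$RC <- rowsum_cat(map$rubble)
  prof$FC <- rowsum_cat(map$framework)
  prof$coral_cover_pct <- 100 * prof$L
  prof
}
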