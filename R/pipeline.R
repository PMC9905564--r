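#' Broadcast fish densities surveyed in one period to all periods
#'
#' Fish assemblages were only surveyed once (spring 2018); the budget model
#' assumes those densities held across the study and fills them
#' forward/backward to every survey period that lacks fish rows. Added rows
#' carry \code{extrapolated = TRUE} so their provenance stays visible in
#' the output.
#'
#' @param grazers grazer density table (see \code{\link{read_grazers}}).
#' @param fish_taxa taxa treated as fish (default: the two parrotfish and
#'   the pufferfish).
#' @param source_period period whose fish densities are broadcast.
#' @return grazer table with an \code{extrapolated} column.
#' @export
broadcast_fish_densities <- function(grazers,
                                     fish_taxa = c("Scarus_ghobban",
                                                   "Scarus_rubroviolaceus",
                                                   "Arothron_meleagris"),
                                     source_period = "spring-2018") {
  if (!"extrapolated" %in% names(grazers)) grazers$extrapolated <- FALSE
  src <- grazers[grazers$taxon %in% fish_taxa &
                   grazers$period == source_period, , drop = FALSE]
  if (nrow(src) == 0L) return(grazers)
  add <- list()
  for (p in setdiff(unique(grazers$period), source_period)) {
    measured <- grazers$taxon %in% fish_taxa & grazers$period == p
    if (any(measured)) next
    f <- src
    f$period <- p
    f$extrapolated <- TRUE
    add[[p]] <- f
  }
  rbind(grazers, do.call(rbind, add))
}

#' Pivot grazer densities to one row per transect
#'
#' @param grazers grazer table (long), ideally after
#'   \code{\link{broadcast_fish_densities}}.
#' @return data.frame with one row per (site, period, transect) and one
#'   density column per taxon, plus \code{fish_extrapolated}.
#' @export
grazers_wide <- function(grazers) {
  if (!"extrapolated" %in% names(grazers)) grazers$extrapolated <- FALSE
  key <- paste(grazers$site, grazers$period, grazers$transect_id, sep = "\r")
  uk <- unique(key)
  out <- grazers[match(uk, key),
                 c("site", "gulf", "period", "transect_id"), drop = FALSE]
  for (tx in unique(grazers$taxon)) {
    sel <- grazers$taxon == tx
    d <- tapply(grazers$density_ind_m2[sel], key[sel], sum)
    out[[tx]] <- as.numeric(d[uk])
    out[[tx]][is.na(out[[tx]])] <- 0
  }
  fx <- tapply(grazers$extrapolated & grazers$taxon != "Diadema_mexicanum",
               key, any)
  out$fish_extrapolated <- as.logical(fx[uk])
  rownames(out) <- NULL
  out
}

#' Per-transect carbonate budget and accretion potential
#'
#' Assembles the full budget for every transect: gross production from the
#' cover profile and taxon rates; the six bioerosion components; total
#' bioerosion and net production; then the porosity-corrected framework
#' density from the site's core summary and the accretion potentials. The
#' identity \code{net = gross - (sum of components)} holds exactly by
#' construction.
#'
#' @param cover cover profiles (see \code{\link{cover_profiles}}).
#' @param grazers grazer density table (long); fish densities are broadcast
#'   across periods first.
#' @param cores per-site core summaries (see \code{\link{read_cores}}); a
#'   site without a core uses compaction 1 (pure framework density) and the
#'   library's default sediment rate.
#' @param lib rate library.
#' @param micro_mode microbioerosion mode (\code{"flat"} or
#'   \code{"scaled"}).
#' @return budget data.frame, one row per transect.
#' @export
reef_budget <- function(cover, grazers, cores = NULL,
                        lib = default_rate_library(),
                        micro_mode = "flat") {
  gw <- grazers_wide(broadcast_fish_densities(grazers))
  idx <- match(paste(cover$site, cover$period, cover$transect_id, sep = "\r"),
               paste(gw$site, gw$period, gw$transect_id, sep = "\r"))
  dens <- function(tx) {
    v <- if (tx %in% names(gw)) gw[[tx]][idx] else rep(NA_real_, nrow(cover))
    v[is.na(v)] <- 0
    v
  }
  urchin <- dens("Diadema_mexicanum")
  fish <- data.frame(Scarus_ghobban = dens("Scarus_ghobban"),
                     Scarus_rubroviolaceus = dens("Scarus_rubroviolaceus"))

  out <- cover[, c("site", "gulf", "period", "transect_id",
                   "coral_cover_pct"), drop = FALSE]
  out$gross <- gross_production(cover, lib)
  out$macroborer <- macroborer_rate(cover, lib)
  out$microborer <- microborer_rate(cover, lib, micro_mode)
  out$sponge <- sponge_rate(cover, lib)
  out$urchin <- urchin_rate(cover, urchin, lib)
  out$parrotfish <- parrotfish_rate(fish, lib)
  out$puffer <- puffer_rate(dens("Arothron_meleagris"), lib)
  comp <- c("macroborer", "microborer", "sponge", "urchin", "parrotfish",
            "puffer")
  out$total_bioerosion <- total_bioerosion(out[comp])
  out$net <- net_production(out$gross, out$total_bioerosion)

  if (is.null(cores)) {
    compaction <- rep(1, nrow(out))
    sediment <- rep(lib$sediment_mm_yr, nrow(out))
  } else {
    m <- match(out$site, cores$site)
    compaction <- ifelse(is.na(m), 1, cores$compaction_fraction[m])
    sediment <- ifelse(is.na(m), lib$sediment_mm_yr, cores$sediment_mm_yr[m])
  }
  out$rho_x <- framework_density(compaction, lib$densities$D_f,
                                 lib$densities$D_w)
  out$sediment_mm_yr <- sediment
  out$rap_mm_yr <- reef_accretion_potential(out$net, out$rho_x, sediment)
  out$millennial_rap_mm_yr <- millennial_rap(out$net, lib$densities$D_f,
                                             sediment)
  out$fish_extrapolated <- if ("fish_extrapolated" %in% names(gw))
    as.logical(gw$fish_extrapolated[idx]) else FALSE
  out$fish_extrapolated[is.na(out$fish_extrapolated)] <- FALSE
  out
}

#' Run the full budget pipeline on a dataset
#'
#' Convenience wrapper: validates a survey table, builds cover profiles,
#' optionally replaces the library's Pocillopora rates with gulf-level
#' annual means estimated from an out-plant table, and returns the
#' per-transect budget.
#'
#' @param survey survey rows (validated or raw data.frame).
#' @param grazers grazer table.
#' @param cores core summaries or NULL.
#' @param outplants out-plant table or NULL.
#' @param lib rate library.
#' @param estimate_calcification if TRUE and \code{outplants} is given,
#'   gulf-mean annual rates estimated from the out-plants replace the
#'   library's Pocillopora entries.
#' @param points points per transect.
#' @return budget data.frame (see \code{\link{reef_budget}}).
#' @export
run_reef_budget <- function(survey, grazers, cores = NULL, outplants = NULL,
                            lib = default_rate_library(),
                            estimate_calcification = FALSE, points = 100L) {
  survey <- validate_benthic_survey(survey, points = points)
  if (estimate_calcification && !is.null(outplants)) {
    est <- outplant_calcification(outplants, lib)
    ann <- aggregate_rates(est, by = "gulf")
    r <- stats::setNames(ann$mean, ann$gulf)
    lib$taxon_calcification$Pocillopora <- r[c("GoP", "GoC")]
  }
  reef_budget(cover_profiles(survey, points = points), grazers, cores, lib)
}
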