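#' Build a single cover profile
#'
#' Convenience constructor for a one-row cover-profile data.frame from
#' category fractions (unspecified categories are 0). Fractions must sum
#' to 1.
#'
#' @param ... named category fractions (names from
#'   \code{\link{benthic_categories}()$all}).
#' @param site,gulf,period,transect_id identifiers.
#' @param map category mapping (see \code{\link{default_category_map}}).
#' @return one-row cover-profile data.frame.
#' @export
cover_profile <- function(..., site = "S", gulf = "GoP", period = "p",
                          transect_id = "T1", map = default_category_map()) {
  fr <- c(...)
  vocab <- benthic_categories()$all
  if (length(fr) && (is.null(names(fr)) || !all(names(fr) %in% vocab)))
    stop("unknown category in cover profile: ",
         paste(setdiff(names(fr), vocab), collapse = ", "))
  if (abs(sum(fr) - 1) > 1e-9)
    stop("cover fractions must sum to 1 (got ", sum(fr), ")")
  prof <- data.frame(site = site, gulf = gulf, period = period,
                     transect_id = transect_id, stringsAsFactors = FALSE)
  for (cat in vocab) prof[[cat]] <- if (cat %in% names(fr)) fr[[cat]] else 0
  one <- function(cats) sum(unlist(prof[1, cats]))
  prof$L <- one(map$live)
  prof$T_turf <- one(map$thick_turf)
  prof$D_dead <- one(map$dead)
  prof$RC <- one(map$rubble)
  prof$FC <- one(map$framework)
  prof$coral_cover_pct <- 100 * prof$L
  prof
}

# per-row taxon rate, resolving per-gulf entries against the gulf column
.taxon_rate_rows <- function(lib, taxon, gulf) {
  unname(vapply(gulf, function(g) taxon_rate(lib, taxon, g), numeric(1)))
}

#' Gross carbonate production
#'
#' Sum over calcifying taxa (coral taxa and CCA) of proportional cover
#' times the taxon calcification rate, converted from g CaCO3 cm^-2 yr^-1
#' to kg CaCO3 m^-2 yr^-1 (factor 10). Planar: transect rugosity is not
#' surveyed, so production is per unit of horizontal reef area.
#'
#' @param cover cover-profile data.frame (any number of rows).
#' @param lib rate library.
#' @return kg CaCO3 m^-2 yr^-1, one value per row.
#' @export
gross_production <- function(cover, lib = default_rate_library()) {
  calcifiers <- c(benthic_categories()$coral, "CCA")
  g <- numeric(nrow(cover))
  for (tx in calcifiers) {
    fr <- cover[[tx]]
    if (any(fr > 0)) {
      # taxon_rate() errors if a covered taxon lacks a library rate
      rate <- .taxon_rate_rows(lib, tx, cover$gulf)
      g <- g + fr * rate * 10
    }
  }
  g
}

#' Macroborer bioerosion rate
#'
#' Internal macroboring scaled by substrate availability:
#' \eqn{MB = L \cdot ml_g + T \cdot mt_g + D \cdot md_g}, with the
#' gulf-specific rates (kg CaCO3 m^-2 yr^-1 per unit cover) for borers in
#' live coral, thick-turf substrate, and dead substrate. Positive
#' magnitude.
#'
#' @inheritParams gross_production
#' @return kg CaCO3 m^-2 yr^-1 per row.
#' @export
macroborer_rate <- function(cover, lib = default_rate_library()) {
  vapply(seq_len(nrow(cover)), function(i) {
    r <- lib$macroborer[[cover$gulf[i]]]
    if (is.null(r)) stop("no macroborer rates for gulf ", cover$gulf[i])
    cover$L[i] * r[["ml"]] + cover$T_turf[i] * r[["mt"]] +
      cover$D_dead[i] * r[["md"]]
  }, numeric(1))
}

#' Microbioerosion rate
#'
#' Default mode applies the flat Indo-Pacific average of 0.233 kg CaCO3
#' m^-2 yr^-1 to every transect (no regional microboring estimates exist).
#' The \code{"scaled"} mode multiplies the constant by the dead-substrate
#' fraction, for sensitivity analyses that restrict microboring to exposed
#' dead carbonate.
#'
#' @inheritParams gross_production
#' @param mode \code{"flat"} (default) or \code{"scaled"}.
#' @return kg CaCO3 m^-2 yr^-1 per row.
#' @export
microborer_rate <- function(cover, lib = default_rate_library(),
                            mode = c("flat", "scaled")) {
  mode <- match.arg(mode)
  k <- lib$microbioerosion
  if (mode == "flat") rep(k, nrow(cover)) else k * cover$D_dead
}

#' Boring-sponge dissolution rate
#'
#' Chemical dissolution by boring sponges on each substrate type weighted
#' by infestation prevalence:
#' \eqn{SB = (L \cdot 0.46 + RC \cdot 0.46 + FC \cdot 0.56) \times 0.85}
#' with the prevalences and dissolution rate taken from the library.
#'
#' @inheritParams gross_production
#' @return kg CaCO3 m^-2 yr^-1 per row.
#' @export
sponge_rate <- function(cover, lib = default_rate_library()) {
  s <- lib$sponge
  (cover$L * s$prev_live + cover$RC * s$prev_rubble +
      cover$FC * s$prev_framework) * s$dissolution
}

#' Sea-urchin bioerosion rate
#'
#' Substrate-specific per-urchin grazing rates (g CaCO3 ind^-1 day^-1)
#' scaled by urchin density and cover, with the daily-gram to
#' yearly-kilogram factor 365/1000:
#' \eqn{UB = (L U ul_g + D U ud_g + T U ut_g) \times 365/1000}.
#'
#' @inheritParams gross_production
#' @param density urchin density, ind m^-2 (recycled to rows of
#'   \code{cover}).
#' @return kg CaCO3 m^-2 yr^-1 per row.
#' @export
urchin_rate <- function(cover, density, lib = default_rate_library()) {
  if (any(density < 0)) stop("urchin density must be non-negative")
  density <- rep_len(density, nrow(cover))
  vapply(seq_len(nrow(cover)), function(i) {
    r <- lib$urchin[[cover$gulf[i]]]
    if (is.null(r)) stop("no urchin rates for gulf ", cover$gulf[i])
    (cover$L[i] * density[i] * r[["ul"]] +
       cover$D_dead[i] * density[i] * r[["ud"]] +
       cover$T_turf[i] * density[i] * r[["ut"]]) * 365 / 1000
  }, numeric(1))
}

#' Per-capita parrotfish bioerosion
#'
#' ReefBudget-style per-individual erosion from feeding observations:
#' bite rate (bites h^-1) x feeding hours per day x 365 x proportion of
#' bites leaving scars x scar volume (cm^3) x substrate density
#' (g cm^-3) / 1000, in kg CaCO3 ind^-1 yr^-1.
#'
#' @param params named numeric vector with \code{bite_rate},
#'   \code{prop_scars}, \code{scar_volume}, \code{feeding_hours}.
#' @param substrate_density g cm^-3 (default the framework density 1.84).
#' @return kg CaCO3 ind^-1 yr^-1.
#' @export
parrotfish_percapita <- function(params, substrate_density = 1.84) {
  need <- c("bite_rate", "prop_scars", "scar_volume", "feeding_hours")
  if (!all(need %in% names(params)))
    stop("missing parrotfish parameter(s): ",
         paste(setdiff(need, names(params)), collapse = ", "))
  if (any(params[need] < 0)) stop("parrotfish parameters must be non-negative")
  unname(params[["bite_rate"]] * params[["feeding_hours"]] * 365 *
           params[["prop_scars"]] * params[["scar_volume"]] *
           substrate_density / 1000)
}

#' Parrotfish assemblage bioerosion rate
#'
#' Sum over species of density (ind m^-2) times the species' per-capita
#' rate from \code{\link{parrotfish_percapita}}.
#'
#' @param densities named numeric vector or data.frame of per-species
#'   densities (ind m^-2); names must match the library's parrotfish
#'   entries.
#' @param lib rate library.
#' @param substrate_density g cm^-3 for the per-capita rates.
#' @return kg CaCO3 m^-2 yr^-1 (vectorised over data.frame rows).
#' @export
parrotfish_rate <- function(densities, lib = default_rate_library(),
                            substrate_density = lib$densities$D_f) {
  if (is.data.frame(densities)) {
    sp <- intersect(names(densities), names(lib$parrotfish))
    out <- numeric(nrow(densities))
    for (s in sp)
      out <- out + densities[[s]] *
        parrotfish_percapita(lib$parrotfish[[s]], substrate_density)
    return(out)
  }
  if (length(densities) == 0L) return(0)
  unknown <- setdiff(names(densities), names(lib$parrotfish))
  if (length(unknown))
    stop("no parrotfish parameters for: ", paste(unknown, collapse = ", "))
  sum(vapply(names(densities), function(s)
    densities[[s]] * parrotfish_percapita(lib$parrotfish[[s]],
                                          substrate_density), numeric(1)))
}

#' Corallivorous pufferfish bioerosion rate
#'
#' Arothron meleagris erosion from its per-fish destruction rate
#' \eqn{d_a} (g CaCO3 ind^-1 day^-1):
#' \eqn{AB = (d_a \times 365/1000 \times A) \times f}, with \eqn{A} the
#' density (ind m^-2) and \eqn{f} the fraction of fish actively feeding
#' (default 0.6).
#'
#' @param density A. meleagris density, ind m^-2.
#' @param lib rate library.
#' @return kg CaCO3 m^-2 yr^-1.
#' @export
puffer_rate <- function(density, lib = default_rate_library()) {
  if (any(density < 0)) stop("puffer density must be non-negative")
  (lib$puffer$d_a * 365 / 1000 * density) * lib$puffer$feeding_fraction
}

#' Total bioerosion
#'
#' Sum of the component magnitudes (macroborers, microborers, sponges,
#' urchins, parrotfish, pufferfish). All components are stored as positive
#' magnitudes; the conventional minus sign is applied only when formatting
#' reports.
#'
#' @param components named list or data.frame of component vectors.
#' @return kg CaCO3 m^-2 yr^-1 per row.
#' @export
total_bioerosion <- function(components) {
  if (length(components) == 0L) return(0)
  Reduce(`+`, as.list(as.data.frame(components)))
}
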