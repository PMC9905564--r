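#' Default rate library
#'
#' All fixed rate constants used by the carbonate-budget model, bundled in a
#' single nested list:
#' \describe{
#'   \item{taxon_calcification}{g CaCO3 cm^-2 yr^-1 per calcifying taxon.
#'     An entry may be a single number or a per-gulf named vector
#'     (\code{c(GoP = , GoC = )}). Defaults: Pocillopora 2.23 (GoP) / 2.08
#'     (GoC) — the in-situ annual buoyant-weight means; minor massive taxa
#'     and CCA carry literature-scale eastern-Pacific values.}
#'   \item{macroborer}{per-gulf kg CaCO3 m^-2 yr^-1 removed by internal
#'     macroborers per unit cover of live coral (\code{ml}), thick algal
#'     turf (\code{mt}) and dead substrate (\code{md}).}
#'   \item{urchin}{per-gulf g CaCO3 ind^-1 day^-1 grazed by Diadema
#'     mexicanum on live coral (\code{ul}), dead substrate (\code{ud}) and
#'     thick turf (\code{ut}).}
#'   \item{sponge}{boring-sponge infestation prevalences on live coral,
#'     rubble, and framework (0.46 / 0.46 / 0.56) and the mean chemical
#'     dissolution rate 0.85 kg m^-2 yr^-1.}
#'   \item{puffer}{Arothron meleagris destruction rate \code{d_a}
#'     (g CaCO3 ind^-1 day^-1) and the fraction of fish actively feeding
#'     (0.6).}
#'   \item{parrotfish}{per-species bite rate (bites h^-1), proportion of
#'     bites leaving scars, scar volume (cm^3), and feeding hours per day.}
#'   \item{microbioerosion}{flat Indo-Pacific microbioerosion rate,
#'     0.233 kg m^-2 yr^-1.}
#'   \item{densities}{framework density \code{D_f} = 1.84 g cm^-3 (waxed
#'     Pocillopora skeletons), seawater \code{D_w} = 1.03 g cm^-3, and
#'     aragonite 2.93 g cm^-3 for the buoyant-weight conversion (seawater
#'     density at the weighing station, 1.023 g cm^-3, lives in
#'     \code{densities$seawater_weighing}).}
#'   \item{sediment_mm_yr}{default sediment contribution S to accretion
#'     (mm yr^-1) used when a site has no core-derived value; 0.}
#' }
#'
#' The gulf-specific borer/urchin rates and the fish parameters are
#' literature-derived configuration values, not survey estimates; override
#' any of them via \code{\link{load_rate_library}}.
#'
#' @return a validated rate-library list.
#' @export
default_rate_library <- function() {
  lib <- list(
    taxon_calcification = list(
      Pocillopora    = c(GoP = 2.23, GoC = 2.08),
      Porites        = 1.19,
      Pavona         = 0.99,
      Gardineroseris = 0.87,
      CCA            = 0.10
    ),
    macroborer = list(
      GoP = c(ml = 10.5, mt = 15.0, md = 5.0),
      GoC = c(ml = 8.5,  mt = 12.0, md = 5.0)
    ),
    urchin = list(
      GoP = c(ul = 0.05, ud = 0.46, ut = 0.30),
      GoC = c(ul = 0.13, ud = 0.90, ut = 0.60)
    ),
    sponge = list(
      prev_live      = 0.46,
      prev_rubble    = 0.46,
      prev_framework = 0.56,
      dissolution    = 0.85
    ),
    puffer = list(d_a = 9.7, feeding_fraction = 0.6),
    parrotfish = list(
      Scarus_ghobban = c(bite_rate = 300, prop_scars = 0.10,
                         scar_volume = 0.05, feeding_hours = 8),
      Scarus_rubroviolaceus = c(bite_rate = 240, prop_scars = 0.15,
                                scar_volume = 0.10, feeding_hours = 8)
    ),
    microbioerosion = 0.233,
    densities = list(D_f = 1.84, D_w = 1.03,
                     aragonite = 2.93, seawater_weighing = 1.023),
    sediment_mm_yr = 0
  )
  validate_rate_library(lib)
}

#' Load a rate library from a YAML configuration file
#'
#' Reads a (possibly partial) YAML file and merges it over the packaged
#' defaults: any field present in the file replaces the default, anything
#' absent keeps its default, so an empty file yields
#' \code{\link{default_rate_library}()} unchanged. Per-gulf entries given in
#' the file must name both gulfs or are merged entry-wise over the default.
#'
#' @param path path to a YAML file; may be empty.
#' @return a validated rate-library list.
#' @export
load_rate_library <- function(path) {
  if (!file.exists(path)) stop("rate-library file not found: ", path)
  user <- yaml::read_yaml(path)
  lib <- default_rate_library()
  if (is.null(user)) return(lib)
  if (!is.list(user)) stop("rate-library file must be a YAML mapping")
  validate_rate_library(.merge_config(lib, user))
}

# recursive merge: named lists merge by name, everything else replaces.
# YAML returns lists where defaults use named numeric vectors; coerce back.
.merge_config <- function(base, user) {
  for (nm in names(user)) {
    u <- user[[nm]]
    if (is.list(u) && !is.null(names(u)) && all(vapply(u, is.numeric, TRUE)) &&
        is.numeric(base[[nm]])) {
      u <- unlist(u)
    }
    if (is.list(base[[nm]]) && is.list(u)) {
      base[[nm]] <- .merge_config(base[[nm]], u)
    } else if (is.numeric(base[[nm]]) && !is.null(names(base[[nm]])) &&
               is.numeric(u) && !is.null(names(u))) {
      b <- base[[nm]]
      b[names(u)] <- u
      base[[nm]] <- b
    } else {
      base[[nm]] <- u
    }
  }
  base
}

#' Validate a rate library
#'
#' Checks that every rate is non-negative, every prevalence/fraction is in
#' \[0, 1\], and every per-gulf table names both gulfs.
#'
#' @param lib a rate-library list.
#' @return \code{lib}, invisibly validated (returned unchanged).
#' @export
validate_rate_library <- function(lib) {
  gulfs <- c("GoP", "GoC")
  num_ok <- function(x, what) {
    if (any(!is.finite(unlist(x))) || any(unlist(x) < 0))
      stop("rate library: negative or non-finite value in ", what)
  }
  for (field in c("taxon_calcification", "macroborer", "urchin", "sponge",
                  "puffer", "parrotfish", "densities"))
    num_ok(lib[[field]], field)
  num_ok(lib$microbioerosion, "microbioerosion")
  needed <- list(macroborer = c("ml", "mt", "md"), urchin = c("ul", "ud", "ut"))
  for (field in names(needed)) {
    if (!all(gulfs %in% names(lib[[field]])))
      stop("rate library: '", field, "' must name both gulfs GoP and GoC")
    for (g in gulfs)
      if (!all(needed[[field]] %in% names(lib[[field]][[g]])))
        stop("rate library: incomplete '", field, "' entry for gulf ", g)
  }
  fr <- c(lib$sponge$prev_live, lib$sponge$prev_rubble,
          lib$sponge$prev_framework, lib$puffer$feeding_fraction,
          unlist(lapply(lib$parrotfish, function(p) p[["prop_scars"]])))
  if (any(fr > 1)) stop("rate library: a prevalence/fraction exceeds 1")
  with(lib$densities, {
    if (seawater_weighing >= aragonite)
      stop("rate library: seawater density must be below aragonite density")
  })
  lib
}

#' Look up a taxon calcification rate
#'
#' @param lib rate library.
#' @param taxon taxon name as used in the survey vocabulary.
#' @param gulf \code{"GoP"} or \code{"GoC"}; used when the taxon carries
#'   per-gulf rates.
#' @return rate in g CaCO3 cm^-2 yr^-1.
#' @export
taxon_rate <- function(lib, taxon, gulf) {
  r <- lib$taxon_calcification[[taxon]]
  if (is.null(r)) stop("no calcification rate for taxon '", taxon, "'")
  if (length(r) > 1L) {
    if (!gulf %in% names(r)) stop("no ", gulf, " rate for taxon '", taxon, "'")
    r <- r[[gulf]]
  }
  unname(r)
}
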