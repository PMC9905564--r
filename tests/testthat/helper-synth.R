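# compact generator config used across tests: one site per gulf, fewer
# transects/corals, shorter tide record
small_cfg <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_sites_per_gulf = 1L, n_transects = 3L,
               n_corals_per_site = 5L, tide_years = 20L, ...)
}

# noise-free variant: exact generator inversion checks
noiseless_cfg <- function(seed = 1L, ...) {
  synth_config(seed = seed, n_sites_per_gulf = 1L, n_transects = 3L,
               n_corals_per_site = 3L, tide_years = 20L,
               noise = list(weight_sd = 0, area_sd = 0, tide_sd = 0,
                            tide_seasonal_amp = 0, tide_missing = 0), ...)
}

# a rate library with simple round-number borer/urchin rates, for
# term-by-term arithmetic checks
fixture_lib <- function() {
  lib <- default_rate_library()
  lib$macroborer$GoP <- c(ml = 0.5, mt = 12, md = 8)
  lib$urchin$GoP <- c(ul = 0.1, ud = 0.3, ut = 0.2)
  lib
}

# random valid cover profile over the full vocabulary (for property tests)
random_profile <- function(gulf = "GoP") {
  vocab <- benthic_categories()$all
  w <- stats::runif(length(vocab))
  fr <- round(w / sum(w), 6)
  fr[1] <- fr[1] + (1 - sum(fr))  # absorb rounding so fractions sum to 1
  names(fr) <- vocab
  cover_profile(fr, gulf = gulf)
}
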