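test_that("generators are deterministic given (seed, cfg)", {
  cfg <- small_cfg(seed = 42)
  expect_identical(synth_dataset(cfg), synth_dataset(cfg))
  cfg2 <- small_cfg(seed = 43)
  expect_false(identical(gen_benthic_transects(cfg),
                         gen_benthic_transects(cfg2)))
})

test_that("degenerate multinomial puts every point on the configured category", {
  one <- setNames(c(1, rep(0, 10)), benthic_categories()$all)
  means <- list(GoP = list(), GoC = list())
  for (p in default_periods()) means$GoP[[p]] <- means$GoC[[p]] <- one
  cfg <- small_cfg(seed = 1, cover_means = means)
  survey <- gen_benthic_transects(cfg)
  poc <- survey$category == "Pocillopora"
  expect_true(all(survey$count[poc] == 100))
  expect_true(all(survey$count[!poc] == 0))
})

test_that("transect-mean coral cover tracks the configured gulf means", {
  cfg <- synth_config(seed = 7)  # 3 sites x 5 periods x 6 transects per gulf
  cov <- cover_profiles(validate_benthic_survey(gen_benthic_transects(cfg)))
  gop <- mean(cov$coral_cover_pct[cov$gulf == "GoP"])
  goc <- mean(cov$coral_cover_pct[cov$gulf == "GoC"])
  # configured means average 78% (GoP) and 45% (GoC) across periods
  expect_lt(abs(gop - 78), 5)
  expect_lt(abs(goc - 45), 5)
})

test_that("noise-free out-plants invert to the configured seasonal truth", {
  cfg <- noiseless_cfg(seed = 2)
  est <- outplant_calcification(gen_outplant_series(cfg))
  agg <- aggregate_rates(est, by = c("gulf", "season"))
  get <- function(g, s) agg$mean[agg$gulf == g & agg$season == s]
  expect_equal(get("GoP", "non_upwelling"), 3.1, tolerance = 1e-12)
  expect_equal(get("GoP", "upwelling"), 2.0, tolerance = 1e-12)
  expect_equal(get("GoC", "non_upwelling"), 2.9, tolerance = 1e-12)
  expect_equal(get("GoC", "upwelling"), 2.3, tolerance = 1e-12)
  expect_equal(get("GoP", "annual"), mean(c(3.1, 2.0)), tolerance = 1e-12)
})

test_that("noisy out-plant gulf-season means recover truth within 2 SE", {
  # pooled over a 5-seed sweep: the combined estimate (mean of per-seed
  # gulf-season means, each over 60 corals) must sit within 2 pooled SE of
  # the generator truth
  sweep <- lapply(1:5, function(seed) {
    cfg <- synth_config(seed = seed)
    agg <- aggregate_rates(outplant_calcification(gen_outplant_series(cfg)),
                           by = c("gulf", "season"))
    agg$seed <- seed
    agg
  })
  r <- do.call(rbind, sweep)
  truth <- synth_config()$true_calcification
  for (g in c("GoP", "GoC")) {
    for (s in c("non_upwelling", "upwelling")) {
      sub <- r[r$gulf == g & r$season == s, ]
      pooled <- mean(sub$mean)
      pooled_se <- sqrt(mean(sub$se^2) / nrow(sub))
      expect_lt(abs(pooled - truth[[g]][[s]]), 2 * pooled_se)
    }
  }
})

test_that("grazer densities are Poisson-consistent with the trajectory", {
  # zero-mean trajectory -> all zeros
  cfg0 <- small_cfg(seed = 1,
                    urchin_traj = list(GoP = rep(0, 5), GoC = rep(0, 5)))
  g0 <- gen_grazer_densities(cfg0)
  expect_true(all(g0$density_ind_m2[g0$taxon == "Diadema_mexicanum"] == 0))

  # default cfg: mean over 36 final-period transects within 3 SE of truth
  cfg <- synth_config(seed = 9)
  gr <- gen_grazer_densities(cfg)
  u <- gr[gr$taxon == "Diadema_mexicanum" & gr$period == "spring-2018", ]
  for (g in c("GoP", "GoC")) {
    lam <- cfg$urchin_traj[[g]][5]
    n <- sum(u$gulf == g)
    se <- sqrt(lam / 25) / sqrt(n)  # counts over 25 m2 belts
    expect_lt(abs(mean(u$density_ind_m2[u$gulf == g]) - lam), 3 * se)
  }
})

test_that("core porosity is the exact complement of compaction", {
  cores <- gen_cores(synth_config(seed = 3))
  expect_equal(cores$porosity + cores$compaction_fraction,
               rep(1, nrow(cores)))
  # degenerate sd: all sites at the configured mean
  cfg <- small_cfg(seed = 1, compaction_mean = 0.65, compaction_sd = 0)
  expect_true(all(gen_cores(cfg)$compaction_fraction == 0.65))
})

test_that("tide-gauge generator recovers the configured trend", {
  # noise-free, no seasonality: OLS slope is exactly the trend
  cfg0 <- noiseless_cfg(seed = 1)
  expect_equal(tide_gauge_trend(gen_tide_gauge(cfg0)), 1.4,
               tolerance = 1e-9)
  # default noise over 50 years: within 0.2 mm/yr of 1.4
  cfg <- synth_config(seed = 5, tide_years = 50)
  expect_lt(abs(tide_gauge_trend(gen_tide_gauge(cfg)) - 1.4), 0.2)
})

test_that("config validation rejects malformed ground truth", {
  expect_error(small_cfg(outplant_dates = as.Date(c("2016-09-15",
                                                    "2016-03-15"))),
               "increasing")
  bad_means <- default_cover_means()
  bad_means$GoP[["spring-2016"]]["sand"] <-
    bad_means$GoP[["spring-2016"]]["sand"] + 0.01
  expect_error(synth_config(cover_means = bad_means), "sum to")
  expect_error(small_cfg(fish_density = c(Scarus_ghobban = -1)),
               "negative")
})
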