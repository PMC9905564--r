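# build noiseless budget-like rows from a known affine truth
affine_rows <- function(intercept, slope, gulf_offset = 0, noise_sd = 0,
                        site_sd = 0, seed = 1) {
  set.seed(seed)
  covers <- rep(seq(20, 90, by = 10), each = 3)
  rows <- expand.grid(cover = covers, gulf = c("GoC", "GoP"),
                      stringsAsFactors = FALSE)
  rows$site <- paste0(rows$gulf, "-S", rep_len(1:3, nrow(rows)))
  site_eff <- setNames(rnorm(length(unique(rows$site)), 0, site_sd),
                       unique(rows$site))
  rows$net <- intercept + ifelse(rows$gulf == "GoP", gulf_offset, 0) +
    slope * rows$cover + site_eff[rows$site] + rnorm(nrow(rows), 0, noise_sd)
  rows$coral_cover_pct <- rows$cover
  rows
}

test_that("noiseless affine data is refit exactly", {
  rows <- affine_rows(-9.6, 0.24, gulf_offset = 1.5)
  m <- fit_cover_model(rows, "net")
  expect_equal(m$cover_slope, 0.24, tolerance = 1e-9)
  expect_equal(m$intercept, -9.6, tolerance = 1e-9)
  expect_equal(unname(m$gulf_offset["GoP"]), 1.5, tolerance = 1e-9)
  expect_equal(m$site_sd, 0)
})

test_that("single-gulf fits succeed with an absent gulf offset", {
  rows <- affine_rows(-6.5, 0.16)
  rows <- rows[rows$gulf == "GoC", ]
  m <- fit_cover_model(rows, "net")
  expect_equal(m$cover_slope, 0.16, tolerance = 1e-9)
  expect_true(all(m$gulf_offset == 0))
})

test_that("constant cover is rejected as rank-deficient", {
  rows <- affine_rows(-6.5, 0.16)
  rows$coral_cover_pct <- 50
  expect_error(fit_cover_model(rows, "net"), "constant")
})

test_that("threshold solving inverts the model, flagging unattainable targets", {
  rows <- affine_rows(-6.5, 0.16)
  rows <- rows[rows$gulf == "GoC", ]
  m <- fit_cover_model(rows, "net")
  thr <- solve_cover_threshold(m, "GoC", 3.3)
  expect_equal(thr$required_cover_pct, (3.3 + 6.5) / 0.16,
               tolerance = 1e-9)  # 61.25
  expect_false(thr$unattainable)
  # target at the intercept -> 0% cover
  thr0 <- solve_cover_threshold(m, "GoC", m$intercept)
  expect_equal(thr0$required_cover_pct, 0, tolerance = 1e-9)
  # out-of-reach target -> flagged
  far <- solve_cover_threshold(m, "GoC", 15)
  expect_equal(far$required_cover_pct, (15 + 6.5) / 0.16,
               tolerance = 1e-9)  # 134.375
  expect_true(far$unattainable)
})

test_that("inverse consistency: predict(solve(target)) == target", {
  rows <- affine_rows(-9.6, 0.24, gulf_offset = 1.2, noise_sd = 0.8,
                      site_sd = 0.5, seed = 4)
  m <- fit_cover_model(rows, "net")
  for (target in c(-3, 0, 1.4, 3.3, 5.7, 12.3)) {
    for (g in c("GoC", "GoP")) {
      cov <- solve_cover_threshold(m, g, target)$required_cover_pct
      expect_equal(predict_cover_model(m, g, cov), target,
                   tolerance = 1e-9)
    }
  }
  # required cover strictly increases with the target rate
  req <- vapply(c(0, 2, 4, 8),
                function(t) solve_cover_threshold(m, "GoC",
                                                  t)$required_cover_pct,
                numeric(1))
  expect_true(all(diff(req) > 0))
})

test_that("generate-and-refit recovers the 0.24 cover slope within 2 SE", {
  for (seed in 1:20) {
    rows <- affine_rows(-9.6, 0.24, gulf_offset = 1.2, noise_sd = 1,
                        site_sd = 0.5, seed = seed)
    m <- fit_cover_model(rows, "net")
    expect_lt(abs(m$cover_slope - 0.24), 2 * m$slope_se + 1e-12)
  }
})

test_that("tide-gauge trend: OLS on available months only", {
  # noise-free synthetic slope is exact
  yrs <- seq(1970, 2019.99, by = 1 / 12)
  s <- data.frame(year = yrs, level_mm = 7000 + 1.4 * (yrs - 1970))
  expect_equal(tide_gauge_trend(s), 1.4, tolerance = 1e-9)
  # missing months are omitted, not imputed
  s2 <- s
  s2$level_mm[seq(5, 300, by = 7)] <- NA
  expect_equal(tide_gauge_trend(s2), 1.4, tolerance = 1e-9)
  # constant series -> zero trend
  s3 <- data.frame(year = yrs, level_mm = 7000)
  expect_equal(tide_gauge_trend(s3), 0, tolerance = 1e-12)
  expect_error(tide_gauge_trend(s[1:10, ]), "24")
})

test_that("projection localization is a linear scaling", {
  expect_equal(localize_projection(4, 1.7, 1.7), 4)
  expect_equal(localize_projection(4, 1.4, 1.7), 4 * 1.4 / 1.7)
  expect_equal(localize_projection(15, 1.394, 1.7), 15 * 0.82,
               tolerance = 0.01)
  expect_equal(localize_projection(4 + 7, 1.4, 1.7),
               localize_projection(4, 1.4, 1.7) +
                 localize_projection(7, 1.4, 1.7))
  expect_error(localize_projection(4, 1.4, 0), "positive")
})

test_that("scenario report combines thresholds, observations and verdicts", {
  # an accretion model chosen so required covers bracket the observations
  rows <- affine_rows(-6.5, 0.16, gulf_offset = -0.3)
  rows$rap_mm_yr <- rows$net
  m <- fit_cover_model(rows, "rap_mm_yr")
  sc <- sea_level_scenarios(local_obs = 1.4, global_obs = 1.7)
  rep <- scenario_report(m, sc, c(GoC = 39, GoP = 75))
  expect_equal(nrow(rep), 8)
  goc26 <- rep[rep$gulf == "GoC" & rep$scenario == "RCP2.6", ]
  gop26 <- rep[rep$gulf == "GoP" & rep$scenario == "RCP2.6", ]
  expect_gt(goc26$required_cover_pct, 39)
  expect_equal(goc26$verdict, "drowns")
  expect_lt(gop26$required_cover_pct, 75)
  expect_equal(gop26$verdict, "keeps_up")
  # RCP 8.5 localized to ~12.3 mm/yr is unattainable at these slopes
  expect_true(all(rep$unattainable[rep$scenario == "RCP8.5"]))
  # empty scenario list -> empty table
  empty <- scenario_report(m, sc[0, ], c(GoC = 39))
  expect_equal(nrow(empty), 0)
})
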