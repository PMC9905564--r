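test_that("gross production converts cover x rate with the factor 10", {
  lib <- default_rate_library()
  # full Pocillopora cover at the GoC annual rate
  full <- cover_profile(c(Pocillopora = 1), gulf = "GoC")
  expect_equal(gross_production(full, lib), 2.08 * 10)
  # all-sand transect produces nothing
  sand <- cover_profile(c(sand = 1))
  expect_equal(gross_production(sand, lib), 0)
  # term-by-term: 50% Pocillopora at 2.0 plus 10% CCA at 0.1
  lib2 <- lib
  lib2$taxon_calcification$Pocillopora <- 2.0
  lib2$taxon_calcification$CCA <- 0.1
  mix <- cover_profile(c(Pocillopora = 0.5, CCA = 0.1, sand = 0.4))
  expect_equal(gross_production(mix, lib2), 0.5 * 2.0 * 10 + 0.1 * 0.1 * 10)
  # a covered taxon without a rate errors
  lib3 <- lib
  lib3$taxon_calcification$Pavona <- NULL
  expect_error(gross_production(cover_profile(c(Pavona = 1)), lib3),
               "no calcification rate")
})

test_that("macroborer rate is the cover-weighted sum of gulf rates", {
  lib <- fixture_lib()  # GoP: ml 0.5, mt 12, md 8
  prof <- cover_profile(c(Pocillopora = 0.75, thick_turf = 0.10,
                          dead_framework = 0.15), gulf = "GoP")
  expect_equal(macroborer_rate(prof, lib),
               0.75 * 0.5 + 0.10 * 12 + 0.15 * 8)  # 2.775
  expect_equal(macroborer_rate(cover_profile(c(sand = 1)), lib), 0)
})

test_that("microbioerosion: flat constant by default, dead-scaled optionally", {
  lib <- default_rate_library()
  prof <- cover_profile(c(Pocillopora = 0.5, dead_framework = 0.5))
  expect_equal(microborer_rate(prof, lib), 0.233)
  expect_equal(microborer_rate(cover_profile(c(sand = 1)), lib), 0.233)
  expect_equal(microborer_rate(cover_profile(c(Pocillopora = 1)), lib,
                               mode = "scaled"), 0)
  expect_equal(microborer_rate(prof, lib, mode = "scaled"), 0.233 * 0.5)
})

test_that("sponge dissolution weights substrates by infestation prevalence", {
  lib <- default_rate_library()
  expect_equal(sponge_rate(cover_profile(c(Pocillopora = 1)), lib),
               0.46 * 0.85)  # 0.391
  prof <- cover_profile(c(Pocillopora = 0.5, rubble = 0.2,
                          dead_framework = 0.1, sand = 0.2))
  expect_equal(sponge_rate(prof, lib),
               0.5 * 0.46 * 0.85 + 0.2 * 0.46 * 0.85 + 0.1 * 0.56 * 0.85)
  expect_equal(sponge_rate(cover_profile(c(sand = 1)), lib), 0)
})

test_that("urchin rate applies the 365/1000 daily-to-annual conversion", {
  lib <- fixture_lib()  # GoP: ul 0.1, ud 0.3, ut 0.2
  prof <- cover_profile(c(Pocillopora = 0.5, dead_framework = 0.3,
                          thick_turf = 0.2), gulf = "GoP")
  expect_equal(urchin_rate(prof, 2, lib),
               (0.5 * 2 * 0.1 + 0.3 * 2 * 0.3 + 0.2 * 2 * 0.2) * 365 / 1000)
  expect_equal(urchin_rate(prof, 0, lib), 0)
  # linear in density
  expect_equal(urchin_rate(prof, 6, lib), 3 * urchin_rate(prof, 2, lib))
  expect_error(urchin_rate(prof, -1, lib), "non-negative")
})

test_that("parrotfish per-capita and assemblage rates", {
  p <- c(bite_rate = 300, prop_scars = 0.1, scar_volume = 0.05,
         feeding_hours = 8)
  e <- parrotfish_percapita(p, 1.84)
  expect_equal(e, 300 * 8 * 365 * 0.1 * 0.05 * 1.84 / 1000)  # 8.0592
  expect_equal(parrotfish_percapita(replace(p, "prop_scars", 0)), 0)
  expect_equal(parrotfish_percapita(replace(p, "scar_volume", 0.1), 1.84),
               2 * e)
  expect_error(parrotfish_percapita(p[-1]), "missing")

  lib <- default_rate_library()
  lib$parrotfish$Scarus_ghobban <- p
  expect_equal(parrotfish_rate(c(Scarus_ghobban = 0.002), lib, 1.84),
               0.002 * e)
  # species contributions are additive
  both <- parrotfish_rate(c(Scarus_ghobban = 0.002,
                            Scarus_rubroviolaceus = 0.001), lib, 1.84)
  expect_equal(both,
               parrotfish_rate(c(Scarus_ghobban = 0.002), lib, 1.84) +
                 parrotfish_rate(c(Scarus_rubroviolaceus = 0.001), lib,
                                 1.84))
  expect_equal(parrotfish_rate(numeric(0), lib), 0)
})

test_that("pufferfish rate scales by the active-feeding fraction", {
  lib <- default_rate_library()
  lib$puffer$d_a <- 5
  expect_equal(puffer_rate(0.01, lib), 5 * 365 / 1000 * 0.01 * 0.6)
  expect_equal(puffer_rate(0, lib), 0)
  lib2 <- lib
  lib2$puffer$feeding_fraction <- 1
  expect_equal(puffer_rate(0.01, lib2), puffer_rate(0.01, lib) / 0.6)
})

test_that("total bioerosion is the order-invariant sum of components", {
  comp <- list(macro = 2.775, micro = 0.233, sponge = 0.3213,
               urchin = 0.1314, parrot = 0.0161, puffer = 0.01095)
  expect_equal(total_bioerosion(comp), sum(unlist(comp)))
  expect_equal(total_bioerosion(rev(comp)), total_bioerosion(comp))
  expect_equal(total_bioerosion(list(a = 0, b = 0)), 0)
})

test_that("components match independent oracles and stay non-negative and linear", {
  set.seed(101)
  lib <- default_rate_library()
  for (i in 1:25) {
    gulf <- sample(c("GoP", "GoC"), 1)
    prof <- random_profile(gulf)
    U <- runif(1, 0, 5)
    mb <- lib$macroborer[[gulf]]
    ub <- lib$urchin[[gulf]]
    L <- prof$L; Tt <- prof$T_turf; D <- prof$D_dead
    RC <- prof$RC; FC <- prof$FC
    # independent arithmetic oracles, written from the model definitions
    expect_equal(macroborer_rate(prof, lib),
                 L * mb[["ml"]] + Tt * mb[["mt"]] + D * mb[["md"]])
    expect_equal(sponge_rate(prof, lib),
                 (L * 0.46 + RC * 0.46 + FC * 0.56) * 0.85)
    expect_equal(urchin_rate(prof, U, lib),
                 (L * U * ub[["ul"]] + D * U * ub[["ud"]] +
                    Tt * U * ub[["ut"]]) * 365 / 1000)
    expect_equal(puffer_rate(U / 100, lib),
                 lib$puffer$d_a * 365 / 1000 * U / 100 * 0.6)
    vals <- c(macroborer_rate(prof, lib), microborer_rate(prof, lib),
              sponge_rate(prof, lib), urchin_rate(prof, U, lib),
              puffer_rate(U / 100, lib))
    expect_true(all(vals >= 0))
  }
})

test_that("doubling covers at fixed rates doubles the linear components", {
  lib <- default_rate_library()
  half <- cover_profile(c(Pocillopora = 0.25, thick_turf = 0.05,
                          dead_framework = 0.1, sand = 0.6), gulf = "GoC")
  full <- cover_profile(c(Pocillopora = 0.5, thick_turf = 0.1,
                          dead_framework = 0.2, sand = 0.2), gulf = "GoC")
  expect_equal(macroborer_rate(full, lib), 2 * macroborer_rate(half, lib))
  expect_equal(urchin_rate(full, 1, lib), 2 * urchin_rate(half, 1, lib))
})
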