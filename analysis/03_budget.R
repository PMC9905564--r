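#!/usr/bin/env Rscript
# Step 3 — per-transect carbonate budgets and accretion potential.
#
# Gross production = cover x taxon calcification; bioerosion from
# macroborers, microborers, boring sponges, urchins, parrotfish and
# pufferfish; net = gross - total bioerosion; accretion potential from
# the porosity-corrected framework density of each site's cores.

suppressPackageStartupMessages(library(reefcarb))

survey <- read_benthic_survey("results/data/survey.csv")
grazers <- read_grazers("results/data/grazers.csv")
cores <- read_cores("results/data/cores.csv")

budget <- run_reef_budget(survey, grazers, cores)
write_budget_table(budget, "results/budget.csv")

gp <- aggregate(cbind(gross, total_bioerosion, net, rap_mm_yr,
                      millennial_rap_mm_yr, coral_cover_pct) ~
                  gulf + period, budget, mean)
write.csv(gp, "results/budget_gulf_period_means.csv", row.names = FALSE)

cat("Gulf-period means (kg CaCO3 m^-2 yr^-1; RAP in mm yr^-1):\n")
s18 <- gp[gp$period == "spring-2018", ]
for (i in seq_len(nrow(s18)))
  cat(sprintf(" - %s spring 2018: gross %.1f, bioerosion -%.1f, net %.1f, RAP %.1f\n",
              s18$gulf[i], s18$gross[i], s18$total_bioerosion[i],
              s18$net[i], s18$rap_mm_yr[i]))

cat("Bioerosion composition (share of total, all periods):\n")
comp_cols <- c("macroborer", "microborer", "sponge", "urchin",
               "parrotfish", "puffer")
for (g in c("GoP", "GoC")) {
  comp <- colMeans(budget[budget$gulf == g, comp_cols])
  share <- round_half_up(100 * comp / sum(comp))
  cat(sprintf(" - %s: %s\n", g,
              paste(names(share), paste0(share, "%"), collapse = ", ")))
}
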