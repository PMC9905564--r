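#!/usr/bin/env Rscript
# Step 4 — coral-cover thresholds against localized sea-level rise.
#
# Fits cover -> budget models on the most recent survey (spring 2018),
# localizes the global RCP rise rates by the ratio of the Balboa
# tide-gauge trend to the global observed trend, solves the cover each
# gulf needs to keep up with each scenario, and classifies the observed
# state.

suppressPackageStartupMessages(library(reefcarb))

budget <- read_budget_table("results/budget.csv")
tide <- read_tide_gauge("results/data/tide.txt")

trend <- tide_gauge_trend(tide)
scenarios <- sea_level_scenarios(local_obs = trend, global_obs = 1.7)
cat(sprintf("Balboa tide-gauge trend: %.2f mm/yr; localized RCP rates: %s mm/yr\n",
            trend,
            paste(sprintf("%.1f", scenarios$local_rate[-1]),
                  collapse = " / ")))

s18 <- budget[budget$period == "spring-2018", ]
net_model <- fit_cover_model(s18, "net")
rap_model <- fit_cover_model(s18, "rap_mm_yr")
cat(sprintf("Cover effect: %.3f kg/m2/yr per %% cover (net); %.3f mm/yr per %% cover (RAP)\n",
            net_model$cover_slope, rap_model$cover_slope))

obs <- vapply(c(GoP = "GoP", GoC = "GoC"), function(g)
  mean(s18$coral_cover_pct[s18$gulf == g]), numeric(1))
for (g in names(obs)) {
  thr <- solve_cover_threshold(net_model, g, 0)
  cat(sprintf("%s needs %.0f%% cover for a net-positive budget (observed %.0f%%)\n",
              g, thr$required_cover_pct, obs[[g]]))
}

report <- scenario_report(rap_model, scenarios, obs)
write.csv(report, "results/scenario_report.csv", row.names = FALSE)
cat("Keep-up verdicts at observed cover:\n")
for (i in seq_len(nrow(report)))
  cat(sprintf(" - %s under %s (%.1f mm/yr): requires %.0f%%%s -> %s\n",
              report$gulf[i], report$scenario[i], report$local_rate[i],
              report$required_cover_pct[i],
              ifelse(report$unattainable[i], " (unattainable)", ""),
              report$verdict[i]))
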