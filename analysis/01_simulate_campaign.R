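#!/usr/bin/env Rscript
# Generate the default synthetic campaign: six (fjord x zone) strata, 30
# casts each, calibrated to the bundled published zone summaries, and write
# the cast table plus the hidden truth records (clearly non-observational).

library(fjordpp)

seed <- 42
dir.create("results", showWarnings = FALSE)

scenarios <- default_campaign_scenarios(n_casts = 30, noise_cv = 0.1)
campaign <- generate_campaign(scenarios, seed = seed)

write_casts(campaign$casts, "results/synthetic_casts.csv")
utils::write.csv(campaign$truth, "results/synthetic_truth.csv",
                 row.names = FALSE)

cat(sprintf("campaign: %d casts, %d incubation levels (seed %d)\n",
            nrow(campaign$truth), nrow(campaign$casts), seed))
cat("strata:\n")
print(table(campaign$truth$fjord, campaign$truth$zone))
cat("wrote results/synthetic_casts.csv and results/synthetic_truth.csv\n")
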