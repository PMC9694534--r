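#!/usr/bin/env Rscript
# Generate the default synthetic campaign: a 50-day particle stream over
# seven bioaerosol/interferent classes, a forced-trigger background
# session, the paired Hirst-style daily observations, and the ground-truth
# table. Writes everything under results/sim/ as plain CSV.
#
# Usage: Rscript analysis/01_simulate.R [seed]

library(wibstools)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 2017
dir.create("results/sim", recursive = TRUE, showWarnings = FALSE)

sc <- default_scenario(seed = seed)

write_particles(sc$particles, "results/sim/particles.csv")
write.csv(sc$forced_trigger, "results/sim/forced_trigger.csv",
          row.names = FALSE)
write_taxon_daily(sc$hirst, "results/sim/hirst.csv")
write.csv(sc$truth, "results/sim/truth.csv", row.names = FALSE)
# truth labels live in a side file, never in the particle table
writeLines(sc$labels, "results/sim/particle_labels.txt")
write_campaign_config(sc$config, "results/sim/config.yaml")

cat(sprintf("campaign: %d particles over %d days (seed %d)\n",
            nrow(sc$particles), length(unique(as.Date(sc$truth$date))),
            seed))
print(aggregate(count ~ class, data = sc$truth, FUN = sum))
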