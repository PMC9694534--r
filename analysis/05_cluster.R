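#!/usr/bin/env Rscript
# K-means clustering of the classified particles on scaled FL1-FL5, size
# and asymmetry factor, with Calinski-Harabasz model selection:
# intra-categorical clustering of the fungal-like (A+AB) and pollen-like
# (high FL2/FL3) selections, then mapping clusters to the Hirst series.
#
# Usage: Rscript analysis/05_cluster.R [seed]   (run after 01 and 02)

library(wibstools)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 2017

cfg <- read_campaign_config("results/sim/config.yaml")
ft <- read_forced_trigger("results/sim/forced_trigger.csv", cfg)
particles <- read_particles("results/sim/particles.csv", cfg)
hirst <- read_taxon_daily("results/sim/hirst.csv")
span <- c(trunc(min(particles$timestamp), "days"),
          trunc(max(particles$timestamp), "days") + 86400)
cls3 <- classify_particles(particles, compute_thresholds(ft, 3))

run <- function(preselect, taxa, seed) {
  ic <- intra_category_cluster(cls3, preselect, k_range = 2:12,
                               seed = seed, restarts = 10)
  cat(sprintf("\n%s: %d particles, CH selects k = %d\n", preselect,
              nrow(ic$particles), ic$best_k))
  print(round(ic$ch, 1))
  mp <- map_clusters_to_taxa(ic$particles, hirst, taxa = taxa,
                             flow = cfg$wibs_flow, span = span)
  for (tx in names(mp$best_union)) {
    u <- mp$best_union[[tx]]
    cat(sprintf("  %s: best cluster union {%s}, R2 = %.3f\n", tx,
                paste(u$clusters, collapse = ","), u$r2))
  }
  write.csv(mp$r_table, sprintf("results/cluster_r_%s.csv", preselect),
            row.names = FALSE)
  ic
}

ic_fungal <- run("fungal_AplusAB", c("fungal", "Ascospores", "Cladosporium"),
                 seed + 100)
ic_pollen <- run("total_pollen", c("total_pollen", "tree", "herb", "grass"),
                 seed + 200)

sizes <- vapply(split(ic_fungal$particles$size, ic_fungal$particles$cluster),
                median, numeric(1))
cat("\nfungal-selection cluster median sizes (um):\n")
print(round(sizes, 1))
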