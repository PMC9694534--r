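# wibstools

Single-particle bioaerosol analysis for five-channel UV-LIF data from a
WIBS-4+ sensor, built for aerobiologists who want to turn raw particle
event streams into taxon-level daily concentrations that can be compared
with — and validated against — the Hirst volumetric method.

Each particle event carries a timestamp, an optical-equivalent diameter
(µm), an asymmetry factor and five fluorescence intensities
(FL1: 280 → 310–400 nm, FL2: 280 → 420–650 nm, FL3: 370 → 420–650 nm,
plus the chlorophyll-band FL4: 280 → 600–750 nm and FL5: 370 → 600–750 nm).
The pipeline:

1. **Calibration** — per-channel thresholds `mean + k·σ` (k ∈ {3, 6, 9})
   from forced-trigger (particle-free) background data.
2. **Classification** — the Perring class from the FL1–FL3 exceedance
   pattern (A, B, C, AB, AC, BC, ABC, NonFluorescent) and the
   chlorophyll class from FL4–FL5 (D, E, DE, None).
3. **Proxy filters** — named size/class/intensity selections: fungal
   A-class at 9σ, A+AB, ascospore (< 5 µm), *Cladosporium* (< 10 µm),
   total pollen (FL2 & FL3 > 1300), tree (ABC > 25 µm), herb
   (D, 10–15 µm), grass (D, > 10 µm), all above the 2 µm comparison floor.
4. **Aggregation** — number concentrations `count / (flow × duration)`
   per m³, normalised diurnal profiles, per-class size/AF summaries.
5. **Comparison** — Pearson r, linear and polynomial R² against
   Hirst-style daily series; σ-escalation response; high-day
   co-occurrence (Euler-region counts at 50/80/80/2500 m⁻³ thresholds).
6. **Clustering** — k-means on standardised FL1–FL5/size/AF with
   Calinski–Harabasz selection, intra-categorical refinement, and
   cluster-to-taxon mapping.
7. **Synthetic campaigns** — a generator with known ground truth
   (class-conditional distributions, Poisson counting, capture
   efficiency, a CV-0.30 Hirst counting-error model) so the whole
   pipeline is testable without field data.

## Worked example

```r
library(wibstools)

sc <- default_scenario(seed = 2017)          # 50-day synthetic campaign
thr <- compute_thresholds(sc$forced_trigger, k = 3)
cls <- classify_particles(sc$particles, thr)
summ <- classification_summary(cls)
round(100 * summ$fluorescent_fraction, 1)
#> [1] 66.3

sel  <- apply_filter(cls, "fungal_AplusAB")  # A+AB, size >= 2 um
conc <- aggregate_concentration(sel, "day", flow = sc$flow, span = sc$span)
correlate_series(pair_series(conc, sc$hirst, "fungal"))
#> fungal_AplusAB vs fungal: n = 50, r = 0.829, R2(linear) = 0.687, R2(poly 2) = 0.701

esc <- sigma_escalation(sc$particles, sc$forced_trigger, sc$hirst,
                        "fungal", "fungal_A9", flow = sc$flow, span = sc$span)
sapply(esc, function(e) round(e$r2_linear, 3))
#>     3     6     9
#> 0.179 0.714 0.816
```

66.3% of simulated particles are fluorescent at 3σ. The combined A+AB
selection tracks the Hirst-observed fungal series at R² ≈ 0.69, and
escalating the threshold from 3σ to 9σ raises the A-class agreement from
0.18 to 0.82: the synthetic anthropogenic interferent sits between the
3σ and 9σ thresholds, so it contaminates the A/AB classes at 3σ and is
removed at 9σ while AB-type spores shift into the A class.

## Analysis workflow

The numbered drivers under `analysis/` run the whole study over the
default synthetic campaign and write tables to `results/`:

```sh
Rscript analysis/01_simulate.R 2017        # campaign + Hirst + truth CSVs
Rscript analysis/02_calibrate_classify.R   # thresholds, classes, size/AF
Rscript analysis/03_concentrations.R       # proxy concentrations, diurnal
Rscript analysis/04_compare_hirst.R        # correlations, escalation, high days
Rscript analysis/05_cluster.R 2017         # k-means, cluster-taxon mapping
```

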