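#!/usr/bin/env Rscript
# Symbiont abundance estimation: FISH cell density and relative fraction
# from the simulated field counts, qPCR volumetric conversion, and a
# read-recruitment worked example.

suppressPackageStartupMessages(library(taurflux))
dir.create("results/abundance", showWarnings = FALSE, recursive = TRUE)

fields <- read_fish_table("results/sim/fish_counts.tsv")
dens <- fish_density(fields)
frac <- fish_relative_fraction(fields)
message(sprintf("FISH density: %.3g +/- %.2g (SD) cells/cm3 over %d fields",
                dens$mean_cells_cm3, dens$sd_cells_cm3, dens$n_fields))
message(sprintf("target fraction of EUB-positive cells: %.1f%% +/- %.1f%%",
                frac$mean_percent, frac$sd_percent))

# qPCR copies/g on the FISH volumetric scale (1.2 g wet wt = 1 cm^3)
copies_per_g <- 2.78e10
message(sprintf("qPCR %.3g copies/g -> %.3g copies/cm3",
                copies_per_g, qpcr_volumetric(copies_per_g, 1.2)))

# read recruitment at the printed scale: 3.02% of total QC fragments
rr <- read_recruitment_fraction(302000, 1e7)
message(sprintf("read recruitment: %.2f%% of total fragments", rr))

out <- data.frame(
  quantity = c("fish_mean_cells_cm3", "fish_sd_cells_cm3",
               "fish_fraction_percent", "qpcr_copies_cm3",
               "read_recruitment_percent"),
  value = c(dens$mean_cells_cm3, dens$sd_cells_cm3, frac$mean_percent,
            qpcr_volumetric(copies_per_g, 1.2), rr))
taurflux:::write_tsv(out, "results/abundance/abundance_summary.tsv")
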