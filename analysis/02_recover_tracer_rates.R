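#!/usr/bin/env Rscript
# Run the tracer-recovery analysis on the simulated bundle: two-pool
# mixing attribution of biomass and dissolved N pools, net ammonium
# release, and wet-weight-normalized assimilation rates (mean +/- SE).
# Then repeat with kinetics calibrated so the true mean rates equal the
# experimentally reported 1.38 nmol C and 0.74 nmol N min^-1 g^-1, to show
# the pipeline recovers known rates through 10% measurement noise.

suppressPackageStartupMessages(library(taurflux))

cfg <- default_run_config(seed = 20260927)
report <- run_analyze(cfg, "results/sim", "results/tracer")
s <- report$rates$summary
message(sprintf("recovered rates: C %.3f +/- %.3f, N %.3f +/- %.3f nmol/min/g",
                s$mean_rate_nmol_min_g[s$element == "C"],
                s$se_rate_nmol_min_g[s$element == "C"],
                s$mean_rate_nmol_min_g[s$element == "N"],
                s$se_rate_nmol_min_g[s$element == "N"]))

# parameter-recovery exercise at known truth
p <- kinetic_params(measurement_cv = 0.10, seed = cfg$seed)
cal <- calibrate_to_rates(p, target_c_rate = 1.38, target_n_rate = 0.74)
sim <- simulate_incubation(cal)
wet <- as.list(stats::setNames(sim$truth$summary$wet_wt_g,
                               sim$truth$summary$vessel))
rec <- recover_assimilation_rates(sim$isotopes, wet, sim$source_at, 48)
s2 <- rec$summary
message(sprintf(
  "calibrated truth C = 1.38, N = 0.74; recovered C %.3f +/- %.3f, N %.3f +/- %.3f",
  s2$mean_rate_nmol_min_g[s2$element == "C"],
  s2$se_rate_nmol_min_g[s2$element == "C"],
  s2$mean_rate_nmol_min_g[s2$element == "N"],
  s2$se_rate_nmol_min_g[s2$element == "N"]))
taurflux:::write_tsv(s2, "results/tracer/calibrated_recovery.tsv")
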