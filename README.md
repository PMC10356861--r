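# taurflux

Mass-balance analysis of stable-isotope taurine tracer experiments in
sponge holobionts — a host sponge together with its microbial symbionts,
one of which dissimilates taurine (2-aminoethanesulfonic acid, C₂H₇NO₃S)
into ammonium and sulfate while the holobiont assimilates part of the
taurine-derived carbon and nitrogen into biomass.

The package is written for researchers running batch incubations of
sponge explants with dual-labeled (¹³C₂/¹⁵N) taurine and bulk EA-IRMS
read-outs, and implements the full accounting chain:

- **Two-pool isotope mixing.** The amount of taurine-derived element X in
  a measured pool is

  n_X,taurine = (a_sample − a_ctrl) / (a_taurine − a_ctrl) × n_X,total

  where the `a` are atom percents (at%), `a_ctrl` comes from unlabeled
  control explants (falling back to natural abundance, 1.07 at% ¹³C /
  0.366 at% ¹⁵N), and the labeled end member `a_taurine` is the
  atom-weighted mean at% of the added substrate mixture
  (`effective_label_atom_fraction()`): the equimolar 99 at% ¹³C₂-taurine /
  98 at% ¹⁵N-taurine design gives 50.04 at% ¹³C and 49.18 at% ¹⁵N.
- **Net ammonium release**, crediting nitrite formed by the
  ammonia-oxidizing symbiont back to the ammonium pool and subtracting
  no-sponge seawater controls:
  n_released = (n_NH₄,sponge − n_NH₄,SW) + (n_NO₂,sponge − n_NO₂,SW).
- **End-point assimilation rates** normalized to explant wet weight
  (nmol min⁻¹ g⁻¹), summarized across replicates as mean ± SE.
- **Incubation accounting**: net concentration changes, baseline and
  medium-control subtraction, per-biomass normalization
  (µM × l / g), tissue molarity via the 1.2 g wet wt = 1 cm³ density
  assumption.
- **Symbiont abundance**: FISH cell densities from ocular-grid field
  counts, fractions of EUB338-positive cells, qPCR copies g⁻¹ → cm⁻³,
  metagenomic read-recruitment percentages.
- **NSAF metaproteomics**: NSAFᵢ = (SpCᵢ/Lᵢ) / Σⱼ(SpCⱼ/Lⱼ), per-bin and
  within-bin protein-set shares.
- **A seeded forward simulator** (`simulate_incubation()`) of the pulsed
  batch-incubation design with exact heavy-atom bookkeeping, so the whole
  pipeline can be exercised and validated end to end without any external
  data.

## Worked example

Simulate the paper-like design (triplicate ~9 g explants in 1 l, taurine
pulses of 1 mM at t = 0 and 0.6 mM at 36 h, equimolar dual label, 10%
measurement CV), then recover assimilation rates from the noisy
end-point measurements:

```r
library(taurflux)

p   <- kinetic_params(measurement_cv = 0.10, seed = 20260927)
cal <- calibrate_to_rates(p, target_c_rate = 1.38, target_n_rate = 0.74)
sim <- simulate_incubation(cal, n_replicates = 3, duration_h = 48)

wet <- as.list(setNames(sim$truth$summary$wet_wt_g,
                        sim$truth$summary$vessel))
rec <- recover_assimilation_rates(sim$isotopes, wet, sim$source_at, 48)
rec$summary[, c("element", "mean_rate_nmol_min_g", "se_rate_nmol_min_g")]
#>   element mean_rate_nmol_min_g se_rate_nmol_min_g
#> 1       C            1.4138014         0.17862650
#> 2       N            0.7421646         0.06092918
```

The simulator was calibrated so the true mean rates are exactly 1.38
nmol C min⁻¹ g⁻¹ and 0.74 nmol N min⁻¹ g⁻¹; the pipeline recovers them
through the 10% measurement noise to within a few percent, with SEs of
the magnitude expected for n = 3. Single-function worked examples:

```r
fish_density(fish_field_counts(rep(260.6, 10)))$mean_cells_cm3
#> [1] 12183797209        # cells per cm^3 sponge
tissue_molarity(5.5, 1.2)
#> [1] 6.6                # mM in tissue from 5.5 umol/g wet wt
```

The numbered scripts under `analysis/` run the whole workflow
(simulate → tracer recovery → abundance → NSAF → sulfonate balance) and
write their tables under `results/`.

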