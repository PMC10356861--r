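# Incubation-series accounting: net changes, control subtraction,
# biomass normalization, tissue molarity.

test_that("series construction enforces its invariants", {
  expect_s3_class(flat_series(), "incubation_series")
  expect_error(flat_series(conc = -1), "non-negative")
  expect_error(flat_series(times = c(12, 0, 24, 36, 48)), "sorted")
  expect_error(
    incubation_series("v", "SFASW", TRUE, FALSE, has_sponge = TRUE,
                      wet_wt_g = NA_real_, volume_l = 1,
                      samples = data.frame(time_h = 0, analyte = "SO4",
                                           conc_uM = 1)),
    "wet weight")
  expect_error(
    incubation_series("v", "SFASW", TRUE, FALSE, has_sponge = FALSE,
                      wet_wt_g = 5, volume_l = 1,
                      samples = data.frame(time_h = 0, analyte = "SO4",
                                           conc_uM = 1)),
    "no-sponge")
})

test_that("net change is the end-point difference and antisymmetric", {
  expect_equal(net_change(flat_series(), "SO4", 0, 48), 0)
  expect_equal(net_change(flat_series(), "SO4", 24, 24), 0)
  # 0.2 mM carryover at t0, 790 uM at 48 h -> 590 uM net accumulation
  s <- flat_series(conc = c(200, 340, 480, 620, 790))
  expect_equal(net_change(s, "SO4", 0, 48), 590)
  expect_equal(net_change(s, "SO4", 48, 0), -590)
  expect_equal(baseline_subtract(s, "SO4", 48), 590)
  expect_error(net_change(s, "SO4", 0, 13), "no SO4 sample")
  expect_error(net_change(s, "NH4", 0, 48), "no NH4 sample")
})

test_that("medium-control subtraction requires matched chemistry", {
  sponge <- flat_series(conc = 100)
  ctrl <- incubation_series("c1", "SFASW", TRUE, FALSE, has_sponge = FALSE,
                            volume_l = 1,
                            samples = data.frame(
                              time_h = c(0, 12, 24, 36, 48),
                              analyte = "SO4", conc_uM = 20))
  expect_equal(subtract_medium_control(sponge, ctrl, "SO4", 48), 80)
  same <- incubation_series("c2", "SFASW", TRUE, FALSE, has_sponge = FALSE,
                            volume_l = 1, samples = ctrl$samples)
  same$samples$conc_uM <- 100
  expect_equal(subtract_medium_control(sponge, same, "SO4", 12), 0)
  hot <- same
  hot$samples$conc_uM <- 150
  expect_warning(out <- subtract_medium_control(sponge, hot, "SO4", 12),
                 "negative")
  expect_equal(out, -50)
  fsw_ctrl <- incubation_series("c3", "FSW", TRUE, FALSE,
                                has_sponge = FALSE, volume_l = 1,
                                samples = ctrl$samples)
  expect_error(subtract_medium_control(sponge, fsw_ctrl, "SO4", 12),
               "mismatch")
  expect_error(subtract_medium_control(ctrl, ctrl, "SO4", 12), "explant")
})

test_that("per-biomass normalization matches the printed pairing", {
  # 590 uM in 1 l over a 10 g explant -> 59.0 umol per g wet weight
  expect_equal(concentration_to_per_biomass(590, 1, 10), 59)
  expect_equal(concentration_to_per_biomass(0, 1, 5), 0)
  # 250-ml vessel geometry
  expect_equal(concentration_to_per_biomass(100, 0.25, 2.98), 8.389,
               tolerance = 1e-3)
  expect_error(concentration_to_per_biomass(1, 0, 1), "positive")
  expect_error(concentration_to_per_biomass(1, 1, -2), "positive")
  # linearity
  expect_equal(concentration_to_per_biomass(2 * 590, 1, 10), 2 * 59)
})

test_that("tissue molarity applies the density assumption", {
  expect_equal(tissue_molarity(5.5, 1.2), 6.6)
  expect_equal(tissue_molarity(5.5), 6.6)  # 1.2 g cm^-3 default
  expect_equal(tissue_molarity(0, 1.2), 0)
  expect_equal(tissue_molarity(1, 1), 1)
  expect_equal(tissue_molarity(3 * 5.5, 1.2), 3 * 6.6)
  expect_error(tissue_molarity(1, 0), "positive")
})
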