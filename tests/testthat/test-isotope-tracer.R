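# Two-pool mixing model and the mass-balance equation chain.

test_that("effective source at% equals the atom-weighted hand oracle", {
  # equimolar 13C2-taurine (99 at%, 2/2 C) + unlabeled taurine (2 C, natural)
  oracle_c <- (0.5 * (2 * 99) + 0.5 * (2 * 1.07)) / 2
  expect_equal(effective_label_atom_fraction(taurine_label_mix("C")),
               oracle_c, tolerance = 1e-12)
  expect_equal(oracle_c, 50.035)

  # equimolar 15N-taurine (98 at%, 1/1 N) + unlabeled (natural 0.366)
  oracle_n <- (0.5 * 98 + 0.5 * 0.366) / 1
  expect_equal(effective_label_atom_fraction(taurine_label_mix("N")),
               oracle_n, tolerance = 1e-12)
  expect_equal(oracle_n, 49.183)
})

test_that("a single component at natural abundance is the identity case", {
  src <- tracer_source("C", 1, purity_at_percent = 1.07,
                       labeled_atoms = 2, total_atoms = 2)
  expect_equal(effective_label_atom_fraction(src), 1.07)
  # a single pure component returns its purity
  pure <- tracer_source("N", 1, 98, 1, 1)
  expect_equal(effective_label_atom_fraction(pure), 98)
})

test_that("mixture at% stays inside the convex hull of component at%", {
  set.seed(42)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    f <- stats::runif(k); f <- f / sum(f)
    total <- sample(1:4, k, replace = TRUE)
    lab <- vapply(total, function(t) sample(0:t, 1), integer(1))
    pur <- stats::runif(k, 0, 100)
    src <- tracer_source("C", f, pur, lab, total)
    at <- effective_label_atom_fraction(src)
    per_atom <- (lab * pur + (total - lab) * 1.07) / total
    expect_gte(at, min(per_atom) - 1e-9)
    expect_lte(at, max(per_atom) + 1e-9)
  }
})

test_that("source with zero atoms of the element is rejected", {
  src <- tracer_source("N", 1, 98, 0, 0)
  expect_error(effective_label_atom_fraction(src), "no atoms")
})

test_that("tracer-derived amount reproduces the mixing-model arithmetic", {
  src <- effective_label_atom_fraction(taurine_label_mix("C"))
  ctl <- isotope_measurement("C", "control", 1.07, 0)
  # zero enrichment and full enrichment endpoints
  at_ctrl <- isotope_measurement("C", "sponge-biomass", 1.07, 1000)
  expect_equal(tracer_derived_amount(at_ctrl, ctl, src), 0)
  at_src <- isotope_measurement("C", "sponge-biomass", src, 1000)
  expect_equal(tracer_derived_amount(at_src, ctl, src), 1000)
  # printed-scale bulk enrichment of 1.19 at% on a 1000 umol C pool
  smp <- isotope_measurement("C", "sponge-biomass", 1.19, 1000)
  oracle <- (1.19 - 1.07) / (50.035 - 1.07) * 1000
  expect_equal(tracer_derived_amount(smp, ctl, src), oracle)
  expect_equal(oracle, 2.4507, tolerance = 1e-4)
})

test_that("tracer-derived amount is monotone in sample at% and bounded", {
  src <- 50.035
  ctl <- isotope_measurement("N", "control", 0.366, 0)
  ats <- seq(0.366, src, length.out = 25)
  n <- vapply(ats, function(a) {
    tracer_derived_amount(
      isotope_measurement("N", "NH4", a, 500), ctl, src)
  }, numeric(1))
  expect_true(all(diff(n) > 0))
  expect_true(all(n >= 0 & n <= 500))
})

test_that("degenerate denominators and element mismatches are rejected", {
  ctl <- isotope_measurement("C", "control", 1.07, 0)
  smp <- isotope_measurement("C", "sponge-biomass", 1.19, 100)
  expect_error(tracer_derived_amount(smp, ctl, 1.07), "degenerate")
  expect_error(tracer_derived_amount(smp, ctl, 0.5), "degenerate")
  ctl_n <- isotope_measurement("N", "control", 0.366, 0)
  expect_error(tracer_derived_amount(smp, ctl_n, 50), "different elements")
})

test_that("negative enrichment warns and honors the clipping policy", {
  ctl <- isotope_measurement("N", "control", 0.40, 0)
  smp <- isotope_measurement("N", "NO2", 0.35, 100)
  expect_warning(n <- tracer_derived_amount(smp, ctl, 49.183), "negative")
  expect_lt(n, 0)
  expect_warning(
    n0 <- tracer_derived_amount(smp, ctl, 49.183, clip = "zero"),
    "negative")
  expect_identical(n0, 0)
})

test_that("net ammonium release sums control-corrected N pools", {
  expect_equal(ammonium_released(0, 0, 0, 0), 0)
  expect_equal(ammonium_released(10, 1, 4, 0), 13)
  # sponge pools equal to seawater controls cancel exactly
  expect_equal(ammonium_released(7.5, 7.5, 2.2, 2.2), 0)
  expect_warning(out <- ammonium_released(1, 3, 0, 0), "negative")
  expect_equal(out, -2)
})

test_that("wet-weight normalization and end-point rates are linear", {
  expect_equal(normalize_to_wet_weight(590, 10), 59)
  expect_equal(normalize_to_wet_weight(0, 5), 0)
  expect_equal(normalize_to_wet_weight(6.6, 1.2), 5.5)
  expect_error(normalize_to_wet_weight(1, 0), "positive")

  expect_equal(assimilation_rate(3.974, 48), 1.38, tolerance = 1e-3)
  expect_equal(assimilation_rate(0, 48), 0)
  expect_equal(assimilation_rate(2.88, 48), 1)
  expect_error(assimilation_rate(1, 0), "positive")

  # rate o normalize is linear in n, inverse-linear in weight and duration
  base <- assimilation_rate(normalize_to_wet_weight(12, 4), 24)
  expect_equal(assimilation_rate(normalize_to_wet_weight(36, 4), 24),
               3 * base)
  expect_equal(assimilation_rate(normalize_to_wet_weight(12, 8), 24),
               base / 2)
  expect_equal(assimilation_rate(normalize_to_wet_weight(12, 4), 48),
               base / 2)
})

test_that("attribution records keep the rate invariant and summarize as SE", {
  a <- rbind(
    tracer_attribution("C", "sponge-biomass", 30, 10, 48, "r1"),
    tracer_attribution("C", "sponge-biomass", 40, 10, 48, "r2"),
    tracer_attribution("C", "sponge-biomass", 50, 10, 48, "r3"))
  expect_equal(a$rate_nmol_min_g,
               a$per_wet_weight_umol_g * 1000 / a$duration_min)
  s <- summarize_attributions(a)
  rates <- c(30, 40, 50) / 10 * 1000 / 2880
  expect_equal(s$mean_rate_nmol_min_g, mean(rates))
  expect_equal(s$se_rate_nmol_min_g, sd(rates) / sqrt(3))
  expect_warning(tracer_attribution("C", "NH4", -1, 10, 48), "clipped")
})

test_that("delta-notation conversion matches the standard-ratio formula", {
  r_vpdb <- 0.011180
  expect_equal(delta_to_atom_percent(0, "C"),
               100 * r_vpdb / (1 + r_vpdb))
  d <- seq(-50, 5000, by = 250)
  expect_true(all(diff(delta_to_atom_percent(d, "N")) > 0))
})
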