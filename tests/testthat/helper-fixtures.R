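# shared fixture builders

noiseless_params <- function(...) {
  kinetic_params(measurement_cv = 0, at_percent_sd = 0, ...)
}

flat_series <- function(conc = 100, analyte = "SO4",
                        times = c(0, 12, 24, 36, 48), ...) {
  incubation_series(
    vessel = "v1", medium = "SFASW", taurine_added = TRUE, labeled = FALSE,
    has_sponge = TRUE, wet_wt_g = 10, volume_l = 1,
    samples = data.frame(time_h = times, analyte = analyte,
                         conc_uM = conc), ...)
}
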