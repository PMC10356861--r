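Package: taurflux
Title: Isotope-Tracer Mass Balance for Taurine Metabolism in Sponge Holobionts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mass-balance analysis of dual-labeled (13C/15N) taurine tracer
    incubations of sponge explants and their microbial symbionts: two-pool
    isotope mixing to attribute biomass and dissolved nitrogen pools to
    taurine-derived atoms, net ammonium-release accounting, wet-weight
    normalized assimilation rates, batch-incubation time-series accounting
    (control subtraction, net changes, tissue-concentration conversions),
    symbiont abundance estimation from FISH field counts, qPCR and read
    recruitment, and NSAF metaproteome quantitation. Includes a seeded
    forward simulator of labeled-taurine batch incubations so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
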