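# Run configuration, the tracer-recovery pipeline, and the two drivers
# binding simulation and analysis into reproducible report bundles.

#' Default run configuration
#'
#' A plain list capturing everything a run depends on: the seed, physical
#' constants, the clipping policy for negative enrichments, the incubation
#' design and the simulator kinetics. It serializes losslessly through
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed Integer seed for every source of randomness.
#' @param density_g_cm3 Tissue density for volumetric conversions
#'   (g cm^-3).
#' @param clip Negative-enrichment policy passed to
#'   [tracer_derived_amount()]: `"report"` or `"zero"`.
#' @param time_tol_h Time-matching tolerance for series lookups (h).
#' @param n_replicates,duration_h,sampling_times Incubation design.
#' @param kinetics Named list of overrides for [kinetic_params()].
#' @return Configuration list of class `"run_config"`.
#' @export
default_run_config <- function(seed = 1L, density_g_cm3 = 1.2,
                               clip = c("report", "zero"),
                               time_tol_h = 0.01, n_replicates = 3L,
                               duration_h = 48,
                               sampling_times = c(0, 12, 24, 36, 48),
                               kinetics = list()) {
  clip <- match.arg(clip)
  stopifnot(density_g_cm3 > 0, time_tol_h > 0, n_replicates >= 1,
            duration_h > 0)
  structure(
    list(seed = as.integer(seed), density_g_cm3 = density_g_cm3,
         clip = clip, time_tol_h = time_tol_h,
         n_replicates = as.integer(n_replicates), duration_h = duration_h,
         sampling_times = sampling_times, kinetics = kinetics),
    class = "run_config")
}

config_params <- function(config) {
  args <- config$kinetics
  if (is.null(args)) args <- list()
  args$seed <- config$seed
  if (!is.null(args$pulses)) args$pulses <- as.data.frame(args$pulses)
  do.call(kinetic_params, args)
}

#' Write / read a run configuration as JSON
#'
#' @param config A [default_run_config()] list.
#' @param path JSON file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns the configuration list.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_run_config(
    seed = x$seed, density_g_cm3 = x$density_g_cm3, clip = x$clip,
    time_tol_h = x$time_tol_h, n_replicates = x$n_replicates,
    duration_h = x$duration_h, sampling_times = x$sampling_times,
    kinetics = as.list(x$kinetics))
  cfg
}

#' Recover assimilation rates from end-point isotope measurements
#'
#' The analysis chain applied to an atom-fraction table: the unlabeled
#' control explants define the background end member (falling back to
#' natural-abundance constants when absent), each labeled explant's bulk
#' biomass enrichment is attributed to the taurine source by two-pool
#' mixing, normalized to wet weight, converted to an end-point rate, and
#' summarized across replicates as mean +/- SE.
#'
#' @param isotopes Atom-fraction data.frame (see
#'   [read_atom_fraction_table()]).
#' @param wet_weights Named numeric vector: wet weight (g) per replicate
#'   id.
#' @param source_at Named vector `c(C = ..., N = ...)` of effective source
#'   at% (from [effective_label_atom_fraction()]).
#' @param duration_h Incubation duration (h).
#' @param clip Negative-enrichment policy for the reported amounts
#'   (rates always clip at zero).
#' @return List with `attributions` (per replicate x element),
#'   `summary` (mean +/- SE) and `controls` (the background at% used).
#' @export
recover_assimilation_rates <- function(isotopes, wet_weights, source_at,
                                       duration_h,
                                       clip = c("report", "zero")) {
  clip <- match.arg(clip)
  stopifnot(is.data.frame(isotopes), nrow(isotopes) > 0)
  ctrl_at <- control_atom_fractions(isotopes)
  bio <- isotopes[isotopes$pool == "sponge-biomass", , drop = FALSE]
  if (nrow(bio) == 0) {
    stop("no sponge-biomass measurements to analyze", call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(bio)), function(i) {
    el <- bio$element[i]
    rep_id <- as.character(bio$replicate[i])
    if (!rep_id %in% names(wet_weights)) {
      stop("no wet weight for replicate ", rep_id, call. = FALSE)
    }
    smp <- isotope_measurement(el, "sponge-biomass",
                               bio$atom_fraction_percent[i],
                               bio$n_total_umol[i], "sponge")
    ctl <- isotope_measurement(el, "control", ctrl_at[[el]], 0, "sponge")
    n <- tracer_derived_amount(smp, ctl, source_at[[el]], clip = clip)
    tracer_attribution(el, "sponge-biomass", n, wet_weights[[rep_id]],
                       duration_h, replicate = rep_id)
  })
  attributions <- do.call(rbind, rows)
  list(attributions = attributions,
       summary = summarize_attributions(attributions),
       controls = ctrl_at)
}

control_atom_fractions <- function(isotopes) {
  ctrl <- isotopes[isotopes$pool == "control", , drop = FALSE]
  sapply(c("C", "N"), function(el) {
    hit <- ctrl$element == el
    if (any(hit)) mean(ctrl$atom_fraction_percent[hit])
    else natural_abundance(el)
  }, simplify = FALSE)
}

#' Net tracer-derived ammonium release accounting
#'
#' Applies the two-pool mixing attribution to the dissolved NH4+ and NO2-
#' end points of each labeled sponge vessel, subtracts the mean of the
#' no-sponge seawater controls, sums the two differences
#' (nitrite having passed through the ammonium pool), and normalizes to
#' wet weight.
#'
#' @inheritParams recover_assimilation_rates
#' @return List with `per_replicate` (vessel, tracer-derived NH4+/NO2-,
#'   net released umol, umol per g) and `seawater_means`.
#' @export
ammonium_release_accounting <- function(isotopes, wet_weights, source_at,
                                        clip = c("report", "zero")) {
  clip <- match.arg(clip)
  ctrl_at <- control_atom_fractions(isotopes)
  attr_n <- function(row) {
    smp <- isotope_measurement("N", row$pool, row$atom_fraction_percent,
                               row$n_total_umol, row$context)
    ctl <- isotope_measurement("N", "control", ctrl_at$N, 0, row$context)
    tracer_derived_amount(smp, ctl, source_at[["N"]], clip = clip)
  }
  diss <- isotopes[isotopes$pool %in% c("NH4", "NO2") &
                     isotopes$element == "N", , drop = FALSE]
  if (nrow(diss) == 0) {
    stop("no dissolved-nitrogen measurements to analyze", call. = FALSE)
  }
  diss$n_tracer_umol <- vapply(seq_len(nrow(diss)),
                               function(i) attr_n(diss[i, ]), numeric(1))
  sw <- diss[diss$context == "seawater", , drop = FALSE]
  sw_mean <- sapply(c("NH4", "NO2"), function(pl) {
    hit <- sw$pool == pl
    if (any(hit)) mean(sw$n_tracer_umol[hit]) else 0
  })
  sponge <- diss[diss$context == "sponge", , drop = FALSE]
  reps <- unique(as.character(sponge$replicate))
  per <- do.call(rbind, lapply(reps, function(r) {
    d <- sponge[sponge$replicate == r, ]
    nh4 <- d$n_tracer_umol[d$pool == "NH4"][1]
    no2 <- d$n_tracer_umol[d$pool == "NO2"][1]
    if (is.na(nh4) || is.na(no2)) {
      stop("replicate ", r, " lacks an NH4 or NO2 measurement",
           call. = FALSE)
    }
    released <- ammonium_released(nh4, sw_mean[["NH4"]], no2,
                                  sw_mean[["NO2"]])
    w <- if (r %in% names(wet_weights)) wet_weights[[r]] else NULL
    data.frame(replicate = r, nh4_tracer_umol = nh4,
               no2_tracer_umol = no2, released_umol = released,
               released_umol_per_g = if (!is.null(w))
                 normalize_to_wet_weight(max(released, 0), w)
               else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_replicate = per, seawater_means = sw_mean)
}

#' Simulate an incubation experiment and write its fixture bundle
#'
#' Runs [simulate_incubation()] plus the FISH and spectral-count fixture
#' generators under the configured seed and writes every TSV dialect the
#' analysis consumes, the noiseless truth as a JSON sidecar, and the
#' configuration itself.
#'
#' @param config A [default_run_config()] list.
#' @param output_dir Directory for the bundle (created if needed).
#' @return Named character vector of written file paths, invisibly.
#' @export
run_simulate <- function(config, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_params(config)
  sim <- simulate_incubation(params, n_replicates = config$n_replicates,
                             duration_h = config$duration_h,
                             sampling_times = config$sampling_times)
  fish <- make_fish_fixture(seed = config$seed)
  prot <- make_proteome_fixture(seed = config$seed)
  paths <- c(
    incubation = file.path(output_dir, "incubation.tsv"),
    isotopes = file.path(output_dir, "atom_fractions.tsv"),
    fish = file.path(output_dir, "fish_counts.tsv"),
    proteome = file.path(output_dir, "spectral_counts.tsv"),
    truth = file.path(output_dir, "truth.json"),
    config = file.path(output_dir, "config.json"))
  write_tsv(sim$measurements, paths[["incubation"]])
  write_tsv(sim$isotopes, paths[["isotopes"]])
  write_tsv(as.data.frame(fish), paths[["fish"]])
  write_tsv(as.data.frame(prot), paths[["proteome"]])
  jsonlite::write_json(
    list(summary = sim$truth$summary, source_at = as.list(sim$source_at),
         duration_h = sim$truth$duration_h),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  write_run_config(config, paths[["config"]])
  invisible(paths)
}

#' Analyze an incubation fixture bundle and write reports
#'
#' Reads the TSV tables written by [run_simulate()] (or hand-assembled in
#' the same dialects), runs the tracer-recovery and ammonium-release
#' accounting, and — when FISH / spectral-count tables are present — the
#' abundance and NSAF summaries. Writes a per-replicate attribution TSV, a
#' JSON summary with mean +/- SE, and a plain-text log recording versions,
#' seed and the configuration hash.
#'
#' @param config A [default_run_config()] list.
#' @param input_dir Directory holding the input tables.
#' @param output_dir Directory for reports (created if needed).
#' @return The report list, invisibly.
#' @export
run_analyze <- function(config, input_dir, output_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  inc <- read_incubation_table(file.path(input_dir, "incubation.tsv"))
  iso <- read_atom_fraction_table(file.path(input_dir,
                                            "atom_fractions.tsv"))
  wet <- wet_weight_lookup(inc)
  params <- config_params(config)
  source_at <- c(C = source_at_percent(params, "C"),
                 N = source_at_percent(params, "N"))
  duration_h <- max(inc$time_h)
  rates <- recover_assimilation_rates(iso, wet, source_at, duration_h,
                                      clip = config$clip)
  release <- ammonium_release_accounting(iso, wet, source_at,
                                         clip = config$clip)
  report <- list(rates = rates, release = release,
                 source_at = source_at, duration_h = duration_h)

  fish_path <- file.path(input_dir, "fish_counts.tsv")
  if (file.exists(fish_path)) {
    fish <- read_fish_table(fish_path)
    report$fish <- list(density = fish_density(fish),
                        fraction = fish_relative_fraction(fish))
  }
  prot_path <- file.path(input_dir, "spectral_counts.tsv")
  if (file.exists(prot_path)) {
    sc <- read_spectral_count_table(prot_path)
    nm <- nsaf_mean(sc)
    shares <- sapply(sort(unique(nm$bin)), function(b)
      bin_share(nm, b), USE.NAMES = TRUE)
    report$nsaf <- list(table = nm, bin_shares_percent = shares)
  }

  write_tsv(rates$attributions, file.path(output_dir, "attributions.tsv"))
  summary_json <- list(
    rates = rates$summary, controls = rates$controls,
    source_at = as.list(source_at),
    release_per_replicate = release$per_replicate)
  if (!is.null(report$fish)) {
    summary_json$fish <- list(
      mean_cells_cm3 = report$fish$density$mean_cells_cm3,
      sd_cells_cm3 = report$fish$density$sd_cells_cm3,
      mean_percent_of_eub = report$fish$fraction$mean_percent)
  }
  if (!is.null(report$nsaf)) {
    summary_json$nsaf_bin_shares_percent <-
      as.list(report$nsaf$bin_shares_percent)
  }
  jsonlite::write_json(summary_json,
                       file.path(output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  cfg_path <- file.path(output_dir, "config.json")
  write_run_config(config, cfg_path)
  log_lines <- c(
    paste("taurflux", as.character(utils::packageVersion("taurflux"))),
    R.version.string,
    paste("seed:", config$seed),
    paste("config md5:", unname(tools::md5sum(cfg_path))),
    paste("inputs:", normalizePath(input_dir)),
    paste("analyzed at duration_h =", duration_h))
  writeLines(log_lines, file.path(output_dir, "run.log"))
  invisible(report)
}

wet_weight_lookup <- function(incubation) {
  u <- unique(incubation[, c("vessel", "wet_wt_g")])
  out <- as.list(stats::setNames(u$wet_wt_g, u$vessel))
  out[!is.na(unlist(out))]
}
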