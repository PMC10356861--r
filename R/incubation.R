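# Batch-incubation time-series accounting: per-vessel containers, control
# subtraction, net changes, biomass normalization and tissue-concentration
# conversions. Concentrations are uM in the incubation medium; amounts umol.

#' Construct a per-vessel incubation time series
#'
#' One incubation vessel with its treatment chemistry and time-resolved
#' analyte concentrations. No-sponge medium controls carry `wet_wt_g = NA`.
#'
#' @param vessel Vessel identifier.
#' @param medium `"FSW"` (filtered seawater) or `"SFASW"` (sulfate-free
#'   artificial seawater).
#' @param taurine_added Logical: was taurine amended?
#' @param labeled Logical: was the amendment isotopically labeled?
#' @param has_sponge Logical: does the vessel contain an explant?
#' @param wet_wt_g Explant wet weight (g); required positive when
#'   `has_sponge`, must be `NA` otherwise.
#' @param volume_l Medium volume (l), positive.
#' @param samples data.frame with columns `time_h`, `analyte` (one of
#'   `"SO4"`, `"NH4"`, `"NO2"`, `"taurine"`), `conc_uM`, and optionally
#'   `at_percent`. Times must be non-negative and sorted within analyte;
#'   concentrations non-negative.
#' @return An object of class `"incubation_series"`.
#' @export
incubation_series <- function(vessel, medium = c("SFASW", "FSW"),
                              taurine_added, labeled, has_sponge,
                              wet_wt_g = NA_real_, volume_l, samples) {
  medium <- match.arg(medium)
  stopifnot(is.logical(taurine_added), is.logical(labeled),
            is.logical(has_sponge), is.numeric(volume_l))
  if (volume_l <= 0) stop("medium volume must be positive", call. = FALSE)
  if (has_sponge) {
    if (is.na(wet_wt_g) || wet_wt_g <= 0) {
      stop("a sponge vessel requires a positive wet weight", call. = FALSE)
    }
  } else if (!is.na(wet_wt_g)) {
    stop("a no-sponge control cannot carry a wet weight", call. = FALSE)
  }
  req <- c("time_h", "analyte", "conc_uM")
  if (!is.data.frame(samples) || !all(req %in% names(samples))) {
    stop("`samples` needs columns time_h, analyte, conc_uM", call. = FALSE)
  }
  if (!"at_percent" %in% names(samples)) samples$at_percent <- NA_real_
  bad <- !samples$analyte %in% c("SO4", "NH4", "NO2", "taurine")
  if (any(bad)) {
    stop("unknown analyte(s): ", paste(unique(samples$analyte[bad]),
                                       collapse = ", "), call. = FALSE)
  }
  if (any(samples$time_h < 0)) {
    stop("sampling times must be non-negative", call. = FALSE)
  }
  if (any(samples$conc_uM < 0, na.rm = TRUE)) {
    stop("concentrations must be non-negative", call. = FALSE)
  }
  for (a in unique(samples$analyte)) {
    tt <- samples$time_h[samples$analyte == a]
    if (is.unsorted(tt, strictly = FALSE)) {
      stop("times must be sorted within analyte ", a, call. = FALSE)
    }
  }
  structure(
    list(vessel = as.character(vessel), medium = medium,
         taurine_added = taurine_added, labeled = labeled,
         has_sponge = has_sponge, wet_wt_g = wet_wt_g,
         volume_l = volume_l,
         samples = samples[, c("time_h", "analyte", "conc_uM", "at_percent")]),
    class = "incubation_series"
  )
}

#' @export
print.incubation_series <- function(x, ...) {
  cat(sprintf(
    "<incubation_series> %s | %s%s%s | %s | %.3g l | %d samples\n",
    x$vessel, x$medium,
    if (x$taurine_added) "+taurine" else "",
    if (x$labeled) "(labeled)" else "",
    if (x$has_sponge) sprintf("sponge %.2f g", x$wet_wt_g) else "no sponge",
    x$volume_l, nrow(x$samples)))
  invisible(x)
}

# exact-time lookup with a small matching tolerance; no interpolation
series_conc_at <- function(series, analyte, time_h, tol_h = 0.01) {
  s <- series$samples
  hit <- s$analyte == analyte & abs(s$time_h - time_h) <= tol_h
  if (!any(hit)) {
    stop("no ", analyte, " sample at t = ", time_h, " h in vessel ",
         series$vessel, call. = FALSE)
  }
  s$conc_uM[which(hit)[1]]
}

#' Net concentration change of an analyte between two time points
#'
#' @param series An [incubation_series()].
#' @param analyte `"SO4"`, `"NH4"`, `"NO2"` or `"taurine"`.
#' @param t0,t1 Time points (h); both must be sampled (matched within
#'   `tol_h`, no interpolation).
#' @param tol_h Time-matching tolerance (h), default 0.01.
#' @return Concentration change in uM; negative for a decline.
#' @export
net_change <- function(series, analyte, t0, t1, tol_h = 0.01) {
  stopifnot(inherits(series, "incubation_series"))
  series_conc_at(series, analyte, t1, tol_h) -
    series_conc_at(series, analyte, t0, tol_h)
}

#' Subtract the no-sponge medium control at one time point
#'
#' Removes abiotic/medium background by subtracting the matched no-sponge
#' control vessel's concentration. The two vessels must share treatment
#' chemistry (medium, taurine amendment, label).
#'
#' @param sponge An [incubation_series()] with an explant.
#' @param control The matched no-sponge [incubation_series()].
#' @param analyte Analyte name.
#' @param t Time point (h).
#' @param tol_h Time-matching tolerance (h).
#' @return Control-corrected concentration (uM); may be negative, in which
#'   case a warning is issued.
#' @export
subtract_medium_control <- function(sponge, control, analyte, t,
                                    tol_h = 0.01) {
  stopifnot(inherits(sponge, "incubation_series"),
            inherits(control, "incubation_series"))
  if (!sponge$has_sponge) {
    stop("`sponge` must contain an explant", call. = FALSE)
  }
  if (control$has_sponge) {
    stop("`control` must be a no-sponge vessel", call. = FALSE)
  }
  if (!identical(sponge$medium, control$medium) ||
      !identical(sponge$taurine_added, control$taurine_added) ||
      !identical(sponge$labeled, control$labeled)) {
    stop("treatment chemistry mismatch between sponge vessel and control",
         call. = FALSE)
  }
  out <- series_conc_at(sponge, analyte, t, tol_h) -
    series_conc_at(control, analyte, t, tol_h)
  if (out < 0) {
    warning("control exceeds sponge vessel for ", analyte, " at t = ", t,
            " h; reporting negative value", call. = FALSE)
  }
  out
}

#' Baseline-subtract a vessel's own t = 0 value
#'
#' Removes per-vessel carryover (e.g. residual sulfate leaching from sponge
#' material into sulfate-free medium) by subtracting the vessel's own
#' initial concentration rather than an external constant.
#'
#' @inheritParams net_change
#' @param t Time point (h).
#' @return Concentration above the vessel's own t = 0 baseline (uM).
#' @export
baseline_subtract <- function(series, analyte, t, tol_h = 0.01) {
  net_change(series, analyte, 0, t, tol_h)
}

#' Convert a medium concentration to an amount per g wet weight
#'
#' @param conc_uM Concentration in the incubation medium (uM).
#' @param volume_l Medium volume (l), positive.
#' @param wet_wt_g Explant wet weight (g), positive.
#' @return umol per g wet weight.
#' @export
#' @examples
#' concentration_to_per_biomass(590, 1, 10)  # 59 umol/g
concentration_to_per_biomass <- function(conc_uM, volume_l, wet_wt_g) {
  stopifnot(is.numeric(conc_uM), is.numeric(volume_l), is.numeric(wet_wt_g))
  if (any(volume_l <= 0)) stop("volume must be positive", call. = FALSE)
  if (any(wet_wt_g <= 0)) stop("wet weight must be positive", call. = FALSE)
  conc_uM * volume_l / wet_wt_g
}

#' Tissue molarity from an amount per wet weight
#'
#' Converts umol per g wet weight into an in-tissue molar concentration
#' using a tissue density assumption (default 1.2 g sponge wet weight per
#' cm^3): umol g^-1 x g cm^-3 = umol cm^-3 = mM.
#'
#' @param amount_per_wet_wt umol per g wet weight.
#' @param density_g_cm3 Tissue density (g cm^-3), positive; default 1.2.
#' @return Tissue concentration in mM.
#' @export
#' @examples
#' tissue_molarity(5.5)  # 6.6 mM
tissue_molarity <- function(amount_per_wet_wt, density_g_cm3 = 1.2) {
  stopifnot(is.numeric(amount_per_wet_wt), is.numeric(density_g_cm3))
  if (any(density_g_cm3 <= 0)) stop("density must be positive", call. = FALSE)
  amount_per_wet_wt * density_g_cm3
}
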