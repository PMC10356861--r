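# Symbiont abundance estimation: FISH cell densities from ocular-grid field
# counts, relative abundance against the general bacterial probe set, qPCR
# copies per gram with volumetric conversion, and metagenomic
# read-recruitment fractions.

#' Construct a table of FISH field-of-view counts
#'
#' Per-field counts of a probe-specific target population and of all cells
#' hybridizing with the general bacterial probe set (EUB338-I-III), together
#' with the ocular-grid geometry defining the counted volume. The default
#' geometry is a 146.25 x 146.25 um grid at 1 um optical section thickness.
#'
#' @param target_count Integer vector of target-probe counts per field.
#' @param eub_count Integer vector of general-probe counts per field (may be
#'   smaller than `target_count`: the probes differ).
#' @param grid_x_um,grid_y_um Ocular grid side lengths (um).
#' @param thickness_um Optical section thickness (um).
#' @param field Field identifiers; defaults to a sequence.
#' @return data.frame of class `"fish_field_counts"`.
#' @export
fish_field_counts <- function(target_count, eub_count = NA_real_,
                              grid_x_um = 146.25, grid_y_um = 146.25,
                              thickness_um = 1,
                              field = seq_along(target_count)) {
  stopifnot(is.numeric(target_count))
  if (any(target_count < 0) || any(eub_count < 0, na.rm = TRUE)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(grid_x_um <= 0) || any(grid_y_um <= 0) || any(thickness_um <= 0)) {
    stop("field geometry must be positive", call. = FALSE)
  }
  out <- data.frame(
    field = field,
    target_count = as.numeric(target_count),
    eub_count = as.numeric(eub_count),
    grid_x_um = grid_x_um,
    grid_y_um = grid_y_um,
    thickness_um = thickness_um
  )
  class(out) <- c("fish_field_counts", "data.frame")
  out
}

# counted volume of one field in cm^3 (um^3 -> cm^3 exact factor 1e-12)
field_volume_cm3 <- function(fields) {
  fields$grid_x_um * fields$grid_y_um * fields$thickness_um * 1e-12
}

#' FISH cell density from field-of-view counts
#'
#' Converts per-field counts into volumetric cell densities
#' (count / field volume, with the um^3 to cm^3 factor 1e-12 applied
#' exactly) and summarizes across fields. The estimator is the mean of
#' per-field densities, not pooled counts over pooled volume, so the
#' reported SD reflects field-to-field variability.
#'
#' @param fields A [fish_field_counts()] table with at least one field.
#' @return List with `mean_cells_cm3`, `sd_cells_cm3`, `n_fields` and the
#'   per-field densities.
#' @export
#' @examples
#' f <- fish_field_counts(rep(260.6, 10))
#' fish_density(f)$mean_cells_cm3  # ~1.22e10
fish_density <- function(fields) {
  stopifnot(inherits(fields, "fish_field_counts"), nrow(fields) >= 1)
  vol <- field_volume_cm3(fields)
  if (any(vol <= 0)) stop("zero field volume", call. = FALSE)
  dens <- fields$target_count / vol
  list(
    mean_cells_cm3 = mean(dens),
    sd_cells_cm3 = if (nrow(fields) > 1) stats::sd(dens) else 0,
    n_fields = nrow(fields),
    per_field_cells_cm3 = dens
  )
}

#' Target population as a fraction of general-probe-positive cells
#'
#' Mean over fields of 100 x target / EUB count. Fields with a zero
#' general-probe count are excluded with a warning.
#'
#' @param fields A [fish_field_counts()] table with `eub_count` populated.
#' @return List with `mean_percent`, `sd_percent`, `n_fields` used.
#' @export
fish_relative_fraction <- function(fields) {
  stopifnot(inherits(fields, "fish_field_counts"))
  if (anyNA(fields$eub_count)) {
    stop("eub_count is required for relative fractions", call. = FALSE)
  }
  keep <- fields$eub_count > 0
  if (!all(keep)) {
    warning(sum(!keep), " field(s) with zero general-probe count excluded",
            call. = FALSE)
  }
  f <- fields[keep, , drop = FALSE]
  if (nrow(f) == 0) stop("no usable fields", call. = FALSE)
  frac <- 100 * f$target_count / f$eub_count
  list(
    mean_percent = mean(frac),
    sd_percent = if (nrow(f) > 1) stats::sd(frac) else 0,
    n_fields = nrow(f)
  )
}

#' Convert qPCR copies per g wet weight to copies per cm^3
#'
#' Uses the tissue density assumption (default 1.2 g sponge wet weight =
#' 1 cm^3) to place gene-copy abundances on the same volumetric scale as
#' FISH cell densities.
#'
#' @param copies_per_g 16S rRNA gene copies per g wet weight.
#' @param density_g_cm3 Tissue density (g cm^-3), default 1.2.
#' @return Copies per cm^3.
#' @export
qpcr_volumetric <- function(copies_per_g, density_g_cm3 = 1.2) {
  stopifnot(is.numeric(copies_per_g), is.numeric(density_g_cm3))
  if (any(density_g_cm3 <= 0)) stop("density must be positive", call. = FALSE)
  copies_per_g * density_g_cm3
}

#' Per-symbiont shares of summed qPCR copies
#'
#' @param copies Named numeric vector of copies per g for each assayed
#'   symbiont.
#' @return Named percentages summing to 100.
#' @export
qpcr_shares <- function(copies) {
  stopifnot(is.numeric(copies))
  if (any(copies < 0)) stop("copy numbers must be non-negative", call. = FALSE)
  total <- sum(copies)
  if (total <= 0) stop("summed copies are zero; shares undefined", call. = FALSE)
  100 * copies / total
}

#' Metagenomic read-recruitment relative abundance
#'
#' Relative abundance of a genome bin as the percentage of sequenced
#' fragments mapping to it: 100 x mapped / total.
#'
#' @param mapped_fragments Fragments mapping to the bin.
#' @param total_fragments Total QC fragments in the dataset; must be
#'   positive and at least `mapped_fragments`.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' read_recruitment_fraction(302, 10000)  # 3.02
read_recruitment_fraction <- function(mapped_fragments, total_fragments) {
  stopifnot(is.numeric(mapped_fragments), is.numeric(total_fragments))
  if (any(total_fragments <= 0)) {
    stop("total fragments must be positive", call. = FALSE)
  }
  if (any(mapped_fragments < 0)) {
    stop("mapped fragments must be non-negative", call. = FALSE)
  }
  if (any(mapped_fragments > total_fragments)) {
    stop("mapped fragments exceed total fragments", call. = FALSE)
  }
  100 * mapped_fragments / total_fragments
}
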