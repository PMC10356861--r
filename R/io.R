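# Tabular readers and writers for the pipeline's TSV dialects. All readers
# hard-error on missing required columns and report per-row diagnostics
# with file line numbers (header = line 1).

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_checked <- function(path, required, table_name) {
  if (!file.exists(path)) {
    stop(table_name, " table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(table_name, " table ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    stop(table_name, " table ", path, " is empty", call. = FALSE)
  }
  df
}

row_check <- function(df, ok, message, table_name) {
  if (any(!ok)) {
    lines <- which(!ok) + 1L  # header occupies line 1
    stop(table_name, ": ", message, " (line",
         if (length(lines) > 1) "s" else "", " ",
         paste(utils::head(lines, 10), collapse = ", "),
         if (length(lines) > 10) ", ..." else "", ")",
         call. = FALSE)
  }
}

#' Read a long-format incubation concentration table
#'
#' Expected columns: `vessel`, `treatment`, `wet_wt_g`, `volume_l`,
#' `time_h`, `analyte`, `conc_uM`, and optionally `at_percent`.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_incubation_table <- function(path) {
  df <- read_tsv_checked(path, c("vessel", "treatment", "wet_wt_g",
                                 "volume_l", "time_h", "analyte",
                                 "conc_uM"), "incubation")
  if (!"at_percent" %in% names(df)) df$at_percent <- NA_real_
  row_check(df, !is.na(df$time_h) & df$time_h >= 0,
            "time_h must be >= 0", "incubation")
  row_check(df, is.na(df$conc_uM) | df$conc_uM >= 0,
            "conc_uM must be >= 0", "incubation")
  row_check(df, df$analyte %in% c("SO4", "NH4", "NO2", "taurine"),
            "unknown analyte", "incubation")
  row_check(df, is.na(df$volume_l) | df$volume_l > 0,
            "volume_l must be positive", "incubation")
  df
}

#' Read an atom-fraction measurement table
#'
#' Expected columns: `element`, `pool`, `context`,
#' `atom_fraction_percent`, `n_total_umol`, `replicate`, `time_h`.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_atom_fraction_table <- function(path) {
  df <- read_tsv_checked(path, c("element", "pool", "context",
                                 "atom_fraction_percent", "n_total_umol",
                                 "replicate", "time_h"), "atom-fraction")
  row_check(df, df$element %in% c("C", "N"),
            "element must be C or N", "atom-fraction")
  row_check(df, df$pool %in% c("sponge-biomass", "nucleic-acids", "NH4",
                               "NO2", "control"),
            "unknown pool", "atom-fraction")
  row_check(df, df$context %in% c("sponge", "seawater"),
            "context must be sponge or seawater", "atom-fraction")
  row_check(df, !is.na(df$atom_fraction_percent) &
              df$atom_fraction_percent >= 0 &
              df$atom_fraction_percent <= 100,
            "atom_fraction_percent must lie in [0, 100]", "atom-fraction")
  row_check(df, !is.na(df$n_total_umol) & df$n_total_umol >= 0,
            "n_total_umol must be >= 0", "atom-fraction")
  df
}

#' Read a FISH field-count table
#'
#' Expected columns: `field`, `target_count`, `eub_count`, `grid_x_um`,
#' `grid_y_um`, `thickness_um`.
#'
#' @param path TSV file path.
#' @return A [fish_field_counts()] table.
#' @export
read_fish_table <- function(path) {
  df <- read_tsv_checked(path, c("field", "target_count", "eub_count",
                                 "grid_x_um", "grid_y_um", "thickness_um"),
                         "FISH")
  fish_field_counts(df$target_count, df$eub_count, df$grid_x_um,
                    df$grid_y_um, df$thickness_um, field = df$field)
}

#' Read a qPCR copy-number table
#'
#' Expected columns: `symbiont`, `copies_per_g`.
#'
#' @param path TSV file path.
#' @return Validated data.frame.
#' @export
read_qpcr_table <- function(path) {
  df <- read_tsv_checked(path, c("symbiont", "copies_per_g"), "qPCR")
  row_check(df, !is.na(df$copies_per_g) & df$copies_per_g >= 0,
            "copies_per_g must be >= 0", "qPCR")
  df
}

#' Read a spectral-count table
#'
#' Expected columns: `sample`, `protein`, `bin`, `spectral_count`,
#' `length_aa`.
#'
#' @param path TSV file path.
#' @return A [spectral_counts()] table.
#' @export
read_spectral_count_table <- function(path) {
  df <- read_tsv_checked(path, c("sample", "protein", "bin",
                                 "spectral_count", "length_aa"),
                         "spectral-count")
  spectral_counts(df$sample, df$protein, df$bin, df$spectral_count,
                  df$length_aa)
}
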