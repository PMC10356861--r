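# NSAF metaproteome quantitation: spectral abundance factors normalized per
# sample, aggregated to genome-bin and protein-set shares.

#' Construct a spectral-count table
#'
#' @param sample Sample identifiers.
#' @param protein Protein identifiers (unique within sample).
#' @param bin Genome-bin assignment (a MAG id, the host, or
#'   `"contaminant"`).
#' @param spectral_count Non-negative integer spectral counts.
#' @param length_aa Protein length in amino acids, positive.
#' @return data.frame of class `"spectral_counts"`.
#' @export
spectral_counts <- function(sample, protein, bin, spectral_count, length_aa) {
  stopifnot(is.numeric(spectral_count), is.numeric(length_aa))
  if (any(spectral_count < 0)) {
    stop("spectral counts must be non-negative", call. = FALSE)
  }
  if (any(abs(spectral_count - round(spectral_count)) > 1e-8)) {
    stop("spectral counts must be integral", call. = FALSE)
  }
  if (any(length_aa <= 0)) {
    stop("protein lengths must be positive", call. = FALSE)
  }
  out <- data.frame(
    sample = as.character(sample), protein = as.character(protein),
    bin = as.character(bin), spectral_count = as.numeric(spectral_count),
    length_aa = as.numeric(length_aa), stringsAsFactors = FALSE
  )
  dup <- duplicated(out[, c("sample", "protein")])
  if (any(dup)) {
    stop("duplicated protein within sample: ",
         paste(unique(out$protein[dup]), collapse = ", "), call. = FALSE)
  }
  class(out) <- c("spectral_counts", "data.frame")
  out
}

#' Normalized spectral abundance factors for one sample
#'
#' SAF_i = SpC_i / L_i (spectral count over length) and
#' NSAF_i = SAF_i / sum_j SAF_j, so NSAF sums to exactly 1 over all
#' identified proteins in a sample. Proteins with zero counts get NSAF 0.
#' The normalization base includes every identified protein in the sample
#' (including contaminant bins); exclude bins downstream via
#' [bin_share()]'s `exclude_bins`.
#'
#' @param records A [spectral_counts()] table, or plain data.frame with the
#'   same columns, for a single sample.
#' @return data.frame with columns `protein`, `bin`, `nsaf`.
#' @export
#' @examples
#' sc <- spectral_counts("s1", c("p1", "p2"), "MAG_1", c(10, 10), c(100, 200))
#' nsaf(sc)$nsaf  # 2/3, 1/3
nsaf <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$sample)) > 1) {
    stop("nsaf() operates on one sample; see nsaf_by_sample()", call. = FALSE)
  }
  saf <- records$spectral_count / records$length_aa
  total <- sum(saf)
  if (total <= 0) {
    stop("all spectral counts are zero; NSAF normalization undefined",
         call. = FALSE)
  }
  data.frame(protein = records$protein, bin = records$bin,
             nsaf = saf / total, stringsAsFactors = FALSE)
}

#' NSAF per sample across a multi-sample table
#'
#' @param records A [spectral_counts()] table covering >= 1 samples.
#' @return data.frame with columns `sample`, `protein`, `bin`, `nsaf`;
#'   NSAF sums to 1 within each sample.
#' @export
nsaf_by_sample <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  out <- lapply(split(records, records$sample), function(d) {
    cbind(sample = d$sample[1], nsaf(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Replicate-averaged NSAF
#'
#' Per-sample NSAF values averaged by arithmetic mean across samples
#' (per-sample normalization first, then the mean — never pooled counts).
#' Proteins absent from a sample contribute 0 to that sample.
#'
#' @param records A multi-sample [spectral_counts()] table.
#' @return data.frame `protein`, `bin`, `mean_nsaf`; `mean_nsaf` sums to 1
#'   when every sample identified the same protein universe.
#' @export
nsaf_mean <- function(records) {
  per <- nsaf_by_sample(records)
  samples <- unique(per$sample)
  key <- unique(per[, c("protein", "bin")])
  m <- matrix(0, nrow(key), length(samples),
              dimnames = list(key$protein, samples))
  for (i in seq_len(nrow(per))) {
    m[per$protein[i], per$sample[i]] <- per$nsaf[i]
  }
  data.frame(protein = key$protein, bin = key$bin,
             mean_nsaf = rowMeans(m), stringsAsFactors = FALSE)
}

#' NSAF share of a genome bin
#'
#' 100 x sum of NSAF over the target bin, optionally renormalized after
#' excluding bins (e.g. `"contaminant"` or the host) from the base.
#'
#' @param nsaf_table Output of [nsaf()] or [nsaf_mean()] (the NSAF column
#'   may be named `nsaf` or `mean_nsaf`).
#' @param target_bin Bin whose share to report; must exist in the table
#'   unless `allow_missing`.
#' @param exclude_bins Character vector of bins dropped from both numerator
#'   and normalization base.
#' @param allow_missing If `TRUE`, an absent target bin yields 0% instead of
#'   an error.
#' @return Percentage in `[0, 100]`.
#' @export
bin_share <- function(nsaf_table, target_bin, exclude_bins = character(),
                      allow_missing = FALSE) {
  v <- nsaf_values(nsaf_table)
  if (!target_bin %in% nsaf_table$bin && !allow_missing) {
    stop("unknown bin: ", target_bin, call. = FALSE)
  }
  keep <- !nsaf_table$bin %in% exclude_bins
  base <- sum(v[keep])
  if (base <= 0) stop("empty normalization base", call. = FALSE)
  100 * sum(v[keep & nsaf_table$bin == target_bin]) / base
}

#' NSAF share of a protein set
#'
#' 100 x sum of NSAF over a protein set relative to a configurable base:
#' the whole sample or the set's genome bin (within-bin renormalization,
#' used e.g. to express a pathway's share of one symbiont's proteome).
#'
#' @inheritParams bin_share
#' @param proteins Character vector of protein ids; must be present in the
#'   table.
#' @param base `"sample"` (default) or `"bin"`.
#' @param bin Required when `base = "bin"`: the bin defining the
#'   normalization base; `proteins` must all belong to it.
#' @return Percentage in `[0, 100]`.
#' @export
protein_set_share <- function(nsaf_table, proteins,
                              base = c("sample", "bin"), bin = NULL) {
  base <- match.arg(base)
  v <- nsaf_values(nsaf_table)
  missing <- setdiff(proteins, nsaf_table$protein)
  if (length(missing)) {
    stop("unknown protein(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  in_set <- nsaf_table$protein %in% proteins
  if (base == "bin") {
    if (is.null(bin)) stop("`bin` required when base = \"bin\"", call. = FALSE)
    if (any(nsaf_table$bin[in_set] != bin)) {
      stop("protein set is not contained in bin ", bin, call. = FALSE)
    }
    denom <- sum(v[nsaf_table$bin == bin])
  } else {
    denom <- sum(v)
  }
  if (denom <= 0) stop("empty normalization base", call. = FALSE)
  100 * sum(v[in_set]) / denom
}

nsaf_values <- function(nsaf_table) {
  stopifnot(is.data.frame(nsaf_table), "bin" %in% names(nsaf_table))
  col <- intersect(c("nsaf", "mean_nsaf"), names(nsaf_table))
  if (!length(col)) stop("no NSAF column found", call. = FALSE)
  nsaf_table[[col[1]]]
}
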