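#' Construct a CSF biomarker table
#'
#' Long-format table of raw cerebrospinal-fluid analyte levels. Recognised
#' analytes are `alpha_synuclein`, `abeta_1_42`, `t_tau` and `p_tau`, all in
#' pg/mL; other analyte labels are allowed but the four CSF analytes are
#' what the downstream models expect.
#'
#' @param sample_id Sample labels.
#' @param analyte Analyte labels.
#' @param raw_level Positive raw levels (pg/mL).
#' @param platform Cohort/kit labels (raw levels from different kits are not
#'   comparable and must be harmonized before joint analysis).
#' @param age_at_lp Age at lumbar puncture in years (optional, `NA` allowed).
#' @return A `biomarker_table` data frame with an empty `harmonized_level`
#'   column.
#' @export
biomarker_table <- function(sample_id, analyte, raw_level, platform,
                            age_at_lp = NA_real_) {
  out <- data.frame(sample_id = as.character(sample_id),
                    analyte = as.character(analyte),
                    raw_level = as.numeric(raw_level),
                    platform = as.character(platform),
                    age_at_lp = as.numeric(age_at_lp),
                    harmonized_level = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Harmonize biomarker levels across platforms
#'
#' Raw CSF analyte levels measured with different kits cannot be pooled
#' directly. Harmonization log10-transforms the raw levels to normalize
#' their skewed distributions and then centers each platform-by-analyte
#' stratum at zero by subtracting the stratum mean of the log10 values.
#' Centering (rather than full z-scoring) preserves each analyte's natural
#' log10-scale dispersion while removing the kit-specific location, and it
#' makes the harmonized values exactly invariant to rescaling all raw
#' levels on one platform by a constant. Strata are platform x analyte
#' only: cases and controls are centered together, so case-control
#' contrasts survive harmonization.
#'
#' @param table A `biomarker_table`.
#' @param log_transform Apply the log10 transform (default `TRUE`). With
#'   `FALSE` the values are treated as already being on the log scale and
#'   only re-centered.
#' @return The table with `harmonized_level` filled in; raw levels are
#'   untouched. Each stratum's harmonized mean is zero to within 1e-9.
#' @export
harmonize <- function(table, log_transform = TRUE) {
  stopifnot(is.data.frame(table))
  vals <- if (log_transform) {
    bad <- !is.na(table$raw_level) & table$raw_level <= 0
    if (any(bad))
      stop("non-positive raw level for sample(s): ",
           paste(unique(table$sample_id[bad]), collapse = ", "))
    log10(table$raw_level)
  } else {
    table$harmonized_level
  }
  key <- interaction(table$platform, table$analyte, drop = TRUE)
  sizes <- table(key[!is.na(vals)])
  if (any(sizes < 2))
    stop("singleton platform-analyte stratum (centering undefined): ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  centered <- vals - stats::ave(vals, key, FUN = function(v) mean(v, na.rm = TRUE))
  table$harmonized_level <- centered
  table
}

#' Read / write long-format biomarker TSV
#'
#' Columns: `sample_id analyte raw_level platform age_at_lp
#' [harmonized_level]`.
#'
#' @param path File path.
#' @return For `read_biomarker_tsv`, a `biomarker_table`.
#' @export
read_biomarker_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  out <- biomarker_table(tab$sample_id, tab$analyte, tab$raw_level,
                         tab$platform,
                         if ("age_at_lp" %in% names(tab)) tab$age_at_lp else NA_real_)
  if ("harmonized_level" %in% names(tab))
    out$harmonized_level <- tab$harmonized_level
  out
}

#' @rdname read_biomarker_tsv
#' @param table A `biomarker_table`.
#' @export
write_biomarker_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
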