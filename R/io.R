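#' Read a dosage matrix from TSV
#'
#' Expects a header row of variant IDs, a first column of sample IDs, and
#' effect-allele dosages in \[0, 2\] (missing as `NA`).
#'
#' @param path Path to the tab-separated dosage file.
#' @param platform Per-sample platform labels, or a single label.
#' @param info_path Optional path to a per-variant INFO-score TSV with
#'   columns `variant_id` and `info`.
#' @return A `dosage_matrix`.
#' @export
read_dosage_tsv <- function(path, platform = "cohort1", info_path = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  info <- NULL
  if (!is.null(info_path)) {
    it <- utils::read.delim(info_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    info <- stats::setNames(it$info, it$variant_id)
  }
  dosage_matrix(d, platform = platform, info_scores = info)
}

#' Write a dosage matrix to TSV
#'
#' @param matrix A `dosage_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(matrix, path) {
  d <- matrix$dosages
  out <- data.frame(sample_id = rownames(d), d, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read effect-allele dosages from a VCF
#'
#' Reads the per-genotype dosage (`DS`) and, when present, genotype
#' probability (`GP`) FORMAT fields of a VCF. Variants are matched to a
#' scoring panel downstream by variant ID and effect allele: the VCF ALT
#' allele must equal the panel's effect allele, otherwise scoring raises an
#' error rather than silently flipping strands.
#'
#' @param path Path to a VCF file (uncompressed or bgzipped).
#' @param platform Per-sample platform labels, or a single label.
#' @return A `dosage_matrix` whose `alt_allele` attribute records each
#'   variant's ALT allele.
#' @export
read_dosage_vcf <- function(path, platform = "cohort1") {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF input requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  # vcfR returns variants x samples; transpose to samples x variants
  d <- t(ds)
  ids <- v@fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(v@fix[, "CHROM"], ":", v@fix[, "POS"])[
    is.na(ids) | ids == "."]
  colnames(d) <- ids
  gp_arr <- NULL
  fmt <- v@gt[, 1]
  if (all(grepl("GP", fmt))) {
    gp <- vcfR::extract.gt(v, element = "GP")
    gp_arr <- array(NA_real_, dim = c(ncol(gp), nrow(gp), 3),
                    dimnames = list(colnames(gp), ids, NULL))
    for (k in 1:3) {
      gp_arr[, , k] <- t(apply(gp, c(1, 2), function(s) {
        if (is.na(s)) NA_real_ else as.numeric(strsplit(s, ",")[[1]][k])
      }))
    }
  }
  m <- dosage_matrix(d, platform = platform, genotype_probabilities = gp_arr)
  attr(m, "alt_allele") <- stats::setNames(v@fix[, "ALT"], ids)
  m
}

#' Write a QC exclusion report
#'
#' @param report The `report` data frame from [variant_filters()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a score set to TSV
#'
#' Columns: `sample_id`, `score`, `n_variants_used`, `tertile`.
#'
#' @param scores A `score_set` data frame from [compute_prs()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scores_tsv <- function(scores, path) {
  cols <- intersect(c("sample_id", "score", "n_variants_used", "tertile"),
                    names(scores))
  utils::write.table(scores[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write association results
#'
#' Writes the tabular results as TSV and, optionally, a JSON bundle of the
#' same rows.
#'
#' @param results A data frame of association results (one row per test).
#' @param path Output TSV path.
#' @param json_path Optional path for a JSON copy.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, json_path = NULL) {
  utils::write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(results, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(path)
}
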