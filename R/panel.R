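#' Log2 odds-ratio weight for a risk variant
#'
#' The per-variant weight of the weighted PRS is the binary logarithm of the
#' published per-effect-allele odds ratio, so risk alleles (OR > 1) receive
#' positive weights and protective alleles (OR < 1) negative ones, and an OR
#' of exactly 1 carries no weight.
#'
#' @param odds_ratio Numeric vector of positive, finite odds ratios.
#' @param variant_id Optional vector of variant labels, used only to make
#'   error messages name the offending variant.
#' @return Numeric vector of weights, `log2(odds_ratio)`.
#' @examples
#' compute_weight(2.307)  # GBA-SYT11 locus: 1.206
#' compute_weight(0.882)  # protective allele: -0.181
#' @export
compute_weight <- function(odds_ratio, variant_id = NULL) {
  bad <- !is.finite(odds_ratio) | odds_ratio <= 0
  if (any(bad)) {
    who <- if (is.null(variant_id)) paste0("element ", which(bad)) else variant_id[bad]
    stop("odds ratio must be positive and finite; offending variant(s): ",
         paste(who, collapse = ", "))
  }
  log2(odds_ratio)
}

#' Load a risk-locus panel table
#'
#' Reads a tab-separated GWAS risk-locus table (one row per variant:
#' identifier, chromosome, position, gene label, effect allele, reference
#' MAF, odds ratio, and optionally study MAF, overall call rate and a
#' pre-computed weight) and returns a validated `risk_variant_table`.
#'
#' Weights are derived from the odds ratio via [compute_weight()]. When the
#' file carries its own `weight` column and `use_printed_weights = TRUE`
#' (the default), those published weights take precedence for rows where
#' they are present, so a score built from the table reproduces the
#' published score verbatim even where the printed weight was not derived
#' by the log2 rule. Rows without an odds ratio are retained but carry no
#' weight and can never be selected into a scoring panel.
#'
#' @param path Path to the tab-separated table. Defaults to the packaged
#'   26-locus Parkinson disease panel.
#' @param use_printed_weights Keep a `weight` column found in the file
#'   (default `TRUE`); if `FALSE` weights are always recomputed as log2(OR).
#' @return A data frame of class `risk_variant_table` with columns
#'   `variant_id`, `chrom`, `pos`, `gene`, `effect_allele`, `ref_maf`,
#'   `odds_ratio`, `study_maf`, `call_rate`, `weight`.
#' @export
load_panel_table <- function(path = pd_panel_path(), use_printed_weights = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  required <- c("variant_id", "chrom", "pos", "effect_allele")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("panel table lacks required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"or" %in% names(tab) && !"odds_ratio" %in% names(tab))
    stop("panel table lacks an odds-ratio column ('or' or 'odds_ratio')")
  if ("or" %in% names(tab)) names(tab)[names(tab) == "or"] <- "odds_ratio"

  if (nrow(tab) == 0) return(empty_panel_table())

  dup <- duplicated(tab$variant_id)
  if (any(dup))
    stop("duplicate variant_id in panel table: ",
         paste(unique(tab$variant_id[dup]), collapse = ", "))
  ok_allele <- tab$effect_allele %in% c("A", "C", "G", "T")
  if (!all(ok_allele))
    stop("malformed effect allele for variant(s): ",
         paste(tab$variant_id[!ok_allele], collapse = ", "))

  for (col in c("ref_maf", "study_maf", "call_rate", "weight", "gene")) {
    if (!col %in% names(tab)) tab[[col]] <- if (col == "gene") NA_character_ else NA_real_
  }
  freq_cols <- c("ref_maf", "study_maf", "call_rate")
  for (col in freq_cols) {
    v <- tab[[col]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      stop(col, " outside [0,1] for variant(s): ",
           paste(tab$variant_id[!is.na(v) & (v < 0 | v > 1)], collapse = ", "))
  }

  has_or <- !is.na(tab$odds_ratio)
  if (any(!has_or))
    warning("variant(s) without an odds ratio are retained but unselectable: ",
            paste(tab$variant_id[!has_or], collapse = ", "))
  computed <- rep(NA_real_, nrow(tab))
  computed[has_or] <- compute_weight(tab$odds_ratio[has_or], tab$variant_id[has_or])
  if (use_printed_weights) {
    use_computed <- is.na(tab$weight) & has_or
    tab$weight[use_computed] <- computed[use_computed]
  } else {
    tab$weight <- computed
  }
  # a variant with no genotype data (no call rate) can never be scored
  tab$weight[is.na(tab$call_rate)] <- tab$weight[is.na(tab$call_rate)]

  out <- tab[, c("variant_id", "chrom", "pos", "gene", "effect_allele",
                 "ref_maf", "odds_ratio", "study_maf", "call_rate", "weight")]
  class(out) <- c("risk_variant_table", "data.frame")
  out
}

empty_panel_table <- function() {
  out <- data.frame(variant_id = character(), chrom = character(),
                    pos = integer(), gene = character(),
                    effect_allele = character(), ref_maf = numeric(),
                    odds_ratio = numeric(), study_maf = numeric(),
                    call_rate = numeric(), weight = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("risk_variant_table", "data.frame")
  out
}

#' Path to the packaged Parkinson disease risk-locus table
#'
#' The 26-locus GWAS meta-analysis panel (effect alleles, odds ratios,
#' study minor-allele frequencies, overall call rates and published
#' weights) shipped with the package.
#'
#' @return File path of the tab-separated panel table.
#' @export
pd_panel_path <- function() {
  system.file("extdata", "pd_risk_panel.tsv", package = "pdprs", mustWork = TRUE)
}

#' Select the scoring panel by overall call rate
#'
#' Applies the panel-selection rule: a variant enters the scoring panel only
#' if its overall (joint genotyped-or-imputed) call rate is strictly greater
#' than `threshold` and it has a defined weight. With the packaged 26-locus
#' table and the default threshold of 0.85 this yields the 16-variant score.
#'
#' @param variants A `risk_variant_table` from [load_panel_table()].
#' @param threshold Call-rate threshold in (0, 1]; the comparison is strict
#'   (`call_rate > threshold`). Default 0.85.
#' @param provenance Free-text description of the table source.
#' @return A `scoring_panel` object: list with `variants` (selected rows in
#'   table order), `excluded` (dropped rows plus a `reason` column),
#'   `call_rate_threshold` and `provenance`.
#' @export
select_panel <- function(variants, threshold = 0.85,
                         provenance = "risk-locus table") {
  # idempotence: accept an already-selected panel
  if (inherits(variants, "scoring_panel")) variants <- variants$variants
  stopifnot(is.data.frame(variants))
  if (!(threshold > 0 && threshold <= 1)) stop("threshold must lie in (0, 1]")

  no_data <- is.na(variants$call_rate)
  no_weight <- is.na(variants$weight)
  low_rate <- !no_data & variants$call_rate <= threshold
  keep <- !no_data & !no_weight & variants$call_rate > threshold

  reason <- rep(NA_character_, nrow(variants))
  reason[low_rate] <- "call rate at or below threshold"
  reason[no_data] <- "no genotype data (call rate unavailable)"
  reason[!keep & is.na(reason)] <- "no weight defined"

  excluded <- variants[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- reason[!keep]
  else excluded$reason <- character(0)

  structure(list(variants = variants[keep, , drop = FALSE],
                 excluded = excluded,
                 call_rate_threshold = threshold,
                 provenance = provenance),
            class = "scoring_panel")
}

#' @export
print.scoring_panel <- function(x, ...) {
  cat("Scoring panel (", nrow(x$variants), " variants, call rate > ",
      x$call_rate_threshold, ")\n", sep = "")
  cat("Source: ", x$provenance, "\n", sep = "")
  print(x$variants[, c("variant_id", "gene", "effect_allele", "odds_ratio",
                       "study_maf", "call_rate", "weight")], row.names = FALSE)
  if (nrow(x$excluded))
    cat(nrow(x$excluded), "variant(s) excluded:",
        paste(x$excluded$variant_id, collapse = ", "), "\n")
  invisible(x)
}

#' The default 16-variant Parkinson disease scoring panel
#'
#' Convenience wrapper: loads the packaged risk-locus table and applies the
#' call-rate selection rule.
#'
#' @inheritParams select_panel
#' @return A `scoring_panel` of the variants passing selection.
#' @export
pd_scoring_panel <- function(threshold = 0.85) {
  select_panel(load_panel_table(), threshold = threshold,
               provenance = "packaged 26-locus PD GWAS panel")
}
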