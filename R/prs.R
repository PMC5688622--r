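#' Compute the weighted polygenic risk score
#'
#' For each sample, the PRS is the weighted sum over panel variants of the
#' effect-allele dosage times the variant's log2 odds-ratio weight. A plain
#' sum (not a per-allele average) is used, so removing a variant's
#' contribution is exactly additive. Missing dosages are handled by policy:
#' `mean_impute` (default) substitutes twice the variant's study MAF (the
#' Hardy-Weinberg expected dosage), `omit` drops the variant from that
#' sample's sum and decrements `n_variants_used`.
#'
#' @param matrix A `dosage_matrix` whose columns include every panel variant.
#' @param panel A `scoring_panel` from [select_panel()].
#' @param missing_policy `"mean_impute"` or `"omit"`.
#' @return A `score_set` data frame: `sample_id`, `score`,
#'   `n_variants_used`, `tertile` (`NA` until [assign_tertiles()]); the
#'   panel provenance is kept in the `panel_id` attribute.
#' @export
compute_prs <- function(matrix, panel,
                        missing_policy = c("mean_impute", "omit")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(panel, "scoring_panel"))
  pv <- panel$variants
  if (nrow(pv) == 0) {
    out <- data.frame(sample_id = rownames(matrix$dosages), score = 0,
                      n_variants_used = 0L, tertile = NA_character_,
                      stringsAsFactors = FALSE)
    return(as_score_set(out, panel$provenance))
  }
  absent <- setdiff(pv$variant_id, colnames(matrix$dosages))
  if (length(absent))
    stop("panel variant(s) absent from the dosage matrix: ",
         paste(absent, collapse = ", "))
  alt <- attr(matrix, "alt_allele")
  if (!is.null(alt)) {
    mism <- pv$variant_id[alt[pv$variant_id] != pv$effect_allele]
    if (length(mism))
      stop("effect allele does not match the genotype file ALT allele for: ",
           paste(mism, collapse = ", "))
  }
  d <- matrix$dosages[, pv$variant_id, drop = FALSE]
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  w <- pv$weight
  miss <- is.na(d)
  n_used <- as.integer(ncol(d) - rowSums(miss))
  if (missing_policy == "mean_impute") {
    if (any(miss)) {
      if (anyNA(pv$study_maf))
        stop("mean imputation needs a study MAF for every panel variant; missing for: ",
             paste(pv$variant_id[is.na(pv$study_maf)], collapse = ", "))
      fill <- rep(2 * pv$study_maf, each = nrow(d))
      dim(fill) <- dim(d)
      d[miss] <- fill[miss]
    }
    n_used <- rep(ncol(d), nrow(d))
  } else {
    d[miss] <- 0
  }
  score <- as.numeric(d %*% w)
  out <- data.frame(sample_id = rownames(matrix$dosages), score = score,
                    n_variants_used = as.integer(n_used),
                    tertile = NA_character_, stringsAsFactors = FALSE)
  as_score_set(out, panel$provenance)
}

as_score_set <- function(df, panel_id) {
  attr(df, "panel_id") <- panel_id
  class(df) <- c("score_set", "data.frame")
  df
}

#' Leave-one-variant-out polygenic risk score
#'
#' Recomputes the PRS with one panel variant excluded, the sensitivity
#' analysis used to test whether a single locus drives an association. On
#' fully observed data the result equals the full score minus the excluded
#' variant's dosage-times-weight contribution, exactly.
#'
#' @inheritParams compute_prs
#' @param excluded_variant Variant ID to drop; must be in the panel.
#' @return A `score_set`, as [compute_prs()].
#' @export
leave_one_out_prs <- function(matrix, panel, excluded_variant,
                              missing_policy = c("mean_impute", "omit")) {
  stopifnot(inherits(panel, "scoring_panel"))
  if (!excluded_variant %in% panel$variants$variant_id)
    stop("variant '", excluded_variant, "' is not in the scoring panel")
  reduced <- panel
  reduced$variants <- panel$variants[panel$variants$variant_id != excluded_variant, ,
                                     drop = FALSE]
  reduced$provenance <- paste0(panel$provenance, " minus ", excluded_variant)
  compute_prs(matrix, reduced, missing_policy = missing_policy)
}

#' Assign PRS tertiles
#'
#' Ranks samples by score (ties broken by sample ID, so the assignment is
#' reproducible), cuts the ranking at `ceiling(n/3)` and `ceiling(2n/3)`,
#' and labels the thirds `T1` (lowest scores) to `T3` (highest).
#'
#' @param scores A `score_set` with at least 3 samples.
#' @return The `score_set` with the `tertile` column filled in.
#' @export
assign_tertiles <- function(scores) {
  n <- nrow(scores)
  if (n < 3) stop("tertile assignment needs at least 3 samples")
  ord <- order(scores$score, scores$sample_id)
  cut1 <- ceiling(n / 3)
  cut2 <- ceiling(2 * n / 3)
  lab <- character(n)
  lab[ord[seq_len(cut1)]] <- "T1"
  lab[ord[seq(cut1 + 1, cut2)]] <- "T2"
  lab[ord[seq(cut2 + 1, n)]] <- "T3"
  scores$tertile <- lab
  scores
}
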