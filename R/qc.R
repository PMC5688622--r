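#' Construct a dosage matrix
#'
#' Container for per-individual effect-allele dosages (samples in rows,
#' variants in columns, values in \[0, 2\] or `NA` for missing), together
#' with per-sample platform labels, optional per-variant imputation INFO
#' scores, and optional per-genotype probability triples.
#'
#' @param dosages Numeric matrix, samples x variants, with row and column
#'   names; entries in \[0, 2\] or `NA`.
#' @param platform Character vector of per-sample cohort/array labels
#'   (recycled if length 1).
#' @param info_scores Optional named numeric vector of per-variant
#'   imputation quality scores in \[0, 1\].
#' @param genotype_probabilities Optional numeric array
#'   `samples x variants x 3` of genotype probabilities (hom-ref, het,
#'   hom-effect order is irrelevant to filtering; only the maximum is used),
#'   each in \[0, 1\] with triple sums at most 1 (plus rounding tolerance).
#' @return A `dosage_matrix` object.
#' @export
dosage_matrix <- function(dosages, platform = "cohort1", info_scores = NULL,
                          genotype_probabilities = NULL) {
  stopifnot(is.matrix(dosages))
  if (is.null(rownames(dosages)) || is.null(colnames(dosages)))
    stop("dosage matrix needs sample IDs as rownames and variant IDs as colnames")
  if (anyDuplicated(rownames(dosages))) stop("duplicate sample IDs")
  if (anyDuplicated(colnames(dosages))) stop("duplicate variant IDs")
  rng <- range(dosages, na.rm = TRUE)
  if (!all(is.na(dosages)) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  if (length(platform) == 1) platform <- rep(platform, nrow(dosages))
  if (length(platform) != nrow(dosages))
    stop("platform must have one label per sample")
  platform <- stats::setNames(as.character(platform), rownames(dosages))
  if (!is.null(info_scores)) {
    if (is.null(names(info_scores))) stop("info_scores must be named by variant")
    if (any(info_scores < 0 | info_scores > 1, na.rm = TRUE))
      stop("info scores must lie in [0, 1]")
  }
  if (!is.null(genotype_probabilities)) {
    gp <- genotype_probabilities
    if (!identical(dim(gp)[1:2], dim(dosages)) || dim(gp)[3] != 3)
      stop("genotype_probabilities must be samples x variants x 3")
    if (any(gp < 0 | gp > 1, na.rm = TRUE)) {
      bad <- which(gp < 0 | gp > 1, arr.ind = TRUE)[1, ]
      stop("genotype probability outside [0,1] at sample ",
           rownames(dosages)[bad[1]], ", variant ", colnames(dosages)[bad[2]])
    }
    sums <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    if (any(sums > 1 + 1e-6, na.rm = TRUE)) {
      bad <- which(sums > 1 + 1e-6, arr.ind = TRUE)
      bad <- matrix(bad, ncol = 2)[1, ]
      stop("genotype probability triple sums above 1 at sample ",
           rownames(dosages)[bad[1]], ", variant ", colnames(dosages)[bad[2]])
    }
  }
  structure(list(dosages = dosages, platform = platform,
                 info_scores = info_scores,
                 genotype_probabilities = genotype_probabilities),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("Dosage matrix:", nrow(x$dosages), "samples x", ncol(x$dosages),
      "variants;", length(unique(x$platform)), "platform(s)\n")
  cr <- variant_call_rates(x)
  cat(sprintf("Call rate: mean %.3f, min %.3f\n",
              mean(cr), if (length(cr)) min(cr) else NA))
  invisible(x)
}

#' Per-variant observed call rates
#'
#' @param matrix A `dosage_matrix`.
#' @param platform Optional platform label; when given, call rates are
#'   computed within that platform only.
#' @return Named numeric vector, fraction of non-missing genotypes per variant.
#' @export
variant_call_rates <- function(matrix, platform = NULL) {
  d <- matrix$dosages
  if (!is.null(platform)) d <- d[matrix$platform == platform, , drop = FALSE]
  colMeans(!is.na(d))
}

#' QC threshold bundle
#'
#' @param hard_call_min_probability Genotypes whose best genotype probability
#'   falls below this are set missing (default 0.9).
#' @param min_info Variants with imputation INFO below this have all
#'   genotypes set missing (default 0.3).
#' @param hwe_alpha Hardy-Weinberg exact-test significance level below which
#'   a variant is dropped (default 1e-6).
#' @param min_variant_call_rate Per-platform genotyping-rate floor
#'   (default 0.95).
#' @param min_joint_call_rate Post-merge overall call-rate floor
#'   (default 0.85).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(hard_call_min_probability = 0.9, min_info = 0.3,
                          hwe_alpha = 1e-6, min_variant_call_rate = 0.95,
                          min_joint_call_rate = 0.85) {
  vals <- c(hard_call_min_probability, min_info, hwe_alpha,
            min_variant_call_rate, min_joint_call_rate)
  if (any(vals <= 0 | vals > 1)) stop("all QC thresholds must lie in (0, 1]")
  structure(list(hard_call_min_probability = hard_call_min_probability,
                 min_info = min_info, hwe_alpha = hwe_alpha,
                 min_variant_call_rate = min_variant_call_rate,
                 min_joint_call_rate = min_joint_call_rate),
            class = "qc_thresholds")
}

#' Hard-call and INFO-score genotype filter
#'
#' Masks (sets to missing) individual genotypes that cannot be called
#' confidently: when genotype probability triples are available, a genotype
#' whose maximum probability is below `hard_call_min_probability`; when only
#' dosages are available, a genotype whose dosage lies farther than 0.1 from
#' the nearest integer (the equivalent confidence requirement on a
#' best-guess dosage). Additionally every genotype of a variant whose
#' imputation INFO score is below `min_info` is masked. Dimensions are
#' unchanged; surviving dosages are never altered.
#'
#' @param matrix A `dosage_matrix`.
#' @param thresholds A [qc_thresholds()] bundle.
#' @return The filtered `dosage_matrix`.
#' @export
hard_call_filter <- function(matrix, thresholds = qc_thresholds()) {
  d <- matrix$dosages
  if (!is.null(matrix$genotype_probabilities)) {
    gp <- matrix$genotype_probabilities
    maxp <- pmax(gp[, , 1], gp[, , 2], gp[, , 3])
    d[!is.na(maxp) & maxp < thresholds$hard_call_min_probability] <- NA
  } else {
    off <- abs(d - round(d))
    d[!is.na(off) & off > 0.1 + 1e-12] <- NA
  }
  if (!is.null(matrix$info_scores)) {
    info <- matrix$info_scores[colnames(d)]
    low <- which(!is.na(info) & info < thresholds$min_info)
    if (length(low)) d[, low] <- NA
  }
  out <- matrix
  out$dosages <- d
  out
}

#' Hardy-Weinberg equilibrium exact test
#'
#' Exact two-sided test of Hardy-Weinberg proportions from genotype counts,
#' conditional on the observed allele counts: the p-value is the sum of the
#' probabilities of all heterozygote counts whose conditional probability
#' does not exceed that of the observed count. The distribution over
#' heterozygote counts is evaluated with a multiplicative recurrence, so
#' large cohorts are handled without factorial overflow.
#'
#' @param n_hom_effect Count of effect-allele homozygotes.
#' @param n_het Count of heterozygotes.
#' @param n_hom_other Count of other-allele homozygotes.
#' @return Exact p-value in (0, 1]. A monomorphic site returns 1.
#' @export
hwe_exact_test <- function(n_hom_effect, n_het, n_hom_other) {
  counts <- c(n_hom_effect, n_het, n_hom_other)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero")
  n_rare <- 2 * min(n_hom_effect, n_hom_other) + n_het
  if (n_rare == 0 || n_rare == 2 * n) return(1)  # monomorphic

  # support: heterozygote counts with the parity of n_rare, up to min(n_rare, 2n - n_rare)
  het_max <- min(n_rare, 2 * n - n_rare)
  het0 <- n_rare %% 2
  hets <- seq(het0, het_max, by = 2)
  probs <- numeric(length(hets))
  probs[1] <- 1
  for (i in seq_along(hets)[-1]) {
    het <- hets[i - 1]
    hom_r <- (n_rare - het) / 2          # rare-allele homozygotes at current het
    hom_c <- n - het - hom_r             # common-allele homozygotes
    # P(het+2) / P(het) = 4 * hom_r * hom_c / ((het+1)(het+2))
    probs[i] <- probs[i - 1] * 4 * hom_r * hom_c / ((het + 1) * (het + 2))
    if (!is.finite(probs[i])) stop("overflow in HWE recurrence")
    if (probs[i] > 1e250) {  # rescale to avoid overflow
      probs[1:i] <- probs[1:i] / probs[i]
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_het, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Variant-level QC filters
#'
#' Drops variants that fail the Hardy-Weinberg exact test (computed on
#' hard-called genotypes, i.e. dosages rounded to the nearest integer, at
#' `hwe_alpha`), variants whose genotyping rate within any platform falls
#' below `min_variant_call_rate`, and variants whose overall call rate in
#' the merged (joint) matrix falls below `min_joint_call_rate`. Intended to
#' run after [hard_call_filter()], so the call rates measure post-hard-call
#' missingness.
#'
#' @param matrix A `dosage_matrix`.
#' @param thresholds A [qc_thresholds()] bundle.
#' @return A list: `matrix`, the surviving submatrix, and `report`, a data
#'   frame (`variant_id`, `reason`, `statistic`) with one row per dropped
#'   variant.
#' @export
variant_filters <- function(matrix, thresholds = qc_thresholds()) {
  d <- matrix$dosages
  variant_ids <- colnames(d)
  reason <- stats::setNames(rep(NA_character_, ncol(d)), variant_ids)
  statval <- stats::setNames(rep(NA_real_, ncol(d)), variant_ids)

  joint_cr <- variant_call_rates(matrix)
  platforms <- unique(matrix$platform)
  plat_cr <- vapply(platforms, function(p) variant_call_rates(matrix, p),
                    numeric(ncol(d)))
  if (is.null(dim(plat_cr))) plat_cr <- rbind(plat_cr)  # single-variant edge
  min_plat_cr <- apply(plat_cr, 1, min)

  hwe_p <- vapply(seq_len(ncol(d)), function(j) {
    g <- round(d[, j])
    g <- g[!is.na(g)]
    if (!length(g)) return(NA_real_)
    hwe_exact_test(sum(g == 2), sum(g == 1), sum(g == 0))
  }, numeric(1))

  fail_hwe <- !is.na(hwe_p) & hwe_p < thresholds$hwe_alpha
  fail_plat <- min_plat_cr < thresholds$min_variant_call_rate
  fail_joint <- joint_cr < thresholds$min_joint_call_rate
  never_seen <- is.na(hwe_p)

  reason[fail_joint] <- "joint call rate below threshold"
  statval[fail_joint] <- joint_cr[fail_joint]
  reason[fail_plat & is.na(reason)] <- "platform call rate below threshold"
  statval[fail_plat & is.na(statval)] <- min_plat_cr[fail_plat & is.na(statval)]
  reason[fail_hwe & is.na(reason)] <- "Hardy-Weinberg exact p below alpha"
  statval[fail_hwe & is.na(statval)] <- hwe_p[fail_hwe & is.na(statval)]
  reason[never_seen & is.na(reason)] <- "no called genotypes"

  drop <- !is.na(reason)
  report <- data.frame(variant_id = variant_ids[drop],
                       reason = reason[drop],
                       statistic = statval[drop],
                       stringsAsFactors = FALSE, row.names = NULL)
  out <- matrix
  out$dosages <- d[, !drop, drop = FALSE]
  if (!is.null(out$info_scores))
    out$info_scores <- out$info_scores[intersect(names(out$info_scores),
                                                 colnames(out$dosages))]
  if (!is.null(out$genotype_probabilities))
    out$genotype_probabilities <- out$genotype_probabilities[, !drop, , drop = FALSE]
  list(matrix = out, report = report)
}

# mean-imputed, allele-frequency standardized dosage matrix for PCA
standardize_dosages <- function(d) {
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    dj[is.na(dj)] <- 2 * p[j]
    d[, j] <- (dj - 2 * p[j]) / sqrt(2 * p[j] * (1 - p[j]))
  }
  d
}

#' Ancestry restriction by principal components
#'
#' Computes principal components of the mean-imputed, allele-frequency
#' standardized dosage matrix, partitions the samples into two groups by
#' k-means on the first two PCs (deterministically initialized at the two
#' most distant samples), and retains the cluster containing a declared
#' reference sample set (majority vote), or the larger cluster when no
#' reference is given. The returned PC1/PC2 coordinates feed the downstream
#' association models as admixture covariates.
#'
#' @param matrix A `dosage_matrix` (post-QC).
#' @param n_components Number of PCs to return (at least 2; default 2).
#' @param reference_samples Optional character vector of sample IDs known to
#'   belong to the target ancestry cluster.
#' @return A list: `samples`, the retained sample IDs; `pcs`, a data frame
#'   of sample ID, cluster and PC coordinates for all samples.
#' @export
ancestry_restrict <- function(matrix, n_components = 2, reference_samples = NULL) {
  d <- matrix$dosages
  if (nrow(d) < 3) stop("ancestry restriction needs at least 3 samples")
  if (nrow(d) <= n_components) stop("fewer samples than requested components")
  z <- standardize_dosages(d)
  if (ncol(z) < 2) stop("fewer than 2 polymorphic variants after QC")
  if (all(abs(z - mean(z)) < 1e-12))
    stop("degenerate input: no genetic variance among samples")
  pca <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pca$x))
  coords <- pca$x[, seq_len(max(2, k)), drop = FALSE]
  xy <- coords[, 1:2, drop = FALSE]
  if (max(stats::dist(xy)) < 1e-10)
    stop("degenerate input: samples are indistinguishable on PC1-PC2")

  # deterministic 2-means: seed centers at the two most distant samples
  dm <- as.matrix(stats::dist(xy))
  far <- which(dm == max(dm), arr.ind = TRUE)[1, ]
  centers <- xy[c(far[1], far[2]), , drop = FALSE]
  km <- stats::kmeans(xy, centers = centers, iter.max = 100)
  cl <- km$cluster

  # a homogeneous sample should not be split: accept the 2-group partition
  # only if the centers are separated relative to the within-cluster spread
  within_rms <- sqrt(sum(km$withinss) / nrow(xy))
  center_sep <- sqrt(sum((km$centers[1, ] - km$centers[2, ])^2))
  if (min(table(cl)) == 0 || center_sep < 2 * within_rms)
    cl <- rep(1L, nrow(xy))

  if (!is.null(reference_samples)) {
    ref <- intersect(reference_samples, rownames(d))
    if (!length(ref)) stop("no reference sample found in the matrix")
    keep_cl <- as.integer(names(which.max(table(cl[ref]))))
  } else {
    keep_cl <- as.integer(names(which.max(table(cl))))
  }
  pcs <- data.frame(sample_id = rownames(d), cluster = cl,
                    coords[, seq_len(k), drop = FALSE],
                    row.names = NULL, stringsAsFactors = FALSE)
  names(pcs)[-(1:2)] <- paste0("pc", seq_len(k))
  list(samples = rownames(d)[cl == keep_cl], pcs = pcs)
}

#' Subset a dosage matrix by sample
#'
#' @param matrix A `dosage_matrix`.
#' @param samples Character vector of sample IDs to keep.
#' @return The subset `dosage_matrix`.
#' @export
subset_samples <- function(matrix, samples) {
  idx <- match(samples, rownames(matrix$dosages))
  if (anyNA(idx)) stop("unknown sample ID(s): ",
                       paste(samples[is.na(idx)], collapse = ", "))
  out <- matrix
  out$dosages <- matrix$dosages[idx, , drop = FALSE]
  out$platform <- matrix$platform[idx]
  if (!is.null(matrix$genotype_probabilities))
    out$genotype_probabilities <- matrix$genotype_probabilities[idx, , , drop = FALSE]
  out
}
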