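#' Construct a phenotype/covariate cohort table
#'
#' One row per individual: case-control status, sex, event and censoring
#' ages, family history, platform label and the first two ancestry PCs.
#' Cases must carry an age at onset and controls must not; all ages must be
#' positive and below 120 years.
#'
#' @param sample_id Sample labels (unique).
#' @param status `"case"` or `"control"`.
#' @param sex `"female"` or `"male"`.
#' @param age_at_onset Years; required for cases, `NA` for controls.
#' @param age_at_last_assessment Years.
#' @param age_at_lp Age at lumbar puncture in years, or `NA`.
#' @param family_history `"yes"`, `"no"` or `"unknown"`.
#' @param platform Cohort/platform label.
#' @param pc1,pc2 Ancestry principal-component coordinates.
#' @return A `cohort_table` data frame.
#' @export
cohort_table <- function(sample_id, status, sex, age_at_onset,
                         age_at_last_assessment, age_at_lp = NA_real_,
                         family_history = "unknown", platform = "cohort1",
                         pc1 = 0, pc2 = 0) {
  out <- data.frame(sample_id = as.character(sample_id),
                    status = as.character(status), sex = as.character(sex),
                    age_at_onset = as.numeric(age_at_onset),
                    age_at_last_assessment = as.numeric(age_at_last_assessment),
                    age_at_lp = as.numeric(age_at_lp),
                    family_history = as.character(family_history),
                    platform = as.character(platform),
                    pc1 = as.numeric(pc1), pc2 = as.numeric(pc2),
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    if (anyDuplicated(out$sample_id)) stop("duplicate sample IDs in cohort")
    if (!all(out$status %in% c("case", "control")))
      stop("status must be 'case' or 'control'")
    if (!all(out$sex %in% c("female", "male")))
      stop("sex must be 'female' or 'male'")
    if (any(out$status == "case" & is.na(out$age_at_onset)))
      stop("every case needs an age at onset")
    if (any(out$status == "control" & !is.na(out$age_at_onset)))
      stop("controls must not carry an age at onset")
    ages <- c(out$age_at_onset, out$age_at_last_assessment, out$age_at_lp)
    if (any(!is.na(ages) & (ages <= 0 | ages >= 120)))
      stop("ages must be positive and below 120 years")
  }
  class(out) <- c("cohort_table", "data.frame")
  out
}

#' Read / write a cohort table TSV
#'
#' @param path File path.
#' @return For `read_cohort_tsv`, a `cohort_table`.
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  do.call(cohort_table, tab[intersect(names(tab), names(formals(cohort_table)))])
}

#' @rdname read_cohort_tsv
#' @param cohort A `cohort_table`.
#' @export
write_cohort_tsv <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- internal helpers -------------------------------------------------------

# merge a score_set with a cohort table; error on scored samples lacking covariates
merge_scores_cohort <- function(scores, cohort) {
  idx <- match(scores$sample_id, cohort$sample_id)
  if (anyNA(idx))
    stop("scored sample(s) missing from the cohort table: ",
         paste(scores$sample_id[is.na(idx)], collapse = ", "))
  dat <- cbind(scores[, c("sample_id", "score", "tertile"), drop = FALSE],
               cohort[idx, setdiff(names(cohort), "sample_id"), drop = FALSE])
  dat$sex_female <- as.numeric(dat$sex == "female")
  dat$is_case <- as.numeric(dat$status == "case")
  dat
}

wald_ci <- function(beta, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(beta - z * se, beta + z * se)
}

association_result <- function(trait, predictor, beta, se, p_value,
                               model_formula, n_used, converged = TRUE,
                               note = NA_character_) {
  ci <- wald_ci(beta, se)
  out <- data.frame(trait = trait, predictor = predictor, beta = beta,
                    ci_low = ci[1], ci_high = ci[2], p_value = p_value,
                    model_formula = model_formula, n_used = n_used,
                    converged = converged, note = note,
                    stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  out
}

# translate covariate names to model-frame columns (sex -> sex_female)
covariate_terms <- function(covariates) {
  ifelse(covariates == "sex", "sex_female", covariates)
}

# ---- status model -----------------------------------------------------------

#' Case-control association of the PRS
#'
#' Logistic regression of disease status on the PRS, adjusting by default
#' for age at last assessment, sex (female = 1) and the first two ancestry
#' PCs. The reported beta is the log-odds change per PRS unit with a Wald
#' 95% interval. Complete outcome separation is reported as a flagged
#' non-converged result rather than an error.
#'
#' @param scores A `score_set`.
#' @param cohort A `cohort_table` covering every scored sample.
#' @param covariates Adjustment covariates (column names of the cohort
#'   table; `"sex"` is coded female = 1).
#' @param predictor_label Label for the predictor in the result row.
#' @return An `association_result` (one-row data frame).
#' @export
status_association <- function(scores, cohort,
                               covariates = c("age_at_last_assessment",
                                              "sex", "pc1", "pc2"),
                               predictor_label = "PRS") {
  dat <- merge_scores_cohort(scores, cohort)
  if (length(unique(dat$is_case)) < 2)
    stop("both cases and controls are required")
  if (stats::var(dat$score) == 0) stop("constant predictor: PRS has no variance")
  rhs <- paste(c("score", covariate_terms(covariates)), collapse = " + ")
  fml <- stats::as.formula(paste("is_case ~", rhs))
  sep_flag <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_flag <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  co <- summary(fit)$coefficients
  # separation can pass glm's own checks: a drifting estimate with an
  # enormous standard error is the practical signature
  if (abs(co["score", "Estimate"]) > 15 || co["score", "Std. Error"] > 1e3)
    sep_flag <- TRUE
  desc <- paste("status ~", predictor_label,
                if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else "")
  association_result(trait = "PD status", predictor = predictor_label,
                     beta = co["score", "Estimate"], se = co["score", "Std. Error"],
                     p_value = co["score", "Pr(>|z|)"],
                     model_formula = trimws(desc),
                     n_used = stats::nobs(fit),
                     converged = fit$converged && !sep_flag,
                     note = if (sep_flag) "possible outcome separation" else NA_character_)
}

# rank (Mann-Whitney) AUC of a score against a binary outcome
auc_rank <- function(outcome, score) {
  n1 <- sum(outcome == 1); n0 <- sum(outcome == 0)
  if (n1 == 0 || n0 == 0) stop("both outcome classes are required for an AUC")
  r <- rank(score)
  (sum(r[outcome == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Incremental discriminative value of the PRS
#'
#' Fits the covariate-only logistic model and the covariates-plus-PRS model
#' and reports the apparent area under the ROC curve of each model's fitted
#' probabilities (Mann-Whitney/trapezoidal AUC, as computed by pROC).
#'
#' @inheritParams status_association
#' @return A list: `auc_base`, `auc_with_prs`, `increment`, `n_used`.
#' @export
roc_increment <- function(scores, cohort,
                          covariates = c("age_at_last_assessment", "sex",
                                         "pc1", "pc2")) {
  dat <- merge_scores_cohort(scores, cohort)
  if (length(unique(dat$is_case)) < 2)
    stop("both cases and controls are required")
  terms <- covariate_terms(covariates)
  base_rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  base_fml <- stats::as.formula(paste("is_case ~", base_rhs))
  full_fml <- stats::as.formula(paste("is_case ~",
                                      paste(c("score", terms), collapse = " + ")))
  fit_base <- stats::glm(base_fml, family = stats::binomial(), data = dat)
  fit_full <- suppressWarnings(
    stats::glm(full_fml, family = stats::binomial(), data = dat))
  auc_base <- as.numeric(pROC::auc(pROC::roc(dat$is_case, stats::fitted(fit_base),
                                             quiet = TRUE, direction = "<")))
  auc_full <- as.numeric(pROC::auc(pROC::roc(dat$is_case, stats::fitted(fit_full),
                                             quiet = TRUE, direction = "<")))
  list(auc_base = auc_base, auc_with_prs = auc_full,
       increment = auc_full - auc_base, n_used = nrow(dat))
}

# ---- survival models --------------------------------------------------------

# build the onset-survival frame: event = PD onset, controls censored at last assessment
survival_frame <- function(dat, cases_only = FALSE) {
  if (cases_only) dat <- dat[dat$status == "case", , drop = FALSE]
  dat$time <- ifelse(dat$status == "case", dat$age_at_onset,
                     dat$age_at_last_assessment)
  dat$event <- as.numeric(dat$status == "case")
  if (any(is.na(dat$time) | dat$time <= 0))
    stop("event/censoring ages must be positive and present")
  dat
}

#' Cox model of age at onset on the PRS
#'
#' Censored survival analysis of age at onset: onset is the event for
#' cases, controls are censored at their age at last assessment. Fits a Cox
#' proportional-hazards model (Efron tie handling) of onset age on the PRS
#' plus covariates (default sex, PC1, PC2; no age covariate, since age is
#' the time scale). A positive hazard beta means higher PRS shifts onset
#' earlier.
#'
#' @inheritParams status_association
#' @param cases_only Drop controls before fitting (sensitivity analysis for
#'   control-censoring artifacts).
#' @return A `survival_result` list: `hazard_beta`, `se`, `p_value`,
#'   `n_used`, `n_events`, `model_formula`.
#' @export
aao_survival <- function(scores, cohort, cases_only = FALSE,
                         covariates = c("sex", "pc1", "pc2"),
                         predictor_label = "PRS") {
  dat <- survival_frame(merge_scores_cohort(scores, cohort), cases_only)
  if (sum(dat$event) < 2) stop("at least 2 onset events are required")
  rhs <- paste(c("score", covariate_terms(covariates)), collapse = " + ")
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~", rhs))
  fit <- survival::coxph(fml, data = dat, ties = "efron")
  co <- summary(fit)$coefficients
  structure(list(hazard_beta = co["score", "coef"],
                 se = co["score", "se(coef)"],
                 p_value = co["score", "Pr(>|z|)"],
                 n_used = fit$n, n_events = fit$nevent,
                 model_formula = paste0("onset ~ ", predictor_label, " + ",
                                        paste(covariates, collapse = " + "),
                                        if (cases_only) " [cases only]" else "")),
            class = "survival_result")
}

#' Kaplan-Meier tertile analysis of age at onset
#'
#' Product-limit onset curves per PRS tertile, a log-rank test comparing the
#' first and third tertiles, and the first-vs-third tertile effect
#' estimated as the exponentiated Cox coefficient of a T3-vs-T1 indicator
#' (fit on the two outer tertiles with the same covariates as
#' [aao_survival()]). The effect is on the hazard-ratio scale.
#'
#' @inheritParams aao_survival
#' @return A `survival_result` list with `km_curves` (data frame `tertile`,
#'   `time`, `surv`, `n_risk`, `n_event`), `logrank_statistic`, `logrank_df`,
#'   `logrank_p`, `tertile_effect` and the T3-vs-T1 Cox `hazard_beta`,
#'   `se`, `p_value`.
#' @export
km_tertile_analysis <- function(scores, cohort,
                                covariates = c("sex", "pc1", "pc2")) {
  if (all(is.na(scores$tertile))) stop("tertiles not assigned; run assign_tertiles()")
  dat <- survival_frame(merge_scores_cohort(scores, cohort))
  tert_n <- table(factor(dat$tertile, levels = c("T1", "T2", "T3")))
  if (any(tert_n == 0)) stop("every tertile must be non-empty")
  if (sum(dat$event) == 0)
    stop("all subjects censored: survival curves are constant and the log-rank test is undefined")
  sf <- survival::survfit(survival::Surv(time, event) ~ tertile, data = dat)
  strata_lab <- rep(sub("^tertile=", "", names(sf$strata)), sf$strata)
  km_curves <- data.frame(tertile = strata_lab, time = sf$time, surv = sf$surv,
                          n_risk = sf$n.risk, n_event = sf$n.event,
                          stringsAsFactors = FALSE)

  outer <- dat[dat$tertile %in% c("T1", "T3"), , drop = FALSE]
  if (sum(outer$event[outer$tertile == "T1"]) < 1 ||
      sum(outer$event[outer$tertile == "T3"]) < 1)
    stop("at least one onset event is required in each outer tertile")
  sd13 <- survival::survdiff(survival::Surv(time, event) ~ tertile, data = outer)
  outer$t3 <- as.numeric(outer$tertile == "T3")
  rhs <- paste(c("t3", covariate_terms(covariates)), collapse = " + ")
  fit <- survival::coxph(stats::as.formula(
    paste("survival::Surv(time, event) ~", rhs)), data = outer, ties = "efron")
  co <- summary(fit)$coefficients
  structure(list(km_curves = km_curves,
                 logrank_statistic = sd13$chisq,
                 logrank_df = length(sd13$n) - 1,
                 logrank_p = stats::pchisq(sd13$chisq, length(sd13$n) - 1,
                                           lower.tail = FALSE),
                 tertile_effect = exp(co["t3", "coef"]),
                 hazard_beta = co["t3", "coef"],
                 se = co["t3", "se(coef)"],
                 p_value = co["t3", "Pr(>|z|)"],
                 n_used = fit$n, n_events = fit$nevent,
                 model_formula = paste("onset ~ T3 vs T1 +",
                                       paste(covariates, collapse = " + "))),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat("Survival model:", x$model_formula, "\n")
  cat(sprintf("  n = %d (%d events)\n", x$n_used, x$n_events))
  if (!is.null(x$hazard_beta))
    cat(sprintf("  hazard beta = %.4f (se %.4f), p = %.3g\n",
                x$hazard_beta, x$se, x$p_value))
  if (!is.null(x$tertile_effect))
    cat(sprintf("  T3 vs T1 effect (hazard-ratio scale) = %.3f; log-rank chi-square = %.3f (df %d, p = %.3g)\n",
                x$tertile_effect, x$logrank_statistic, x$logrank_df, x$logrank_p))
  invisible(x)
}

# ---- biomarker model --------------------------------------------------------

#' Association of harmonized CSF biomarker levels with the PRS
#'
#' Linear model of the harmonized (log10, platform-centered) analyte level
#' on the PRS, adjusting by default for age at lumbar puncture, sex and the
#' first two ancestry PCs.
#'
#' @inheritParams status_association
#' @param biomarkers A harmonized `biomarker_table`.
#' @param analyte Analyte label to test (e.g. `"t_tau"`).
#' @return An `association_result`.
#' @export
biomarker_association <- function(scores, biomarkers, cohort, analyte,
                                  covariates = c("age_at_lp", "sex",
                                                 "pc1", "pc2"),
                                  predictor_label = "PRS") {
  bm <- biomarkers[biomarkers$analyte == analyte, , drop = FALSE]
  if (!nrow(bm)) stop("analyte '", analyte, "' absent from the biomarker table")
  if (all(is.na(bm$harmonized_level)))
    stop("analyte '", analyte, "' has no harmonized levels; run harmonize()")
  dat <- merge_scores_cohort(scores, cohort)
  idx <- match(bm$sample_id, dat$sample_id)
  bm <- bm[!is.na(idx), , drop = FALSE]
  dat <- dat[idx[!is.na(idx)], , drop = FALSE]
  dat$harmonized_level <- bm$harmonized_level
  # prefer the LP age recorded with the measurement
  dat$age_at_lp <- ifelse(is.na(bm$age_at_lp), dat$age_at_lp, bm$age_at_lp)
  dat <- dat[stats::complete.cases(dat[, c("harmonized_level", "score",
                                           covariate_terms(covariates))]), ,
             drop = FALSE]
  if (nrow(dat) < 10) stop("fewer than 10 usable samples for analyte '", analyte, "'")
  rhs <- paste(c("score", covariate_terms(covariates)), collapse = " + ")
  fit <- stats::lm(stats::as.formula(paste("harmonized_level ~", rhs)), data = dat)
  co <- summary(fit)$coefficients
  association_result(trait = paste("CSF", analyte), predictor = predictor_label,
                     beta = co["score", "Estimate"], se = co["score", "Std. Error"],
                     p_value = co["score", "Pr(>|t|)"],
                     model_formula = paste(analyte, "~", predictor_label, "+",
                                           paste(covariates, collapse = " + ")),
                     n_used = stats::nobs(fit))
}

# ---- single-variant and stratified reruns -----------------------------------

#' Per-variant association tests
#'
#' Substitutes each panel variant's dosage for the PRS in the chosen model
#' (disease status, onset survival, or a CSF analyte). Results are nominal:
#' no multiple-testing correction is applied. Monomorphic variants are
#' flagged degenerate and skipped with a warning; the result keeps exactly
#' one row per panel variant.
#'
#' @param matrix A `dosage_matrix`.
#' @param panel A `scoring_panel`.
#' @param cohort A `cohort_table`.
#' @param trait `"status"`, `"onset"`, or an analyte label present in
#'   `biomarkers`.
#' @param biomarkers Harmonized `biomarker_table` (required for analyte
#'   traits).
#' @param missing_policy Dosage missing-data policy, as [compute_prs()].
#' @return A data frame with one `association_result` row per panel variant.
#' @export
single_variant_tests <- function(matrix, panel, cohort, trait = "status",
                                 biomarkers = NULL,
                                 missing_policy = "mean_impute") {
  stopifnot(inherits(panel, "scoring_panel"))
  rows <- lapply(seq_len(nrow(panel$variants)), function(i) {
    v <- panel$variants[i, , drop = FALSE]
    one <- panel
    one$variants <- v
    sc <- compute_prs(matrix, one, missing_policy = missing_policy)
    if (stats::var(sc$score, na.rm = TRUE) == 0) {
      warning("variant ", v$variant_id, " is monomorphic; skipped")
      return(association_result(trait = trait, predictor = v$variant_id,
                                beta = NA_real_, se = NA_real_,
                                p_value = NA_real_, model_formula = "degenerate",
                                n_used = 0L, converged = FALSE,
                                note = "monomorphic variant"))
    }
    res <- if (trait == "status") {
      status_association(sc, cohort, predictor_label = v$variant_id)
    } else if (trait == "onset") {
      s <- aao_survival(sc, cohort, predictor_label = v$variant_id)
      association_result(trait = "onset", predictor = v$variant_id,
                         beta = s$hazard_beta, se = s$se, p_value = s$p_value,
                         model_formula = s$model_formula, n_used = s$n_used)
    } else {
      biomarker_association(sc, biomarkers, cohort, analyte = trait,
                            predictor_label = v$variant_id)
    }
    res$note <- paste0(if (!is.na(res$note)) paste0(res$note, "; "), "nominal")
    res
  })
  do.call(rbind, rows)
}

#' Re-run a model within a family-history stratum
#'
#' Splits the case population by family history of PD and re-runs the given
#' model on the subset. For status models the controls are retained in both
#' strata (the split applies to cases only).
#'
#' @param model_fn One of the model functions taking `(scores, cohort, ...)`
#'   (e.g. [status_association()], [aao_survival()]).
#' @param scores A `score_set`.
#' @param cohort A `cohort_table`.
#' @param stratum `"yes"` or `"no"` (family history), or `"all"` for no split.
#' @param ... Passed through to `model_fn`.
#' @return The model result, with a `stratum` label attached.
#' @export
stratified_rerun <- function(model_fn, scores, cohort, stratum, ...) {
  if (!identical(stratum, "all")) {
    keep <- cohort$status == "control" |
      (cohort$status == "case" & cohort$family_history == stratum)
    cohort <- cohort[keep, , drop = FALSE]
    if (!any(cohort$status == "case"))
      stop("empty case stratum: family_history == '", stratum, "'")
    scores <- scores[scores$sample_id %in% cohort$sample_id, , drop = FALSE]
  }
  res <- model_fn(scores, cohort, ...)
  if (is.data.frame(res)) res$stratum <- stratum else res$stratum <- stratum
  res
}

# ---- demographics -----------------------------------------------------------

#' Demographic summary of a cohort
#'
#' Per status group, within each platform and combined: sample size, female
#' count and percentage (2 decimal places), mean ages (onset, last
#' assessment, lumbar puncture) and family-history count and percentage.
#'
#' @param cohort A `cohort_table`.
#' @return A data frame with one row per (group, status) cell.
#' @export
summarize_cohort <- function(cohort) {
  if (!nrow(cohort)) {
    return(data.frame(group = character(), status = character(), n = integer(),
                      n_female = integer(), pct_female = numeric(),
                      mean_age_onset = numeric(), mean_age_last = numeric(),
                      mean_age_lp = numeric(), n_family_history = integer(),
                      pct_family_history = numeric(), stringsAsFactors = FALSE))
  }
  groups <- unique(c("combined", cohort$platform))
  rows <- list()
  for (g in groups) {
    sub <- if (g == "combined") cohort else cohort[cohort$platform == g, , drop = FALSE]
    for (st in c("control", "case")) {
      s <- sub[sub$status == st, , drop = FALSE]
      if (!nrow(s)) next
      rows[[length(rows) + 1]] <- data.frame(
        group = g, status = st, n = nrow(s),
        n_female = sum(s$sex == "female"),
        pct_female = round(100 * mean(s$sex == "female"), 2),
        mean_age_onset = if (st == "case") mean(s$age_at_onset, na.rm = TRUE) else NA_real_,
        mean_age_last = mean(s$age_at_last_assessment, na.rm = TRUE),
        mean_age_lp = mean(s$age_at_lp, na.rm = TRUE),
        n_family_history = sum(s$family_history == "yes"),
        pct_family_history = round(100 * mean(s$family_history == "yes"), 2),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
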