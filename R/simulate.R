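#' Configuration for the synthetic two-cohort generator
#'
#' Bundles the study-design quantities the generator emulates: per-platform
#' case/control counts, the scoring panel whose study MAFs, call rates and
#' weights drive genotypes, disease liability and missingness, the onset
#' model, demographic rates and per-platform biomarker scales. Defaults
#' mirror a two-platform Parkinson disease case-control study of 829 cases
#' and 432 controls (336/139 on the first platform, 493/293 on the second).
#'
#' @param n_cases,n_controls Named integer vectors (one entry per platform).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   config and seed.
#' @param panel A `scoring_panel`; defaults to the packaged 16-variant panel.
#' @param effect_scale Multiplier on the panel's log2-OR weights in the
#'   logistic disease liability (1.0 = per-allele odds ratios equal to the
#'   panel's published ORs; 0 = null generator).
#' @param onset_shift_per_prs_unit Years of onset shift per PRS unit
#'   (default -4: higher PRS, earlier onset).
#' @param baseline_onset_mean,baseline_onset_sd Case onset-age distribution
#'   (years; defaults 61, 9); onset ages are truncated to \[25, 95\].
#' @param control_age_mean,control_age_sd Control age at last assessment
#'   (years; defaults 64, 9).
#' @param female_fraction Named fractions for `case` and `control`.
#' @param family_history_rate Named fractions for `case` and `control`.
#' @param biomarker_log10_means Matrix (platform x analyte) of log10 pg/mL
#'   location per platform, emulating kit-specific scales.
#' @param biomarker_log10_sd Residual sd of log10 levels (default 0.15).
#' @param prs_biomarker_beta Named per-analyte effect of the PRS on log10
#'   levels (default 0 for all analytes).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_cases = c(PPMI = 336, WUSTL = 493),
                              n_controls = c(PPMI = 139, WUSTL = 293),
                              seed = 1L,
                              panel = pd_scoring_panel(),
                              effect_scale = 1.0,
                              onset_shift_per_prs_unit = -4,
                              baseline_onset_mean = 61, baseline_onset_sd = 9,
                              control_age_mean = 64, control_age_sd = 9,
                              female_fraction = c(case = 0.3353, control = 0.4560),
                              family_history_rate = c(case = 0.25, control = 0.03),
                              biomarker_log10_means = default_biomarker_means(),
                              biomarker_log10_sd = 0.15,
                              prs_biomarker_beta = c(alpha_synuclein = 0,
                                                     abeta_1_42 = 0,
                                                     t_tau = 0, p_tau = 0)) {
  if (!all(names(n_cases) %in% rownames(biomarker_log10_means))) {
    # custom platform labels: recycle the supplied kit scales across platforms
    idx <- rep(seq_len(nrow(biomarker_log10_means)), length.out = length(n_cases))
    biomarker_log10_means <- biomarker_log10_means[idx, , drop = FALSE]
    rownames(biomarker_log10_means) <- names(n_cases)
  }
  stopifnot(identical(names(n_cases), names(n_controls)),
            all(n_cases > 0), all(n_controls > 0),
            baseline_onset_sd > 0, control_age_sd > 0,
            biomarker_log10_sd >= 0,
            all(female_fraction >= 0 & female_fraction <= 1),
            all(family_history_rate >= 0 & family_history_rate <= 1))
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 seed = as.integer(seed), panel = panel,
                 effect_scale = effect_scale,
                 onset_shift_per_prs_unit = onset_shift_per_prs_unit,
                 baseline_onset_mean = baseline_onset_mean,
                 baseline_onset_sd = baseline_onset_sd,
                 control_age_mean = control_age_mean,
                 control_age_sd = control_age_sd,
                 female_fraction = female_fraction,
                 family_history_rate = family_history_rate,
                 biomarker_log10_means = biomarker_log10_means,
                 biomarker_log10_sd = biomarker_log10_sd,
                 prs_biomarker_beta = prs_biomarker_beta),
            class = "simulation_config")
}

#' Default per-platform biomarker locations
#'
#' log10 of kit-scale control-mean levels (pg/mL) for the four CSF analytes
#' on the two emulated platforms; the roughly 2.4-fold amyloid-beta scale
#' difference between kits is what harmonization has to remove.
#'
#' @return A 2 x 4 matrix of log10 means (platforms x analytes).
#' @export
default_biomarker_means <- function() {
  m <- rbind(PPMI = log10(c(alpha_synuclein = 2173.5, abeta_1_42 = 378.40,
                            t_tau = 53.95, p_tau = 17.49)),
             WUSTL = log10(c(alpha_synuclein = 1725.0, abeta_1_42 = 926.40,
                             t_tau = 250.40, p_tau = 47.00)))
  m
}

#' Simulate effect-allele dosages
#'
#' Draws genotypes per variant as Binomial(2, study MAF) — i.e. under
#' Hardy-Weinberg equilibrium at the panel's study allele frequencies —
#' attaches hard-call-consistent genotype probability triples, and masks
#' each genotype with probability one minus the variant's published call
#' rate, so observed missingness matches the panel in expectation. Samples
#' are labelled by platform.
#'
#' @param config A [simulation_config()].
#' @return A `dosage_matrix`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pv <- config$panel$variants
  platforms <- names(config$n_cases)
  n_per <- config$n_cases + config$n_controls
  n <- sum(n_per)
  sample_ids <- unlist(lapply(platforms, function(p)
    sprintf("%s_%05d", p, seq_len(n_per[[p]]))))
  platform <- rep(platforms, n_per)

  d <- vapply(seq_len(nrow(pv)), function(j)
    stats::rbinom(n, 2, pv$study_maf[j]), numeric(n))
  dimnames(d) <- list(sample_ids, pv$variant_id)

  gp <- array(0, dim = c(n, nrow(pv), 3),
              dimnames = list(sample_ids, pv$variant_id, NULL))
  for (k in 0:2) {
    sel <- d == k
    gpk <- gp[, , k + 1]
    gpk[sel] <- 1
    gp[, , k + 1] <- gpk
  }
  for (j in seq_len(nrow(pv))) {
    cr <- pv$call_rate[j]
    if (!is.na(cr) && cr < 1) {
      miss <- stats::runif(n) > cr
      d[miss, j] <- NA
      gp[miss, j, ] <- NA
    }
  }
  dosage_matrix(d, platform = platform,
                info_scores = stats::setNames(rep(1, nrow(pv)), pv$variant_id),
                genotype_probabilities = gp)
}

#' Simulate phenotypes from genotypes
#'
#' Disease status follows a logistic liability on the raw PRS: case
#' probability is `plogis(alpha + effect_scale * PRS)`, with `alpha` solved
#' numerically per platform so the expected case fraction matches the
#' configured counts. Case age at onset is shifted by
#' `onset_shift_per_prs_unit` years per PRS unit around the baseline mean
#' (Gaussian noise, truncated to \[25, 95\]); controls get a Gaussian age at
#' last assessment. Cases' age at last assessment is onset plus an
#' exponential follow-up (mean 3 years). Sex and family history are drawn
#' at the configured per-status rates, and PC1/PC2 are computed from the
#' standardized dosages.
#'
#' @param matrix A `dosage_matrix` from [simulate_genotypes()].
#' @param config The same [simulation_config()].
#' @return A `cohort_table`.
#' @export
simulate_phenotypes <- function(matrix, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 1L)
  scores <- compute_prs(matrix, config$panel, missing_policy = "mean_impute")
  s <- scores$score
  n <- length(s)
  platform <- matrix$platform

  status <- character(n)
  for (p in names(config$n_cases)) {
    idx <- which(platform == p)
    target <- config$n_cases[[p]] / (config$n_cases[[p]] + config$n_controls[[p]])
    eta <- config$effect_scale * s[idx]
    f <- function(a) mean(stats::plogis(a + eta)) - target
    if (f(-35) > 0 || f(35) < 0)
      stop("target case fraction ", target, " unattainable for platform ", p)
    alpha <- stats::uniroot(f, c(-35, 35), tol = 1e-10)$root
    status[idx] <- ifelse(stats::runif(length(idx)) <
                            stats::plogis(alpha + eta), "case", "control")
  }
  # guard degenerate draws: models need both classes on each platform
  for (p in names(config$n_cases)) {
    idx <- which(platform == p)
    if (all(status[idx] == "case")) status[idx[1]] <- "control"
    if (all(status[idx] == "control")) status[idx[1]] <- "case"
  }
  is_case <- status == "case"

  onset <- rep(NA_real_, n)
  onset[is_case] <- config$baseline_onset_mean +
    config$onset_shift_per_prs_unit * (s[is_case] - mean(s)) +
    stats::rnorm(sum(is_case), 0, config$baseline_onset_sd)
  onset[is_case] <- pmin(pmax(onset[is_case], 25), 95)

  age_last <- numeric(n)
  age_last[!is_case] <- pmin(pmax(
    stats::rnorm(sum(!is_case), config$control_age_mean, config$control_age_sd),
    25), 95)
  age_last[is_case] <- pmin(onset[is_case] + stats::rexp(sum(is_case), 1 / 3), 119)

  age_lp <- pmax(age_last - stats::rexp(n, 1), 25)

  sex <- ifelse(stats::runif(n) < config$female_fraction[status], "female", "male")
  fh <- ifelse(stats::runif(n) < config$family_history_rate[status], "yes", "no")

  z <- standardize_dosages(matrix$dosages)
  if (ncol(z) >= 2 && nrow(z) >= 3) {
    pcs <- stats::prcomp(z, center = TRUE, scale. = FALSE)$x
    pc1 <- pcs[, 1]
    pc2 <- if (ncol(pcs) >= 2) pcs[, 2] else rep(0, n)
  } else {
    pc1 <- pc2 <- rep(0, n)
  }

  cohort_table(sample_id = rownames(matrix$dosages), status = status,
               sex = sex, age_at_onset = onset,
               age_at_last_assessment = age_last, age_at_lp = age_lp,
               family_history = fh, platform = platform,
               pc1 = pc1, pc2 = pc2)
}

#' Simulate CSF biomarker levels
#'
#' log10 levels are the platform/analyte location plus a per-analyte PRS
#' effect on the centered score plus Gaussian noise; raw levels are the
#' back-transformed values, so each platform keeps its kit-specific scale.
#'
#' @param cohort A `cohort_table`.
#' @param scores The matching `score_set`.
#' @param config The same [simulation_config()].
#' @return A long-format `biomarker_table` (unharmonized).
#' @export
simulate_biomarkers <- function(cohort, scores, config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed + 2L)
  s <- scores$score[match(cohort$sample_id, scores$sample_id)]
  sc <- s - mean(s)
  analytes <- colnames(config$biomarker_log10_means)
  rows <- lapply(analytes, function(a) {
    mu <- config$biomarker_log10_means[cohort$platform, a]
    beta <- config$prs_biomarker_beta[[a]]
    log10_level <- mu + beta * sc +
      stats::rnorm(nrow(cohort), 0, config$biomarker_log10_sd)
    biomarker_table(cohort$sample_id, a, 10^log10_level, cohort$platform,
                    cohort$age_at_lp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("biomarker_table", "data.frame")
  out
}

#' Simulate a complete two-cohort study
#'
#' Runs the three generator stages and the scorer: genotypes, PRS,
#' phenotypes, tertiles and biomarkers, all deterministic given the config.
#'
#' @param config A [simulation_config()].
#' @return A list: `genotypes` (`dosage_matrix`), `scores` (`score_set` with
#'   tertiles), `cohort` (`cohort_table`), `biomarkers`
#'   (`biomarker_table`, unharmonized), `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  geno <- simulate_genotypes(config)
  cohort <- simulate_phenotypes(geno, config)
  scores <- assign_tertiles(compute_prs(geno, config$panel,
                                        missing_policy = "mean_impute"))
  biomarkers <- simulate_biomarkers(cohort, scores, config)
  list(genotypes = geno, scores = scores, cohort = cohort,
       biomarkers = biomarkers, config = config)
}

#' Write a simulated study to disk
#'
#' Writes the dosage, cohort and biomarker TSVs plus a JSON manifest echoing
#' the seed and scalar configuration (the interface used by the
#' `simulate.R` helper script).
#'
#' @param sim Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_dosage_tsv(sim$genotypes, file.path(dir, "dosages.tsv"))
  write_cohort_tsv(sim$cohort, file.path(dir, "cohort.tsv"))
  write_biomarker_tsv(sim$biomarkers, file.path(dir, "biomarkers.tsv"))
  write_scores_tsv(sim$scores, file.path(dir, "scores.tsv"))
  cfg <- sim$config
  manifest <- list(seed = cfg$seed,
                   n_cases = as.list(cfg$n_cases),
                   n_controls = as.list(cfg$n_controls),
                   effect_scale = cfg$effect_scale,
                   onset_shift_per_prs_unit = cfg$onset_shift_per_prs_unit,
                   baseline_onset_mean = cfg$baseline_onset_mean,
                   baseline_onset_sd = cfg$baseline_onset_sd,
                   control_age_mean = cfg$control_age_mean,
                   control_age_sd = cfg$control_age_sd,
                   female_fraction = as.list(cfg$female_fraction),
                   family_history_rate = as.list(cfg$family_history_rate),
                   biomarker_log10_sd = cfg$biomarker_log10_sd,
                   prs_biomarker_beta = as.list(cfg$prs_biomarker_beta),
                   n_panel_variants = nrow(cfg$panel$variants))
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}
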