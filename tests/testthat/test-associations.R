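test_that("logistic beta on a binary predictor equals the 2x2 log odds ratio", {
  # exposed cases 30, exposed controls 10, unexposed cases 10, unexposed controls 30
  status <- rep(c("case", "control", "case", "control"), c(30, 10, 10, 30))
  exposed <- rep(c(1, 1, 0, 0), c(30, 10, 10, 30))
  ids <- sprintf("s%03d", seq_along(status))
  cohort <- make_cohort_for(ids, status)
  res <- status_association(make_scores(ids, exposed), cohort,
                            covariates = character(0))
  expect_equal(res$beta, log(30 * 30 / (10 * 10)), tolerance = 1e-6)
  expect_true(res$ci_low <= res$beta && res$beta <= res$ci_high)
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("status model validates degenerate inputs and flags separation", {
  ids <- sprintf("s%03d", 1:40)
  cohort <- make_cohort_for(ids, rep(c("case", "control"), each = 20))
  expect_error(status_association(make_scores(ids, rep(1, 40)), cohort),
               "constant")
  case_only <- make_cohort_for(ids, rep("case", 40))
  expect_error(status_association(make_scores(ids, rnorm(40)), case_only),
               "cases and controls")
  # perfectly separating score: flagged, not a crash
  sep_score <- ifelse(cohort$status == "case", 1, 0) + seq(0, 0.01, length.out = 40)
  res <- status_association(make_scores(ids, sep_score), cohort,
                            covariates = character(0))
  expect_false(res$converged)
  expect_match(res$note, "separation")
})

test_that("AUC matches the brute-force pairwise oracle and the null is 0.5", {
  ids <- sprintf("s%03d", 1:30)
  status <- rep(c("case", "control"), 15)
  cohort <- make_cohort_for(ids, status)
  set.seed(51)
  # informative score (so the logistic slope is positive and the fitted
  # probabilities are increasing in it); rounding forces some ties
  sc <- round(as.numeric(status == "case") + rnorm(30), 1)
  res <- roc_increment(make_scores(ids, sc), cohort, covariates = character(0))
  # with no informative covariates the base model is a constant: AUC 0.5
  expect_equal(res$auc_base, 0.5, tolerance = 1e-9)
  expect_equal(res$auc_with_prs,
               auc_pairwise_oracle(as.numeric(status == "case"), sc),
               tolerance = 1e-9)

  # perfectly separating score
  sep <- ifelse(status == "case", 2, 0)
  res2 <- roc_increment(make_scores(ids, sep), cohort, covariates = character(0))
  expect_equal(res2$auc_with_prs, 1.0)

  # score independent of status, n = 2000
  set.seed(52)
  ids_big <- sprintf("b%04d", 1:2000)
  cohort_big <- make_cohort_for(ids_big, rep(c("case", "control"), 1000))
  res3 <- roc_increment(make_scores(ids_big, rnorm(2000)), cohort_big,
                        covariates = character(0))
  expect_equal(res3$auc_with_prs, 0.5, tolerance = 0.03)
})

test_that("Cox fit matches a 1-D partial-likelihood grid on a 3-subject fixture", {
  ids <- c("p1", "p2", "p3")
  cohort <- cohort_table(ids, "case", c("female", "male", "female"),
                         age_at_onset = c(50, 60, 70),
                         age_at_last_assessment = c(52, 61, 72))
  x <- c(1, 0, 1)
  fit <- aao_survival(make_scores(ids, x), cohort, cases_only = TRUE,
                      covariates = character(0))
  grid <- seq(-5, 5, by = 1e-4)
  ll <- vapply(grid, cox_partial_loglik, numeric(1),
               time = c(50, 60, 70), event = c(1, 1, 1), x = x)
  expect_equal(fit$hazard_beta, grid[which.max(ll)], tolerance = 1e-3)
})

test_that("Cox model recovers a known hazard ratio and rejects degenerate input", {
  set.seed(53)
  n <- 400
  group <- rep(0:1, each = n / 2)
  times <- rexp(n, rate = ifelse(group == 1, 2, 1))  # rate ratio 2
  onset <- 25 + 60 * (times / max(times))  # rank-preserving map into age range
  ids <- sprintf("s%04d", 1:n)
  cohort <- cohort_table(ids, "case", sample(c("female", "male"), n, TRUE),
                         age_at_onset = onset,
                         age_at_last_assessment = onset + 1)
  fit <- aao_survival(make_scores(ids, group), cohort, cases_only = TRUE,
                      covariates = character(0))
  expect_lt(abs(fit$hazard_beta - log(2)), 0.15)
  expect_lt(fit$p_value, 0.01)

  no_events <- make_cohort_for(ids, rep("control", n))
  expect_error(aao_survival(make_scores(ids, group), no_events), "events")
})

test_that("PRS permuted against onset is null in at least 90% of replicates", {
  set.seed(54)
  n <- 200
  rejections <- 0
  reps <- 100
  ids <- sprintf("s%03d", 1:n)
  status <- rep(c("case", "control"), each = n / 2)
  cohort <- make_cohort_for(ids, status, seed = 54)
  base_score <- rnorm(n)
  for (r in seq_len(reps)) {
    fit <- aao_survival(make_scores(ids, sample(base_score)), cohort,
                        covariates = character(0))
    rejections <- rejections + (fit$p_value <= 0.05)
  }
  expect_gte(1 - rejections / reps, 0.90)
})

test_that("KM tertile curves equal the hand product-limit on a planted fixture", {
  # T1 is the 5-subject fixture: events at 50, 55, 60; censored at 58, 65
  ids <- sprintf("s%02d", 1:15)
  status <- c("case", "case", "control", "case", "control",
              rep(c("case", "control"), c(8, 2)))
  # T3 onsets interleave T1's so the T3-vs-T1 hazard ratio is finite
  onset <- c(50, 55, NA, 60, NA, 61:65, 52, 59, 75, NA, NA)
  last <- c(51, 56, 58, 61, 65, 62:66, 53, 60, 76, 70, 71)
  cohort <- cohort_table(ids, status, rep(c("female", "male"), c(8, 7)),
                         age_at_onset = onset, age_at_last_assessment = last,
                         pc1 = rnorm(15, 0, 0.1), pc2 = rnorm(15, 0, 0.1))
  scores <- assign_tertiles(make_scores(ids, c(rep(0, 5), rep(1, 5), rep(2, 5))))
  expect_identical(scores$tertile, rep(c("T1", "T2", "T3"), each = 5))
  km <- km_tertile_analysis(scores, cohort, covariates = character(0))
  t1 <- km$km_curves[km$km_curves$tertile == "T1" & km$km_curves$n_event > 0, ]
  oracle <- km_product_limit_oracle(time = c(50, 55, 58, 60, 65),
                                    event = c(1, 1, 0, 1, 0))
  expect_equal(t1$time, oracle$time)
  expect_equal(t1$surv, oracle$surv, tolerance = 1e-12)
  # KM curves are non-increasing and within [0, 1]
  for (t in c("T1", "T2", "T3")) {
    cc <- km$km_curves[km$km_curves$tertile == t, ]
    expect_true(all(diff(cc$surv) <= 1e-12))
    expect_true(all(cc$surv >= 0 & cc$surv <= 1))
  }
  expect_true(is.finite(km$logrank_statistic))
  expect_equal(km$logrank_df, 1)
  expect_gt(km$tertile_effect, 0)
})

test_that("KM tertile analysis rejects all-censored and empty-tertile input", {
  ids <- sprintf("s%02d", 1:9)
  cohort <- make_cohort_for(ids, rep("control", 9))
  scores <- assign_tertiles(make_scores(ids, 1:9))
  expect_error(km_tertile_analysis(scores, cohort, covariates = character(0)),
               "censored|events")
  scores2 <- make_scores(ids, 1:9)  # tertiles never assigned
  expect_error(km_tertile_analysis(scores2, make_cohort_for(ids, rep("case", 9))),
               "tertiles")
})

test_that("biomarker model recovers a planted PRS effect and interpolates exactly", {
  set.seed(55)
  n <- 500
  ids <- sprintf("s%04d", 1:n)
  cohort <- make_cohort_for(ids, rep(c("case", "control"), n / 2), seed = 55)
  prs <- rnorm(n, 0, 0.5)
  lvl <- 10^(2.5 - 0.4 * prs + rnorm(n, 0, 0.15))
  bm <- harmonize(biomarker_table(ids, "t_tau", lvl, "A", 60))
  res <- biomarker_association(make_scores(ids, prs), bm, cohort, "t_tau",
                               covariates = character(0))
  expect_gt(res$beta, -0.5)
  expect_lt(res$beta, -0.3)
  expect_lt(res$p_value, 1e-6)

  # exact linear relation: beta recovered exactly, residuals zero
  ids12 <- sprintf("e%02d", 1:12)
  prs12 <- seq(-1, 1, length.out = 12)
  lvl12 <- 10^(2 + 0.25 * prs12)
  bm12 <- harmonize(biomarker_table(ids12, "p_tau", lvl12, "A", 60))
  res12 <- suppressWarnings(  # lm flags the deliberately perfect fit
    biomarker_association(make_scores(ids12, prs12), bm12,
                          make_cohort_for(ids12, rep(c("case", "control"), 6)),
                          "p_tau", covariates = character(0)))
  expect_equal(res12$beta, 0.25, tolerance = 1e-10)
  expect_error(biomarker_association(make_scores(ids12, prs12), bm12,
                                     make_cohort_for(ids12, rep(c("case", "control"), 6)),
                                     "abeta_1_42"),
               "absent")
})

test_that("single-variant tests yield one row per panel variant and flag monomorphs", {
  panel <- pd_scoring_panel()
  m <- make_panel_matrix(n = 120, seed = 56)
  m$dosages[, "rs117896735"] <- 0  # force a monomorphic variant
  ids <- rownames(m$dosages)
  cohort <- make_cohort_for(ids, rep(c("case", "control"), 60), seed = 56)
  expect_warning(res <- single_variant_tests(m, panel, cohort, trait = "status"),
                 "monomorphic")
  expect_equal(nrow(res), 16)
  expect_identical(res$predictor, panel$variants$variant_id)
  mono <- res[res$predictor == "rs117896735", ]
  expect_true(is.na(mono$beta))
  expect_match(mono$note, "monomorphic")
  expect_true(all(grepl("nominal", res$note[res$predictor != "rs117896735"])))
})

test_that("stratified reruns subset cases and keep controls", {
  set.seed(57)
  n <- 300
  ids <- sprintf("s%04d", 1:n)
  status <- rep(c("case", "control"), c(200, 100))
  cohort <- make_cohort_for(ids, status, seed = 57)
  cohort$family_history <- ifelse(status == "case",
                                  sample(c("yes", "no"), n, TRUE), "no")
  scores <- make_scores(ids, rnorm(n, ifelse(status == "case", 0.3, 0), 0.5))

  full <- status_association(scores, cohort)
  all_strat <- stratified_rerun(status_association, scores, cohort, "all")
  expect_equal(all_strat$beta, full$beta)
  expect_identical(all_strat$stratum, "all")

  yes <- stratified_rerun(status_association, scores, cohort, "yes")
  n_yes_cases <- sum(cohort$status == "case" & cohort$family_history == "yes")
  expect_equal(yes$n_used, n_yes_cases + 100)  # all controls retained

  no_cases <- cohort[cohort$status == "control", ]
  expect_error(stratified_rerun(status_association,
                                scores[scores$sample_id %in% no_cases$sample_id, ],
                                no_cases, "yes"),
               "empty case stratum")
})

test_that("equal effects in both strata rarely differ by more than twice the pooled SE", {
  set.seed(58)
  reps <- 50
  n <- 400
  agree <- 0
  ids <- sprintf("s%04d", 1:n)
  for (r in seq_len(reps)) {
    prs <- rnorm(n, 0, 0.5)
    p_case <- plogis(-0.2 + 1.0 * prs)  # same PRS effect everywhere
    status <- ifelse(runif(n) < p_case, "case", "control")
    cohort <- make_cohort_for(ids, status, seed = 58000 + r)
    cohort$family_history <- ifelse(status == "case",
                                    sample(c("yes", "no"), n, TRUE), "no")
    scores <- make_scores(ids, prs)
    b_yes <- stratified_rerun(status_association, scores, cohort, "yes",
                              covariates = character(0))
    b_no <- stratified_rerun(status_association, scores, cohort, "no",
                             covariates = character(0))
    se_yes <- (b_yes$ci_high - b_yes$beta) / qnorm(0.975)
    se_no <- (b_no$ci_high - b_no$beta) / qnorm(0.975)
    pooled <- sqrt(se_yes^2 + se_no^2)
    agree <- agree + (abs(b_yes$beta - b_no$beta) < 2 * pooled)
  }
  expect_gte(agree / reps, 0.90)
})

test_that("cohort summaries reproduce printed-count arithmetic", {
  status <- rep(c("control", "case"), c(432, 829))
  sex <- c(rep(c("female", "male"), c(197, 432 - 197)),
           rep(c("female", "male"), c(278, 829 - 278)))
  ids <- sprintf("s%04d", seq_along(status))
  onset <- ifelse(status == "case", 61, NA)
  cohort <- cohort_table(ids, status, sex, onset,
                         age_at_last_assessment = 64,
                         family_history = ifelse(status == "case", "yes", "no"),
                         platform = "combined")
  summ <- summarize_cohort(cohort)
  comb <- summ[summ$group == "combined", ]
  expect_equal(sum(comb$n), 1261)
  expect_equal(comb$pct_female[comb$status == "control"], 45.60)
  expect_equal(comb$pct_female[comb$status == "case"], 33.53)
  expect_equal(nrow(summarize_cohort(cohort[0, ])), 0)
})

test_that("association results round-trip through the TSV/JSON writers", {
  ids <- sprintf("s%03d", 1:60)
  cohort <- make_cohort_for(ids, rep(c("case", "control"), 30), seed = 59)
  res <- status_association(make_scores(ids, rnorm(60)), cohort)
  tmp <- tempfile(fileext = ".tsv")
  jtmp <- tempfile(fileext = ".json")
  write_results(res, tmp, json_path = jtmp)
  back <- utils::read.delim(tmp, stringsAsFactors = FALSE)
  expect_equal(back$beta, res$beta, tolerance = 1e-6)
  jback <- jsonlite::read_json(jtmp, simplifyVector = TRUE)
  expect_equal(jback$beta, res$beta, tolerance = 1e-12)
})
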