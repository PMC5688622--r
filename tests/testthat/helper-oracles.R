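# Independent oracles and small fixture builders shared across the suite.
# Each oracle is a deliberately naive reimplementation (enumeration, brute
# force, closed form) against which the package's fast path is checked.

# exact HWE p-value by direct enumeration over all heterozygote counts
# consistent with the allele counts (log-factorial form; no recurrence)
hwe_enumeration_oracle <- function(a, h, b) {
  n <- a + h + b
  n_eff <- 2 * a + h
  hets <- seq(n_eff %% 2, min(n_eff, 2 * n - n_eff), by = 2)
  pr <- vapply(hets, function(het) {
    homa <- (n_eff - het) / 2
    homb <- n - het - homa
    if (homa < 0 || homb < 0) return(0)
    exp(lfactorial(n) - lfactorial(homa) - lfactorial(het) - lfactorial(homb) +
          het * log(2) + lfactorial(n_eff) + lfactorial(2 * n - n_eff) -
          lfactorial(2 * n))
  }, numeric(1))
  pobs <- pr[match(h, hets)]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# 1-df chi-square HWE test
hwe_chisq <- function(a, h, b) {
  n <- a + h + b
  p <- (2 * a + h) / (2 * n)
  e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
  stats::pchisq(sum((c(a, h, b) - e)^2 / e), 1, lower.tail = FALSE)
}

# per-sample loop-and-accumulate PRS oracle (mean-impute policy)
prs_loop_oracle <- function(dosages, weights, study_maf) {
  n <- nrow(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_along(weights)) {
      d <- dosages[i, j]
      if (is.na(d)) d <- 2 * study_maf[j]
      acc <- acc + d * weights[j]
    }
    out[i] <- acc
  }
  out
}

# brute-force pairwise-concordance AUC
auc_pairwise_oracle <- function(outcome, score) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  conc <- 0
  for (a in pos) for (b in neg) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(pos) * length(neg))
}

# hand product-limit estimator: returns survival at each distinct event time
km_product_limit_oracle <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ut))
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / at_risk)
    out[k] <- s
  }
  data.frame(time = ut, surv = out)
}

# Cox partial log-likelihood for a single covariate, no ties (Breslow = Efron)
cox_partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# small fully-observed dosage matrix over the packaged panel
make_panel_matrix <- function(n = 20, seed = 11, panel = pd_scoring_panel()) {
  set.seed(seed)
  pv <- panel$variants
  d <- vapply(pv$study_maf, function(p) stats::rbinom(n, 2, p), numeric(n))
  dimnames(d) <- list(sprintf("s%03d", seq_len(n)), pv$variant_id)
  dosage_matrix(d)
}

# minimal cohort matching a score set; ages drawn deterministically
make_cohort_for <- function(sample_ids, status, seed = 5) {
  set.seed(seed)
  n <- length(sample_ids)
  onset <- ifelse(status == "case", round(stats::runif(n, 40, 80), 1), NA)
  cohort_table(sample_id = sample_ids, status = status,
               sex = sample(c("female", "male"), n, replace = TRUE),
               age_at_onset = onset,
               age_at_last_assessment = ifelse(status == "case",
                                               onset + 3, round(stats::runif(n, 50, 85), 1)),
               age_at_lp = round(stats::runif(n, 45, 80), 1),
               family_history = sample(c("yes", "no"), n, replace = TRUE),
               platform = "fix", pc1 = stats::rnorm(n, 0, 0.1),
               pc2 = stats::rnorm(n, 0, 0.1))
}

# score_set wrapper for hand-built scores
make_scores <- function(sample_ids, score, tertile = NA_character_) {
  out <- data.frame(sample_id = sample_ids, score = score,
                    n_variants_used = 16L, tertile = tertile,
                    stringsAsFactors = FALSE)
  class(out) <- c("score_set", "data.frame")
  out
}
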