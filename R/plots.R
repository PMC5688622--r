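#' Plot PRS distributions by case-control status
#'
#' Overlaid density curves of the score in controls (solid) and cases
#' (dotted), the standard visual check that the score separates the groups.
#'
#' @param scores A `score_set`.
#' @param cohort A `cohort_table`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the two density objects.
#' @export
plot_prs_distribution <- function(scores, cohort, ...) {
  dat <- merge_scores_cohort(scores, cohort)
  d_ctrl <- stats::density(dat$score[dat$status == "control"])
  d_case <- stats::density(dat$score[dat$status == "case"])
  ylim <- range(0, d_ctrl$y, d_case$y)
  graphics::plot(d_ctrl, lty = 1, ylim = ylim, xlab = "PRS (weighted sum)",
                 main = "PRS distribution by PD status", ...)
  graphics::lines(d_case, lty = 3)
  graphics::legend("topright", legend = c("controls", "cases"), lty = c(1, 3),
                   bty = "n")
  invisible(list(control = d_ctrl, case = d_case))
}

#' Plot Kaplan-Meier onset curves by PRS tertile
#'
#' @param km A `survival_result` from [km_tertile_analysis()].
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `km`.
#' @export
plot_km_tertiles <- function(km, ...) {
  curves <- km$km_curves
  terts <- sort(unique(curves$tertile))
  cols <- c(T1 = "black", T2 = "red", T3 = "darkgreen")[terts]
  graphics::plot(range(curves$time), c(0, 1), type = "n",
                 xlab = "Age at onset (years)", ylab = "Onset-free fraction",
                 main = "Age at onset by PRS tertile", ...)
  for (t in terts) {
    cc <- curves[curves$tertile == t, ]
    graphics::lines(stats::stepfun(cc$time, c(1, cc$surv)), do.points = FALSE,
                    col = cols[[t]])
  }
  graphics::legend("bottomleft", legend = terts, col = cols, lty = 1, bty = "n")
  invisible(km)
}
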