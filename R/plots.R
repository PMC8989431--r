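# Base-graphics figures: ROC curves, risk-group prevalence bars,
# calibration curves.

#' Plot ROC curves for paired predictions
#'
#' @param y binary outcome vector.
#' @param p_iprs,p_prs paired prediction vectors.
#' @param ... passed to [graphics::plot()].
#' @export
plot_roc <- function(y, p_iprs, p_prs, ...) {
  roc_points <- function(p) {
    th <- sort(unique(p), decreasing = TRUE)
    tpr <- vapply(th, function(t) mean(p[y == 1] >= t), numeric(1))
    fpr <- vapply(th, function(t) mean(p[y == 0] >= t), numeric(1))
    cbind(c(0, fpr, 1), c(0, tpr, 1))
  }
  r1 <- roc_points(p_iprs); r2 <- roc_points(p_prs)
  graphics::plot(r1, type = "l", col = "firebrick", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = "ROC", ...)
  graphics::lines(r2, col = "steelblue", lwd = 2)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = c("firebrick", "steelblue"),
                   legend = c(sprintf("iPRS model (AUC %.3f)", auc(y, p_iprs)),
                              sprintf("PRS model (AUC %.3f)", auc(y, p_prs))))
  invisible(NULL)
}

#' Plot risk-group prevalences for two models
#'
#' @param st_iprs,st_prs `"strat_table"` objects.
#' @export
plot_prevalence <- function(st_iprs, st_prs) {
  h <- rbind(iPRS = st_iprs$prevalence, PRS = st_prs$prevalence)
  colnames(h) <- st_iprs$group
  graphics::barplot(h, beside = TRUE, col = c("firebrick", "steelblue"),
                    ylab = "Prevalence", main = "Risk stratification",
                    legend.text = TRUE, args.legend = list(bty = "n"))
  invisible(NULL)
}

#' Plot calibration curves for two models
#'
#' @param cal_iprs,cal_prs data.frames from [calibration_curve()].
#' @export
plot_calibration <- function(cal_iprs, cal_prs) {
  rng <- range(c(cal_iprs$mean_pred, cal_iprs$obs_freq,
                 cal_prs$mean_pred, cal_prs$obs_freq))
  graphics::plot(cal_iprs$mean_pred, cal_iprs$obs_freq, type = "b", pch = 16,
                 col = "firebrick", xlim = rng, ylim = rng,
                 xlab = "Mean predicted risk", ylab = "Observed frequency",
                 main = "Calibration")
  graphics::lines(cal_prs$mean_pred, cal_prs$obs_freq, type = "b", pch = 17,
                  col = "steelblue")
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("topleft", bty = "n", pch = c(16, 17),
                   col = c("firebrick", "steelblue"),
                   legend = c("iPRS model", "PRS model"))
  invisible(NULL)
}

#' @export
plot.iprs_eval <- function(x, which = c("roc", "prevalence", "calibration"),
                           y = NULL, p_iprs = NULL, p_prs = NULL, ...) {
  which <- match.arg(which)
  switch(which,
    roc = {
      if (is.null(y)) stop_iprs("plot(..., which='roc') needs y, p_iprs, p_prs")
      plot_roc(y, p_iprs, p_prs)
    },
    prevalence = plot_prevalence(x$stratification_iprs, x$stratification_prs),
    calibration = plot_calibration(x$calibration_iprs, x$calibration_prs))
  invisible(x)
}
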