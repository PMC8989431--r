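# Discrimination, stratification and calibration metrics.

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a random case outscores a
#' random control, ties counted 1/2.
#'
#' @param y binary outcome vector (0/1).
#' @param p scores or predicted probabilities.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(y, p) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop_iprs("auc: both outcome classes must be present")
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties 1/2), and vice versa.
.placements <- function(y, p) {
  cases <- p[y == 1]; ctrls <- p[y == 0]
  r_all <- rank(c(cases, ctrls), ties.method = "average")
  m <- length(cases); n <- length(ctrls)
  r_cases <- rank(cases, ties.method = "average")
  r_ctrls <- rank(ctrls, ties.method = "average")
  V10 <- (r_all[seq_len(m)] - r_cases) / n             # per-case placement
  V01 <- 1 - (r_all[m + seq_len(n)] - r_ctrls) / m     # per-control placement
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two prediction vectors evaluated on the same
#' samples, using the covariance of their placement values.
#'
#' @param y binary outcome vector.
#' @param p1,p2 paired prediction vectors.
#' @return list: `auc1`, `auc2`, `z`, `p`, `degenerate` (TRUE when the
#'   variance estimate is zero, in which case `p = 1`).
#' @export
delong_test <- function(y, p1, p2) {
  stopifnot(length(y) == length(p1), length(y) == length(p2))
  if (!all(y %in% c(0, 1)) || length(unique(y)) < 2)
    stop_iprs("delong_test: both outcome classes must be present")
  a <- .placements(y, p1); b <- .placements(y, p2)
  m <- length(a$V10); n <- length(a$V01)
  s10 <- var(a$V10 - b$V10); s01 <- var(a$V01 - b$V01)
  v <- s10 / m + s01 / n
  d <- a$auc - b$auc
  if (!is.finite(v) || v <= 0) {
    return(list(auc1 = a$auc, auc2 = b$auc, z = 0, p = 1, degenerate = TRUE))
  }
  z <- d / sqrt(v)
  list(auc1 = a$auc, auc2 = b$auc, z = z, p = 2 * pnorm(-abs(z)),
       degenerate = FALSE)
}

#' Risk stratification by score percentiles
#'
#' Partitions samples at the 5th and 95th empirical percentiles (type-7
#' quantiles) of the score into low / intermediate / high risk groups and
#' reports disease prevalence per group. Samples strictly below the lower
#' cut are low risk, strictly above the upper cut high risk; ties at a cut
#' fall into the lower of the two adjacent groups.
#'
#' @param p scores or predicted probabilities.
#' @param y binary outcome vector.
#' @param cuts quantile cut points (default `c(0.05, 0.95)`).
#' @return data.frame of class `"strat_table"`: `group`, `lower`, `upper`,
#'   `n`, `n_cases`, `prevalence`.
#' @export
stratify <- function(p, y, cuts = c(0.05, 0.95)) {
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  if (length(p) < 20) stop_iprs("stratify: need at least 20 samples")
  q <- quantile(p, cuts, type = 7, names = FALSE)
  grp <- ifelse(p < q[1], "low", ifelse(p > q[2], "high", "intermediate"))
  if (q[1] == q[2]) {
    warning("stratify: degenerate scores, all samples intermediate", call. = FALSE)
    grp[] <- "intermediate"
  }
  lev <- c("low", "intermediate", "high")
  out <- data.frame(
    group = lev,
    lower = c(-Inf, q[1], q[2]),
    upper = c(q[1], q[2], Inf),
    n = vapply(lev, function(g) sum(grp == g), integer(1)),
    n_cases = vapply(lev, function(g) sum(y[grp == g] == 1), integer(1)),
    stringsAsFactors = FALSE
  )
  out$prevalence <- ifelse(out$n > 0, out$n_cases / out$n, NA_real_)
  rownames(out) <- NULL
  class(out) <- c("strat_table", "data.frame")
  out
}

#' Chi-square comparison of two stratification tables
#'
#' Pearson chi-square on the 2 (models) x 3 (risk groups) table of case
#' counts. Note this treats the two models' case counts as independent
#' samples even though they are computed on the same cohort; the test is
#' reported as printed in the field, with this caveat documented.
#'
#' @param tableA,tableB `"strat_table"` objects on the same cohort.
#' @return list: `chi2`, `df`, `p`, `warning_small_cells`.
#' @export
prevalence_chisq <- function(tableA, tableB) {
  stopifnot(inherits(tableA, "strat_table"), inherits(tableB, "strat_table"))
  if (sum(tableA$n) != sum(tableB$n))
    stop_iprs("stratification tables refer to different sample totals")
  tab <- rbind(A = tableA$n_cases, B = tableB$n_cases)
  colnames(tab) <- tableA$group
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  small <- any(ct$expected < 1)
  chi2 <- unname(ct$statistic)
  if (!is.finite(chi2)) chi2 <- 0
  p <- unname(ct$p.value); if (!is.finite(p)) p <- 1
  list(chi2 = chi2, df = unname(ct$parameter), p = p,
       warning_small_cells = small)
}

#' Brier score with bootstrap confidence interval
#'
#' Mean squared difference between the outcome and the predicted
#' probability, with a seeded percentile bootstrap over samples.
#'
#' @param y binary outcome vector.
#' @param p predicted probabilities.
#' @param ci_reps bootstrap replicates (default 2000; 0 skips the CI).
#' @param seed RNG seed for the bootstrap.
#' @return list: `score`, `ci_low`, `ci_high`.
#' @export
brier_score <- function(y, p, ci_reps = 2000, seed = 1) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  sq <- (y - p)^2
  score <- mean(sq)
  if (ci_reps <= 0) return(list(score = score, ci_low = NA_real_, ci_high = NA_real_))
  n <- length(y)
  boots <- with_seed(seed, {
    vapply(seq_len(ci_reps), function(i) mean(sq[sample.int(n, n, replace = TRUE)]),
           numeric(1))
  })
  ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
  list(score = score, ci_low = ci[1], ci_high = ci[2])
}

#' Calibration curve
#'
#' Quantile bins of the predicted probability (deciles by default); per bin
#' the mean prediction, observed outcome frequency and bin size. Bins that
#' collapse under ties are merged; empty bins are omitted.
#'
#' @param y binary outcome vector.
#' @param p predicted probabilities.
#' @param n_bins number of quantile bins (default 10).
#' @param smooth return a lowess-smoothed curve of observed outcome against
#'   prediction instead of binned points (default FALSE), for smooth
#'   calibration figures.
#' @return data.frame: `mean_pred`, `obs_freq`, `n`.
#' @export
calibration_curve <- function(y, p, n_bins = 10, smooth = FALSE) {
  stopifnot(length(y) == length(p))
  if (smooth) {
    lo <- stats::lowess(p, y, f = 2 / 3)
    return(data.frame(mean_pred = lo$x, obs_freq = pmin(pmax(lo$y, 0), 1),
                      n = length(y)))
  }
  br <- unique(quantile(p, seq(0, 1, length.out = n_bins + 1), names = FALSE))
  if (length(br) < 2) {
    return(data.frame(mean_pred = mean(p), obs_freq = mean(y), n = length(y)))
  }
  bin <- cut(p, br, include.lowest = TRUE)
  agg <- lapply(split(seq_along(p), bin), function(ix) {
    if (!length(ix)) return(NULL)
    data.frame(mean_pred = mean(p[ix]), obs_freq = mean(y[ix]), n = length(ix))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out
}

#' Spiegelhalter's z test of calibration
#'
#' \deqn{z = \frac{\sum (y_i - p_i)(1 - 2 p_i)}
#'   {\sqrt{\sum (1 - 2 p_i)^2 p_i (1 - p_i)}}}
#' with a two-sided normal p-value. All `p` equal to 0.5 makes the
#' denominator zero; by convention `z = 0` is returned with a degenerate
#' flag.
#'
#' @param y binary outcome vector.
#' @param p predicted probabilities strictly inside (0, 1).
#' @return list: `z`, `p`, `degenerate`.
#' @export
spiegelhalter_test <- function(y, p) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  if (any(p <= 0 | p >= 1)) stop_iprs("predicted probabilities must be in (0, 1)")
  num <- sum((y - p) * (1 - 2 * p))
  den <- sqrt(sum((1 - 2 * p)^2 * p * (1 - p)))
  if (den == 0) return(list(z = 0, p = 1, degenerate = TRUE))
  z <- num / den
  list(z = z, p = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Cox recalibration slope and intercept
#'
#' Logistic regression of the outcome on the logit of the predicted
#' probability; slope 1 and intercept 0 indicate perfect calibration.
#'
#' @param y binary outcome vector.
#' @param p predicted probabilities strictly inside (0, 1).
#' @return list: `slope`, `intercept`.
#' @export
cox_calibration <- function(y, p) {
  stopifnot(length(y) == length(p), all(y %in% c(0, 1)))
  if (any(p <= 0 | p >= 1)) stop_iprs("predicted probabilities must be in (0, 1)")
  lp <- qlogis(p)
  gf <- .glm_fit_quiet(y ~ lp, data.frame(y = y, lp = lp))
  if (gf$suspect) stop_iprs("cox_calibration: separation, recalibration fit did not converge")
  cf <- coef(gf$fit)
  list(slope = unname(cf["lp"]), intercept = unname(cf["(Intercept)"]))
}

#' Evaluate two paired prediction models
#'
#' Runs the full battery on paired predictions from the iPRS and PRS
#' prediction models: AUC per model with the DeLong comparison, 5/90/5
#' percentile risk stratification with the prevalence chi-square, Brier
#' scores with bootstrap CIs, calibration curves, Spiegelhalter's z and the
#' Cox recalibration slope/intercept.
#'
#' @param y binary outcome vector.
#' @param p_iprs predicted probabilities from the iPRS model.
#' @param p_prs predicted probabilities from the PRS model.
#' @param ci_reps bootstrap replicates for the Brier CIs.
#' @param seed RNG seed for the bootstrap.
#' @return list of class `"iprs_eval"`.
#' @export
evaluate_predictions <- function(y, p_iprs, p_prs, ci_reps = 2000, seed = 1) {
  p_iprs <- clamp_prob(p_iprs); p_prs <- clamp_prob(p_prs)
  dl <- delong_test(y, p_iprs, p_prs)
  st_i <- stratify(p_iprs, y); st_p <- stratify(p_prs, y)
  res <- list(
    auc_iprs = dl$auc1, auc_prs = dl$auc2,
    delong = dl,
    stratification_iprs = st_i,
    stratification_prs = st_p,
    prevalence_test = prevalence_chisq(st_i, st_p),
    brier_iprs = brier_score(y, p_iprs, ci_reps, seed = seed),
    brier_prs = brier_score(y, p_prs, ci_reps, seed = derive_seed(seed, 1)),
    calibration_iprs = calibration_curve(y, p_iprs),
    calibration_prs = calibration_curve(y, p_prs),
    spiegelhalter_iprs = spiegelhalter_test(y, p_iprs),
    spiegelhalter_prs = spiegelhalter_test(y, p_prs),
    cox_iprs = cox_calibration(y, p_iprs),
    cox_prs = cox_calibration(y, p_prs),
    n = length(y)
  )
  class(res) <- "iprs_eval"
  res
}

#' @export
print.iprs_eval <- function(x, ...) {
  cat(sprintf("Evaluation on %d samples\n", x$n))
  cat(sprintf("  AUC  iPRS model: %.4f   PRS model: %.4f   (DeLong p = %.4g)\n",
              x$auc_iprs, x$auc_prs, x$delong$p))
  hi <- x$stratification_iprs$prevalence[x$stratification_iprs$group == "high"]
  hp <- x$stratification_prs$prevalence[x$stratification_prs$group == "high"]
  cat(sprintf("  High-risk prevalence  iPRS: %.2f%%   PRS: %.2f%%   (chi2 p = %.4g)\n",
              100 * hi, 100 * hp, x$prevalence_test$p))
  cat(sprintf("  Brier  iPRS: %.4f [%.4f, %.4f]   PRS: %.4f [%.4f, %.4f]\n",
              x$brier_iprs$score, x$brier_iprs$ci_low, x$brier_iprs$ci_high,
              x$brier_prs$score, x$brier_prs$ci_low, x$brier_prs$ci_high))
  cat(sprintf("  Spiegelhalter z  iPRS: %.3f (p=%.3f)   PRS: %.3f (p=%.3f)\n",
              x$spiegelhalter_iprs$z, x$spiegelhalter_iprs$p,
              x$spiegelhalter_prs$z, x$spiegelhalter_prs$p))
  cat(sprintf("  Cox slope/intercept  iPRS: %.3f / %.3g   PRS: %.3f / %.3g\n",
              x$cox_iprs$slope, x$cox_iprs$intercept,
              x$cox_prs$slope, x$cox_prs$intercept))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param ev an `"iprs_eval"`.
#' @param path optional output file.
#' @return JSON string.
#' @export
eval_report_json <- function(ev, path = NULL) {
  stopifnot(inherits(ev, "iprs_eval"))
  obj <- ev
  obj$stratification_iprs <- as.data.frame(obj$stratification_iprs)
  obj$stratification_prs <- as.data.frame(obj$stratification_prs)
  obj$metadata <- list(
    stratification = "groups at 5th/95th percentile of the predicted value",
    prevalence_test = "Pearson chi-square on the 2-model x 3-group case counts")
  js <- jsonlite::toJSON(unclass(obj), auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
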