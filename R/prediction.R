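# Second-stage prediction models and cross-validated pipeline.
#
# The two second-stage designs, fitted by maximum likelihood with an
# intercept (the constructed-score covariates are re-weighted on the
# training data, the standard two-stage practice):
#   prs_model:  logit P(y=1) = b0 + b1*PRS + b2*(PRS*E) + b3*E
#   iprs_model: logit P(y=1) = b0 + b1*iPRS + b2*E

#' Fit a second-stage risk model
#'
#' @param kind `"iprs_model"` (regressors score + E) or `"prs_model"`
#'   (regressors score + score*E + E).
#' @param scores score vector from [compute_prs()] / [compute_iprs()].
#' @param e exposure vector.
#' @param y binary outcome vector.
#' @param fold optional fold label used in error messages.
#' @return list of class `"risk_model"`: `kind`, `coefficients`, `fold`.
#' @export
fit_risk_model <- function(kind = c("iprs_model", "prs_model"), scores, e, y,
                           fold = NA) {
  kind <- match.arg(kind)
  stopifnot(length(scores) == length(y), length(e) == length(y))
  if (!all(y %in% c(0, 1))) stop_iprs("outcome y must be coded 0/1")
  if (var(scores) == 0)
    stop_iprs("%s (fold %s): score is constant, model not estimable", kind, fold)
  dat <- data.frame(y = y, s = as.numeric(scores), e = e)
  form <- if (kind == "iprs_model") y ~ s + e else y ~ s + s:e + e
  # rank check before fitting: constant or collinear design columns
  mm <- stats::model.matrix(form, dat)
  if (qr(mm)$rank < ncol(mm))
    stop_iprs(paste0("%s (fold %s): design is rank deficient (a regressor is ",
                     "constant or collinear, e.g. exposure identically zero); ",
                     "drop the offending term(s)"), kind, fold)
  gf <- .glm_fit_quiet(form, dat)
  if (gf$suspect || anyNA(coef(gf$fit)))
    stop_iprs("%s (fold %s): separation, fit did not converge", kind, fold)
  structure(list(kind = kind, coefficients = coef(gf$fit), fold = fold),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("Second-stage %s (fold %s)\n", x$kind, x$fold))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.risk_model <- function(object, ...) object$coefficients

.risk_lp <- function(model, scores, e) {
  cf <- model$coefficients
  s <- as.numeric(scores)
  if (model$kind == "iprs_model") {
    cf["(Intercept)"] + cf["s"] * s + cf["e"] * e
  } else {
    cf["(Intercept)"] + cf["s"] * s + cf["e"] * e + cf["s:e"] * s * e
  }
}

#' Predicted probabilities from a risk model
#'
#' Inverse-logit of the linear predictor; values are clamped strictly inside
#' (0, 1).
#'
#' @param model a `"risk_model"`.
#' @param scores score vector.
#' @param e exposure vector.
#' @return probability vector.
#' @export
predict_risk <- function(model, scores, e) {
  stopifnot(inherits(model, "risk_model"), length(scores) == length(e))
  clamp_prob(unname(plogis(.risk_lp(model, scores, e))))
}

#' @export
predict.risk_model <- function(object, scores, e, ...) {
  predict_risk(object, scores, e)
}

# Score a dataset against a flipped weight set: columns listed in
# flipped_ids are counted on the other allele (dosage 2 - g). Processed in
# column blocks so large panels never materialize a full double copy.
.score_dataset <- function(ds, weights, flipped_ids, e = NULL) {
  idx <- match(weights$variant_id, ds$variants$id)
  if (anyNA(idx))
    stop_iprs("dataset lacks score variants: %s",
              paste(weights$variant_id[is.na(idx)], collapse = ", "))
  n <- n_samples(ds); J <- length(idx)
  flip <- weights$variant_id %in% flipped_ids
  # flipping a variant replaces w*g by w*(2-g) = 2w - w*g: flip the weight
  # sign and add a constant, so no dosage columns are rewritten
  sgn <- ifelse(flip, -1, 1)
  wm <- weights$beta_main * sgn
  wi <- weights$beta_gxe * sgn
  const_m <- 2 * sum(weights$beta_main[flip])
  const_i <- 2 * sum(weights$beta_gxe[flip])
  W <- if (is.null(e)) cbind(wm) else cbind(wm, wi)
  acc <- matrix(0, nrow = n, ncol = ncol(W))
  cs <- max(1L, min(J, floor(5e6 / n)))
  for (start in seq(1L, J, by = cs)) {
    jj <- start:min(J, start + cs - 1L)
    dos <- ds$dosages[, idx[jj], drop = FALSE]
    if (anyNA(dos)) dos <- impute_mean(dos) else storage.mode(dos) <- "double"
    acc <- acc + dos %*% W[jj, , drop = FALSE]
  }
  s <- if (is.null(e)) acc[, 1] + const_m
  else (acc[, 1] + const_m) + (acc[, 2] + const_i) * e
  setNames(s, sample_keys(ds))
}

# Shared stage-1 pipeline: scans, selection, weights, flip, training scores,
# second-stage fits for both model kinds.
.build_pipeline <- function(ds, y, e, covariates = NULL, p_threshold = 5e-6,
                            rule = "main_or_interaction", select = TRUE,
                            fold = NA, fit_stage2 = TRUE) {
  scan_int <- genome_scan(ds, y, e, covariates, model = "interaction")
  scan_marg <- genome_scan(ds, y, e, covariates, model = "marginal")
  ids <- if (select) {
    select_variants(scan_int, p_threshold, rule)
  } else {
    scan_int$variant_id[scan_int$converged]
  }
  ids <- intersect(ids, scan_marg$variant_id[scan_marg$converged])
  if (length(ids) == 0)
    stop_iprs("fold %s: no variants selected (threshold %g); cannot build scores",
              fold, p_threshold)
  w_iprs <- weights_from_scan(scan_int, ids, kind = "iprs")
  w_prs <- weights_from_scan(scan_marg, ids, kind = "prs")
  flip_i <- w_iprs$variant_id[w_iprs$beta_main < 0]
  flip_p <- w_prs$variant_id[w_prs$beta_main < 0]
  fw_iprs <- w_iprs; fw_iprs$beta_main <- abs(fw_iprs$beta_main)
  fw_iprs$beta_gxe[w_iprs$beta_main < 0] <- -fw_iprs$beta_gxe[w_iprs$beta_main < 0]
  fw_prs <- w_prs; fw_prs$beta_main <- abs(fw_prs$beta_main)
  s_iprs <- .score_dataset(ds, fw_iprs, flip_i, e)
  s_prs <- .score_dataset(ds, fw_prs, flip_p)
  list(scan_interaction = scan_int, scan_marginal = scan_marg,
       selected = ids,
       weights_iprs = fw_iprs, flipped_iprs = flip_i,
       weights_prs = fw_prs, flipped_prs = flip_p,
       model_iprs = if (fit_stage2)
         fit_risk_model("iprs_model", s_iprs, e, y, fold = fold),
       model_prs = if (fit_stage2)
         fit_risk_model("prs_model", s_prs, e, y, fold = fold),
       train_scores_iprs = s_iprs, train_scores_prs = s_prs)
}

#' Fit an iPRS (or traditional PRS) prediction model end to end
#'
#' The central fitting function: per-variant logistic scans on the supplied
#' data, optional p-value variant selection, risk-allele flipping, score
#' construction and the second-stage logistic risk model, returned as a
#' single fitted object that can predict on new genotype data.
#'
#' @param ds a `"genotypes"` object (post-QC).
#' @param y binary outcome vector aligned to samples.
#' @param e exposure vector aligned to samples.
#' @param covariates optional covariate matrix for the scans.
#' @param kind `"iprs"` or `"prs"`.
#' @param select apply p-value variant selection (default TRUE). With
#'   `FALSE`, all converged variants are scored (the polygenic reading).
#' @param p_threshold selection threshold (default 5e-6).
#' @param rule selection rule, see [select_variants()].
#' @return An object of class `"iprs_fit"` with `print`, `coef`, `predict`,
#'   `summary` and `residuals` methods.
#' @export
iprs_fit <- function(ds, y, e, covariates = NULL, kind = c("iprs", "prs"),
                     select = TRUE, p_threshold = 5e-6,
                     rule = c("main_or_interaction", "main_only")) {
  kind <- match.arg(kind); rule <- match.arg(rule)
  pipe <- .build_pipeline(ds, y, e, covariates, p_threshold, rule, select)
  scores <- if (kind == "iprs") pipe$train_scores_iprs else pipe$train_scores_prs
  model <- if (kind == "iprs") pipe$model_iprs else pipe$model_prs
  weights <- if (kind == "iprs") pipe$weights_iprs else pipe$weights_prs
  flipped <- if (kind == "iprs") pipe$flipped_iprs else pipe$flipped_prs
  fitted_p <- predict_risk(model, scores, e)
  structure(list(kind = kind, weights = weights, flipped = flipped,
                 model = model, selected = pipe$selected,
                 train_scores = scores, fitted = fitted_p, y = y, e = e,
                 n = length(y)),
            class = "iprs_fit")
}

#' @export
print.iprs_fit <- function(x, ...) {
  cat(sprintf("%s prediction model: %d variants, %d training samples\n",
              toupper(x$kind), nrow(x$weights), x$n))
  cat("Second-stage coefficients:\n")
  print(round(x$model$coefficients, 4))
  invisible(x)
}

#' @export
coef.iprs_fit <- function(object, ...) {
  list(stage1 = object$weights, stage2 = object$model$coefficients)
}

#' @export
predict.iprs_fit <- function(object, ds, e, ...) {
  s <- .score_dataset(ds, object$weights, object$flipped,
                      e = if (object$kind == "iprs") e else NULL)
  predict_risk(object$model, s, e)
}

#' @export
residuals.iprs_fit <- function(object, ...) object$y - object$fitted

#' @export
summary.iprs_fit <- function(object, ...) {
  cat(sprintf("%s prediction model\n", toupper(object$kind)))
  cat(sprintf("  variants scored: %d (of which %d flipped to risk allele)\n",
              nrow(object$weights), length(object$flipped)))
  cat(sprintf("  training AUC: %.4f\n", auc(object$y, object$fitted)))
  br <- brier_score(object$y, clamp_prob(object$fitted), ci_reps = 0)
  cat(sprintf("  training Brier score: %.4f\n", br$score))
  invisible(object)
}

# Stratified, seeded fold assignment by outcome class.
.assign_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      ix <- which(y == cls)
      fold[ix] <- sample(rep_len(seq_len(k), length(ix)))
    }
  })
  fold
}

#' Cross-validated comparison of the iPRS and PRS prediction models
#'
#' Stratified k-fold cross-validation. By default the whole stage-1
#' pipeline (scans, selection, weights) is re-estimated inside every
#' training fold, so test-fold samples never influence the weights
#' (leakage-free). `whole_sample_weights = TRUE` reproduces the alternative
#' reading in which scans and selection use the full sample and only the
#' second-stage models are refit per fold.
#'
#' @param ds a `"genotypes"` object (post-QC).
#' @param y binary outcome vector.
#' @param e exposure vector.
#' @param covariates optional covariate matrix.
#' @param k number of folds (default 5).
#' @param seed RNG seed for fold assignment.
#' @param select apply p-value variant selection (default TRUE).
#' @param p_threshold selection threshold (default 5e-6).
#' @param rule selection rule, see [select_variants()].
#' @param whole_sample_weights estimate stage-1 artifacts on the full
#'   sample (default FALSE).
#' @return An object of class `"iprs_cv"`: `predictions` (data.frame with
#'   `fid`, `iid`, `fold`, `y`, `p_prs_model`, `p_iprs_model`), per-fold
#'   `folds` artifacts, and the call settings.
#' @export
cross_validate <- function(ds, y, e, covariates = NULL, k = 5, seed = 1,
                           select = TRUE, p_threshold = 5e-6,
                           rule = c("main_or_interaction", "main_only"),
                           whole_sample_weights = FALSE) {
  rule <- match.arg(rule)
  n <- n_samples(ds)
  if (k < 2) stop_iprs("cross_validate: k must be at least 2")
  if (n < 10 * k) stop_iprs("cross_validate: need at least 10 samples per fold")
  stopifnot(length(y) == n, length(e) == n)
  fold <- .assign_folds(y, k, seed)
  for (f in seq_len(k)) {
    if (length(unique(y[fold != f])) < 2 || length(unique(y[fold == f])) < 2)
      stop_iprs("fold %d has a single outcome class; use fewer folds", f)
  }
  whole <- if (whole_sample_weights) {
    .build_pipeline(ds, y, e, covariates, p_threshold, rule, select, fold = "all")
  } else NULL
  p_prs <- p_iprs <- rep(NA_real_, n)
  fold_art <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    ds_tr <- subset_samples(ds, tr)
    if (whole_sample_weights) {
      s_iprs_tr <- .score_dataset(ds_tr, whole$weights_iprs, whole$flipped_iprs, e[tr])
      s_prs_tr <- .score_dataset(ds_tr, whole$weights_prs, whole$flipped_prs)
      art <- list(weights_iprs = whole$weights_iprs, flipped_iprs = whole$flipped_iprs,
                  weights_prs = whole$weights_prs, flipped_prs = whole$flipped_prs,
                  selected = whole$selected,
                  model_iprs = fit_risk_model("iprs_model", s_iprs_tr, e[tr], y[tr], fold = f),
                  model_prs = fit_risk_model("prs_model", s_prs_tr, e[tr], y[tr], fold = f))
    } else {
      cov_tr <- if (is.null(covariates)) NULL else covariates[tr, , drop = FALSE]
      art <- .build_pipeline(ds_tr, y[tr], e[tr], cov_tr,
                             p_threshold, rule, select, fold = f)
    }
    ds_te <- subset_samples(ds, te)
    s_iprs_te <- .score_dataset(ds_te, art$weights_iprs, art$flipped_iprs, e[te])
    s_prs_te <- .score_dataset(ds_te, art$weights_prs, art$flipped_prs)
    p_iprs[te] <- predict_risk(art$model_iprs, s_iprs_te, e[te])
    p_prs[te] <- predict_risk(art$model_prs, s_prs_te, e[te])
    fold_art[[f]] <- art[c("weights_iprs", "flipped_iprs", "weights_prs",
                           "flipped_prs", "selected", "model_iprs", "model_prs")]
  }
  structure(list(
    predictions = data.frame(fid = ds$samples$fid, iid = ds$samples$iid,
                             fold = fold, y = y,
                             p_prs_model = p_prs, p_iprs_model = p_iprs,
                             stringsAsFactors = FALSE),
    folds = fold_art,
    settings = list(k = k, seed = seed, select = select,
                    p_threshold = p_threshold, rule = rule,
                    whole_sample_weights = whole_sample_weights)
  ), class = "iprs_cv")
}

#' @export
print.iprs_cv <- function(x, ...) {
  pr <- x$predictions
  cat(sprintf("%d-fold cross-validation, %d samples (%d cases)\n",
              x$settings$k, nrow(pr), sum(pr$y)))
  cat(sprintf("  test AUC  iPRS model: %.4f   PRS model: %.4f\n",
              auc(pr$y, pr$p_iprs_model), auc(pr$y, pr$p_prs_model)))
  invisible(x)
}

#' @export
summary.iprs_cv <- function(object, ci_reps = 2000, seed = 1, ...) {
  pr <- object$predictions
  evaluate_predictions(pr$y, pr$p_iprs_model, pr$p_prs_model,
                       ci_reps = ci_reps, seed = seed)
}

#' Write cross-validated predictions
#'
#' Columns `FID`, `IID`, `fold`, `y`, `p_prs_model`, `p_iprs_model`.
#'
#' @param cv an `"iprs_cv"`.
#' @param path output path.
#' @export
write_cv_predictions <- function(cv, path) {
  pr <- cv$predictions
  out <- data.frame(FID = pr$fid, IID = pr$iid, fold = pr$fold, y = pr$y,
                    p_prs_model = pr$p_prs_model,
                    p_iprs_model = pr$p_iprs_model)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
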