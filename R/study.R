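# Replicated simulation studies: generate -> scan -> (select) -> score ->
# fit second-stage models -> evaluate, aggregated over replicates.

#' Run a replicated simulation study
#'
#' For each replicate, a dataset is generated from `cfg` (with a
#' replicate-specific seed derived from `seed`), both prediction models are
#' built and evaluated, and per-replicate metrics are collected.
#'
#' Evaluation mode defaults depend on the design. The sparse design fits and
#' evaluates on the full simulated dataset (`"insample"`, the single-dataset
#' analysis; with 10 SNPs the optimism is negligible). The polygenic design
#' defaults to `"split"`: per-variant weights for tens of thousands of
#' variants memorize the training outcomes to the point of separation when
#' evaluated in-sample, so each replicate is split into stratified halves,
#' weights and second-stage models are estimated on the training half and
#' all metrics are computed on the held-out half. `"cv"` (stratified k-fold)
#' is available for either design.
#'
#' By default no p-value selection is applied: the sparse design emulates a
#' panel of already-selected GWAS SNPs and the polygenic design assumes all
#' variants contribute; pass `select = TRUE` for thresholded selection.
#'
#' @param design `"sparse"` or `"polygenic"`.
#' @param cfg matching config object; defaults to the canonical config for
#'   the design.
#' @param n_replicates number of replicates.
#' @param seed master seed; replicate r runs under `derive_seed(seed, r)`.
#' @param select apply p-value variant selection (default FALSE).
#' @param p_threshold,rule selection settings, see [select_variants()].
#' @param evaluation `"insample"`, `"split"` or `"cv"`; default depends on
#'   the design (see Details).
#' @param k folds when `evaluation = "cv"`.
#' @param ci_reps Brier bootstrap replicates per replicate (default 0, no CI).
#' @return An object of class `"iprs_study"`: `replicates` (one row per
#'   replicate), `aggregate` (means over successful replicates), `n_failed`.
#' @export
run_simulation_study <- function(design = c("sparse", "polygenic"),
                                 cfg = NULL, n_replicates = 100, seed = 1,
                                 select = FALSE, p_threshold = 5e-6,
                                 rule = c("main_or_interaction", "main_only"),
                                 evaluation = NULL, k = 5,
                                 ci_reps = 0) {
  design <- match.arg(design); rule <- match.arg(rule)
  evaluation <- evaluation %||% if (design == "sparse") "insample" else "split"
  evaluation <- match.arg(evaluation, c("insample", "split", "cv"))
  if (is.null(cfg)) {
    cfg <- if (design == "sparse") sparse_sim_config() else polygenic_sim_config()
  }
  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    rows[[r]] <- run_study_replicate(design, cfg, replicate = r, seed = seed,
                                     select = select, p_threshold = p_threshold,
                                     rule = rule, evaluation = evaluation,
                                     k = k, ci_reps = ci_reps)
  }
  reps <- do.call(rbind, rows)
  ok <- !reps$failed
  num <- setdiff(names(reps), c("replicate", "failed", "error"))
  aggregate <- as.data.frame(lapply(reps[ok, num, drop = FALSE],
                                    mean, na.rm = TRUE))
  structure(list(design = design, replicates = reps, aggregate = aggregate,
                 n_failed = sum(!ok),
                 settings = list(seed = seed, select = select,
                                 p_threshold = p_threshold, rule = rule,
                                 evaluation = evaluation, k = k)),
            class = "iprs_study")
}

#' Run a single study replicate
#'
#' Exposed so an interrupted study can be resumed replicate by replicate:
#' replicate `r` under master seed `s` is fully reproducible in isolation.
#'
#' @inheritParams run_simulation_study
#' @param replicate replicate index (1-based).
#' @return one-row data.frame of metrics.
#' @export
run_study_replicate <- function(design, cfg, replicate, seed = 1,
                                select = FALSE, p_threshold = 5e-6,
                                rule = "main_or_interaction",
                                evaluation = NULL, k = 5, ci_reps = 0) {
  evaluation <- evaluation %||% if (design == "sparse") "insample" else "split"
  rep_seed <- derive_seed(seed, replicate)
  cfg$seed <- rep_seed
  out <- tryCatch({
    sim <- if (design == "sparse") simulate_sparse(cfg) else simulate_polygenic(cfg)
    ev <- if (evaluation == "insample") {
      pipe <- .build_pipeline(sim$genotypes, sim$y, sim$e, NULL,
                              p_threshold, rule, select, fold = replicate)
      p_i <- predict_risk(pipe$model_iprs, pipe$train_scores_iprs, sim$e)
      p_p <- predict_risk(pipe$model_prs, pipe$train_scores_prs, sim$e)
      n_sel <- length(pipe$selected)
      evaluate_predictions(sim$y, p_i, p_p, ci_reps = ci_reps, seed = rep_seed)
    } else if (evaluation == "split") {
      # discovery/target design: per-variant weights from the training half,
      # second-stage models fitted and evaluated on the held-out half (whose
      # scores are out-of-sample with respect to the weights)
      half <- .assign_folds(sim$y, 2, derive_seed(rep_seed, 1))
      tr <- half == 1L; te <- !tr
      ds_tr <- subset_samples(sim$genotypes, tr)
      pipe <- .build_pipeline(ds_tr, sim$y[tr], sim$e[tr], NULL,
                              p_threshold, rule, select, fold = replicate,
                              fit_stage2 = FALSE)
      ds_te <- subset_samples(sim$genotypes, te)
      s_i <- .score_dataset(ds_te, pipe$weights_iprs, pipe$flipped_iprs, sim$e[te])
      s_p <- .score_dataset(ds_te, pipe$weights_prs, pipe$flipped_prs)
      m_i <- fit_risk_model("iprs_model", s_i, sim$e[te], sim$y[te], fold = replicate)
      m_p <- fit_risk_model("prs_model", s_p, sim$e[te], sim$y[te], fold = replicate)
      p_i <- predict_risk(m_i, s_i, sim$e[te])
      p_p <- predict_risk(m_p, s_p, sim$e[te])
      n_sel <- length(pipe$selected)
      evaluate_predictions(sim$y[te], p_i, p_p, ci_reps = ci_reps, seed = rep_seed)
    } else {
      cv <- cross_validate(sim$genotypes, sim$y, sim$e, k = k, seed = rep_seed,
                           select = select, p_threshold = p_threshold,
                           rule = rule)
      n_sel <- length(unique(unlist(lapply(cv$folds, `[[`, "selected"))))
      summary(cv, ci_reps = ci_reps, seed = rep_seed)
    }
    prev <- function(st, g) st$prevalence[st$group == g]
    data.frame(
      replicate = replicate,
      auc_iprs = ev$auc_iprs, auc_prs = ev$auc_prs,
      auc_diff = ev$auc_iprs - ev$auc_prs,
      delong_p = ev$delong$p,
      prev_high_iprs = prev(ev$stratification_iprs, "high"),
      prev_high_prs = prev(ev$stratification_prs, "high"),
      prev_low_iprs = prev(ev$stratification_iprs, "low"),
      prev_low_prs = prev(ev$stratification_prs, "low"),
      chisq_p = ev$prevalence_test$p,
      brier_iprs = ev$brier_iprs$score, brier_prs = ev$brier_prs$score,
      n_selected = n_sel,
      failed = FALSE, error = NA_character_)
  }, error = function(e) {
    data.frame(replicate = replicate, auc_iprs = NA_real_, auc_prs = NA_real_,
               auc_diff = NA_real_, delong_p = NA_real_,
               prev_high_iprs = NA_real_, prev_high_prs = NA_real_,
               prev_low_iprs = NA_real_, prev_low_prs = NA_real_,
               chisq_p = NA_real_, brier_iprs = NA_real_, brier_prs = NA_real_,
               n_selected = NA_integer_, failed = TRUE,
               error = conditionMessage(e))
  })
  out
}

#' @export
print.iprs_study <- function(x, ...) {
  cat(sprintf("%s simulation study: %d replicates (%d failed)\n",
              x$design, nrow(x$replicates), x$n_failed))
  ag <- x$aggregate
  cat(sprintf("  mean AUC  iPRS model: %.4f   PRS model: %.4f   (mean gain %.4f)\n",
              ag$auc_iprs, ag$auc_prs, ag$auc_diff))
  cat(sprintf("  mean high-risk prevalence  iPRS: %.2f%%   PRS: %.2f%%\n",
              100 * ag$prev_high_iprs, 100 * ag$prev_high_prs))
  cat(sprintf("  mean Brier  iPRS: %.4f   PRS: %.4f\n",
              ag$brier_iprs, ag$brier_prs))
  invisible(x)
}
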