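# Per-variant logistic scans: the marginal model
#   logit P(y=1) = a + bM*g + bE*e + bC*c
# and the GxE interaction model
#   logit P(y=1) = a + bM*g + bE*e + bI*(g*e) + bC*c
# with Wald tests on the genotype and interaction coefficients.

.check_assoc_inputs <- function(y, g, e, covariates) {
  if (!all(y %in% c(0, 1))) stop_iprs("outcome y must be coded 0/1")
  n <- length(y)
  if (length(g) != n || length(e) != n)
    stop_iprs("y, g and e must have equal length")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop_iprs("covariate matrix has %d rows, expected %d",
                                         nrow(covariates), n)
  }
  if (var(g) == 0) stop_iprs("genotype vector is constant; coefficient not estimable")
  covariates
}

.glm_fit_quiet <- function(formula, data) {
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(formula, data = data, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(fit = fit, suspect = sep || !fit$converged)
}

.wald <- function(fit, term) {
  cf <- coef(summary(fit))
  if (!term %in% rownames(cf)) return(c(NA_real_, NA_real_, NA_real_))
  cf[term, c(1, 2, 4)]
}

#' Fit the marginal per-variant logistic model
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' variant's dosage, the exposure, and optional covariates, without an
#' interaction term. The genotype coefficient is the marginal log-odds per
#' counted allele, tested by a Wald test.
#'
#' @param y binary outcome vector (0/1).
#' @param g dosage vector.
#' @param e exposure vector.
#' @param covariates optional numeric covariate matrix.
#' @return A list of class `"marginal_fit"`: `alpha`, `beta_g_marginal`,
#'   `beta_e`, `beta_c`, `se_g`, `p_main`, `converged`.
#' @export
fit_marginal <- function(y, g, e, covariates = NULL) {
  covariates <- .check_assoc_inputs(y, g, e, covariates)
  dat <- data.frame(y = y, g = g, e = e)
  form <- y ~ g + e
  if (!is.null(covariates)) {
    cn <- paste0("c", seq_len(ncol(covariates)))
    dat[cn] <- covariates
    form <- stats::reformulate(c("g", "e", cn), response = "y")
  }
  gf <- .glm_fit_quiet(form, dat)
  w <- .wald(gf$fit, "g")
  structure(list(
    alpha = unname(coef(gf$fit)["(Intercept)"]),
    beta_g_marginal = if (gf$suspect) NA_real_ else unname(w[1]),
    beta_e = unname(coef(gf$fit)["e"]),
    beta_c = if (is.null(covariates)) numeric(0) else
      unname(coef(gf$fit)[paste0("c", seq_len(ncol(covariates)))]),
    se_g = if (gf$suspect) NA_real_ else unname(w[2]),
    p_main = if (gf$suspect) NA_real_ else unname(w[3]),
    converged = !gf$suspect
  ), class = "marginal_fit")
}

#' Fit the per-variant GxE interaction logistic model
#'
#' As [fit_marginal()] but adding the genotype-by-exposure product. The
#' genotype coefficient is the main effect (the variant's log-odds at
#' exposure zero); the product coefficient is the interaction log-odds.
#'
#' @inheritParams fit_marginal
#' @return A list of class `"interaction_fit"`: `alpha`, `beta_g_main`,
#'   `beta_e`, `beta_gxe`, `beta_c`, `se_g`, `se_gxe`, `p_main`,
#'   `p_interaction`, `converged`, `interaction_estimable`.
#' @export
fit_interaction <- function(y, g, e, covariates = NULL) {
  covariates <- .check_assoc_inputs(y, g, e, covariates)
  if (var(g * e) == 0) {
    # interaction term is constant (e.g. e identically 0): drop it, flag it
    mf <- fit_marginal(y, g, e, covariates)
    return(structure(list(
      alpha = mf$alpha, beta_g_main = mf$beta_g_marginal, beta_e = mf$beta_e,
      beta_gxe = NA_real_, beta_c = mf$beta_c,
      se_g = mf$se_g, se_gxe = NA_real_,
      p_main = mf$p_main, p_interaction = NA_real_,
      converged = mf$converged, interaction_estimable = FALSE
    ), class = "interaction_fit"))
  }
  dat <- data.frame(y = y, g = g, e = e)
  form <- y ~ g + e + g:e
  if (!is.null(covariates)) {
    cn <- paste0("c", seq_len(ncol(covariates)))
    dat[cn] <- covariates
    form <- stats::reformulate(c("g", "e", "g:e", cn), response = "y")
  }
  gf <- .glm_fit_quiet(form, dat)
  wg <- .wald(gf$fit, "g"); wi <- .wald(gf$fit, "g:e")
  bad <- gf$suspect || anyNA(coef(gf$fit))
  structure(list(
    alpha = unname(coef(gf$fit)["(Intercept)"]),
    beta_g_main = if (bad) NA_real_ else unname(wg[1]),
    beta_e = unname(coef(gf$fit)["e"]),
    beta_gxe = if (bad) NA_real_ else unname(wi[1]),
    beta_c = if (is.null(covariates)) numeric(0) else
      unname(coef(gf$fit)[paste0("c", seq_len(ncol(covariates)))]),
    se_g = if (bad) NA_real_ else unname(wg[2]),
    se_gxe = if (bad) NA_real_ else unname(wi[2]),
    p_main = if (bad) NA_real_ else unname(wg[3]),
    p_interaction = if (bad) NA_real_ else unname(wi[3]),
    converged = !bad, interaction_estimable = TRUE
  ), class = "interaction_fit")
}

#' Read a phenotype/exposure/covariate table
#'
#' Whitespace- or tab-separated file with a header line and columns
#' `FID`, `IID`, `outcome`, `exposure`, then any covariate columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_phenotype <- function(path) {
  ph <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("FID", "IID", "outcome", "exposure")
  if (!all(need %in% names(ph)))
    stop_iprs("phenotype file must have columns %s", paste(need, collapse = ", "))
  if (!all(ph$outcome %in% c(0, 1)))
    stop_iprs("phenotype outcome must be coded 0/1")
  ph
}

#' Align a phenotype table to a genotype dataset
#'
#' Matches on (FID, IID); any sample present in only one of the two inputs
#' is an error listing the offending ids.
#'
#' @param ds a `"genotypes"` object.
#' @param pheno data.frame as returned by [read_phenotype()].
#' @return list with `y`, `e` and covariate matrix `covariates` (or NULL),
#'   ordered as the genotype samples.
#' @export
align_phenotype <- function(ds, pheno) {
  gid <- paste(ds$samples$fid, ds$samples$iid, sep = "_")
  pid <- paste(pheno$FID, pheno$IID, sep = "_")
  only_g <- setdiff(gid, pid); only_p <- setdiff(pid, gid)
  if (length(only_g) || length(only_p))
    stop_iprs("sample id mismatch between genotypes and phenotypes; genotype-only: [%s]; phenotype-only: [%s]",
              paste(head(only_g, 10), collapse = ", "),
              paste(head(only_p, 10), collapse = ", "))
  idx <- match(gid, pid)
  covs <- setdiff(names(pheno), c("FID", "IID", "outcome", "exposure"))
  list(y = pheno$outcome[idx], e = pheno$exposure[idx],
       covariates = if (length(covs)) as.matrix(pheno[idx, covs, drop = FALSE]) else NULL)
}

#' Per-variant association scan
#'
#' Fits the chosen model to every variant. Missing dosages are mean-imputed
#' per variant before fitting. When the exposure is binary 0/1, dosages are
#' complete integer counts and there are no covariates, an exact
#' sufficient-statistic Newton solver is used (identical likelihood and Wald
#' statistics to `glm`, validated in the test suite); otherwise each variant
#' is fitted with [stats::glm()].
#'
#' @param ds a `"genotypes"` object (post-QC).
#' @param y binary outcome vector aligned to samples.
#' @param e exposure vector aligned to samples.
#' @param covariates optional covariate matrix.
#' @param model `"interaction"` (default) or `"marginal"`.
#' @return A data.frame of class `"iprs_scan"` with one row per variant:
#'   `variant_id`, `chrom`, `pos`, `risk_allele`, `alpha`, `beta_main`,
#'   `se_main`, `p_main`, `beta_e`, `beta_gxe`, `se_gxe`, `p_gxe`,
#'   `converged`.
#' @export
genome_scan <- function(ds, y, e, covariates = NULL,
                        model = c("interaction", "marginal")) {
  model <- match.arg(model)
  stopifnot(inherits(ds, "genotypes"))
  if (length(y) != n_samples(ds) || length(e) != n_samples(ds))
    stop_iprs("y and e must match the %d genotype samples", n_samples(ds))
  if (!all(y %in% c(0, 1))) stop_iprs("outcome y must be coded 0/1")

  fast_ok <- is.null(covariates) && all(e %in% c(0, 1)) && var(e) > 0 &&
    !anyNA(ds$dosages)
  if (fast_ok) {
    res <- fast_scan(ds$dosages, y, e, model = model)
  } else {
    dos <- impute_mean(ds$dosages)
    res <- do.call(rbind, lapply(seq_len(ncol(dos)), function(j) {
      g <- dos[, j]
      if (var(g) == 0) {
        return(data.frame(alpha = NA_real_, beta_main = NA_real_,
                          se_main = NA_real_, p_main = NA_real_,
                          beta_e = NA_real_, beta_gxe = NA_real_,
                          se_gxe = NA_real_, p_gxe = NA_real_,
                          converged = FALSE))
      }
      if (model == "marginal") {
        f <- fit_marginal(y, g, e, covariates)
        data.frame(alpha = f$alpha, beta_main = f$beta_g_marginal,
                   se_main = f$se_g, p_main = f$p_main, beta_e = f$beta_e,
                   beta_gxe = NA_real_, se_gxe = NA_real_, p_gxe = NA_real_,
                   converged = f$converged)
      } else {
        f <- fit_interaction(y, g, e, covariates)
        data.frame(alpha = f$alpha, beta_main = f$beta_g_main,
                   se_main = f$se_g, p_main = f$p_main, beta_e = f$beta_e,
                   beta_gxe = f$beta_gxe, se_gxe = f$se_gxe,
                   p_gxe = f$p_interaction, converged = f$converged)
      }
    }))
  }
  out <- cbind(data.frame(variant_id = ds$variants$id,
                          chrom = ds$variants$chrom,
                          pos = ds$variants$pos,
                          risk_allele = ds$variants$allele1,
                          stringsAsFactors = FALSE),
               res)
  rownames(out) <- NULL
  class(out) <- c("iprs_scan", "data.frame")
  attr(out, "model") <- model
  out
}

#' Select variants from scan results
#'
#' Under `main_or_interaction` (the default, mirroring a fixed genome-wide
#' threshold applied to either the main effect or the interaction), a variant
#' is kept iff `min(p_main, p_gxe) < p_threshold`; under `main_only`, iff
#' `p_main < p_threshold`. Non-converged rows are never selected.
#'
#' @param stats an `"iprs_scan"` data.frame.
#' @param p_threshold selection threshold (default 5e-6).
#' @param rule `"main_or_interaction"` or `"main_only"`.
#' @return Character vector of selected variant ids.
#' @export
select_variants <- function(stats, p_threshold = 5e-6,
                            rule = c("main_or_interaction", "main_only")) {
  rule <- match.arg(rule)
  if (nrow(stats) == 0) stop_iprs("empty scan table")
  pm <- stats$p_main
  pi_ <- if ("p_gxe" %in% names(stats)) stats$p_gxe else rep(NA_real_, nrow(stats))
  crit <- if (rule == "main_only") pm else pmin(pm, pi_, na.rm = TRUE)
  crit[is.na(pm) & is.na(pi_)] <- NA_real_
  if (rule == "main_only") crit[is.na(pm)] <- NA_real_
  keep <- !is.na(crit) & crit < p_threshold & stats$converged
  sort(stats$variant_id[keep])
}

#' Write a scan table to a tab-separated file
#'
#' @param stats an `"iprs_scan"` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan <- function(stats, path) {
  cols <- c("variant_id", "chrom", "pos", "risk_allele", "beta_main",
            "se_main", "p_main", "beta_gxe", "se_gxe", "p_gxe", "converged")
  write.table(stats[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
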