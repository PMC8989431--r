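# Score construction: traditional PRS and interaction-aware iPRS.

#' Construct a weight set
#'
#' Per-variant scoring weights: the counted (risk) allele, the main-effect
#' weight `beta_main` and the interaction weight `beta_gxe`. A traditional
#' PRS is represented by an all-zero `beta_gxe` column.
#'
#' @param variant_id character vector, unique.
#' @param risk_allele counted allele per variant.
#' @param beta_main main-effect weights.
#' @param beta_gxe interaction weights (default all zero).
#' @param other_allele optional non-counted allele.
#' @param exposure_name name of the exposure the interaction refers to.
#' @return data.frame of class `"weight_set"`.
#' @export
weight_set <- function(variant_id, risk_allele, beta_main,
                       beta_gxe = rep(0, length(variant_id)),
                       other_allele = rep(NA_character_, length(variant_id)),
                       exposure_name = "E") {
  variant_id <- as.character(variant_id)
  if (anyDuplicated(variant_id)) stop_iprs("weight_set: duplicated variant ids")
  if (length(variant_id) == 0) stop_iprs("weight_set: empty weight set")
  stopifnot(length(risk_allele) == length(variant_id),
            length(beta_main) == length(variant_id),
            length(beta_gxe) == length(variant_id))
  if (anyNA(beta_main) || anyNA(beta_gxe))
    stop_iprs("weight_set: weights must be finite (drop non-converged variants first)")
  structure(data.frame(variant_id = variant_id,
                       risk_allele = as.character(risk_allele),
                       other_allele = as.character(other_allele),
                       beta_main = as.numeric(beta_main),
                       beta_gxe = as.numeric(beta_gxe),
                       exposure_name = exposure_name,
                       stringsAsFactors = FALSE),
            class = c("weight_set", "data.frame"))
}

#' Extract scoring weights from a scan table
#'
#' @param stats an `"iprs_scan"` data.frame.
#' @param ids variant ids to keep (default: all converged rows).
#' @param kind `"iprs"` takes both main and interaction weights from an
#'   interaction scan; `"prs"` takes main weights only (interaction weights
#'   set to zero).
#' @return A `"weight_set"`.
#' @export
weights_from_scan <- function(stats, ids = NULL, kind = c("iprs", "prs")) {
  kind <- match.arg(kind)
  rows <- stats[stats$converged & !is.na(stats$beta_main), , drop = FALSE]
  if (!is.null(ids)) rows <- rows[rows$variant_id %in% ids, , drop = FALSE]
  if (nrow(rows) == 0) stop_iprs("no usable variants for weight extraction")
  bI <- if (kind == "iprs" && "beta_gxe" %in% names(rows)) {
    ifelse(is.na(rows$beta_gxe), 0, rows$beta_gxe)
  } else rep(0, nrow(rows))
  weight_set(rows$variant_id, rows$risk_allele, rows$beta_main, bI)
}

#' Flip weights and genotypes to the risk-allele convention
#'
#' For every variant whose main-effect weight is negative, the counted
#' allele is swapped, dosages are replaced by `2 - g`, and both weights are
#' negated, so that after flipping every main weight is non-negative. A main
#' weight of exactly zero is treated as already risk-oriented.
#'
#' @param weights a `"weight_set"`.
#' @param ds a `"genotypes"` object containing every weight variant.
#' @return list with flipped `weights` and `dataset`.
#' @export
flip_to_risk <- function(weights, ds) {
  stopifnot(inherits(weights, "weight_set"), inherits(ds, "genotypes"))
  idx <- match(weights$variant_id, ds$variants$id)
  if (anyNA(idx))
    stop_iprs("weights reference variants absent from the dataset: %s",
              paste(weights$variant_id[is.na(idx)], collapse = ", "))
  flip <- weights$beta_main < 0
  w <- weights
  w$beta_main[flip] <- -w$beta_main[flip]
  w$beta_gxe[flip] <- -w$beta_gxe[flip]
  a1 <- w$risk_allele[flip]
  w$risk_allele[flip] <- w$other_allele[flip]
  w$other_allele[flip] <- a1
  dos <- ds$dosages
  v <- ds$variants
  jf <- idx[flip]
  if (length(jf)) {
    dos[, jf] <- 2L - dos[, jf]
    tmp <- v$allele1[jf]
    v$allele1[jf] <- v$allele2[jf]
    v$allele2[jf] <- tmp
    # keep weight-set allele labels in sync with the dataset
    w$risk_allele[flip] <- v$allele1[jf]
    w$other_allele[flip] <- v$allele2[jf]
  }
  list(weights = w, dataset = genotype_dataset(dos, v, ds$samples))
}

.aligned_dosages <- function(ds, weights) {
  idx <- match(weights$variant_id, ds$variants$id)
  if (anyNA(idx))
    stop_iprs("weights reference variants absent from the dataset: %s",
              paste(weights$variant_id[is.na(idx)], collapse = ", "))
  impute_mean(ds$dosages[, idx, drop = FALSE])
}

#' Compute a traditional polygenic risk score
#'
#' `score_i = sum_j beta_main(j) * g_ij`, with per-variant mean imputation of
#' missing dosages.
#'
#' @param ds a `"genotypes"` object.
#' @param weights a `"weight_set"` (normally risk-allele flipped).
#' @param standardize z-standardize the returned scores (default FALSE).
#' @return Named numeric vector of scores (names are `FID_IID`).
#' @export
compute_prs <- function(ds, weights, standardize = FALSE) {
  dos <- .aligned_dosages(ds, weights)
  s <- drop(dos %*% weights$beta_main)
  if (standardize) s <- (s - mean(s)) / sd(s)
  setNames(s, sample_keys(ds))
}

#' Compute an interaction polygenic risk score
#'
#' `score_i = sum_j beta_main(j) * g_ij + sum_j beta_gxe(j) * g_ij * e_i`.
#'
#' @inheritParams compute_prs
#' @param e exposure vector aligned to the dataset samples (no missing).
#' @return Named numeric vector of scores.
#' @export
compute_iprs <- function(ds, e, weights, standardize = FALSE) {
  if (length(e) != n_samples(ds))
    stop_iprs("exposure has length %d, expected %d", length(e), n_samples(ds))
  if (anyNA(e)) stop_iprs("exposure missing for %d scored sample(s)", sum(is.na(e)))
  dos <- .aligned_dosages(ds, weights)
  s <- drop(dos %*% weights$beta_main) + drop(dos %*% weights$beta_gxe) * e
  if (standardize) s <- (s - mean(s)) / sd(s)
  setNames(s, sample_keys(ds))
}

#' Read / write weight files
#'
#' Tab-separated with header: `variant_id`, `risk_allele`, `other_allele`,
#' `beta_main`, `beta_gxe`, `exposure_name`.
#'
#' @param path file path.
#' @return A `"weight_set"` (for `read_weights`).
#' @export
read_weights <- function(path) {
  w <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  weight_set(w$variant_id, w$risk_allele, w$beta_main, w$beta_gxe,
             other_allele = w$other_allele,
             exposure_name = w$exposure_name[1] %||% "E")
}

#' @rdname read_weights
#' @param weights a `"weight_set"`.
#' @export
write_weights <- function(weights, path) {
  write.table(weights, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scores to a file
#'
#' Columns `FID`, `IID`, `score`.
#'
#' @param scores named score vector as returned by [compute_prs()].
#' @param ds the `"genotypes"` object the scores were computed on.
#' @param path output path.
#' @export
write_scores <- function(scores, ds, path) {
  out <- data.frame(FID = ds$samples$fid, IID = ds$samples$iid,
                    score = as.numeric(scores))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
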