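# Quality control: sample call-rate screen first, then per-variant filters.

#' Apply genotype quality control
#'
#' Samples below the call-rate threshold are removed first; the remaining
#' variants are then tested, in order, for minor allele frequency, exact
#' Hardy-Weinberg equilibrium, missingness, and duplication (same identifier,
#' or same chromosome, position and allele pair). Each removed variant is
#' tallied under the first rule it fails. LD-based "related SNP" pruning is
#' deliberately not implemented.
#'
#' @param ds a `"genotypes"` object.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param variant_missing_max maximum variant missingness (default 0.05).
#' @param sample_call_rate_min minimum sample call rate (default 0.95).
#' @param drop_duplicates remove duplicated variants (default TRUE).
#' @return A list with elements `dataset` (filtered `"genotypes"`) and
#'   `report` (a `"qc_report"`).
#' @export
qc_filter <- function(ds, maf_min = 0.01, hwe_p_min = 1e-6,
                      variant_missing_max = 0.05,
                      sample_call_rate_min = 0.95,
                      drop_duplicates = TRUE) {
  stopifnot(inherits(ds, "genotypes"))
  if (n_variants(ds) == 0 || n_samples(ds) == 0)
    stop_iprs("qc_filter: empty dataset")
  n_in <- n_variants(ds)

  call_rate <- rowMeans(!is.na(ds$dosages))
  keep_s <- call_rate >= sample_call_rate_min
  n_samples_removed <- sum(!keep_s)
  ds <- subset_samples(ds, keep_s)
  if (n_samples(ds) == 0) stop_iprs("qc_filter: all samples removed by call-rate filter")

  dos <- ds$dosages
  n_nonmiss <- colSums(!is.na(dos))
  miss_frac <- 1 - n_nonmiss / nrow(dos)
  p1 <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p1, 1 - p1)
  maf[n_nonmiss == 0] <- 0
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- dos[, j]
    nAA <- sum(g == 2L, na.rm = TRUE)
    nAa <- sum(g == 1L, na.rm = TRUE)
    naa <- sum(g == 0L, na.rm = TRUE)
    if (nAA + nAa + naa == 0) return(1)
    hwe_exact_test(nAA, nAa, naa)
  }, numeric(1))

  v <- ds$variants
  dup <- if (drop_duplicates) {
    key_pos <- paste(v$chrom, v$pos,
                     pmin(v$allele1, v$allele2), pmax(v$allele1, v$allele2))
    duplicated(v$id) | duplicated(key_pos)
  } else rep(FALSE, nrow(v))

  fail_maf <- maf < maf_min
  fail_hwe <- hwe_p < hwe_p_min
  fail_mis <- miss_frac > variant_missing_max
  # attribute each removal to the first failing rule, in MAF -> HWE ->
  # missingness -> duplicate order
  why <- rep("keep", nrow(v))
  why[fail_maf] <- "maf"
  why[fail_hwe & why == "keep"] <- "hwe"
  why[fail_mis & why == "keep"] <- "missingness"
  why[dup & why == "keep"] <- "duplicate"
  keep_v <- why == "keep"

  out <- subset_variants(ds, keep_v)
  report <- structure(list(
    n_variants_in = n_in,
    n_removed_maf = sum(why == "maf"),
    n_removed_hwe = sum(why == "hwe"),
    n_removed_missingness = sum(why == "missingness"),
    n_removed_duplicate = sum(why == "duplicate"),
    n_samples_removed_call_rate = n_samples_removed,
    n_variants_out = sum(keep_v),
    n_samples_out = n_samples(out)
  ), class = "qc_report")
  if (report$n_variants_out == 0)
    warning("qc_filter: all variants removed", call. = FALSE)
  list(dataset = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d variants in, %d out; %d samples retained\n",
              x$n_variants_in, x$n_variants_out, x$n_samples_out))
  cat(sprintf("  removed by MAF filter:        %d\n", x$n_removed_maf))
  cat(sprintf("  removed by HWE filter:        %d\n", x$n_removed_hwe))
  cat(sprintf("  removed by missingness:       %d\n", x$n_removed_missingness))
  cat(sprintf("  removed as duplicates:        %d\n", x$n_removed_duplicate))
  cat(sprintf("  samples removed (call rate):  %d\n", x$n_samples_removed_call_rate))
  invisible(x)
}

#' Serialize a QC report to JSON
#'
#' @param report a `"qc_report"`.
#' @param path optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
qc_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "qc_report"))
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
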