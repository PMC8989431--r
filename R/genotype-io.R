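# PLINK 1 binary genotype IO and the genotype container.
#
# The .bed codec is written out by hand: two magic bytes 0x6C 0x1B, a mode
# byte 0x01 (SNP-major), then ceil(n/4) bytes per variant, two bits per
# sample starting at the least-significant pair. Bit codes (for the counted
# allele = .bim column 5, "allele1"):
#   00 -> homozygous allele1 (dosage 2)
#   01 -> missing             (dosage NA)
#   10 -> heterozygous        (dosage 1)
#   11 -> homozygous allele2  (dosage 0)

#' Construct a genotype dataset
#'
#' The container used throughout the package: a samples x variants dosage
#' matrix of counted-allele copies (0, 1, 2 or `NA` for missing) plus variant
#' and sample metadata in `.bim`/`.fam` column order.
#'
#' @param dosages integer matrix, `n_samples` x `n_variants`; entries in
#'   `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `id`, `chrom`, `pos` (1-based),
#'   `allele1` (the counted allele), `allele2`.
#' @param samples data.frame with columns `fid`, `iid`, `sex`, `phenotype`.
#' @return An object of class `"genotypes"`.
#' @export
genotype_dataset <- function(dosages, variants, samples) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (!is.integer(dosages)) storage.mode(dosages) <- "integer"
  need_v <- c("id", "chrom", "pos", "allele1", "allele2")
  need_s <- c("fid", "iid", "sex", "phenotype")
  if (!all(need_v %in% names(variants)))
    stop_iprs("variants must have columns: %s", paste(need_v, collapse = ", "))
  if (!all(need_s %in% names(samples)))
    stop_iprs("samples must have columns: %s", paste(need_s, collapse = ", "))
  if (nrow(samples) != nrow(dosages) || nrow(variants) != ncol(dosages))
    stop_iprs("dosage matrix is %d x %d but there are %d samples and %d variants",
              nrow(dosages), ncol(dosages), nrow(samples), nrow(variants))
  if (length(dosages)) {
    rng <- suppressWarnings(range(dosages, na.rm = TRUE))  # integer: range check suffices
    if (is.finite(rng[1]) && (rng[1] < 0L || rng[2] > 2L))
      stop_iprs("non-missing dosages must be 0, 1 or 2")
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants$id <- as.character(variants$id)
  rownames(variants) <- NULL
  rownames(samples) <- NULL
  .new_genotypes(dosages, variants, samples)
}

# Internal constructor without validation, for trusted paths that subset or
# rebuild an already-validated object (skips another pass over what may be a
# very large matrix). Dosage dimnames are deliberately never set: assigning
# dimnames would copy the matrix; ids live in the metadata tables.
.new_genotypes <- function(dosages, variants, samples) {
  structure(list(dosages = dosages, variants = variants, samples = samples),
            class = "genotypes")
}

#' @export
print.genotypes <- function(x, ...) {
  n_mis <- sum(is.na(x$dosages))
  cat(sprintf("Genotype dataset: %d samples x %d variants (%d missing calls, %.2f%%)\n",
              nrow(x$dosages), ncol(x$dosages), n_mis,
              100 * n_mis / max(1, length(x$dosages))))
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosages)

n_samples <- function(ds) nrow(ds$dosages)
n_variants <- function(ds) ncol(ds$dosages)

# dosage value for each 2-bit code 0..3 (counted allele = allele1)
.bed_code_to_dosage <- c(2L, NA_integer_, 1L, 0L)
.bed_dosage_to_code <- function(d) {
  code <- integer(length(d))
  code[is.na(d)] <- 1L
  code[!is.na(d) & d == 2L] <- 0L
  code[!is.na(d) & d == 1L] <- 2L
  code[!is.na(d) & d == 0L] <- 3L
  code
}

# 256 x 4 lookup: byte value -> four dosages (LSB pair first)
.bed_lookup <- local({
  b <- 0:255
  m <- cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  matrix(.bed_code_to_dosage[m + 1L], nrow = 256L)
})

#' Read a PLINK 1 binary fileset
#'
#' Reads `prefix.bed` / `prefix.bim` / `prefix.fam` into a
#' [genotype_dataset()]. Only the SNP-major bed layout (mode byte `0x01`) is
#' accepted. Dosages count copies of bim allele1.
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A `"genotypes"` object.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  for (p in paths) if (!file.exists(p)) stop_iprs("file not found: %s", p)
  bim <- read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "id", "cm", "pos", "allele1", "allele2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "phenotype"))
  n <- nrow(fam); m <- nrow(bim)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop_iprs("%s: bad magic bytes, not a PLINK 1 .bed file", paths[1])
  if (raw[3] == as.raw(0x00))
    stop_iprs("%s: individual-major .bed layout is not supported", paths[1])
  if (raw[3] != as.raw(0x01))
    stop_iprs("%s: unknown .bed mode byte 0x%02x", paths[1], as.integer(raw[3]))
  bpv <- ceiling(n / 4)
  if (length(raw) - 3L != bpv * m)
    stop_iprs(".bed payload is %d bytes but .bim/.fam imply %d (%d variants x %d bytes)",
              length(raw) - 3L, bpv * m, m, bpv)
  bytes <- as.integer(raw[-(1:3)])
  # each byte expands to 4 dosages; columns are variants
  dos <- matrix(t(.bed_lookup[bytes + 1L, , drop = FALSE]), nrow = 4L * bpv)
  dos <- dos[seq_len(n), , drop = FALSE]
  genotype_dataset(dos,
                   variants = bim[, c("id", "chrom", "pos", "allele1", "allele2")],
                   samples = fam[, c("fid", "iid", "sex", "phenotype")])
}

#' Write a PLINK 1 binary fileset
#'
#' Inverse of [read_plink()]: writes SNP-major `.bed` plus `.bim`/`.fam`.
#'
#' @param ds a `"genotypes"` object.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(ds, prefix) {
  stopifnot(inherits(ds, "genotypes"))
  n <- n_samples(ds); m <- n_variants(ds)
  bpv <- ceiling(n / 4)
  codes <- matrix(1L, nrow = 4L * bpv, ncol = m)  # pad with "missing" bits
  codes[seq_len(n), ] <- matrix(.bed_dosage_to_code(as.vector(ds$dosages)),
                                nrow = n)
  bytes <- codes[c(TRUE, FALSE, FALSE, FALSE), , drop = FALSE] +
    4L * codes[c(FALSE, TRUE, FALSE, FALSE), , drop = FALSE] +
    16L * codes[c(FALSE, FALSE, TRUE, FALSE), , drop = FALSE] +
    64L * codes[c(FALSE, FALSE, FALSE, TRUE), , drop = FALSE]
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  v <- ds$variants
  bim <- data.frame(v$chrom, v$id, 0, v$pos, v$allele1, v$allele2)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  s <- ds$samples
  fam <- data.frame(s$fid, s$iid, 0, 0, s$sex, s$phenotype)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

# Counted-allele frequency per variant, on non-missing calls.
allele1_freq <- function(ds) {
  colMeans(ds$dosages, na.rm = TRUE) / 2
}

# Per-variant mean imputation of missing dosages; returns a numeric matrix.
impute_mean <- function(dosages) {
  dos <- dosages
  storage.mode(dos) <- "double"
  mis <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(mis)) {
    mu <- colMeans(dos, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    dos[mis] <- mu[mis[, 2]]
  }
  dos
}

# Subset helpers keeping metadata aligned.
subset_samples <- function(ds, idx) {
  s <- ds$samples[idx, , drop = FALSE]; rownames(s) <- NULL
  .new_genotypes(ds$dosages[idx, , drop = FALSE], ds$variants, s)
}

subset_variants <- function(ds, idx) {
  v <- ds$variants[idx, , drop = FALSE]; rownames(v) <- NULL
  .new_genotypes(ds$dosages[, idx, drop = FALSE], v, ds$samples)
}

# FID_IID keys for score/prediction vectors.
sample_keys <- function(ds) paste(ds$samples$fid, ds$samples$iid, sep = "_")
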