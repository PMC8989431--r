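test_that("PLINK round-trip preserves dosages, metadata and missingness", {
  ds <- rand_ds(17, 5, seed = 3, miss_rate = 0.1)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink(ds, prefix)
  back <- read_plink(prefix)
  expect_identical(unname(back$dosages), unname(ds$dosages))
  expect_identical(back$variants$id, ds$variants$id)
  expect_identical(back$variants$allele1, ds$variants$allele1)
  expect_identical(back$samples$iid, ds$samples$iid)
  # second round trip is byte-identical
  prefix2 <- file.path(withr::local_tempdir(), "rt2")
  write_plink(back, prefix2)
  expect_identical(readBin(paste0(prefix, ".bed"), "raw", 1e4),
                   readBin(paste0(prefix2, ".bed"), "raw", 1e4))
})

test_that("bed decoding matches hand-packed bytes, including a missing call", {
  # 3 samples x 2 variants; 2-bit codes packed LSB-first by hand:
  # variant 1: sample1 = 2 copies of allele1 (00), sample2 = het (10),
  #            sample3 = missing (01) -> byte 0b00011000 = 0x18
  # variant 2: sample1 = hom allele2 (11), sample2 = hom allele1 (00),
  #            sample3 = het (10) -> byte 0b00100011 = 0x23
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "hand")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x18, 0x23)), paste0(prefix, ".bed"))
  writeLines(c("1\tsnpA\t0\t100\tA\tB", "1\tsnpB\t0\t200\tC\tG"),
             paste0(prefix, ".bim"))
  writeLines(c("f1\ti1\t0\t0\t1\t-9", "f2\ti2\t0\t0\t2\t-9",
               "f3\ti3\t0\t0\t1\t-9"), paste0(prefix, ".fam"))
  ds <- read_plink(prefix)
  expect_identical(unname(ds$dosages),
                   matrix(c(2L, 1L, NA, 0L, 2L, 1L), nrow = 3))
  expect_identical(sum(is.na(ds$dosages)), 1L)
  expect_true(is.na(ds$dosages[3, 1]))
})

test_that("malformed bed inputs are rejected with specific errors", {
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "bad")
  writeLines("1\tsnpA\t0\t100\tA\tB", paste0(prefix, ".bim"))
  writeLines("f1\ti1\t0\t0\t1\t-9", paste0(prefix, ".fam"))
  expect_error(read_plink(prefix), "bad\\.bed")   # missing file named
  writeBin(as.raw(c(0x6c, 0x1b, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "individual-major")
  writeBin(as.raw(c(0xde, 0xad, 0x01, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "magic")
  writeBin(as.raw(c(0x6c, 0x1b, 0x01, 0x00, 0x00)), paste0(prefix, ".bed"))
  expect_error(read_plink(prefix), "imply")      # payload size inconsistent
})

test_that("HWE exact test matches the enumeration oracle and edge cases", {
  expect_identical(hwe_exact_test(100, 0, 0), 1)
  expect_lt(hwe_exact_test(50, 0, 50), 1e-6)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), ">= 0")
  # brute-force agreement on a sweep of small tables (totals <= 50)
  for (n_tot in c(5, 11, 20, 37, 50)) {
    for (nAA in seq(0, n_tot, by = max(1, n_tot %/% 5))) {
      for (nAa in seq(0, n_tot - nAA, by = max(1, (n_tot - nAA) %/% 4 + 1))) {
        naa <- n_tot - nAA - nAa
        expect_equal(hwe_exact_test(nAA, nAa, naa), hwe_oracle(nAA, nAa, naa),
                     tolerance = 1e-12,
                     label = sprintf("table (%d,%d,%d)", nAA, nAa, naa))
      }
    }
  }
  # the (25, 50, 25) example against the oracle
  expect_equal(hwe_exact_test(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
})

test_that("qc_filter removes one variant per failed rule and tallies them", {
  n <- 200
  withr::with_seed(42, {
    v_maf <- c(rep(0L, n - 1), 1L)                     # MAF = 1/400 < 0.01
    v_hwe <- rep(c(0L, 2L), each = n / 2)              # no hets: HWE p tiny
    v_mis <- rbinom(n, 2L, 0.4); v_mis[1:20] <- NA     # 10% missing
    v_ok <- rbinom(n, 2L, 0.4)
    filler <- matrix(rbinom(n * 17, 2L, 0.4), nrow = n)  # keeps sample call
  })                                                     # rates above 95%
  G <- cbind(v_maf, v_hwe, v_mis, v_ok, filler)
  ds <- ds_from_matrix(G)
  res <- qc_filter(ds)
  expect_identical(res$report$n_samples_removed_call_rate, 0L)
  expect_identical(res$report$n_removed_maf, 1L)
  expect_identical(res$report$n_removed_hwe, 1L)
  expect_identical(res$report$n_removed_missingness, 1L)
  expect_identical(res$report$n_removed_duplicate, 0L)
  expect_false(any(c("v1", "v2", "v3") %in% res$dataset$variants$id))
  expect_true("v4" %in% res$dataset$variants$id)
  expect_identical(res$report$n_variants_out, 18L)
})

test_that("qc_filter is the identity on clean data and idempotent otherwise", {
  clean <- rand_ds(100, 6, seed = 9, maf_low = 0.2, maf_high = 0.5)
  res <- qc_filter(clean)
  expect_identical(res$dataset$dosages, clean$dosages)
  expect_identical(res$report$n_variants_out, 6L)
  expect_identical(res$report$n_removed_maf + res$report$n_removed_hwe +
                     res$report$n_removed_missingness +
                     res$report$n_removed_duplicate, 0L)

  messy <- rand_ds(120, 12, seed = 10, miss_rate = 0.03, maf_low = 0.005,
                   maf_high = 0.5)
  once <- qc_filter(messy)
  twice <- qc_filter(once$dataset)
  expect_identical(twice$dataset$dosages, once$dataset$dosages)
  expect_identical(twice$report$n_variants_out, once$report$n_variants_out)
  expect_identical(twice$report$n_samples_removed_call_rate, 0L)
})

test_that("duplicated variants are dropped (by id or by position+alleles)", {
  base <- rand_ds(80, 3, seed = 5, maf_low = 0.3)
  v <- base$variants
  v$id[2] <- v$id[1]                       # duplicate id
  ds <- genotype_dataset(base$dosages, v, base$samples)
  res <- qc_filter(ds)
  expect_identical(res$report$n_removed_duplicate, 1L)
  expect_identical(nrow(res$dataset$variants), 2L)

  v2 <- base$variants
  v2$pos[3] <- v2$pos[1]                   # same chrom/pos/alleles, new id
  ds2 <- genotype_dataset(base$dosages, v2, base$samples)
  res2 <- qc_filter(ds2)
  expect_identical(res2$report$n_removed_duplicate, 1L)
})

test_that("low call-rate samples are removed before variant filters", {
  ds <- rand_ds(60, 20, seed = 11, maf_low = 0.3)
  G <- ds$dosages
  G[1, 1:3] <- NA   # sample 1: 15% missing
  ds <- genotype_dataset(G, ds$variants, ds$samples)
  res <- qc_filter(ds)
  expect_identical(res$report$n_samples_removed_call_rate, 1L)
  expect_identical(res$report$n_samples_out, 59L)
  # with the bad sample gone, no variant exceeds the missingness cap
  expect_identical(res$report$n_removed_missingness, 0L)
})

test_that("QC report serializes to JSON", {
  res <- qc_filter(rand_ds(50, 4, seed = 2, maf_low = 0.2))
  path <- withr::local_tempfile(fileext = ".json")
  qc_report_json(res$report, path)
  parsed <- jsonlite::fromJSON(path)
  expect_identical(parsed$n_variants_in, 4L)
  expect_identical(parsed$n_variants_out, res$report$n_variants_out)
})
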