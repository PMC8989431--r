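# Shared fixture builders: everything is generated in code at test time.

toy_variants <- function(m, prefix = "v") {
  data.frame(id = paste0(prefix, seq_len(m)), chrom = 1L,
             pos = seq_len(m) * 100L, allele1 = "A", allele2 = "B",
             stringsAsFactors = FALSE)
}

toy_samples <- function(n) {
  data.frame(fid = paste0("F", seq_len(n)), iid = paste0("I", seq_len(n)),
             sex = 0L, phenotype = -9L, stringsAsFactors = FALSE)
}

# Random genotype dataset with optional missingness.
rand_ds <- function(n, m, seed = 1, miss_rate = 0, maf_low = 0.1,
                    maf_high = 0.5) {
  withr::with_seed(seed, {
    maf <- runif(m, maf_low, maf_high)
    G <- matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n)
    if (miss_rate > 0) G[runif(n * m) < miss_rate] <- NA_integer_
    genotype_dataset(G, toy_variants(m), toy_samples(n))
  })
}

# Dataset built from an explicit dosage matrix.
ds_from_matrix <- function(G) {
  genotype_dataset(G, toy_variants(ncol(G)), toy_samples(nrow(G)))
}

# Independent brute-force HWE oracle: conditional probabilities from the
# ratio recurrence P(h+2)/P(h) = 4 nAA nBB / ((h+2)(h+1)), normalized.
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hs <- seq.int(rare %% 2, rare, by = 2)
  pr <- numeric(length(hs))
  pr[1] <- 1
  if (length(hs) > 1) {
    for (i in seq_len(length(hs) - 1)) {
      h <- hs[i]
      hom1 <- (nA - h) / 2
      hom2 <- (2 * n - nA - h) / 2
      pr[i + 1] <- pr[i] * 4 * hom1 * hom2 / ((h + 2) * (h + 1))
    }
  }
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-9)]))
}

# Pair-enumeration AUC oracle.
auc_oracle <- function(y, p) {
  cases <- p[y == 1]; ctrls <- p[y == 0]
  tot <- 0
  for (a in cases) for (b in ctrls)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cases) * length(ctrls))
}
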