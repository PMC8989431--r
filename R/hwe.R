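#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test on the heterozygote count: given the observed
#' allele counts, every possible number of heterozygotes (same parity as the
#' minor-allele count) is assigned its conditional probability
#' \deqn{P(h \mid n, n_A) = \frac{n!\, 2^h}{n_{AA}!\, h!\, n_{aa}!}
#'   \Big/ \binom{2n}{n_A}}
#' and the p-value is the summed probability of all outcomes no more likely
#' than the observed one (no mid-p correction).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (hom, het, hom).
#' @return p-value in `[0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(length(n_AA) == 1, length(n_Aa) == 1, length(n_aa) == 1)
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop_iprs("genotype counts must be >= 0")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop_iprs("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa            # counted-allele copies
  rare <- min(nA, 2 * n - nA)      # minor-allele copies
  if (rare == 0) return(1)         # monomorphic: single possible table
  hs <- seq.int(rare %% 2, rare, by = 2)   # feasible het counts
  # log conditional probability for each h
  lp <- lgamma(n + 1) + hs * log(2) -
    lgamma((nA - hs) / 2 + 1) - lgamma(hs + 1) - lgamma((2 * n - nA - hs) / 2 + 1) -
    (lgamma(2 * n + 1) - lgamma(nA + 1) - lgamma(2 * n - nA + 1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[match(n_Aa, hs)]
  if (is.na(obs)) stop_iprs("heterozygote count %d impossible given allele counts", n_Aa)
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}
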