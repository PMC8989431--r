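# Phenotype simulators: the sparse 10-SNP case-control design with quota
# sampling, and the polygenic design with synthetic independent genotypes.
#
# Genotypes are binomial allele counts, g ~ Binomial(2, MAF) with MAF drawn
# uniformly per variant; the exposure is Bernoulli(0.5); phenotypes follow
# logit P(y=1) = alpha + sum_j bM_j g_j + sum_j bI_j g_j e + bE e.

#' Configuration for the sparse simulation design
#'
#' Defaults encode the canonical study conditions: 10 independent SNPs with
#' MAF ~ U(0.1, 0.5), 6 causal SNPs with main effect log(1.5), 4 of them
#' interacting with the binary exposure at magnitude log(1.5), exposure
#' effect log(1.5), baseline intercept logit(0.1), and exactly 1000 cases
#' and 1000 controls per dataset via quota sampling.
#'
#' @param n_snps number of SNPs (default 10).
#' @param maf_low,maf_high uniform MAF range (defaults 0.1, 0.5).
#' @param n_causal_main SNPs with non-zero main effect (default 6).
#' @param n_interacting SNPs with non-zero interaction (default 4).
#' @param interacting_require_main draw interacting SNPs from the causal set
#'   (default TRUE); FALSE allows interaction-only SNPs with no main effect.
#' @param scenario interaction sign pattern relative to the main effect:
#'   `"all_antagonistic"`, `"all_synergistic"` or `"half_half"`.
#' @param beta_main_mag main-effect magnitude (default log(1.5)).
#' @param beta_gxe_mag interaction magnitude (default log(1.5)).
#' @param beta_e exposure effect (default log(1.5)).
#' @param alpha baseline intercept (default logit(0.1)).
#' @param n_cases,n_controls quota per dataset (defaults 1000, 1000).
#' @param draw_budget maximum individuals drawn before giving up.
#' @param seed RNG seed.
#' @return list of class `"sparse_sim_config"`.
#' @export
sparse_sim_config <- function(n_snps = 10, maf_low = 0.1, maf_high = 0.5,
                              n_causal_main = 6, n_interacting = 4,
                              interacting_require_main = TRUE,
                              scenario = c("all_antagonistic",
                                           "all_synergistic", "half_half"),
                              beta_main_mag = log(1.5),
                              beta_gxe_mag = log(1.5),
                              beta_e = log(1.5), alpha = qlogis(0.1),
                              n_cases = 1000, n_controls = 1000,
                              draw_budget = 400 * (n_cases + n_controls),
                              seed = 1) {
  scenario <- match.arg(scenario)
  if (n_interacting > n_snps)
    stop_iprs("n_interacting (%d) exceeds n_snps (%d)", n_interacting, n_snps)
  if (interacting_require_main && n_interacting > n_causal_main)
    stop_iprs("interacting SNPs must be a subset of the %d causal SNPs", n_causal_main)
  structure(list(n_snps = n_snps, maf_low = maf_low, maf_high = maf_high,
                 n_causal_main = n_causal_main, n_interacting = n_interacting,
                 interacting_require_main = interacting_require_main,
                 scenario = scenario, beta_main_mag = beta_main_mag,
                 beta_gxe_mag = beta_gxe_mag, beta_e = beta_e, alpha = alpha,
                 n_cases = n_cases, n_controls = n_controls,
                 draw_budget = draw_budget, seed = seed),
            class = "sparse_sim_config")
}

#' Simulate a sparse case-control dataset
#'
#' Individuals are drawn from the generative model until exactly
#' `n_cases` cases and `n_controls` controls have accumulated; the excess is
#' discarded. The truth record is sufficient to recompute every sample's
#' outcome probability.
#'
#' @param cfg a [sparse_sim_config()].
#' @return list of class `"sim_dataset"`: `genotypes`, `e`, `y`, `truth`.
#' @export
simulate_sparse <- function(cfg) {
  stopifnot(inherits(cfg, "sparse_sim_config"))
  with_seed(cfg$seed, {
    J <- cfg$n_snps
    maf <- runif(J, cfg$maf_low, cfg$maf_high)
    causal <- sort(sample.int(J, cfg$n_causal_main))
    beta_m <- numeric(J)
    beta_m[causal] <- cfg$beta_main_mag
    pool <- if (cfg$interacting_require_main) causal else seq_len(J)
    interacting <- sort(sample(pool, cfg$n_interacting))
    beta_i <- numeric(J)
    # sign convention: main effects are risk (+); "antagonistic" opposes the
    # risk direction (negative interaction), also for interaction-only SNPs
    sign_i <- switch(cfg$scenario,
      all_antagonistic = rep(-1, cfg$n_interacting),
      all_synergistic = rep(1, cfg$n_interacting),
      half_half = {
        s <- rep(1, cfg$n_interacting)
        s[sample.int(cfg$n_interacting, floor(cfg$n_interacting / 2))] <- -1
        s
      })
    beta_i[interacting] <- sign_i * cfg$beta_gxe_mag

    need_ca <- cfg$n_cases; need_co <- cfg$n_controls
    G_ca <- G_co <- matrix(0L, nrow = 0, ncol = J)
    e_ca <- e_co <- integer(0)
    drawn <- 0L; raw_cases <- 0L
    while (need_ca > 0 || need_co > 0) {
      if (drawn >= cfg$draw_budget)
        stop_iprs(paste0("simulate_sparse: draw budget %d exhausted with %d cases/",
                         "%d controls still needed; choose a less extreme alpha"),
                  cfg$draw_budget, need_ca, need_co)
      b <- min(max(2000L, 4L * (need_ca + need_co)), cfg$draw_budget - drawn)
      G <- matrix(rbinom(b * J, 2L, rep(maf, each = b)), nrow = b)
      e <- rbinom(b, 1L, 0.5)
      eta <- cfg$alpha + drop(G %*% beta_m) + drop(G %*% beta_i) * e +
        cfg$beta_e * e
      y <- rbinom(b, 1L, plogis(eta))
      drawn <- drawn + b
      raw_cases <- raw_cases + sum(y)
      if (need_ca > 0) {
        ix <- which(y == 1L)[seq_len(min(need_ca, sum(y)))]
        G_ca <- rbind(G_ca, G[ix, , drop = FALSE]); e_ca <- c(e_ca, e[ix])
        need_ca <- need_ca - length(ix)
      }
      if (need_co > 0) {
        ix <- which(y == 0L)[seq_len(min(need_co, sum(1 - y)))]
        G_co <- rbind(G_co, G[ix, , drop = FALSE]); e_co <- c(e_co, e[ix])
        need_co <- need_co - length(ix)
      }
    }
    G_all <- rbind(G_ca, G_co)
    e_all <- c(e_ca, e_co)
    y_all <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
    ord <- sample.int(length(y_all))
    G_all <- G_all[ord, , drop = FALSE]
    e_all <- e_all[ord]; y_all <- y_all[ord]
    n <- length(y_all)
    ds <- genotype_dataset(
      G_all,
      variants = data.frame(id = paste0("snp", seq_len(J)), chrom = 1L,
                            pos = seq_len(J) * 1000L, allele1 = "A",
                            allele2 = "B", stringsAsFactors = FALSE),
      samples = data.frame(fid = paste0("F", seq_len(n)),
                           iid = paste0("I", seq_len(n)), sex = 0L,
                           phenotype = y_all + 1L, stringsAsFactors = FALSE))
    truth <- list(design = "sparse", scenario = cfg$scenario, maf = maf,
                  alpha = cfg$alpha, beta_main = beta_m, beta_gxe = beta_i,
                  beta_e = cfg$beta_e,
                  causal_ids = paste0("snp", causal),
                  interacting_ids = paste0("snp", interacting),
                  n_raw_draws = drawn, n_raw_cases = raw_cases,
                  seed = cfg$seed)
    structure(list(genotypes = ds, e = e_all, y = y_all, truth = truth),
              class = "sim_dataset")
  })
}

#' Configuration for the polygenic simulation design
#'
#' Defaults encode the polygenic study conditions at desk scale: synthetic
#' independent genotypes for 5000 samples x 40000 variants, 1% of variants
#' causal with standardized effects drawn from N(0, h2 / n_causal) so the
#' genetic linear predictor has variance h2 = 0.3, 0.1 per mille of variants
#' interacting with the exposure (70% antagonistic), exposure effect
#' log(1.5), baseline intercept logit(0.1).
#'
#' @param m total number of variants (default 40000).
#' @param n_samples cohort size (default 5000).
#' @param causal_fraction fraction of variants with main effects (default 0.01).
#' @param h2 variance of the genetic linear predictor (default 0.3).
#' @param interacting_fraction fraction of variants interacting (default 1e-4).
#' @param antagonistic_proportion fraction of interactions whose sign opposes
#'   the main effect (default 0.7).
#' @param beta_e exposure effect (default log(1.5)).
#' @param alpha baseline intercept (default logit(0.1)).
#' @param maf_low,maf_high synthetic MAF range (defaults 0.05, 0.5).
#' @param genotype_source `"synthetic"` or `"plink"`.
#' @param plink_prefix PLINK prefix when `genotype_source = "plink"`.
#' @param interacting_subset_of_causal draw interacting variants from the
#'   causal set (default TRUE).
#' @param seed RNG seed.
#' @return list of class `"polygenic_sim_config"`.
#' @export
polygenic_sim_config <- function(m = 40000, n_samples = 5000,
                                 causal_fraction = 0.01, h2 = 0.3,
                                 interacting_fraction = 1e-4,
                                 antagonistic_proportion = 0.7,
                                 beta_e = log(1.5), alpha = qlogis(0.1),
                                 maf_low = 0.05, maf_high = 0.5,
                                 genotype_source = c("synthetic", "plink"),
                                 plink_prefix = NULL,
                                 interacting_subset_of_causal = TRUE,
                                 seed = 1) {
  genotype_source <- match.arg(genotype_source)
  stopifnot(antagonistic_proportion >= 0, antagonistic_proportion <= 1)
  if (genotype_source == "plink" &&
      (is.null(plink_prefix) || !file.exists(paste0(plink_prefix, ".bed"))))
    stop_iprs("plink genotype source requires an existing .bed at plink_prefix")
  structure(list(m = m, n_samples = n_samples,
                 causal_fraction = causal_fraction, h2 = h2,
                 interacting_fraction = interacting_fraction,
                 antagonistic_proportion = antagonistic_proportion,
                 beta_e = beta_e, alpha = alpha,
                 maf_low = maf_low, maf_high = maf_high,
                 genotype_source = genotype_source,
                 plink_prefix = plink_prefix,
                 interacting_subset_of_causal = interacting_subset_of_causal,
                 seed = seed),
            class = "polygenic_sim_config")
}

#' Synthesize independent binomial genotypes
#'
#' Independent variants with per-variant MAF drawn from
#' `U(maf_low, maf_high)` and dosages `Binomial(2, MAF)`; no missingness and
#' no linkage disequilibrium.
#'
#' @param n_samples,m dimensions.
#' @param maf_low,maf_high MAF range (defaults 0.05, 0.5).
#' @param seed RNG seed.
#' @return list: `dataset` (a `"genotypes"`), `maf` (drawn frequencies).
#' @export
synthesize_genotypes <- function(n_samples, m, maf_low = 0.05,
                                 maf_high = 0.5, seed = 1) {
  stopifnot(n_samples >= 1, m >= 1)
  with_seed(seed, {
    maf <- runif(m, maf_low, maf_high)
    G <- matrix(0L, nrow = n_samples, ncol = m)
    cs <- max(1L, min(m, floor(5e6 / n_samples)))
    for (start in seq(1L, m, by = cs)) {
      idx <- start:min(m, start + cs - 1L)
      # inverse-CDF draw of Binomial(2, p): one uniform per genotype
      p <- maf[idx]
      t0 <- rep((1 - p)^2, each = n_samples)     # P(g = 0)
      t1 <- rep(1 - p^2, each = n_samples)       # P(g <= 1)
      u <- runif(n_samples * length(idx))
      G[, idx] <- (u > t0) + (u > t1)
    }
    # dosages are in {0,1,2} by construction; skip the validating constructor
    # (its range pass over a fresh multi-hundred-MB matrix is not free)
    ds <- .new_genotypes(
      G,
      variants = data.frame(id = paste0("v", seq_len(m)), chrom = 1L,
                            pos = seq_len(m) * 100L, allele1 = "A",
                            allele2 = "B", stringsAsFactors = FALSE),
      samples = data.frame(fid = paste0("F", seq_len(n_samples)),
                           iid = paste0("I", seq_len(n_samples)), sex = 0L,
                           phenotype = -9L, stringsAsFactors = FALSE))
    list(dataset = ds, maf = maf)
  })
}

#' Simulate a polygenic cohort dataset
#'
#' Causal effects are drawn from `N(0, h2 / n_causal)` and applied to
#' standardized dosages, so the genetic linear predictor has variance `h2`
#' in expectation. Interaction magnitudes are `|N(0, h2 / n_causal)|` with a
#' `antagonistic_proportion` share of signs opposing the main effect
#' (interaction-only variants oppose the positive direction by convention).
#'
#' @param cfg a [polygenic_sim_config()].
#' @return list of class `"sim_dataset"`.
#' @export
simulate_polygenic <- function(cfg) {
  stopifnot(inherits(cfg, "polygenic_sim_config"))
  with_seed(cfg$seed, {
    if (cfg$genotype_source == "plink") {
      ds <- read_plink(cfg$plink_prefix)
    } else {
      ds <- synthesize_genotypes(cfg$n_samples, cfg$m, cfg$maf_low,
                                 cfg$maf_high,
                                 seed = derive_seed(cfg$seed, 999))$dataset
    }
    n <- n_samples(ds); m <- n_variants(ds)
    n_causal <- max(1L, round(cfg$causal_fraction * m))
    n_int <- round(cfg$interacting_fraction * m)
    causal <- sort(sample.int(m, n_causal))
    beta <- rnorm(n_causal, 0, sqrt(cfg$h2 / n_causal))
    if (n_int < 1) {
      warning("interacting count rounded to zero; pure main-effect simulation",
              call. = FALSE)
      interacting <- integer(0); beta_i <- numeric(0)
    } else {
      pool <- if (cfg$interacting_subset_of_causal) causal else seq_len(m)
      interacting <- sort(sample(pool, n_int))
      mag <- abs(rnorm(n_int, 0, sqrt(cfg$h2 / n_causal)))
      n_ant <- round(cfg$antagonistic_proportion * n_int)
      ant <- rep(FALSE, n_int)
      if (n_ant > 0) ant[sample.int(n_int, n_ant)] <- TRUE
      ref <- beta[match(interacting, causal)]   # NA for interaction-only
      ref_sign <- ifelse(is.na(ref) | ref == 0, 1, sign(ref))
      beta_i <- ifelse(ant, -ref_sign, ref_sign) * mag
    }
    # standardize only the columns entering the linear predictor
    Gc <- ds$dosages[, causal, drop = FALSE]
    storage.mode(Gc) <- "double"
    mu <- colMeans(Gc); sdv <- apply(Gc, 2, sd)
    sdv[sdv == 0] <- 1
    Gc <- sweep(sweep(Gc, 2, mu), 2, sdv, "/")
    e <- rbinom(n, 1L, 0.5)
    eta <- cfg$alpha + drop(Gc %*% beta) + cfg$beta_e * e
    if (length(interacting)) {
      Gi <- ds$dosages[, interacting, drop = FALSE]
      storage.mode(Gi) <- "double"
      mui <- colMeans(Gi); sdi <- apply(Gi, 2, sd); sdi[sdi == 0] <- 1
      Gi <- sweep(sweep(Gi, 2, mui), 2, sdi, "/")
      eta <- eta + drop(Gi %*% beta_i) * e
    }
    y <- rbinom(n, 1L, plogis(eta))
    truth <- list(design = "polygenic", h2 = cfg$h2, alpha = cfg$alpha,
                  beta_e = cfg$beta_e,
                  causal_ids = ds$variants$id[causal],
                  beta_std = beta,
                  causal_mean = mu, causal_sd = sdv,
                  interacting_ids = ds$variants$id[interacting],
                  beta_gxe_std = beta_i,
                  n_antagonistic = if (length(interacting))
                    sum(sign(beta_i) != ref_sign) else 0L,
                  seed = cfg$seed)
    structure(list(genotypes = ds, e = e, y = y, truth = truth),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated %s dataset: %d samples (%d cases), %d variants\n",
              x$truth$design, length(x$y), sum(x$y), n_variants(x$genotypes)))
  invisible(x)
}

#' Export a simulated dataset
#'
#' Writes the PLINK triplet, a phenotype table (`FID IID outcome exposure`)
#' and the truth record as JSON into a directory.
#'
#' @param sim a `"sim_dataset"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_plink(sim$genotypes, file.path(dir, "genotypes"))
  ph <- data.frame(FID = sim$genotypes$samples$fid,
                   IID = sim$genotypes$samples$iid,
                   outcome = sim$y, exposure = sim$e)
  write.table(ph, file.path(dir, "pheno.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(jsonlite::toJSON(sim$truth, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(dir, "truth.json"))
  invisible(dir)
}

#' Read / write flat key-value simulation configs
#'
#' One `key value` (or `key = value`) pair per line; `#` starts a comment.
#' Keys mirror the [sparse_sim_config()] / [polygenic_sim_config()]
#' arguments; the `design` key selects the constructor.
#'
#' @param path file path.
#' @return the constructed config object.
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- lapply(lines, function(l) {
    parts <- strsplit(sub("=", " ", l, fixed = TRUE), "[[:space:]]+")[[1]]
    if (length(parts) < 2) stop_iprs("malformed config line: '%s'", l)
    val <- paste(parts[-1], collapse = " ")
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
    else if (toupper(val) %in% c("TRUE", "FALSE")) as.logical(toupper(val))
    else val
    setNames(list(parsed), parts[1])
  })
  cfg <- do.call(c, kv)
  design <- cfg$design %||% "sparse"
  cfg$design <- NULL
  maker <- switch(design, sparse = sparse_sim_config,
                  polygenic = polygenic_sim_config,
                  stop_iprs("unknown design '%s' (expected sparse or polygenic)",
                            design))
  bad <- setdiff(names(cfg), names(formals(maker)))
  if (length(bad))
    stop_iprs("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(maker, cfg)
}
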