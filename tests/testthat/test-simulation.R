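test_that("quota sampler yields exact case/control counts regardless of alpha", {
  for (al in c(qlogis(0.1), qlogis(0.05))) {
    cfg <- sparse_sim_config(alpha = al, n_cases = 150, n_controls = 120,
                             seed = 91)
    sim <- simulate_sparse(cfg)
    expect_identical(sum(sim$y == 1), 150L)
    expect_identical(sum(sim$y == 0), 120L)
    expect_identical(n_variants(sim$genotypes), 10L)
  }
  # impossible quota within budget: error advises on alpha
  cfg_bad <- sparse_sim_config(alpha = -15, n_cases = 50, n_controls = 50,
                               draw_budget = 2000, seed = 92)
  expect_error(simulate_sparse(cfg_bad), "alpha")
})

test_that("scenario sign patterns follow the config contract", {
  for (sc in c("all_antagonistic", "all_synergistic", "half_half")) {
    sim <- simulate_sparse(sparse_sim_config(scenario = sc, seed = 93,
                                             n_cases = 50, n_controls = 50))
    tr <- sim$truth
    ii <- match(tr$interacting_ids, paste0("snp", 1:10))
    bi <- tr$beta_gxe[ii]; bm <- tr$beta_main[ii]
    expect_true(all(bm > 0))   # interacting SNPs drawn from the causal set
    neg <- sum(sign(bi) != sign(bm))
    expect_identical(neg, switch(sc, all_antagonistic = 4L,
                                 all_synergistic = 0L, half_half = 2L))
    expect_identical(sum(tr$beta_main != 0), 6L)
  }
})

test_that("null generator produces ~50% cases among raw draws", {
  cfg <- sparse_sim_config(beta_main_mag = 0, beta_gxe_mag = 0, beta_e = 0,
                           alpha = 0, n_cases = 500, n_controls = 500,
                           seed = 94)
  sim <- simulate_sparse(cfg)
  frac <- sim$truth$n_raw_cases / sim$truth$n_raw_draws
  se <- sqrt(0.25 / sim$truth$n_raw_draws)
  expect_lt(abs(frac - 0.5), 4 * se)
})

test_that("synthetic genotypes: determinism, MAF point mass, frequency accuracy", {
  g1 <- synthesize_genotypes(50, 30, seed = 95)
  g2 <- synthesize_genotypes(50, 30, seed = 95)
  expect_identical(g1$dataset$dosages, g2$dataset$dosages)
  expect_identical(g1$maf, g2$maf)

  gp <- synthesize_genotypes(500, 10, maf_low = 0.5, maf_high = 0.5, seed = 96)
  expect_true(all(gp$maf == 0.5))
  expect_lt(max(abs(colMeans(gp$dataset$dosages) - 1)), 0.2)

  gf <- synthesize_genotypes(10000, 50, seed = 97)
  phat <- colMeans(gf$dataset$dosages) / 2
  se <- sqrt(gf$maf * (1 - gf$maf) / (2 * 10000))
  expect_true(all(abs(phat - gf$maf) <= 4 * se))
  expect_gte(sum(abs(phat - gf$maf) <= 3 * se), 47)
})

test_that("polygenic truth: causal/interacting counts, signs and effect variance", {
  cfg <- polygenic_sim_config(m = 40000, n_samples = 400, seed = 98)
  sim <- simulate_polygenic(cfg)
  tr <- sim$truth
  expect_identical(length(tr$causal_ids), 400L)      # 1% of 40,000
  expect_identical(length(tr$interacting_ids), 4L)   # 0.1 per mille
  expect_identical(tr$n_antagonistic, 3L)            # round(0.7 * 4)
  expect_true(all(tr$interacting_ids %in% tr$causal_ids))
  # sampling bound for the draw variance of the causal effects
  v <- var(tr$beta_std)
  s2 <- cfg$h2 / 400
  bounds <- s2 * qchisq(c(0.0015, 0.9985), df = 399) / 399
  expect_gt(v, bounds[1]); expect_lt(v, bounds[2])

  # zero interacting count after rounding: warning, pure main effects
  expect_warning(
    sim0 <- simulate_polygenic(polygenic_sim_config(m = 2000, n_samples = 100,
                                                    seed = 99)),
    "zero")
  expect_identical(length(sim0$truth$interacting_ids), 0L)
})

test_that("interaction model refit on a large sparse dataset recovers the truth", {
  cfg <- sparse_sim_config(seed = 100, n_cases = 30000, n_controls = 30000,
                           draw_budget = 1e6)
  sim <- simulate_sparse(cfg)
  sc <- genome_scan(sim$genotypes, sim$y, sim$e, model = "interaction")
  tr <- sim$truth
  for (j in 1:10) {
    expect_true(sc$converged[j])
    expect_lt(abs(sc$beta_main[j] - tr$beta_main[j]), 3 * sc$se_main[j])
    expect_lt(abs(sc$beta_gxe[j] - tr$beta_gxe[j]), 3 * sc$se_gxe[j])
  }
})

test_that("study aggregation equals recomputation from the replicate table", {
  st <- run_simulation_study("sparse",
                             sparse_sim_config(n_cases = 150, n_controls = 150),
                             n_replicates = 6, seed = 101)
  expect_identical(st$n_failed, 0L)
  expect_identical(nrow(st$replicates), 6L)
  ok <- !st$replicates$failed
  expect_equal(st$aggregate$auc_iprs, mean(st$replicates$auc_iprs[ok]))
  expect_equal(st$aggregate$auc_diff,
               mean(st$replicates$auc_iprs[ok] - st$replicates$auc_prs[ok]))
  # replicate-seed isolation: rerunning replicate 3 alone reproduces its row
  row3 <- run_study_replicate("sparse",
                              sparse_sim_config(n_cases = 150, n_controls = 150),
                              replicate = 3, seed = 101)
  expect_equal(row3$auc_iprs, st$replicates$auc_iprs[3], tolerance = 1e-12)
})

test_that("simulated datasets export to PLINK + phenotype + truth and read back", {
  sim <- simulate_sparse(sparse_sim_config(seed = 102, n_cases = 40,
                                           n_controls = 40))
  dir <- withr::local_tempdir()
  write_sim_dataset(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("genotypes.bed", "genotypes.bim",
                                               "genotypes.fam", "pheno.tsv",
                                               "truth.json")))))
  back <- read_plink(file.path(dir, "genotypes"))
  expect_identical(unname(back$dosages), unname(sim$genotypes$dosages))
  ph <- read_phenotype(file.path(dir, "pheno.tsv"))
  al <- align_phenotype(back, ph)
  expect_equal(al$y, sim$y, ignore_attr = TRUE)
  expect_equal(al$e, sim$e, ignore_attr = TRUE)
  tr <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  expect_equal(tr$beta_e, sim$truth$beta_e)
})
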