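test_that("AUC: examples and pair-enumeration oracle equivalence", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(auc(c(0, 1), c(0.2, 0.9)), 1.0)
  expect_equal(auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)   # all ties
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both")
  for (s in 1:5) {
    withr::with_seed(300 + s, {
      n <- sample(20:200, 1)
      y <- rbinom(n, 1, 0.4); if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
      p <- round(runif(n), 2)   # force some ties
    })
    expect_equal(auc(y, p), auc_oracle(y, p), tolerance = 1e-12)
  }
})

test_that("DeLong test: degenerate, antisymmetric, rank-invariant", {
  withr::with_seed(71, {
    y <- rbinom(150, 1, 0.4)
    p1 <- runif(150); p2 <- plogis(2 * qlogis(p1) + rnorm(150))
  })
  same <- delong_test(y, p1, p1)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_equal(same$auc1, same$auc2)

  ab <- delong_test(y, p1, p2)
  ba <- delong_test(y, p2, p1)
  expect_equal(ab$z, -ba$z, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)

  # strictly monotone transforms of both arms leave the test unchanged
  tr <- delong_test(y, exp(3 * p1), qlogis(p2 / 1.0001 + 1e-5))
  expect_equal(tr$z, ab$z, tolerance = 1e-9)
})

test_that("DeLong agrees with pROC and with a paired-bootstrap oracle", {
  skip_if_not_installed("pROC")
  withr::with_seed(72, {
    n <- 200
    x <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.5 + 1.2 * x))
    p1 <- plogis(x + rnorm(n, sd = 0.8))
    p2 <- plogis(0.5 * x + rnorm(n, sd = 0.8))
  })
  ours <- delong_test(y, p1, p2)
  ref <- pROC::roc.test(pROC::roc(y, p1, quiet = TRUE),
                        pROC::roc(y, p2, quiet = TRUE), method = "delong")
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_equal(abs(ours$z), abs(unname(ref$statistic)), tolerance = 1e-9)

  boots <- withr::with_seed(73, {
    vapply(seq_len(10000), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[ix])) < 2) return(NA_real_)
      auc(y[ix], p1[ix]) - auc(y[ix], p2[ix])
    }, numeric(1))
  })
  boots <- boots[!is.na(boots)]
  p_boot <- 2 * min(mean(boots <= 0), mean(boots >= 0))
  expect_lt(abs(ours$p - p_boot), 0.02)
})

test_that("stratification cuts 5/90/5 and reports group prevalence", {
  withr::with_seed(74, {
    p <- runif(1000)   # distinct scores
    y <- rbinom(1000, 1, p)
  })
  st <- stratify(p, y)
  expect_identical(st$n, c(50L, 900L, 50L))
  expect_equal(sum(st$n_cases), sum(y))
  # independent group-by oracle
  q <- quantile(p, c(0.05, 0.95), type = 7)
  for (g in c("low", "intermediate", "high")) {
    idx <- switch(g, low = p < q[1], high = p > q[2],
                  intermediate = p >= q[1] & p <= q[2])
    expect_equal(st$prevalence[st$group == g], mean(y[idx]))
  }
  st1 <- stratify(runif(100), rep(1, 100))
  expect_true(all(st1$prevalence == 1))
  expect_warning(st_tied <- stratify(rep(0.3, 50), rbinom(50, 1, 0.5)),
                 "degenerate")
  expect_identical(st_tied$n[st_tied$group == "intermediate"], 50L)
})

test_that("prevalence chi-square matches hand computation and is label-invariant", {
  withr::with_seed(75, {
    p1 <- runif(400); p2 <- p1 + rnorm(400, sd = 0.3)
    y <- rbinom(400, 1, p1)
  })
  sA <- stratify(p1, y); sB <- stratify(p2, y)
  same <- prevalence_chisq(sA, sA)
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  res <- prevalence_chisq(sA, sB)
  tab <- rbind(sA$n_cases, sB$n_cases)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2_hand <- sum((tab - expected)^2 / expected)
  expect_equal(res$chi2, chi2_hand, tolerance = 1e-10)
  expect_identical(res$df, 2L)

  perm <- c(3, 1, 2)
  sAp <- sA[perm, ]; class(sAp) <- class(sA)
  sBp <- sB[perm, ]; class(sBp) <- class(sB)
  expect_equal(prevalence_chisq(sAp, sBp)$chi2, res$chi2, tolerance = 1e-12)
})

test_that("Brier score values and seeded bootstrap interval", {
  y <- c(1, 0)
  expect_equal(brier_score(y, c(1, 0), ci_reps = 0)$score, 0)
  expect_equal(brier_score(y, c(0.5, 0.5), ci_reps = 0)$score, 0.25)
  expect_equal(brier_score(y, c(0.8, 0.3), ci_reps = 0)$score, 0.065)
  withr::with_seed(76, {
    yy <- rbinom(300, 1, 0.3); pp <- runif(300)
  })
  b1 <- brier_score(yy, pp, ci_reps = 500, seed = 11)
  b2 <- brier_score(yy, pp, ci_reps = 500, seed = 11)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$score)
  expect_gte(b1$ci_high, b1$score)
})

test_that("calibration curve is near the diagonal for calibrated forecasts", {
  withr::with_seed(77, {
    p <- runif(100000)
    y <- rbinom(100000, 1, p)
  })
  curve <- calibration_curve(y, p)
  expect_identical(nrow(curve), 10L)
  expect_lt(max(abs(curve$mean_pred - curve$obs_freq)), 0.02)
  expect_identical(sum(curve$n), 100000L)
  # calibrated forecasts keep the Brier score at or below the 1/4 bound
  expect_lte(brier_score(y, p, ci_reps = 0)$score, 0.25 + 0.005)

  one_bin <- calibration_curve(c(0, 1, 1), rep(0.6, 3))
  expect_identical(nrow(one_bin), 1L)
  expect_identical(one_bin$n, 3L)

  sm <- calibration_curve(y[1:5000], p[1:5000], smooth = TRUE)
  expect_true(all(sm$obs_freq >= 0 & sm$obs_freq <= 1))
  mid <- abs(sm$mean_pred - 0.5) < 0.1
  expect_lt(max(abs(sm$obs_freq[mid] - sm$mean_pred[mid])), 0.05)
})

test_that("Spiegelhalter z: symmetry point, type-I error, and power", {
  deg <- spiegelhalter_test(c(0, 1, 1, 0), rep(0.5, 4))
  expect_true(deg$degenerate)
  expect_equal(deg$z, 0)

  rej <- withr::with_seed(78, {
    vapply(seq_len(1000), function(i) {
      p <- runif(200, 0.05, 0.95)
      y <- rbinom(200, 1, p)
      spiegelhalter_test(y, p)$p < 0.05
    }, logical(1))
  })
  band <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(mean(rej) - 0.05), band + 1e-9)

  withr::with_seed(79, {
    p_true <- runif(10000, 0.05, 0.95)
    y <- rbinom(10000, 1, p_true)
    p_shrunk <- 0.5 + 0.5 * (p_true - 0.5)   # toward 0.5: miscalibrated
  })
  expect_gt(abs(spiegelhalter_test(y, p_shrunk)$z), 1.96)
})

test_that("Cox slope/intercept: refit fixed point, halving, and null", {
  withr::with_seed(80, {
    x <- rnorm(5000)
    y <- rbinom(5000, 1, plogis(-1 + 0.8 * x))
  })
  p_hat <- fitted(glm(y ~ x, family = binomial()))
  cc <- cox_calibration(y, p_hat)
  expect_equal(cc$slope, 1, tolerance = 1e-6)
  expect_equal(cc$intercept, 0, tolerance = 1e-6)

  withr::with_seed(81, {
    z <- rnorm(50000)
    y2 <- rbinom(50000, 1, plogis(z))
  })
  over <- plogis(2 * z)   # doubled logit: slope should recalibrate to ~0.5
  cc2 <- cox_calibration(y2, over)
  expect_lt(abs(cc2$slope - 0.5), 0.05)

  y_shuf <- withr::with_seed(82, sample(y2))
  cc3 <- cox_calibration(y_shuf, over)
  expect_lt(abs(cc3$slope), 0.05)
})

test_that("evaluate_predictions assembles the full battery and serializes", {
  withr::with_seed(83, {
    n <- 400
    x <- rnorm(n); e <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1 + x + 0.3 * e))
    p_i <- plogis(-1 + x + 0.3 * e)
    p_p <- plogis(-1 + 0.6 * x + 0.3 * e)
  })
  ev <- evaluate_predictions(y, p_i, p_p, ci_reps = 200, seed = 4)
  expect_s3_class(ev, "iprs_eval")
  expect_gt(ev$auc_iprs, ev$auc_prs)
  expect_output(print(ev), "DeLong")
  js <- jsonlite::fromJSON(eval_report_json(ev))
  expect_equal(js$auc_iprs, ev$auc_iprs, tolerance = 1e-9)
  expect_identical(js$n, 400L)
})
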