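weights_2snp <- tibble::tibble(
  snp_id = c("rs1", "rs2"), or = c(1.2, 1.5),
  risk_allele = "minor", weight = log(c(1.2, 1.5)))

test_that("the wGRS is the exact weighted risk-allele sum", {
  g <- dosage_tibble(matrix(c(2L, 0L, 1L,
                              1L, 0L, 2L), ncol = 2), c("rs1", "rs2"))
  s <- compute_wgrs(g, weights_2snp)
  expect_equal(s$wgrs[1], 2 * log(1.2) + log(1.5))  # hand-evaluated sum
  expect_equal(s$wgrs[2], 0)                         # all non-risk homozygote
  w2 <- dplyr::mutate(weights_2snp, weight = 2 * weight)
  expect_equal(compute_wgrs(g, w2)$wgrs, 2 * s$wgrs)  # linearity
})

test_that("the wGRS is invariant to SNP ordering and excludes missing rows", {
  g <- dosage_tibble(matrix(c(2L, NA, 1L,
                              1L, 0L, 2L), ncol = 2), c("rs1", "rs2"))
  s12 <- compute_wgrs(g, weights_2snp)
  s21 <- compute_wgrs(g, weights_2snp[2:1, ])
  expect_equal(s12$wgrs, s21$wgrs)
  expect_true(is.na(s12$wgrs[2]))
  expect_equal(attr(s12, "excluded"), g$individual_id[2])
  expect_error(compute_wgrs(g, dplyr::mutate(weights_2snp, snp_id = c("rs1", "zz"))),
               "zz")
})

test_that("weight derivation flips protective SNPs to non-negative weights", {
  w <- wgrs_weights(tibble::tibble(snp_id = c("a", "b", "c"),
                                   or = c(0.5, 2, NA)))
  expect_equal(w$snp_id, c("a", "b"))
  expect_equal(w$risk_allele, c("major", "minor"))
  expect_equal(w$weight, c(log(2), log(2)))
})

test_that("Mann-Whitney anchors: symmetry, separation and exact toy U", {
  same <- tibble::tibble(score = rep(c(1, 2, 3), 2),
                         status = rep(c("case", "control"), each = 3))
  mw <- mann_whitney_test(same, score)
  expect_equal(mw$u, 9 / 2)
  expect_equal(mw$z, 0)
  expect_equal(mw$p, 1)
  sep <- tibble::tibble(score = c(4, 5, 6, 1, 2, 3),
                        status = rep(c("case", "control"), each = 3))
  mws <- mann_whitney_test(sep, score)
  expect_equal(mws$u, 9)  # n1*n2: complete separation
  # 6-observation toy with a tie: U equals brute-force pair counting
  toy <- tibble::tibble(score = c(3, 5, 5, 2, 5, 7),
                        status = rep(c("case", "control"), each = 3))
  mwt <- mann_whitney_test(toy, score)
  cases <- toy$score[toy$status == "case"]
  ctrls <- toy$score[toy$status == "control"]
  brute_u <- sum(outer(cases, ctrls, ">") + 0.5 * outer(cases, ctrls, "=="))
  expect_equal(mwt$u, brute_u)
  # tie-corrected normal approximation agrees with the stats oracle
  w <- stats::wilcox.test(cases, ctrls, correct = FALSE, exact = FALSE)
  expect_equal(mwt$p, w$p.value, tolerance = 1e-9)
})

test_that("ROC anchors: perfect separation, degeneracy and the Youden point", {
  sep <- tibble::tibble(score = c(4, 5, 6, 1, 2, 3),
                        status = rep(c("case", "control"), each = 3))
  roc <- roc_analysis(sep, score)
  expect_equal(roc$auc, 1)
  expect_equal(roc$youden$sensitivity, 1)
  expect_equal(roc$youden$specificity, 1)
  flat <- tibble::tibble(score = rep(1, 6),
                         status = rep(c("case", "control"), each = 3))
  rocf <- roc_analysis(flat, score)
  expect_equal(rocf$auc, 0.5)
  expect_true(rocf$degenerate)
})

test_that("AUC equals the Mann-Whitney estimator and the concordance count", {
  set.seed(77)
  for (i in 1:20) {
    n1 <- sample(3:10, 1); n0 <- sample(3:10, 1)
    df <- tibble::tibble(
      score = round(c(rnorm(n1, 0.5), rnorm(n0)), 1),  # rounding forces ties
      status = rep(c("case", "control"), c(n1, n0)))
    roc <- roc_analysis(df, score)
    mw <- mann_whitney_test(df, score)
    expect_equal(roc$auc, mw$u / (n1 * n0), tolerance = 1e-12)
    cases <- df$score[df$status == "case"]
    ctrls <- df$score[df$status == "control"]
    brute_auc <- (sum(outer(cases, ctrls, ">")) +
                    0.5 * sum(outer(cases, ctrls, "=="))) / (n1 * n0)
    expect_equal(roc$auc, brute_auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  df <- tibble::tibble(score = round(rnorm(200), 1),
                       status = sample(c("case", "control"), 200, TRUE))
  roc <- roc_analysis(df, score)
  ref <- pROC::roc(response = df$status, predictor = df$score,
                   levels = c("control", "case"), direction = "<",
                   quiet = TRUE)
  expect_equal(roc$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-9)
})

test_that("the per-unit logistic OR is shift-invariant and recovers the slope", {
  set.seed(99)
  b <- 0.65
  x <- rnorm(20000)
  y <- rbinom(20000, 1, stats::plogis(-0.2 + b * x))
  df <- tibble::tibble(score = x,
                       status = ifelse(y == 1, "case", "control"))
  fit <- score_logistic(df, score)
  expect_lt(abs(log(fit$or) - b), 0.06)
  shifted <- dplyr::mutate(df, score = score + 10)
  fit2 <- score_logistic(shifted, score)
  expect_equal(fit$or, fit2$or, tolerance = 1e-6)
  # independence -> OR near 1
  null_df <- dplyr::mutate(df, score = rnorm(20000))
  expect_lt(abs(log(score_logistic(null_df, score)$or)), 0.05)
})

test_that("risk-allele orientation does not change AUC or |Z|", {
  cfg <- tnfaip3_panel_config(n_cases = 400, n_controls = 400, seed = 61)
  sim <- simulate_cohort(cfg)
  tnfaip3 <- cfg$snps$snp_id[cfg$snps$gene == "TNFAIP3"]
  prof <- wgrs_analysis(sim$genotypes, sim$phenotypes, snps = tnfaip3)
  flipped <- dplyr::mutate(prof$weights,
    risk_allele = ifelse(risk_allele == "minor", "major", "minor"))
  prof2 <- wgrs_analysis(sim$genotypes, sim$phenotypes, weights = flipped)
  expect_equal(prof$roc$auc, 1 - prof2$roc$auc, tolerance = 1e-12)
  expect_equal(abs(prof$mann_whitney$z), abs(prof2$mann_whitney$z),
               tolerance = 1e-9)
})

test_that("template cohorts sit in the weak-discrimination AUC regime", {
  aucs <- vapply(1:3, function(s) {
    cfg <- tnfaip3_panel_config(seed = s)
    sim <- simulate_cohort(cfg)
    tnfaip3 <- cfg$snps$snp_id[cfg$snps$gene == "TNFAIP3"]
    prof <- wgrs_analysis(sim$genotypes, sim$phenotypes, snps = tnfaip3)
    prof$roc$auc
  }, 0)
  expect_true(all(aucs > 0.45 & aucs < 0.65))
})

test_that("glance and autoplot summarise a wGRS profile", {
  cfg <- tnfaip3_panel_config(n_cases = 300, n_controls = 300, seed = 14)
  sim <- simulate_cohort(cfg)
  prof <- wgrs_analysis(sim$genotypes, sim$phenotypes)
  gl <- glance(prof)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  expect_true(gl$sensitivity >= 0 && gl$specificity <= 1)
  expect_equal(tidy(prof), prof$weights)
  expect_s3_class(autoplot(prof), "ggplot")
})
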