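# Published values used below were hand-verified from the printed genotype
# counts with the direct formulas before being frozen here.

PUB_ALLELIC <- tibble::tribble(
  ~snp_id,      ~or,    ~lo,    ~hi,     ~p,
  "rs610604",   0.982,  0.754,  1.279,  0.893,
  "rs10499194", 0.619,  0.430,  0.889,  0.009,
  "rs13207033", 0.807,  0.633,  1.029,  0.083,
  "rs2230926",  0.831,  0.557,  1.238,  0.361,
  "rs6920220",  1.402,  0.444,  4.429,  0.563,
  "rs4958881",  0.952,  0.724,  1.253,  0.727,
  "rs3792783",  1.000,  0.835,  1.198,  1.000,
  "rs6889239",  0.976,  0.819,  1.164,  0.788
)

PUB_HWE <- c(rs610604 = 0.259, rs10499194 = 0.104, rs13207033 = 0.639,
             rs2230926 = 0.396, rs6920220 = 0.923, rs2233287 = 1.000,
             rs4958881 = 0.292, rs3792783 = 0.937, rs6889239 = 0.969)

test_that("HWE chi-square reproduces the published control column", {
  hw <- hwe_test(published_panel_counts(), "control")
  expect_equal(round(hw$p_hwe, 3), unname(PUB_HWE[hw$snp_id]))
  # independent direct-formula check for one row
  o <- c(517, 139, 11); n <- sum(o)
  q <- (o[2] + 2 * o[3]) / (2 * n); p <- 1 - q
  e <- n * c(p^2, 2 * p * q, q^2)
  expect_equal(hw$p_hwe[hw$snp_id == "rs13207033"],
               pchisq(sum((o - e)^2 / e), 1, lower.tail = FALSE))
})

test_that("exact HWE proportions give chi-square 0 and monomorphic SNPs P = 1", {
  g <- toy_geno(list(rs1 = c(rep("AA", 25), rep("AG", 50), rep("GG", 25))))
  p <- toy_pheno(rep("control", 100))
  hw <- hwe_test(count_genotypes(g, p), "control")
  expect_equal(hw$chisq, 0)
  expect_equal(hw$p_hwe, 1)
  hw2 <- hwe_test(published_panel_counts(), "control")
  expect_true(hw2$monomorphic[hw2$snp_id == "rs2233287"])
})

test_that("odds_ratio matches the cross-product and the published Woolf CI", {
  o <- odds_ratio(50, 79, 1284, 1255)
  expect_equal(o$or, (50 * 1255) / (79 * 1284))
  expect_equal(round(o$or, 3), 0.619)
  expect_lt(abs(o$ci_low - 0.430), 5.1e-4)
  expect_lt(abs(o$ci_high - 0.889), 5.1e-4)
  expect_false(o$corrected)
})

test_that("balanced 2x2 gives OR 1 with a log-symmetric CI", {
  o <- odds_ratio(10, 10, 10, 10)
  expect_equal(o$or, 1)
  expect_equal(o$ci_low * o$ci_high, 1, tolerance = 1e-12)
})

test_that("zero cells get the Haldane-Anscombe correction and a flag", {
  o <- odds_ratio(5, 0, 1329, 1334)
  expect_true(o$corrected)
  expect_equal(o$or, (5.5 * 1334.5) / (0.5 * 1329.5))
  expect_error(odds_ratio(0, 0, 10, 10), "entirely zero")
})

test_that("relabelling the exposure allele inverts the OR and swaps the CI", {
  o1 <- odds_ratio(50, 79, 1284, 1255)
  o2 <- odds_ratio(1284, 1255, 50, 79)
  expect_equal(o2$or, 1 / o1$or)
  expect_equal(o2$ci_low, 1 / o1$ci_high)
  expect_equal(o2$ci_high, 1 / o1$ci_low)
})

test_that("allelic tests reproduce all published ORs, CIs and P values", {
  at <- allelic_test(published_panel_counts())
  at <- at[match(PUB_ALLELIC$snp_id, at$snp_id), ]
  expect_equal(round(at$or, 3), PUB_ALLELIC$or)
  expect_true(all(abs(at$ci_low - PUB_ALLELIC$lo) < 5.1e-4))
  expect_true(all(abs(at$ci_high - PUB_ALLELIC$hi) < 5.1e-4))
  expect_equal(round(at$p, 3), PUB_ALLELIC$p)
})

test_that("the expected-cell rule picks chi-square for rs6920220, Fisher when <5", {
  at <- allelic_test(published_panel_counts())
  expect_equal(at$method[at$snp_id == "rs6920220"], "chisq")  # expected cells 6
  expect_equal(at$method[at$snp_id == "rs2233287"], "fisher") # expected 2.5
})

test_that("allelic chi-square equals a brute-force Pearson computation", {
  at <- allelic_test(published_panel_counts())
  brute <- function(a, b, c, d) {
    tab <- matrix(c(a, b, c, d), 2)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - e)^2 / e)
  }
  r <- at[at$snp_id == "rs13207033", ]
  expect_equal(r$statistic,
               brute(r$case_minor, r$control_minor, r$case_major,
                     r$control_major))
})

test_that("monomorphic SNPs yield an NA allelic row, not an error", {
  g <- toy_geno(list(rs1 = c("CC", "CC", "CC", "CC")))
  p <- toy_pheno(c("case", "case", "control", "control"))
  at <- allelic_test(count_genotypes(g, p))
  expect_true(is.na(at$or))
  expect_equal(at$method, "monomorphic")
})

test_that("genetic models reproduce the published CT-vs-CC result", {
  gm <- genotype_model_test(published_panel_counts())
  het <- gm[gm$model == "het" & gm$snp_id == "rs10499194", ]
  expect_equal(round(het$or, 3), 0.603)
  expect_lt(abs(het$ci_low - 0.416), 5.1e-4)
  expect_lt(abs(het$ci_high - 0.875), 5.1e-4)
  expect_equal(round(het$p, 3), 0.007)
  geno_610604 <- gm[gm$model == "genotypic" & gm$snp_id == "rs610604", ]
  expect_equal(round(geno_610604$p, 3), 0.859)
})

test_that("an empty genotype class gives NA for that model only", {
  gm <- genotype_model_test(published_panel_counts())
  rec <- gm[gm$model == "recessive" & gm$snp_id == "rs10499194", ]
  expect_true(is.na(rec$or))  # TT absent in both groups
  dom <- gm[gm$model == "dominant" & gm$snp_id == "rs10499194", ]
  expect_false(is.na(dom$or))
})

test_that("group-symmetric genotype counts give OR 1 under every model", {
  g <- toy_geno(list(rs1 = rep(c("CC", "CT", "TT"), times = c(20, 10, 4))))
  p <- toy_pheno(rep(c("case", "control"), 17))
  cts <- count_genotypes(g, p)
  cts$control_hom_major <- cts$case_hom_major
  cts$control_het <- cts$case_het
  cts$control_hom_minor <- cts$case_hom_minor
  cts$control_major <- cts$case_major
  cts$control_minor <- cts$case_minor
  gm <- genotype_model_test(cts, models = c("het", "hom", "dominant",
                                            "recessive"))
  expect_true(all(gm$or == 1))
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni(0.007, 9), 0.063)
  expect_gt(bonferroni(0.007, 9), 0.05)  # significance lost after correction
  expect_equal(bonferroni(0.5, 9), 1)
  expect_equal(bonferroni(0, 9), 0)
})

test_that("Woolf CI coverage of the true OR is near nominal under the null", {
  set.seed(20240901)
  n <- 400; q <- 0.3
  covered <- vapply(seq_len(1000), function(i) {
    a <- rbinom(1, 2 * n, q); b <- rbinom(1, 2 * n, q)
    o <- odds_ratio(a, b, 2 * n - a, 2 * n - b)
    o$ci_low <= 1 && 1 <= o$ci_high
  }, TRUE)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("adjusted OR tracks the crude OR when covariates are independent", {
  cfg <- one_snp_config(maf = 0.3, or = 0.6, n_cases = 4000,
                        n_controls = 4000, seed = 31)
  sim <- simulate_cohort(cfg)
  crude <- allelic_test(count_genotypes(sim$genotypes, sim$phenotypes))
  adj <- adjusted_or(sim$genotypes, sim$phenotypes, "rs0001",
                     contrast = "additive")
  expect_lt(abs(log(adj$or) - log(crude$or)), 0.05)
  expect_true(adj$adjusted)
})

test_that("sex-confounded simulations are de-biased by adjustment", {
  cov_conf <- candgene:::default_covariates()
  cov_conf$male_frac_case <- 0.85
  cov_conf$male_frac_control <- 0.25
  cfg <- one_snp_config(maf = 0.3, or = 1.0, n_cases = 6000,
                        n_controls = 6000, seed = 77,
                        covariates = cov_conf,
                        confounding = list(snp_id = "rs0001", sex_log_or = 1))
  sim <- simulate_cohort(cfg)
  crude <- allelic_test(count_genotypes(sim$genotypes, sim$phenotypes))
  adj <- adjusted_or(sim$genotypes, sim$phenotypes, "rs0001",
                     contrast = "additive")
  expect_gt(abs(log(crude$or)), 0.1)          # crude OR is biased off 1
  expect_lt(abs(log(adj$or)), abs(log(crude$or)))  # adjustment shrinks bias
})

test_that("Wald P of the null additive model is calibrated", {
  set.seed(424242)
  hits <- 0L
  n_rep <- 400
  for (i in seq_len(n_rep)) {
    n <- 150
    dose <- matrix(rbinom(2 * n, 2, 0.3), ncol = 1)
    g <- dosage_tibble(dose, "rs1")
    p <- toy_pheno(rep(c("case", "control"), each = n),
                   ids = g$individual_id,
                   sex = factor(sample(c("male", "female"), 2 * n, TRUE),
                                levels = c("male", "female")),
                   age = rnorm(2 * n, 30, 8))
    fit <- adjusted_or(g, p, "rs1", contrast = "additive")
    if (fit$p < 0.05) hits <- hits + 1L
  }
  expect_lt(abs(hits / n_rep - 0.05), 0.03)
})

test_that("a perfectly separating genotype raises a separation error", {
  dose <- matrix(c(rep(2L, 30), rep(0L, 30)), ncol = 1)
  g <- dosage_tibble(dose, "rs1")
  p <- toy_pheno(rep(c("case", "control"), each = 30), ids = g$individual_id,
                 sex = factor(rep(c("male", "female"), 30),
                              levels = c("male", "female")),
                 age = rnorm(60, 30, 5))
  expect_error(adjusted_or(g, p, "rs1", contrast = "additive"), "separation")
})

test_that("an all-inclusive stratum reproduces the unstratified analysis", {
  cfg <- one_snp_config(maf = 0.2, or = 0.7, n_cases = 500, n_controls = 500,
                        seed = 12)
  sim <- simulate_cohort(cfg)
  st <- stratified_test(sim$genotypes, sim$phenotypes, "rs0001",
                        stratum_var = "age", age_cut = 0, contrast = "het")
  full <- genotype_model_test(count_genotypes(sim$genotypes, sim$phenotypes),
                              m = 1)
  het <- full[full$model == "het", ]
  all_in <- st[st$stratum == ">=0", ]
  expect_equal(all_in$or, het$or)
  expect_equal(all_in$p, het$p)
  empty <- st[st$stratum == "<0", ]
  expect_true(is.na(empty$or))  # zero-case stratum -> NA row
})

test_that("a male-only effect appears in the male stratum only", {
  cfg_m <- one_snp_config(maf = 0.3, or = 0.5, n_cases = 2500,
                          n_controls = 2500, seed = 21)
  cfg_f <- one_snp_config(maf = 0.3, or = 1.0, n_cases = 2500,
                          n_controls = 2500, seed = 22)
  males <- simulate_cohort(cfg_m)
  females <- simulate_cohort(cfg_f)
  males$phenotypes$sex <- factor("male", levels = c("male", "female"))
  females$phenotypes$sex <- factor("female", levels = c("male", "female"))
  females$genotypes$individual_id <-
    paste0("F", females$genotypes$individual_id)
  females$phenotypes$individual_id <-
    paste0("F", females$phenotypes$individual_id)
  geno <- dplyr::bind_rows(males$genotypes, females$genotypes)
  attr(geno, "snp_info") <- snp_info(males$genotypes)
  pheno <- dplyr::bind_rows(males$phenotypes, females$phenotypes)
  st <- stratified_test(geno, pheno, "rs0001", stratum_var = "sex",
                        contrast = "additive")
  expect_lt(st$ci_high[st$stratum == "male"], 1)
  expect_true(st$ci_low[st$stratum == "female"] < 1 &&
                st$ci_high[st$stratum == "female"] > 1)
})

test_that("clinical strata keep all controls in each comparison", {
  cfg <- tnfaip3_panel_config(n_cases = 200, n_controls = 200, seed = 33)
  sim <- simulate_cohort(cfg)
  st <- stratified_test(sim$genotypes, sim$phenotypes, "rs10499194",
                        stratum_var = "hla_b27")
  expect_equal(st$n_control, c(200, 200))
  expect_lt(st$n_case[1], 200)
})
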