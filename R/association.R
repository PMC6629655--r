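#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square test (1 df, no continuity correction) of the observed
#' genotype triple against the expectation `n * (p^2, 2pq, q^2)` at the
#' observed allele frequency. Monomorphic SNPs return chi-square 0, P = 1,
#' flagged.
#'
#' @param counts Counts tibble from [count_genotypes()] (or
#'   [published_panel_counts()]).
#' @param group `"control"` (the usual genotyping QC) or `"case"`.
#' @return A tibble per SNP: `snp_id`, `group`, `chisq`, `df`, `p_hwe`,
#'   observed and expected genotype counts, `monomorphic`.
#' @export
hwe_test <- function(counts, group = c("control", "case")) {
  group <- arg_match(group)
  pre <- paste0(group, "_")
  obs <- cbind(counts[[paste0(pre, "hom_major")]],
               counts[[paste0(pre, "het")]],
               counts[[paste0(pre, "hom_minor")]])
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    o <- as.numeric(obs[i, ])
    n <- sum(o)
    if (n <= 0) abort(paste0("no genotyped individuals for ", counts$snp_id[i]))
    q <- (o[2] + 2 * o[3]) / (2 * n)
    p <- 1 - q
    mono <- q == 0 || q == 1
    e <- n * c(p^2, 2 * p * q, q^2)
    if (mono) {
      chisq <- 0
      pval <- 1
    } else {
      chisq <- sum((o - e)^2 / e)
      pval <- pchisq(chisq, df = 1, lower.tail = FALSE)
    }
    tibble(snp_id = counts$snp_id[i], group = group,
           chisq = chisq, df = 1L, p_hwe = pval,
           obs_hom_major = o[1], obs_het = o[2], obs_hom_minor = o[3],
           exp_hom_major = e[1], exp_het = e[2], exp_hom_minor = e[3],
           monomorphic = mono)
  })
  bind_rows(rows)
}

#' Odds ratio of a 2x2 table with Woolf confidence interval
#'
#' Cross-product odds ratio `ad/bc` with the Woolf (log-scale Wald) 95% CI,
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is zero
#' the Haldane-Anscombe correction (+0.5 to all four cells) is applied and the
#' result flagged `corrected`. A row or column that is entirely zero leaves
#' the OR undefined and is an error.
#'
#' Orientation: `a` and `b` are exposed (e.g. minor-allele) counts in cases
#' and controls, `c` and `d` the unexposed counts, so OR > 1 means the
#' exposure is enriched in cases.
#'
#' @param a,b,c,d Non-negative cell counts (fractional counts allowed, as for
#'   EM-expected haplotype counts); vectorised.
#' @param conf_z Normal quantile for the CI half-width (1.96 for 95%).
#' @return Tibble with `or`, `ci_low`, `ci_high`, `log_or_se`, `corrected`.
#' @export
odds_ratio <- function(a, b, c, d, conf_z = qnorm(0.975)) {
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n,
            all(c(a, b, c, d) >= 0))
  rowzero <- (a + b == 0) | (c + d == 0)
  colzero <- (a + c == 0) | (b + d == 0)
  if (any(rowzero | colzero)) {
    abort("odds ratio undefined: a row or column of the 2x2 is entirely zero")
  }
  corrected <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  a2 <- a + 0.5 * corrected; b2 <- b + 0.5 * corrected
  c2 <- c + 0.5 * corrected; d2 <- d + 0.5 * corrected
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  tibble(or = or,
         ci_low = exp(log(or) - conf_z * se),
         ci_high = exp(log(or) + conf_z * se),
         log_or_se = se,
         corrected = corrected)
}

#' Bonferroni correction
#'
#' Maps each raw P to `min(1, m * p)`. The family size `m` defaults to the
#' number of P values, but in a per-SNP panel analysis it should be the number
#' of SNPs tested, applied separately per comparison type.
#'
#' @param p Numeric vector of raw P values.
#' @param m Family size; must be at least `length(p)` when the vector is the
#'   whole family.
#' @return Corrected P values.
#' @export
bonferroni <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, p * m)
}

# Pearson chi-square P (no continuity correction) for a 2xk count table,
# tolerating fractional counts; falls back to Fisher's exact test when any
# expected cell is below `fisher_threshold` and the counts are integral.
two_by_k_test <- function(tab, fisher_threshold = 5) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  keep <- cs > 0
  tab <- tab[, keep, drop = FALSE]
  cs <- cs[keep]
  if (ncol(tab) < 2L || any(rs == 0)) {
    return(list(statistic = NA_real_, df = NA_integer_, p = NA_real_,
                method = "undefined"))
  }
  expected <- outer(rs, cs) / n
  df <- (nrow(tab) - 1L) * (ncol(tab) - 1L)
  if (any(expected < fisher_threshold)) {
    if (all(abs(tab - round(tab)) < 1e-9)) {
      p <- fisher.test(round(tab))$p.value
      return(list(statistic = NA_real_, df = df, p = p, method = "fisher"))
    }
    # fractional counts (EM-expected): exact test unavailable, keep chi-square
  }
  stat <- sum((tab - expected)^2 / expected)
  list(statistic = stat, df = df,
       p = pchisq(stat, df = df, lower.tail = FALSE), method = "chisq")
}

#' Allelic case-control association test
#'
#' For each SNP, tests the 2x2 table of minor/major allele counts by group:
#' Pearson chi-square without continuity correction, switching to Fisher's
#' exact test when any expected cell is below `fisher_threshold`. The OR
#' (minor vs major allele) and Woolf CI come from [odds_ratio()]. Monomorphic
#' SNPs yield an NA row rather than an error.
#'
#' @param counts Counts tibble from [count_genotypes()].
#' @param m Bonferroni family size; defaults to the number of SNPs in
#'   `counts`.
#' @param fisher_threshold Expected-cell cutoff for the Fisher switch.
#' @return Tibble per SNP: comparison label, the four allele counts used,
#'   `or`, `ci_low`, `ci_high`, `statistic`, `method`, `p`, `p_bonferroni`,
#'   `corrected` (Haldane flag).
#' @export
allelic_test <- function(counts, m = nrow(counts), fisher_threshold = 5) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    base <- tibble(
      snp_id = r$snp_id,
      comparison = paste0(r$allele_minor, " vs ", r$allele_major),
      case_minor = r$case_minor, control_minor = r$control_minor,
      case_major = r$case_major, control_major = r$control_major
    )
    if (is.na(r$allele_minor) || (r$case_minor + r$control_minor) == 0) {
      return(mutate(base, comparison = NA_character_, or = NA_real_,
                    ci_low = NA_real_, ci_high = NA_real_,
                    statistic = NA_real_, method = "monomorphic",
                    p = NA_real_, log_or_se = NA_real_, corrected = NA))
    }
    tab <- rbind(case = c(minor = r$case_minor, major = r$case_major),
                 control = c(minor = r$control_minor, major = r$control_major))
    tst <- two_by_k_test(tab, fisher_threshold)
    orr <- odds_ratio(r$case_minor, r$control_minor, r$case_major,
                      r$control_major)
    mutate(base, or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
           statistic = tst$statistic, method = tst$method, p = tst$p,
           log_or_se = orr$log_or_se, corrected = orr$corrected)
  })
  out <- bind_rows(rows)
  mutate(out, p_bonferroni = bonferroni(.data$p, m))
}

#' Genetic-model (genotype-level) association tests
#'
#' For each SNP, compares genotype classes between groups under the standard
#' inheritance models, each as a 2x2 with OR/CI/P per the [allelic_test()]
#' rules:
#'
#' * `het` — heterozygote vs major-homozygote (codominant);
#' * `hom` — minor-homozygote vs major-homozygote (codominant);
#' * `dominant` — het + minor-hom vs major-hom;
#' * `recessive` — minor-hom vs het + major-hom;
#' * `genotypic` — the overall genotype-distribution chi-square over all
#'   non-empty genotype classes (no OR).
#'
#' A comparison whose exposed class is empty in both groups returns an NA row;
#' the other comparisons still run.
#'
#' @inheritParams allelic_test
#' @param models Subset of the comparisons to run.
#' @return Tibble with one row per SNP x model; Bonferroni correction is
#'   applied separately within each model across SNPs (family size `m`).
#' @export
genotype_model_test <- function(counts, m = nrow(counts),
                                models = c("genotypic", "het", "hom",
                                           "dominant", "recessive"),
                                fisher_threshold = 5) {
  models <- match.arg(models, several.ok = TRUE,
                      choices = c("genotypic", "het", "hom", "dominant",
                                  "recessive"))
  one_2x2 <- function(r, label, a, b, c, d) {
    base <- tibble(snp_id = r$snp_id, model = label,
                   case_exposed = a, control_exposed = b,
                   case_reference = c, control_reference = d)
    if ((a + b) == 0 || (c + d) == 0) {
      return(mutate(base, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    statistic = NA_real_, df = NA_integer_,
                    method = "empty class", p = NA_real_, corrected = NA))
    }
    tst <- two_by_k_test(rbind(c(a, c), c(b, d)), fisher_threshold)
    orr <- odds_ratio(a, b, c, d)
    mutate(base, or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
           statistic = tst$statistic, df = tst$df, method = tst$method,
           p = tst$p, corrected = orr$corrected)
  }
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    out <- list()
    if ("genotypic" %in% models) {
      tab <- rbind(case = c(r$case_hom_major, r$case_het, r$case_hom_minor),
                   control = c(r$control_hom_major, r$control_het,
                               r$control_hom_minor))
      tst <- two_by_k_test(tab, fisher_threshold)
      out$genotypic <- tibble(
        snp_id = r$snp_id, model = "genotypic",
        case_exposed = NA_real_, control_exposed = NA_real_,
        case_reference = NA_real_, control_reference = NA_real_,
        or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
        statistic = tst$statistic, df = tst$df, method = tst$method,
        p = tst$p, corrected = NA)
    }
    if ("het" %in% models) {
      out$het <- one_2x2(r, "het", r$case_het, r$control_het,
                         r$case_hom_major, r$control_hom_major)
    }
    if ("hom" %in% models) {
      out$hom <- one_2x2(r, "hom", r$case_hom_minor, r$control_hom_minor,
                         r$case_hom_major, r$control_hom_major)
    }
    if ("dominant" %in% models) {
      out$dominant <- one_2x2(r, "dominant",
                              r$case_het + r$case_hom_minor,
                              r$control_het + r$control_hom_minor,
                              r$case_hom_major, r$control_hom_major)
    }
    if ("recessive" %in% models) {
      out$recessive <- one_2x2(r, "recessive",
                               r$case_hom_minor, r$control_hom_minor,
                               r$case_hom_major + r$case_het,
                               r$control_hom_major + r$control_het)
    }
    bind_rows(out)
  })
  out <- bind_rows(rows)
  out %>%
    group_by(.data$model) %>%
    mutate(p_bonferroni = bonferroni(.data$p, m)) %>%
    ungroup()
}

# Dose-code a genotype column against snp_info: count of minor-allele copies.
genotype_dosage <- function(geno, snp_id, info = snp_info(geno)) {
  x <- geno[[snp_id]]
  if (is.null(x)) abort(paste0("SNP absent from genotypes: ", snp_id))
  if (is.numeric(x)) return(as.integer(x))
  inf <- info[info$snp_id == snp_id, , drop = FALSE]
  maj <- inf$allele_major; mnr <- inf$allele_minor
  if (is.na(mnr)) return(ifelse(is.na(x), NA_integer_, 0L))
  dplyr::case_when(
    is.na(x) ~ NA_integer_,
    x == paste0(maj, maj) ~ 0L,
    x == paste(sort(c(maj, mnr)), collapse = "") ~ 1L,
    x == paste0(mnr, mnr) ~ 2L
  )
}

# Build the analysis frame for logistic models: status, dosage, covariates.
logistic_frame <- function(geno, pheno, snp_id, covariates) {
  dose <- genotype_dosage(geno, snp_id)
  df <- tibble(individual_id = geno$individual_id, dosage = dose)
  df <- left_join(df, pheno, by = "individual_id")
  miss_cov <- setdiff(covariates, names(df))
  if (length(miss_cov) > 0L) {
    abort(paste0("covariate(s) absent from phenotype table: ",
                 paste(miss_cov, collapse = ", ")))
  }
  df <- df[stats::complete.cases(df[, c("status", "dosage", covariates)]), ]
  df
}

contrast_predictor <- function(df, contrast) {
  switch(contrast,
    additive = list(df = df, x = df$dosage),
    het = {
      keep <- df$dosage %in% c(0L, 1L)
      list(df = df[keep, ], x = as.integer(df$dosage[keep] == 1L))
    },
    hom = {
      keep <- df$dosage %in% c(0L, 2L)
      list(df = df[keep, ], x = as.integer(df$dosage[keep] == 2L))
    },
    dominant = list(df = df, x = as.integer(df$dosage >= 1L)),
    recessive = list(df = df, x = as.integer(df$dosage == 2L))
  )
}

#' Covariate-adjusted odds ratio by logistic regression
#'
#' Fits `status ~ genotype + covariates` by maximum-likelihood logistic
#' regression (IRLS via [stats::glm()]) and reports the Wald OR, 95% CI and P
#' for the genotype term. The genotype enters under a chosen contrast:
#' `"additive"` (minor-allele dosage 0/1/2), `"het"` (heterozygote vs
#' major-homozygote, dropping minor homozygotes), `"hom"`, `"dominant"` or
#' `"recessive"`. Rows with missing status, genotype or covariates are
#' dropped. Complete separation and non-convergence raise errors (exact
#' logistic methods are then advisable).
#'
#' @inheritParams count_genotypes
#' @param snp_id SNP to model.
#' @param contrast Genotype coding (see above).
#' @param covariates Character vector of phenotype columns to adjust for;
#'   `character(0)` gives the crude logistic OR.
#' @return One-row tibble: `snp_id`, `contrast`, `or`, `ci_low`, `ci_high`,
#'   `z`, `p`, `n_case`, `n_control`, `adjusted`, `covariates`.
#' @export
adjusted_or <- function(geno, pheno, snp_id, contrast = "additive",
                        covariates = c("sex", "age")) {
  contrast <- match.arg(contrast, c("additive", "het", "hom", "dominant",
                                    "recessive"))
  df <- logistic_frame(geno, pheno, snp_id, covariates)
  cp <- contrast_predictor(df, contrast)
  df <- cp$df
  df$`.g` <- cp$x
  if (sum(df$status == "case") == 0L || sum(df$status == "control") == 0L) {
    abort("need at least one case and one control after filtering")
  }
  fit_logistic_or(df, "`.g`", covariates) %>%
    mutate(snp_id = snp_id, contrast = contrast, .before = 1)
}

fit_logistic_or <- function(df, term, covariates) {
  rhs <- paste(c(term, covariates), collapse = " + ")
  form <- stats::as.formula(paste("status ~", rhs))
  fit <- suppressWarnings(glm(form, family = binomial(), data = df))
  if (!fit$converged) abort("logistic model did not converge")
  term_name <- grep("\\.g|^score$|^wgrs$", names(coef(fit)), value = TRUE)[1]
  if (is.na(term_name)) term_name <- names(coef(fit))[2]
  b <- coef(fit)[[term_name]]
  se <- sqrt(diag(vcov(fit)))[[term_name]]
  if (!is.finite(b) || !is.finite(se) || abs(b) > 15 || se > 10) {
    abort(paste0("apparent complete or quasi-complete separation for term ",
                 term_name, "; consider exact logistic methods"))
  }
  tibble(or = exp(b),
         ci_low = exp(b - qnorm(0.975) * se),
         ci_high = exp(b + qnorm(0.975) * se),
         z = b / se,
         p = 2 * pnorm(-abs(b / se)),
         n_case = sum(df$status == "case"),
         n_control = sum(df$status == "control"),
         adjusted = length(covariates) > 0L,
         covariates = paste(covariates, collapse = "+"))
}

#' Stratified case-control association for one SNP
#'
#' Reruns the 2x2 comparison within strata of a phenotype variable, reporting
#' per stratum the crude OR/CI/P (chi-square or Fisher per the
#' [allelic_test()] rule) and the sex/age-adjusted logistic OR. Stratification
#' follows the patients-vs-controls design used for clinical strata: for `sex`
#' and `age` both arms are restricted to the stratum; for `hla_b27`, `basdai`
#' and `basfi` (case-only clinical variables) cases are restricted while all
#' controls are retained in every stratum. Age is dichotomised at `age_cut`
#' (default 29), BASDAI/BASFI at `score_cut` (default 4). A stratum with zero
#' cases yields an NA row.
#'
#' @inheritParams adjusted_or
#' @param stratum_var One of `"sex"`, `"age"`, `"hla_b27"`, `"basdai"`,
#'   `"basfi"`.
#' @param age_cut,score_cut Dichotomisation cutpoints.
#' @param adjust_covariates Covariates for the adjusted OR (dropped from
#'   adjustment when identical to the stratum variable's source column).
#' @return Tibble with one row per stratum: crude `or`/`ci_low`/`ci_high`/`p`
#'   and `adj_or`/`adj_ci_low`/`adj_ci_high`/`adj_p`.
#' @export
stratified_test <- function(geno, pheno, snp_id, stratum_var,
                            contrast = "het", age_cut = 29, score_cut = 4,
                            adjust_covariates = c("sex", "age")) {
  stratum_var <- match.arg(stratum_var,
                           c("sex", "age", "hla_b27", "basdai", "basfi"))
  both_arms <- stratum_var %in% c("sex", "age")
  strata <- switch(stratum_var,
    sex = list(male = function(p) !is.na(p$sex) & p$sex == "male",
               female = function(p) !is.na(p$sex) & p$sex == "female"),
    age = setNames(list(
      function(p) !is.na(p$age) & p$age < age_cut,
      function(p) !is.na(p$age) & p$age >= age_cut
    ), c(paste0("<", age_cut), paste0(">=", age_cut))),
    hla_b27 = list(
      positive = function(p) !is.na(p$hla_b27) & p$hla_b27 == "positive",
      negative = function(p) !is.na(p$hla_b27) & p$hla_b27 == "negative"),
    setNames(list(
      function(p) !is.na(p[[stratum_var]]) & p[[stratum_var]] < score_cut,
      function(p) !is.na(p[[stratum_var]]) & p[[stratum_var]] >= score_cut
    ), c(paste0("<", score_cut), paste0(">=", score_cut)))
  )
  adj <- setdiff(adjust_covariates, if (both_arms) stratum_var else character(0))
  rows <- lapply(names(strata), function(lab) {
    in_stratum <- strata[[lab]](pheno)
    keep_id <- if (both_arms) {
      pheno$individual_id[in_stratum]
    } else {
      pheno$individual_id[(pheno$status == "case" & in_stratum) |
                          pheno$status == "control"]
    }
    ph <- pheno[pheno$individual_id %in% keep_id, ]
    gn <- geno[geno$individual_id %in% keep_id, ]
    attr(gn, "snp_info") <- snp_info(geno)
    base <- tibble(snp_id = snp_id, stratum_var = stratum_var, stratum = lab,
                   n_case = sum(ph$status == "case"),
                   n_control = sum(ph$status == "control"))
    if (base$n_case == 0L || base$n_control == 0L) {
      return(mutate(base, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    p = NA_real_, adj_or = NA_real_, adj_ci_low = NA_real_,
                    adj_ci_high = NA_real_, adj_p = NA_real_))
    }
    cts <- count_genotypes(gn, ph, snps = snp_id)
    crude <- if (contrast == "additive") {
      allelic_test(cts, m = 1)
    } else {
      filter(genotype_model_test(cts, m = 1, models = contrast),
             .data$model == contrast)
    }
    adj_row <- tryCatch(
      adjusted_or(gn, ph, snp_id, contrast = contrast, covariates = adj),
      error = function(e) tibble(or = NA_real_, ci_low = NA_real_,
                                 ci_high = NA_real_, p = NA_real_)
    )
    mutate(base, or = crude$or[1], ci_low = crude$ci_low[1],
           ci_high = crude$ci_high[1], p = crude$p[1],
           adj_or = adj_row$or[1], adj_ci_low = adj_row$ci_low[1],
           adj_ci_high = adj_row$ci_high[1], adj_p = adj_row$p[1])
  })
  bind_rows(rows)
}
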