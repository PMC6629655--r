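#' Per-SNP weights for a weighted genetic risk score
#'
#' Derives wGRS weights from allelic odds ratios: each SNP's risk allele is
#' the minor allele when its OR exceeds 1 and the major allele otherwise
#' (protective SNPs are flipped so every weight, `ln OR` of the risk allele,
#' is non-negative). The score is affine-invariant under this flip, so AUC
#' and the Mann-Whitney |Z| do not depend on the orientation choice.
#'
#' @param assoc Tibble with columns `snp_id` and `or`, typically from
#'   [allelic_test()] on the study's own data (external weights can be
#'   supplied the same way).
#' @return Tibble: `snp_id`, `or`, `risk_allele` (`"minor"`/`"major"`),
#'   `weight` (natural log of the risk-allele OR).
#' @export
wgrs_weights <- function(assoc) {
  stopifnot(all(c("snp_id", "or") %in% names(assoc)))
  ok <- !is.na(assoc$or)
  tibble(snp_id = assoc$snp_id[ok],
         or = assoc$or[ok],
         risk_allele = ifelse(assoc$or[ok] >= 1, "minor", "major"),
         weight = abs(log(assoc$or[ok])))
}

#' Compute per-individual weighted genetic risk scores
#'
#' `wGRS = sum over SNPs of (risk-allele count 0..2) x weight`, exactly.
#' Individuals missing a genotype at any scored SNP get `NA` and are listed
#' in the `"excluded"` attribute.
#'
#' @inheritParams count_genotypes
#' @param weights Tibble from [wgrs_weights()].
#' @return Tibble: `individual_id`, `wgrs`.
#' @export
compute_wgrs <- function(geno, weights) {
  missing_snps <- setdiff(weights$snp_id, snp_cols(geno))
  if (length(missing_snps) > 0L) {
    abort(paste0("weighted SNP(s) absent from genotypes: ",
                 paste(missing_snps, collapse = ", ")))
  }
  info <- snp_info(geno)
  score <- numeric(nrow(geno))
  miss <- logical(nrow(geno))
  for (i in seq_len(nrow(weights))) {
    dose <- genotype_dosage(geno, weights$snp_id[i], info)
    risk_count <- if (weights$risk_allele[i] == "minor") dose else 2L - dose
    miss <- miss | is.na(dose)
    score <- score + ifelse(is.na(risk_count), 0, risk_count) * weights$weight[i]
  }
  score[miss] <- NA_real_
  out <- tibble(individual_id = geno$individual_id, wgrs = score)
  attr(out, "excluded") <- geno$individual_id[miss]
  out
}

#' Mann-Whitney U test with tie-corrected normal approximation
#'
#' Rank-sum U (mid-ranks for ties) comparing a numeric score between the two
#' `status` groups, with the tie-corrected normal approximation for Z and a
#' two-sided P. U counts pairs where the case outranks the control (+ half
#' ties), so `U / (n_case * n_control)` is the concordance probability (AUC).
#'
#' @param data Data frame with the score and group columns.
#' @param score,group Unquoted column names; `group` must have exactly the
#'   levels `control` and `case` (factor or character).
#' @return One-row tibble: `u`, `z`, `p`, `n_case`, `n_control`,
#'   `median_case`, `iqr_case`, `median_control`, `iqr_control`.
#' @export
mann_whitney_test <- function(data, score, group = status) {
  x <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  n1 <- sum(g == "case"); n0 <- sum(g == "control")
  if (n1 == 0L || n0 == 0L) abort("both groups must be non-empty")
  r <- rank(x)  # mid-ranks
  u <- sum(r[g == "case"]) - n1 * (n1 + 1) / 2
  n <- n1 + n0
  mu <- n1 * n0 / 2
  ties <- table(x)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n0 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (v > 0) (u - mu) / sqrt(v) else 0
  p <- if (v > 0) 2 * pnorm(-abs(z)) else 1
  iqr <- function(v_) diff(quantile(v_, c(0.25, 0.75), names = FALSE))
  tibble(u = u, z = z, p = p, n_case = n1, n_control = n0,
         median_case = median(x[g == "case"]),
         iqr_case = iqr(x[g == "case"]),
         median_control = median(x[g == "control"]),
         iqr_control = iqr(x[g == "control"]))
}

#' Empirical ROC curve, AUC and Youden operating point
#'
#' Sweeps every distinct score as a threshold (score >= threshold predicts
#' case), computing sensitivity and specificity; the AUC is the tie-corrected
#' concordance probability (identical to the trapezoid area and to
#' `U / (n_case * n_control)` from [mann_whitney_test()]); its 95% CI uses
#' the Hanley-McNeil standard error. The Youden-optimal threshold maximises
#' `sensitivity + specificity - 1`, ties broken toward the lower threshold.
#' Constant scores return AUC 0.5 with `degenerate = TRUE`.
#'
#' @inheritParams mann_whitney_test
#' @return Object of class `roc_result`: list with `curve` (tibble of
#'   threshold/sensitivity/specificity), `auc`, `auc_ci_low`, `auc_ci_high`,
#'   `auc_p` (vs 0.5), `youden` (one-row tibble), `n_case`, `n_control`,
#'   `degenerate`.
#' @export
roc_analysis <- function(data, score, group = status) {
  x <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ group }}))
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  n1 <- sum(g == "case"); n0 <- sum(g == "control")
  if (n1 == 0L || n0 == 0L) abort("both groups must be non-empty")
  degenerate <- length(unique(x)) < 2L
  r <- rank(x)
  auc <- (sum(r[g == "case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thresholds <- sort(unique(x))
  curve <- tibble(
    threshold = thresholds,
    sensitivity = vapply(thresholds, function(t) mean(x[g == "case"] >= t), 0),
    specificity = vapply(thresholds, function(t) mean(x[g == "control"] < t), 0)
  )
  j <- curve$sensitivity + curve$specificity - 1
  best <- which(j == max(j))[1]  # ties -> lower threshold (sorted ascending)
  se <- hanley_mcneil_se(auc, n1, n0)
  zstat <- if (se > 0) (auc - 0.5) / se else 0
  structure(list(
    curve = curve,
    auc = if (degenerate) 0.5 else auc,
    auc_se = se,
    auc_ci_low = max(0, auc - qnorm(0.975) * se),
    auc_ci_high = min(1, auc + qnorm(0.975) * se),
    auc_p = if (degenerate) 1 else 2 * pnorm(-abs(zstat)),
    youden = curve[best, ] %>% mutate(j = j[best]),
    n_case = n1, n_control = n0, degenerate = degenerate
  ), class = "roc_result")
}

hanley_mcneil_se <- function(a, n1, n0) {
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (n1 - 1) * (q1 - a^2) + (n0 - 1) * (q2 - a^2)) /
         (n1 * n0))
}

#' Per-unit logistic odds ratio of a score
#'
#' Fits `status ~ score` by logistic regression and reports the Wald OR per
#' one-point score increase with 95% CI. The slope is invariant to constant
#' shifts of the score.
#'
#' @inheritParams mann_whitney_test
#' @return One-row tibble as [adjusted_or()] (without SNP columns).
#' @export
score_logistic <- function(data, score, group = status) {
  df <- tibble(score = dplyr::pull(data, {{ score }}),
               status = factor(as.character(dplyr::pull(data, {{ group }})),
                               levels = c("control", "case")))
  df <- df[stats::complete.cases(df), ]
  fit_logistic_or(df, "score", character(0))
}

#' Full weighted genetic risk score analysis
#'
#' One-stop wrapper: derives weights (from the data's own allelic ORs unless
#' `weights` is given), computes per-individual scores, and evaluates them by
#' Mann-Whitney U, per-unit logistic OR and ROC/AUC/Youden.
#'
#' @inheritParams count_genotypes
#' @param snps SNPs to score (default: all with a defined allelic OR).
#' @param weights Optional externally supplied [wgrs_weights()] tibble.
#' @return Object of class `wgrs_profile` with elements `weights`, `scores`
#'   (individual_id, status, wgrs), `mann_whitney`, `logistic`, `roc`.
#'   [tidy()] returns the weights, [glance()] the headline statistics,
#'   [autoplot()] the ROC curve.
#' @export
wgrs_analysis <- function(geno, pheno, snps = NULL, weights = NULL) {
  if (is.null(weights)) {
    counts <- count_genotypes(geno, pheno, snps = snps)
    weights <- wgrs_weights(allelic_test(counts))
  }
  scores <- compute_wgrs(geno, weights)
  scores <- left_join(scores, select(pheno, "individual_id", "status"),
                      by = "individual_id")
  scores <- filter(scores, !is.na(.data$wgrs), !is.na(.data$status))
  structure(list(
    weights = weights,
    scores = scores,
    mann_whitney = mann_whitney_test(scores, wgrs),
    logistic = score_logistic(scores, wgrs),
    roc = roc_analysis(scores, wgrs)
  ), class = "wgrs_profile")
}

#' @export
tidy.wgrs_profile <- function(x, ...) x$weights

#' @export
glance.wgrs_profile <- function(x, ...) {
  tibble(n_case = x$mann_whitney$n_case, n_control = x$mann_whitney$n_control,
         median_case = x$mann_whitney$median_case,
         median_control = x$mann_whitney$median_control,
         u = x$mann_whitney$u, z = x$mann_whitney$z, p_mw = x$mann_whitney$p,
         or_per_unit = x$logistic$or, or_ci_low = x$logistic$ci_low,
         or_ci_high = x$logistic$ci_high, p_logistic = x$logistic$p,
         auc = x$roc$auc, auc_ci_low = x$roc$auc_ci_low,
         auc_ci_high = x$roc$auc_ci_high, auc_p = x$roc$auc_p,
         youden_threshold = x$roc$youden$threshold,
         sensitivity = x$roc$youden$sensitivity,
         specificity = x$roc$youden$specificity)
}

#' @export
autoplot.wgrs_profile <- function(object, ...) autoplot(object$roc, ...)

#' @export
autoplot.roc_result <- function(object, ...) {
  df <- object$curve %>% arrange(dplyr::desc(.data$threshold))
  df <- dplyr::bind_rows(
    tibble(threshold = Inf, sensitivity = 0, specificity = 1), df,
    tibble(threshold = -Inf, sensitivity = 1, specificity = 0))
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::annotate("point",
                      x = 1 - object$youden$specificity,
                      y = object$youden$sensitivity, colour = "firebrick") +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC = %.3f (%.3f-%.3f)", object$auc,
                                     object$auc_ci_low, object$auc_ci_high)) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @export
print.wgrs_profile <- function(x, ...) {
  cat("Weighted genetic risk score profile\n")
  cat(sprintf("  %d SNPs scored; %d cases / %d controls\n",
              nrow(x$weights), x$mann_whitney$n_case,
              x$mann_whitney$n_control))
  cat(sprintf("  Mann-Whitney: U = %.1f, Z = %.3f, P = %.4g\n",
              x$mann_whitney$u, x$mann_whitney$z, x$mann_whitney$p))
  cat(sprintf("  Per-unit OR = %.3f (%.3f-%.3f)\n", x$logistic$or,
              x$logistic$ci_low, x$logistic$ci_high))
  cat(sprintf("  AUC = %.3f (%.3f-%.3f); Youden: sens %.3f, spec %.3f at %.4f\n",
              x$roc$auc, x$roc$auc_ci_low, x$roc$auc_ci_high,
              x$roc$youden$sensitivity, x$roc$youden$specificity,
              x$roc$youden$threshold))
  invisible(x)
}
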