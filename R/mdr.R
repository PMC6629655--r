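#' Multifactor dimensionality reduction interaction search
#'
#' Exhaustive MDR over SNP combinations: genotypes are coded 0/1/2 (count of
#' minor alleles); for each combination of size k and each cross-validation
#' fold, every k-dimensional genotype cell of the training split is labelled
#' high-risk iff its case:control ratio is at least the training split's
#' overall ratio (ties high-risk; cells empty in training are low-risk by
#' policy), and the fold's testing split is scored by balanced accuracy
#' `(sensitivity + specificity) / 2`. Per k, the combination with the best
#' mean testing balanced accuracy is reported together with its
#' cross-validation consistency (number of folds in which it was that fold's
#' best) and a permutation P from `n_perm` label permutations of the full
#' search. Folds are stratified by status and everything is seeded.
#'
#' @inheritParams count_genotypes
#' @param k_range Combination sizes to search (each at most the SNP count).
#' @param n_folds Cross-validation folds (default 10).
#' @param n_perm Label permutations for the null distribution of the best
#'   mean testing balanced accuracy (0 skips the permutation test).
#' @param seed Integer seed controlling folds and permutations.
#' @param snps Optional SNP subset.
#' @return Object of class `mdr_result`; [tidy()] gives one row per k with
#'   `snps`, `mean_train_ba`, `mean_test_ba`, `cvc`, `perm_p`.
#' @export
mdr_search <- function(geno, pheno, k_range = 1:2, n_folds = 10L,
                       n_perm = 1000L, seed = 1L, snps = NULL) {
  ids <- snps %||% snp_cols(geno)
  if (length(ids) < 2L) abort("MDR needs at least 2 SNPs")
  if (max(k_range) > length(ids)) {
    abort("k exceeds the number of SNPs available")
  }
  info <- snp_info(geno)
  dose <- vapply(ids, function(id) genotype_dosage(geno, id, info),
                 integer(nrow(geno)))
  status <- pheno$status[match(geno$individual_id, pheno$individual_id)]
  keep <- rowSums(is.na(dose)) == 0L & !is.na(status)
  dose <- dose[keep, , drop = FALSE]
  y <- status[keep] == "case"
  if (sum(y) == 0L || sum(!y) == 0L) abort("both classes must be present")
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(seed)
  folds <- stratified_folds(y, n_folds)
  perm_dist <- list()
  rows <- lapply(k_range, function(k) {
    res <- mdr_best_for_k(dose, y, k, folds, ids)
    perm_p <- NA_real_
    if (n_perm > 0L) {
      perm_ba <- vapply(seq_len(n_perm), function(b) {
        yp <- sample(y)
        fp <- stratified_folds(yp, n_folds)
        mdr_best_for_k(dose, yp, k, fp, ids)$mean_test_ba
      }, 0)
      perm_p <- (1 + sum(perm_ba >= res$mean_test_ba)) / (n_perm + 1)
      perm_dist[[as.character(k)]] <<- perm_ba
    }
    mutate(res, k = k, perm_p = perm_p, .before = 1)
  })
  structure(list(models = bind_rows(rows), n = length(y),
                 n_folds = n_folds, n_perm = n_perm, seed = seed,
                 perm_dist = perm_dist),
            class = "mdr_result")
}

# Stratified fold assignment: cases and controls are shuffled separately and
# dealt round-robin, so every fold keeps both classes.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cls in c(TRUE, FALSE)) {
    idx <- sample(which(y == cls))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

# Evaluate every k-combination across all folds; return the best by mean
# testing BA (ties -> first in combn enumeration order) with its CVC.
mdr_best_for_k <- function(dose, y, k, folds, ids) {
  combos <- utils::combn(ncol(dose), k)
  n_folds <- max(folds)
  n_combo <- ncol(combos)
  test_ba <- matrix(NA_real_, n_combo, n_folds)
  train_ba <- matrix(NA_real_, n_combo, n_folds)
  for (ci in seq_len(n_combo)) {
    cols <- combos[, ci]
    cell <- cell_index(dose[, cols, drop = FALSE])
    for (f in seq_len(n_folds)) {
      tr <- folds != f
      lab <- label_cells(cell[tr], y[tr], 3L^k)
      train_ba[ci, f] <- balanced_accuracy(lab[cell[tr]], y[tr])
      test_ba[ci, f] <- balanced_accuracy(lab[cell[!tr]], y[!tr])
    }
  }
  mean_test <- rowMeans(test_ba)
  best <- which.max(mean_test)
  fold_best <- apply(test_ba, 2, which.max)
  tibble(snps = paste(ids[combos[, best]], collapse = "+"),
         mean_train_ba = mean(train_ba[best, ]),
         mean_test_ba = mean_test[best],
         cvc = sum(fold_best == best),
         n_combos = n_combo)
}

cell_index <- function(d) {
  k <- ncol(d)
  idx <- rep(1L, nrow(d))
  for (j in seq_len(k)) idx <- idx + d[, j] * 3L^(j - 1L)
  idx
}

# High-risk labelling of genotype cells from training counts.
label_cells <- function(cell, y, n_cells) {
  case_n <- tabulate(cell[y], nbins = n_cells)
  ctrl_n <- tabulate(cell[!y], nbins = n_cells)
  thr <- sum(y) / sum(!y)
  # ratio >= threshold -> high risk; empty cells low risk; ctrl 0 & case > 0
  # -> infinite ratio -> high risk
  high <- (ctrl_n == 0 & case_n > 0) |
          (ctrl_n > 0 & case_n / ctrl_n >= thr)
  high
}

balanced_accuracy <- function(pred_case, truth) {
  sens <- if (any(truth)) mean(pred_case[truth]) else NA_real_
  spec <- if (any(!truth)) mean(!pred_case[!truth]) else NA_real_
  (sens + spec) / 2
}

#' @export
tidy.mdr_result <- function(x, ...) x$models

#' @export
glance.mdr_result <- function(x, ...) {
  best <- x$models[which.max(x$models$mean_test_ba), ]
  tibble(n = x$n, n_folds = x$n_folds, n_perm = x$n_perm,
         best_k = best$k, best_snps = best$snps,
         best_test_ba = best$mean_test_ba, best_cvc = best$cvc,
         best_perm_p = best$perm_p)
}

#' @export
autoplot.mdr_result <- function(object, ...) {
  ggplot2::ggplot(object$models,
                  ggplot2::aes(x = factor(.data$k), y = .data$mean_test_ba)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "interaction order k", y = "mean testing balanced accuracy") +
    ggplot2::theme_minimal()
}

#' @export
print.mdr_result <- function(x, ...) {
  cat(sprintf("MDR search (n = %d, %d-fold CV, %d permutations)\n",
              x$n, x$n_folds, x$n_perm))
  print(x$models)
  invisible(x)
}
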