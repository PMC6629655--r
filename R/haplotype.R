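#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard expectation-maximisation under random mating (Hardy-Weinberg at
#' the haplotype level): the E step distributes each multi-heterozygote over
#' its consistent phase pairs in proportion to current haplotype-frequency
#' products, the M step re-estimates frequencies from the expected haplotype
#' counts, iterating until the log-likelihood gain falls below `tol` or
#' `max_iter` is reached. Initialisation is the uniform distribution over all
#' `2^k` haplotypes (deterministic). Individuals with a missing call at any of
#' the `snps` are excluded (complete-case over the locus set). When `pheno`
#' is supplied the EM runs separately for cases, controls and pooled.
#'
#' The log-likelihood is non-decreasing across iterations (checked every run)
#' and at the fixed point the implied marginal allele frequencies equal the
#' sample allele frequencies.
#'
#' @inheritParams count_genotypes
#' @param snps Character vector of 2..8 SNP ids defining the locus set (order
#'   defines the haplotype labels).
#' @param pheno Optional phenotype tibble for per-group estimates.
#' @param tol Convergence tolerance on the log-likelihood gain.
#' @param max_iter Maximum EM iterations; non-convergence is flagged, not an
#'   error.
#' @param n_starts Number of EM starts. The first is always the uniform
#'   initialisation; additional starts jitter it multiplicatively (seeded) and
#'   the best final log-likelihood wins. The uniform start alone is fully
#'   deterministic but can park on a symmetric saddle of the likelihood when
#'   phase is weakly identified; a handful of jittered restarts probes for
#'   that.
#' @param seed Seed for the jittered restarts (ignored when `n_starts = 1`).
#' @return An object of class `haplo_em`: per group, haplotype frequencies,
#'   log-likelihood trace, iterations, convergence flag and the number of
#'   individuals used. Use [tidy()] for a long tibble of frequencies and
#'   [haplotype_association()] for case-control tests.
#' @export
em_haplotypes <- function(geno, snps, pheno = NULL, tol = 1e-8,
                          max_iter = 1000L, n_starts = 1L, seed = 1L) {
  k <- length(snps)
  if (k < 2L) abort("need at least 2 loci")
  if (k > 8L) abort("haplotype state space too large: at most 8 loci")
  missing_snps <- setdiff(snps, snp_cols(geno))
  if (length(missing_snps) > 0L) {
    abort(paste0("SNP(s) absent from genotypes: ",
                 paste(missing_snps, collapse = ", ")))
  }
  info <- snp_info(geno)
  dose <- vapply(snps, function(id) genotype_dosage(geno, id, info),
                 integer(nrow(geno)))
  if (is.null(dim(dose))) dose <- matrix(dose, ncol = k)
  complete <- rowSums(is.na(dose)) == 0L
  labels <- hap_labels(snps, info)
  groups <- list(pooled = rep(TRUE, nrow(geno)))
  if (!is.null(pheno)) {
    status <- pheno$status[match(geno$individual_id, pheno$individual_id)]
    groups$case <- !is.na(status) & status == "case"
    groups$control <- !is.na(status) & status == "control"
  }
  fits <- lapply(groups, function(sel) {
    em_multistart(dose[sel & complete, , drop = FALSE], k, tol, max_iter,
                  labels, n_starts, seed)
  })
  structure(list(snps = snps, labels = labels, groups = fits,
                 tol = tol, max_iter = max_iter),
            class = "haplo_em")
}

hap_labels <- function(snps, info) {
  idx <- hap_allele_matrix(length(snps))
  alle <- vapply(seq_along(snps), function(j) {
    inf <- info[info$snp_id == snps[j], ]
    mnr <- if (is.na(inf$allele_minor)) inf$allele_major else inf$allele_minor
    c(inf$allele_major, mnr)
  }, character(2))
  apply(idx, 1, function(row) {
    paste(vapply(seq_along(row), function(j) alle[row[j] + 1L, j], ""),
          collapse = "")
  })
}

em_multistart <- function(dose, k, tol, max_iter, labels, n_starts, seed) {
  H <- 2^k
  starts <- list(rep(1 / H, H))
  if (n_starts > 1L) {
    jitter <- withr_seed_safe(seed, function() {
      lapply(seq_len(n_starts - 1L), function(i) {
        f <- exp(rnorm(H, sd = 0.3)) / H
        f / sum(f)
      })
    })
    starts <- c(starts, jitter)
  }
  fits <- lapply(starts, function(f0) em_fit(dose, k, tol, max_iter, labels, f0))
  lls <- vapply(fits, function(x) ifelse(is.na(x$loglik), -Inf, x$loglik), 0)
  if (all(!is.finite(lls))) return(fits[[1]])
  fits[[which.max(lls)]]
}

# Run fn() under a temporary RNG state so EM restarts do not disturb the
# caller's random stream.
withr_seed_safe <- function(seed, fn) {
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  fn()
}

# Core EM on an n x k dosage matrix (0/1/2, no NAs). Haplotypes are bit
# vectors (1 = minor), indexed 1..2^k with locus 1 as the high bit.
em_fit <- function(dose, k, tol, max_iter, labels, f0 = NULL) {
  n <- nrow(dose)
  H <- 2^k
  if (n == 0L) {
    return(list(freq = setNames(rep(NA_real_, H), labels), n = 0L,
                loglik = NA_real_, loglik_trace = numeric(0), iterations = 0L,
                converged = FALSE))
  }
  key <- apply(dose, 1, paste, collapse = "")
  tab <- table(key)
  uniq <- do.call(rbind, strsplit(names(tab), "", fixed = TRUE))
  storage.mode(uniq) <- "integer"
  ng <- as.numeric(tab)
  pairs <- lapply(seq_len(nrow(uniq)), function(i) phase_pairs(uniq[i, ], k))
  f <- f0 %||% rep(1 / H, H)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    counts <- numeric(H)
    ll <- 0
    for (i in seq_along(pairs)) {
      pp <- pairs[[i]]
      w <- f[pp$h1] * f[pp$h2] * pp$mult
      tot <- sum(w)
      ll <- ll + ng[i] * log(tot)
      w <- w / tot
      inc <- ng[i] * w
      for (j in seq_along(inc)) {
        counts[pp$h1[j]] <- counts[pp$h1[j]] + inc[j]
        counts[pp$h2[j]] <- counts[pp$h2[j]] + inc[j]
      }
    }
    f_new <- counts / (2 * n)
    trace <- c(trace, ll)
    if (iter > 1L) {
      gain <- trace[iter] - trace[iter - 1L]
      if (gain < -1e-9) {
        abort("EM log-likelihood decreased; numerical fault")
      }
      if (gain < tol) {
        converged <- TRUE
        f <- f_new
        break
      }
    }
    f <- f_new
    if (iter >= max_iter) break
  }
  list(freq = setNames(f, labels), n = n, loglik = trace[length(trace)],
       loglik_trace = trace, iterations = iter, converged = converged)
}

# Consistent phase pairs for one multilocus genotype (dosage vector).
# Returns haplotype indices (1-based) and a multiplicity (2 for ordered
# heterozygous pairs, 1 for identical pairs).
phase_pairs <- function(g, k) {
  het <- which(g == 1L)
  base <- integer(k)
  base[g == 2L] <- 1L
  pow <- 2L^((k - 1L):0L)
  if (length(het) == 0L) {
    h <- sum(base * pow) + 1L
    return(list(h1 = h, h2 = h, mult = 1))
  }
  nh <- length(het)
  first <- het[1L]
  rest <- het[-1L]
  m <- 2L^(nh - 1L)
  h1 <- integer(m); h2 <- integer(m)
  assign_rest <- hap_allele_matrix(max(nh - 1L, 1L))
  if (nh == 1L) assign_rest <- matrix(0L, nrow = 1, ncol = 0)
  for (r in seq_len(m)) {
    a <- base; b <- base
    a[first] <- 0L; b[first] <- 1L
    if (nh > 1L) {
      bits <- assign_rest[r, ]
      a[rest] <- bits
      b[rest] <- 1L - bits
    }
    h1[r] <- sum(a * pow) + 1L
    h2[r] <- sum(b * pow) + 1L
  }
  list(h1 = h1, h2 = h2, mult = rep(2, m))
}

#' Pairwise linkage disequilibrium from two-locus haplotype frequencies
#'
#' Given the four haplotype frequencies (order: major-major, major-minor,
#' minor-major, minor-minor), computes the raw disequilibrium coefficient
#' `D = p_AB - p_A * p_B` (A, B the major alleles), Lewontin's
#' `D' = |D| / D_max` and `r^2 = D^2 / (p_A p_a p_B p_b)`. `D_max` is
#' `min(p_A p_b, p_a p_B)` for positive D and `min(p_A p_B, p_a p_b)`
#' otherwise. A monomorphic locus yields NA statistics, flagged.
#'
#' @param freqs Numeric length-4 vector summing to 1.
#' @return One-row tibble: `d`, `d_prime`, `r2`, `monomorphic`.
#' @export
ld_from_haplotypes <- function(freqs) {
  stopifnot(length(freqs) == 4L, all(freqs >= 0))
  if (abs(sum(freqs) - 1) > 1e-6) abort("haplotype frequencies must sum to 1")
  pA <- freqs[1] + freqs[2]; pB <- freqs[1] + freqs[3]
  pa <- 1 - pA; pb <- 1 - pB
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    return(tibble(d = NA_real_, d_prime = NA_real_, r2 = NA_real_,
                  monomorphic = TRUE))
  }
  d <- freqs[1] - pA * pB
  dmax <- if (d > 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (d == 0) 0 else abs(d) / dmax
  r2 <- d^2 / (pA * pa * pB * pb)
  tibble(d = d, d_prime = d_prime, r2 = r2, monomorphic = FALSE)
}

#' Pairwise D'/r-squared matrix over a SNP set
#'
#' Runs the two-locus EM on every SNP pair (pooled sample by default) and
#' evaluates [ld_from_haplotypes()] on the fitted frequencies.
#'
#' @inheritParams em_haplotypes
#' @param group `"pooled"`, `"case"` or `"control"` (the latter two need
#'   `pheno`).
#' @return Tibble with one row per pair: `snp_a`, `snp_b`, `d`, `d_prime`,
#'   `r2`.
#' @export
ld_matrix <- function(geno, snps, pheno = NULL, group = "pooled") {
  if (length(snps) < 2L) abort("need at least 2 SNPs")
  pairs <- utils::combn(snps, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    em <- em_haplotypes(geno, pairs[, i], pheno = pheno)
    f <- em$groups[[group]]$freq
    ld <- ld_from_haplotypes(as.numeric(f))
    mutate(ld, snp_a = pairs[1, i], snp_b = pairs[2, i], .before = 1)
  })
  bind_rows(rows)
}

#' Haplotype case-control association
#'
#' For each haplotype, forms the 2x2 of this-haplotype-vs-all-others expected
#' chromosome counts per group (`frequency x 2N`, fractional counts used
#' directly, Haploview-style) and reports the OR with Woolf CI and the
#' Pearson chi-square P. Haplotypes below `min_freq` pooled frequency are
#' dropped as rare; if all are rare an empty tibble is returned with a
#' warning.
#'
#' Input is either a `haplo_em` fitted with case/control groups, or a tibble
#' with columns `haplotype`, `case_freq`, `control_freq` (e.g. published
#' frequencies) plus explicit `n_case`/`n_control`.
#'
#' @param x A `haplo_em` object or a frequency tibble.
#' @param n_case,n_control Numbers of case/control individuals (chromosome
#'   counts are twice these); taken from the EM fit when `x` is a `haplo_em`.
#' @param min_freq Pooled-frequency threshold below which a haplotype is
#'   dropped.
#' @return Tibble per retained haplotype: frequencies, expected counts, `or`,
#'   `ci_low`, `ci_high`, `statistic`, `p`.
#' @export
haplotype_association <- function(x, n_case = NULL, n_control = NULL,
                                  min_freq = 0.03) {
  if (inherits(x, "haplo_em")) {
    if (!all(c("case", "control") %in% names(x$groups))) {
      abort("haplo_em was fitted without case/control groups")
    }
    freqs <- tibble(haplotype = x$labels,
                    case_freq = as.numeric(x$groups$case$freq),
                    control_freq = as.numeric(x$groups$control$freq))
    n_case <- n_case %||% x$groups$case$n
    n_control <- n_control %||% x$groups$control$n
  } else {
    freqs <- as_tibble(x)
    stopifnot(all(c("haplotype", "case_freq", "control_freq") %in% names(freqs)))
    if (is.null(n_case) || is.null(n_control)) {
      abort("supply n_case and n_control with a frequency tibble")
    }
  }
  n_chrom_case <- 2 * n_case
  n_chrom_control <- 2 * n_control
  pooled <- (freqs$case_freq * n_chrom_case +
             freqs$control_freq * n_chrom_control) /
            (n_chrom_case + n_chrom_control)
  keep <- pooled >= min_freq
  if (!any(keep)) {
    warn("all haplotypes are below the rare-haplotype threshold")
    return(tibble(haplotype = character(0)))
  }
  freqs <- freqs[keep, ]
  rows <- lapply(seq_len(nrow(freqs)), function(i) {
    a <- freqs$case_freq[i] * n_chrom_case
    b <- freqs$control_freq[i] * n_chrom_control
    c_ <- n_chrom_case - a
    d <- n_chrom_control - b
    orr <- odds_ratio(a, b, c_, d)
    tst <- two_by_k_test(rbind(c(a, c_), c(b, d)))
    tibble(haplotype = freqs$haplotype[i],
           case_freq = freqs$case_freq[i],
           control_freq = freqs$control_freq[i],
           case_count = a, control_count = b,
           or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
           statistic = tst$statistic, p = tst$p)
  })
  bind_rows(rows)
}

#' @export
tidy.haplo_em <- function(x, ...) {
  rows <- lapply(names(x$groups), function(g) {
    fit <- x$groups[[g]]
    tibble(group = g, haplotype = x$labels, frequency = as.numeric(fit$freq))
  })
  bind_rows(rows)
}

#' @export
glance.haplo_em <- function(x, ...) {
  rows <- lapply(names(x$groups), function(g) {
    fit <- x$groups[[g]]
    tibble(group = g, n = fit$n, loglik = fit$loglik,
           iterations = fit$iterations, converged = fit$converged)
  })
  bind_rows(rows)
}

#' @export
autoplot.haplo_em <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$haplotype, y = .data$frequency,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "haplotype", y = "EM frequency") +
    ggplot2::theme_minimal()
}

#' LD heatmap
#'
#' Tile plot of pairwise D' (lower-left legend) from [ld_matrix()] output.
#'
#' @param ld Tibble from [ld_matrix()].
#' @param stat Column to plot, `"d_prime"` or `"r2"`.
#' @return A ggplot object.
#' @export
plot_ld <- function(ld, stat = c("d_prime", "r2")) {
  stat <- arg_match(stat)
  ggplot2::ggplot(ld, ggplot2::aes(x = .data$snp_a, y = .data$snp_b,
                                   fill = .data[[stat]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data[[stat]])),
                       colour = "white") +
    ggplot2::scale_fill_gradient(limits = c(0, 1), low = "grey85",
                                 high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = stat) +
    ggplot2::theme_minimal()
}
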