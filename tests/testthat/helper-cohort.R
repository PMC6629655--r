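# Builders shared across test files. Everything is generated in code; no
# binary fixtures.

toy_geno <- function(calls, snp_ids = names(calls),
                     ids = sprintf("P%03d", seq_len(length(calls[[1]])))) {
  df <- tibble::tibble(individual_id = ids)
  for (i in seq_along(calls)) df[[snp_ids[i]]] <- calls[[i]]
  candgene:::validate_genotypes(df)
}

toy_pheno <- function(status, ids = sprintf("P%03d", seq_along(status)), ...) {
  tibble::tibble(individual_id = ids,
                 status = factor(status, levels = c("control", "case")), ...)
}

# One-SNP case-control cohort config with no LD and fixed covariates.
one_snp_config <- function(maf, or, n_cases, n_controls, seed,
                           snp_id = "rs0001", alleles = c("C", "T"), ...) {
  cohort_config(
    snps = tibble::tibble(snp_id = snp_id, gene = "GENE",
                          allele_major = alleles[1], allele_minor = alleles[2],
                          maf = maf, or = or),
    n_cases = n_cases, n_controls = n_controls, seed = seed, ...
  )
}

# Direct two-locus genotype-class log-likelihood under random mating, used as
# an EM-independent oracle. `n9` is the 3x3 genotype count table flattened
# with dosage of locus 1 slow (g1 in 0:2, g2 in 0:2), f = (AB, Ab, aB, ab).
loglik_2locus <- function(n9, f) {
  p <- c(
    f[1]^2,                 # g1=0,g2=0
    2 * f[1] * f[2],        # 0,1
    f[2]^2,                 # 0,2
    2 * f[1] * f[3],        # 1,0
    2 * f[1] * f[4] + 2 * f[2] * f[3],  # 1,1
    2 * f[2] * f[4],        # 1,2
    f[3]^2,                 # 2,0
    2 * f[3] * f[4],        # 2,1
    f[4]^2                  # 2,2
  )
  keep <- n9 > 0
  if (any(p[keep] <= 0)) return(-Inf)
  sum(n9[keep] * log(p[keep]))
}

# Genotype-class counts (length 9, locus 1 slow) from a 2-column dosage matrix.
counts9 <- function(dose) {
  idx <- dose[, 1] * 3 + dose[, 2] + 1
  tabulate(idx, nbins = 9)
}

# Grid search over the 4-haplotype simplex with the given step; returns the
# maximum log-likelihood. Independent oracle for the 2-locus EM.
grid_max_loglik <- function(n9, step = 0.02) {
  m <- round(1 / step)
  best <- -Inf
  for (i in 0:m) for (j in 0:(m - i)) {
    kk <- 0:(m - i - j)
    f1 <- i / m; f2 <- j / m; f3 <- kk / m; f4 <- 1 - f1 - f2 - f3
    for (t in seq_along(kk)) {
      ll <- loglik_2locus(n9, c(f1, f2, f3[t], f4[t]))
      if (ll > best) best <- ll
    }
  }
  best
}

# Multilocus genotype log-likelihood by exhaustive enumeration of ordered
# haplotype pairs; independent oracle for k-locus EM (small k).
loglik_klocus <- function(dose, f) {
  k <- ncol(dose)
  H <- 2^k
  bits <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  ll <- 0
  for (i in seq_len(nrow(dose))) {
    g <- dose[i, ]
    p <- 0
    for (h1 in 1:H) for (h2 in 1:H) {
      if (all(bits[h1, ] + bits[h2, ] == g)) p <- p + f[h1] * f[h2]
    }
    if (p <= 0) return(-Inf)
    ll <- ll + log(p)
  }
  ll
}

# Random dosage panel with guaranteed polymorphism at each locus.
random_panel <- function(n, k, seed) {
  set.seed(seed)
  repeat {
    dose <- matrix(rbinom(n * k, 2, runif(k, 0.15, 0.5)[rep(1:k, each = n)]),
                   nrow = n)
    if (all(colSums(dose) > 0) && all(colSums(2 - dose) > 0)) return(dose)
  }
}

dosage_tibble <- function(dose, snp_ids = paste0("rs", seq_len(ncol(dose)))) {
  colnames(dose) <- snp_ids
  out <- dplyr::bind_cols(
    tibble::tibble(individual_id = sprintf("I%04d", seq_len(nrow(dose)))),
    tibble::as_tibble(dose))
  attr(out, "snp_info") <- tibble::tibble(
    snp_id = snp_ids, gene = "GENE", allele_major = "A", allele_minor = "G")
  out
}
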