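#' Build a synthetic-cohort configuration
#'
#' Defines the generative model for a case-control SNP cohort: control
#' genotypes in Hardy-Weinberg equilibrium at stated minor-allele
#' frequencies; case genotypes under a multiplicative (allele-level) risk
#' model with stated per-SNP allelic odds ratios; optional within-gene
#' linkage-disequilibrium blocks specified as haplotype frequency vectors;
#' and covariates (sex, age, HLA-B27, BASDAI, BASFI) drawn independently of
#' genotype unless a confounding knob is set.
#'
#' For a block over k SNPs, `haplotypes` is a length-`2^k` frequency vector in
#' lexicographic allele order with the first SNP slowest and the major allele
#' before the minor (two SNPs: major-major, major-minor, minor-major,
#' minor-minor). Block marginals must equal the member SNPs' `maf` to 1e-9.
#' Case haplotype frequencies are obtained by iterative proportional fitting
#' of a multiplicative tilt so every member SNP hits its target case allele
#' frequency exactly, preserving the block's association structure.
#'
#' @param snps Tibble with columns `snp_id`, `gene`, `allele_major`,
#'   `allele_minor`, `maf` (control minor-allele frequency in (0, 0.5]),
#'   `or` (allelic odds ratio, > 0).
#' @param n_cases,n_controls Arm sizes.
#' @param seed Integer seed; fully determines the cohort.
#' @param ld_blocks List of blocks, each `list(snp_ids = c(...), haplotypes =
#'   c(...))`.
#' @param covariates List with elements `male_frac_case`, `male_frac_control`,
#'   `age_mean_case`, `age_sd_case`, `age_mean_control`, `age_sd_control`,
#'   `hla_b27_pos_frac_case`, `basdai_shape`, `basdai_scale`, `basfi_shape`,
#'   `basfi_scale`.
#' @param confounding Optional `list(snp_id =, sex_log_or =)`: shifts that
#'   SNP's allele frequency on the logit scale for males in both arms, so a
#'   case-control imbalance in sex confounds the crude OR.
#' @return A validated object of class `cohort_config`.
#' @seealso [simulate_cohort()], [tnfaip3_panel_config()]
#' @export
cohort_config <- function(snps, n_cases, n_controls, seed,
                          ld_blocks = list(), covariates = default_covariates(),
                          confounding = NULL) {
  snps <- as_tibble(snps)
  req <- c("snp_id", "gene", "allele_major", "allele_minor", "maf", "or")
  if (!all(req %in% names(snps))) {
    abort(paste0("snps needs columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(snps$snp_id)) abort("duplicate snp_id in panel")
  if (any(snps$maf <= 0 | snps$maf > 0.5)) abort("maf must lie in (0, 0.5]")
  if (any(snps$or <= 0)) abort("or must be positive")
  q_case <- case_allele_freq(snps$maf, snps$or)
  if (any(q_case <= 0 | q_case >= 1)) {
    abort("or forces a case allele frequency outside (0, 1)")
  }
  blocked <- character(0)
  for (b in ld_blocks) {
    if (!all(c("snp_ids", "haplotypes") %in% names(b))) {
      abort("each ld_block needs snp_ids and haplotypes")
    }
    k <- length(b$snp_ids)
    if (length(b$haplotypes) != 2^k) {
      abort(paste0("block over ", k, " SNPs needs ", 2^k,
                   " haplotype frequencies"))
    }
    if (abs(sum(b$haplotypes) - 1) > 1e-9 || any(b$haplotypes < 0)) {
      abort("block haplotype frequencies must be non-negative and sum to 1")
    }
    if (!all(b$snp_ids %in% snps$snp_id)) {
      abort("ld_block references SNP(s) not in the panel")
    }
    if (any(b$snp_ids %in% blocked)) abort("SNP in more than one ld_block")
    blocked <- c(blocked, b$snp_ids)
    marg <- block_marginals(b$haplotypes, k)
    target <- snps$maf[match(b$snp_ids, snps$snp_id)]
    if (any(abs(marg - target) > 1e-9)) {
      abort(paste0("block marginal MAFs (", paste(signif(marg, 8), collapse = ", "),
                   ") inconsistent with the member SNPs' maf"))
    }
  }
  structure(list(snps = snps, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), seed = as.integer(seed),
                 ld_blocks = ld_blocks, covariates = covariates,
                 confounding = confounding),
            class = "cohort_config")
}

case_allele_freq <- function(q, or) or * q / (1 - q + or * q)

# Minor-allele marginal frequencies of a 2^k haplotype vector (first SNP
# slowest, major allele first).
block_marginals <- function(freqs, k) {
  idx <- hap_allele_matrix(k)
  as.numeric(crossprod(idx, freqs))
}

# 2^k x k matrix; entry 1 when haplotype carries the minor allele at locus j.
hap_allele_matrix <- function(k) {
  m <- as.matrix(expand.grid(rep(list(0:1), k))[, k:1, drop = FALSE])
  colnames(m) <- NULL
  m
}

default_covariates <- function() {
  list(male_frac_case = 542 / 667, male_frac_control = 559 / 667,
       age_mean_case = 28.47, age_sd_case = 9.08,
       age_mean_control = 28.88, age_sd_control = 7.68,
       hla_b27_pos_frac_case = 412 / 667,
       basdai_shape = 1.3, basdai_scale = 2.0,
       basfi_shape = 0.8, basfi_scale = 1.8)
}

#' Ready-made nine-SNP TNFAIP3/TNIP1 panel configuration
#'
#' A [cohort_config()] emulating the published ankylosing spondylitis
#' candidate-gene study design: 667 cases / 667 controls; five TNFAIP3 SNPs
#' and four TNIP1 SNPs at the published control minor-allele frequencies and
#' allelic odds ratios; two TNFAIP3 LD pairs (rs13207033-rs10499194,
#' rs2230926-rs610604) and the TNIP1 triple (rs4958881-rs3792783-rs6889239)
#' with haplotype frequencies consistent with the published control haplotype
#' distribution (high D', modest r-squared). rs2233287, whose minor allele
#' was absent from the published controls, is given control MAF 2/1334 with
#' OR 2.5 so its expected case frequency matches the published case carrier
#' count.
#'
#' @param n_cases,n_controls Arm sizes (default 667/667).
#' @param seed Integer seed.
#' @return A `cohort_config`.
#' @export
tnfaip3_panel_config <- function(n_cases = 667, n_controls = 667, seed = 1L) {
  snps <- tibble(
    snp_id = c("rs610604", "rs10499194", "rs13207033", "rs2230926",
               "rs6920220", "rs2233287", "rs4958881", "rs3792783",
               "rs6889239"),
    gene = c(rep("TNFAIP3", 5), rep("TNIP1", 4)),
    allele_major = c("T", "C", "G", "T", "G", "G", "T", "A", "C"),
    allele_minor = c("G", "T", "A", "G", "A", "A", "C", "G", "T"),
    maf = c(122, 79, 161, 55, 5, 2, 114, 304, 334) / 1334,
    or = c(0.982, 0.619, 0.807, 0.831, 1.402, 2.5, 0.952, 1.000, 0.976)
  )
  # Haplotype order: (major,major), (major,minor), (minor,major), (minor,minor)
  b1 <- list(snp_ids = c("rs13207033", "rs10499194"),
             haplotypes = c(1 - 161 / 1334 - 79 / 1334 + 0.058,  # GC
                            79 / 1334 - 0.058,                    # GT
                            161 / 1334 - 0.058,                   # AC
                            0.058))                               # AT
  b2 <- list(snp_ids = c("rs2230926", "rs610604"),
             haplotypes = c(1 - 122 / 1334 - 0.041,               # TT
                            122 / 1334 - (55 / 1334 - 0.041),     # TG
                            0.041,                                # GT
                            55 / 1334 - 0.041))                   # GG
  # TNIP1 triple: support {TAC, TAT, TGC, CGC} per the published control
  # haplotypes, scaled so the marginals equal the control MAFs exactly.
  cgc <- 114 / 1334; tgc <- 304 / 1334 - cgc; tat <- 334 / 1334
  tac <- 1 - cgc - tgc - tat
  h3 <- numeric(8)
  h3[1] <- tac  # 000 TAC
  h3[2] <- tat  # 001 TAT
  h3[3] <- tgc  # 010 TGC
  h3[7] <- cgc  # 110 CGC
  b3 <- list(snp_ids = c("rs4958881", "rs3792783", "rs6889239"),
             haplotypes = h3)
  cohort_config(snps, n_cases, n_controls, seed,
                ld_blocks = list(b1, b2, b3))
}

# Iterative proportional fitting of a multiplicative tilt of `freqs` whose
# minor-allele marginals equal `target`; preserves the haplotype interaction
# structure (zeros stay zero).
ipf_tilt <- function(freqs, target, tol = 1e-12, max_iter = 10000L) {
  k <- length(target)
  idx <- hap_allele_matrix(k)
  g <- freqs
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      mj <- sum(g[idx[, j] == 1])
      if (mj <= 0 || mj >= 1) {
        abort("ld_block marginals unreachable under the case risk model")
      }
      g[idx[, j] == 1] <- g[idx[, j] == 1] * target[j] / mj
      g[idx[, j] == 0] <- g[idx[, j] == 0] * (1 - target[j]) / (1 - mj)
    }
    if (max(abs(block_marginals(g, k) - target)) < tol) return(g / sum(g))
  }
  abort("IPF for case haplotype frequencies did not converge")
}

#' Simulate a case-control SNP cohort
#'
#' Draws a cohort from a [cohort_config()]: control genotypes under HWE at the
#' stated MAFs (LD-block SNPs: two haplotypes per individual from the block's
#' haplotype distribution, then paired); case genotypes from the case
#' distribution implied by the multiplicative allele-level risk model (case
#' allele frequency `or*q / (1 - q + or*q)`; block case haplotype frequencies
#' by IPF tilt); covariates from the configured distributions (controls'
#' HLA-B27/BASDAI/BASFI are left missing, as for typical healthy volunteers).
#' Everything is reproducible from `config$seed`.
#'
#' @param config A `cohort_config`.
#' @param format `"calls"` for character genotypes (`"CT"`, ...), `"dosage"`
#'   for integer minor-allele counts (fast path for large simulations).
#' @return `list(genotypes = <tibble>, phenotypes = <tibble>)`; the genotype
#'   tibble carries the panel as its `"snp_info"` attribute.
#' @export
simulate_cohort <- function(config, format = c("calls", "dosage")) {
  stopifnot(inherits(config, "cohort_config"))
  format <- arg_match(format)
  snps <- config$snps
  n1 <- config$n_cases; n0 <- config$n_controls; n <- n1 + n0
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
          add = TRUE)
  set.seed(config$seed)

  status <- factor(rep(c("case", "control"), c(n1, n0)),
                   levels = c("control", "case"))
  sex <- draw_sex(config, status)
  dose <- matrix(NA_integer_, nrow = n, ncol = nrow(snps),
                 dimnames = list(NULL, snps$snp_id))
  blocked <- unlist(lapply(config$ld_blocks, `[[`, "snp_ids"))
  q_case <- case_allele_freq(snps$maf, snps$or)

  for (j in seq_len(nrow(snps))) {
    id <- snps$snp_id[j]
    if (id %in% blocked) next
    q <- ifelse(status == "case", q_case[j], snps$maf[j])
    q <- apply_confounding(q, id, sex, config)
    dose[, j] <- rbinom(n, 2L, q)
  }
  for (b in config$ld_blocks) {
    k <- length(b$snp_ids)
    jj <- match(b$snp_ids, snps$snp_id)
    g_case <- ipf_tilt(b$haplotypes, case_allele_freq(snps$maf[jj], snps$or[jj]))
    idx <- hap_allele_matrix(k)
    draw_block <- function(m, freqs) {
      h1 <- sample.int(2^k, m, replace = TRUE, prob = freqs)
      h2 <- sample.int(2^k, m, replace = TRUE, prob = freqs)
      idx[h1, , drop = FALSE] + idx[h2, , drop = FALSE]
    }
    dose[status == "case", jj] <- draw_block(n1, g_case)
    dose[status == "control", jj] <- draw_block(n0, b$haplotypes)
  }

  individual_id <- sprintf("S%04d", seq_len(n))
  pheno <- draw_phenotypes(config, status, sex, individual_id)
  geno <- build_geno_tibble(dose, snps, individual_id, format)
  list(genotypes = geno, phenotypes = pheno)
}

draw_sex <- function(config, status) {
  cv <- config$covariates
  pm <- ifelse(status == "case", cv$male_frac_case, cv$male_frac_control)
  factor(ifelse(runif(length(status)) < pm, "male", "female"),
         levels = c("male", "female"))
}

apply_confounding <- function(q, id, sex, config) {
  cf <- config$confounding
  if (is.null(cf) || !identical(cf$snp_id, id)) return(q)
  logit <- log(q / (1 - q)) + ifelse(sex == "male", cf$sex_log_or, 0)
  1 / (1 + exp(-logit))
}

draw_phenotypes <- function(config, status, sex, individual_id) {
  cv <- config$covariates
  n <- length(status)
  is_case <- status == "case"
  age <- rnorm(n,
               mean = ifelse(is_case, cv$age_mean_case, cv$age_mean_control),
               sd = ifelse(is_case, cv$age_sd_case, cv$age_sd_control))
  age <- round(pmin(pmax(age, 16), 75), 1)
  hla <- rep(NA_character_, n)
  hla[is_case] <- ifelse(runif(sum(is_case)) < cv$hla_b27_pos_frac_case,
                         "positive", "negative")
  basdai <- rep(NA_real_, n)
  basdai[is_case] <- round(pmin(rgamma(sum(is_case), shape = cv$basdai_shape,
                                       scale = cv$basdai_scale), 10), 1)
  basfi <- rep(NA_real_, n)
  basfi[is_case] <- round(pmin(rgamma(sum(is_case), shape = cv$basfi_shape,
                                      scale = cv$basfi_scale), 10), 1)
  tibble(individual_id = individual_id, status = status, sex = sex, age = age,
         hla_b27 = factor(hla, levels = c("negative", "positive")),
         basdai = basdai, basfi = basfi)
}

build_geno_tibble <- function(dose, snps, individual_id, format) {
  if (format == "dosage") {
    out <- dplyr::bind_cols(tibble(individual_id = individual_id),
                            as_tibble(dose))
  } else {
    calls <- vapply(seq_len(nrow(snps)), function(j) {
      maj <- snps$allele_major[j]; mnr <- snps$allele_minor[j]
      het <- paste(sort(c(maj, mnr)), collapse = "")
      c(paste0(maj, maj), het, paste0(mnr, mnr))[dose[, j] + 1L]
    }, character(nrow(dose)))
    if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(dose))
    colnames(calls) <- snps$snp_id
    out <- dplyr::bind_cols(tibble(individual_id = individual_id),
                            as_tibble(calls))
  }
  attr(out, "snp_info") <- select(snps, "snp_id", "gene", "allele_major",
                                  "allele_minor")
  out
}
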