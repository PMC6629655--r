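#' Tabulate per-SNP genotype and allele counts by case-control group
#'
#' Joins genotypes to phenotypes on `individual_id` and counts, per SNP and
#' per group, the three genotype classes (major homozygote, heterozygote,
#' minor homozygote) and the two allele classes, excluding missing calls per
#' SNP (complete-case per SNP; no imputation). Genotype classes are oriented
#' so that "minor" is the minor allele in the pooled case+control sample, a
#' frequency tie breaking toward the lexicographically smaller base.
#'
#' Genotype columns may be character calls (`"CT"`) or integer minor-allele
#' dosages 0/1/2 (as produced by [simulate_cohort()] with
#' `format = "dosage"`); dosage input requires the `"snp_info"` attribute for
#' allele labels.
#'
#' @param geno Genotype tibble (see [read_genotypes()]).
#' @param pheno Phenotype tibble (see [read_phenotypes()]); every genotyped
#'   individual must appear in it.
#' @param snps Optional character vector restricting/ordering the SNPs.
#' @return A tibble with one row per SNP and columns `snp_id`, `allele_major`,
#'   `allele_minor`, and per group (`case_`/`control_` prefixes) `hom_major`,
#'   `het`, `hom_minor`, `n_missing`, `major`, `minor` (allele counts).
#'   Conservation holds by construction: `minor = 2*hom_minor + het`.
#' @export
count_genotypes <- function(geno, pheno, snps = NULL) {
  stopifnot(is.data.frame(geno), is.data.frame(pheno))
  ids <- snp_cols(geno)
  if (!is.null(snps)) {
    missing_snps <- setdiff(snps, ids)
    if (length(missing_snps) > 0L) {
      abort(paste0("SNP(s) absent from genotypes: ",
                   paste(missing_snps, collapse = ", ")))
    }
    ids <- snps
  }
  unmatched <- setdiff(geno$individual_id, pheno$individual_id)
  if (length(unmatched) > 0L) {
    abort(paste0("genotyped individual(s) absent from phenotype table: ",
                 paste(head(unmatched, 10L), collapse = ", "),
                 if (length(unmatched) > 10L) ", ..." else ""))
  }
  status <- pheno$status[match(geno$individual_id, pheno$individual_id)]
  info <- snp_info(geno)
  is_dosage <- vapply(ids, function(id) is.numeric(geno[[id]]), TRUE)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    inf <- info[info$snp_id == id, , drop = FALSE]
    if (nrow(inf) == 0L) abort(paste0("no snp_info for ", id))
    if (is_dosage[i]) {
      count_one_dosage(geno[[id]], status, inf)
    } else {
      count_one_calls(geno[[id]], status, inf)
    }
  })
  bind_rows(rows)
}

count_one_dosage <- function(dose, status, inf) {
  if (is.na(inf$allele_minor)) {
    # monomorphic: every non-missing dosage must be 0
    stopifnot(all(dose[!is.na(dose)] == 0))
  }
  per_group <- function(g) {
    d <- dose[status == g]
    c(hom_major = sum(d == 0, na.rm = TRUE),
      het = sum(d == 1, na.rm = TRUE),
      hom_minor = sum(d == 2, na.rm = TRUE),
      n_missing = sum(is.na(d)))
  }
  assemble_counts(inf, per_group("case"), per_group("control"))
}

count_one_calls <- function(calls, status, inf) {
  maj <- inf$allele_major
  mnr <- inf$allele_minor
  hom_major_call <- paste0(maj, maj)
  het_call <- if (!is.na(mnr)) paste(sort(c(maj, mnr)), collapse = "") else NA
  hom_minor_call <- if (!is.na(mnr)) paste0(mnr, mnr) else NA
  per_group <- function(g) {
    x <- calls[status == g]
    c(hom_major = sum(x == hom_major_call, na.rm = TRUE),
      het = if (is.na(het_call)) 0L else sum(x == het_call, na.rm = TRUE),
      hom_minor = if (is.na(hom_minor_call)) 0L else
        sum(x == hom_minor_call, na.rm = TRUE),
      n_missing = sum(is.na(x)))
  }
  assemble_counts(inf, per_group("case"), per_group("control"))
}

assemble_counts <- function(inf, cs, ct) {
  tibble(
    snp_id = inf$snp_id,
    gene = if ("gene" %in% names(inf)) inf$gene else NA_character_,
    allele_major = inf$allele_major,
    allele_minor = inf$allele_minor,
    case_hom_major = cs[["hom_major"]], case_het = cs[["het"]],
    case_hom_minor = cs[["hom_minor"]], case_n_missing = cs[["n_missing"]],
    control_hom_major = ct[["hom_major"]], control_het = ct[["het"]],
    control_hom_minor = ct[["hom_minor"]], control_n_missing = ct[["n_missing"]],
    case_major = 2L * cs[["hom_major"]] + cs[["het"]],
    case_minor = 2L * cs[["hom_minor"]] + cs[["het"]],
    control_major = 2L * ct[["hom_major"]] + ct[["het"]],
    control_minor = 2L * ct[["hom_minor"]] + ct[["het"]]
  )
}

#' Published nine-SNP TNFAIP3/TNIP1 panel genotype counts
#'
#' Genotype counts by case-control group for five TNFAIP3 SNPs and four TNIP1
#' SNPs from a published ankylosing spondylitis candidate-gene study
#' (667 cases / 667 controls of Eastern Chinese Han ancestry). This
#' counts-only fixture drives the association stages without individual-level
#' data; stages needing individual genotypes (EM haplotypes, wGRS, MDR) cannot
#' run from it.
#'
#' @return A counts tibble in the [count_genotypes()] layout.
#' @export
published_panel_counts <- function() {
  path <- system.file("extdata", "tnfaip3_tnip1_counts.tsv",
                      package = "candgene", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = "c", gene = "c", allele_major = "c", allele_minor = "c",
    .default = "i"), progress = FALSE)
  mutate(raw,
    case_major = 2L * .data$case_hom_major + .data$case_het,
    case_minor = 2L * .data$case_hom_minor + .data$case_het,
    control_major = 2L * .data$control_hom_major + .data$control_het,
    control_minor = 2L * .data$control_hom_minor + .data$control_het
  )
}
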