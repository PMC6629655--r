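#' Run the full candidate-gene association analysis
#'
#' Orchestrates every stage over one cohort and writes the report files:
#' cohort description (`table1.tsv`), per-SNP HWE + allelic association
#' (`table2.tsv`), genetic models (`models.tsv`), stratified analysis
#' (`table3.tsv`), haplotype frequencies/association (`table4.tsv`), pairwise
#' LD (`ld.tsv`), risk-score summary (`grs_summary.json`), MDR models
#' (`mdr.tsv`) and a machine-readable run manifest (`run.json`). Every stage
#' is individually skippable; any stage error aborts with the stage name
#' after writing the manifest of completed stages.
#'
#' The cohort comes from exactly one of three sources in `config`:
#' `genotypes`+`phenotypes` (paths or tibbles), `simulate` (a
#' [cohort_config()]), or `counts` (a counts tibble, a TSV path in the
#' [count_genotypes()] layout, or `"published"` for the bundled panel
#' fixture). Counts-only input supports only the HWE/association/model
#' stages; stages needing individual-level data (stratified, haplotype, GRS,
#' MDR) then refuse with a clear message.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure. Recognised fields: `genotypes`, `phenotypes`, `simulate`,
#'   `counts`, `stages` (default all), `bonferroni_m` (default the SNP
#'   count), `blocks` (list of SNP-id vectors for the haplotype stage),
#'   `stratify` (list with `snp_id`, `vars`), `wgrs_snps`, `mdr` (list with
#'   `k_range`, `n_folds`, `n_perm`), `seed`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a named list with every stage's tibble plus the run
#'   manifest.
#' @export
run_full_analysis <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||%
    c("table1", "assoc", "models", "stratified", "haplo", "grs", "mdr")
  results <- list()
  manifest <- list(package = "candgene",
                   version = as.character(utils::packageVersion("candgene")),
                   seed = config$seed, stages = stages,
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  done <- character(0)
  fail <- function(stage, err) {
    manifest$completed <- done
    manifest$failed_stage <- stage
    jsonlite::write_json(manifest, file.path(out_dir, "run.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    abort(paste0("stage `", stage, "` failed: ", conditionMessage(err)))
  }
  run_stage <- function(stage, expr) {
    if (!stage %in% stages) return(invisible(NULL))
    res <- tryCatch(expr, error = function(e) fail(stage, e))
    done <<- c(done, stage)
    res
  }

  src <- load_cohort(config)
  counts_only <- is.null(src$genotypes)
  need_individuals <- function(stage) {
    abort(paste0("stage `", stage,
                 "` needs individual-level genotypes; counts-only input ",
                 "supports only the association stages"))
  }
  counts <- src$counts %||% count_genotypes(src$genotypes, src$phenotypes)
  m <- config$bonferroni_m %||% nrow(counts)

  results$table1 <- run_stage("table1", {
    t1 <- cohort_description(src)
    readr::write_tsv(t1, file.path(out_dir, "table1.tsv"), progress = FALSE)
    t1
  })
  results$table2 <- run_stage("assoc", {
    t2 <- left_join(allelic_test(counts, m = m),
                    select(hwe_test(counts, "control"), "snp_id", "p_hwe"),
                    by = "snp_id")
    readr::write_tsv(t2, file.path(out_dir, "table2.tsv"), progress = FALSE)
    t2
  })
  results$models <- run_stage("models", {
    mod <- genotype_model_test(counts, m = m)
    readr::write_tsv(mod, file.path(out_dir, "models.tsv"), progress = FALSE)
    mod
  })
  results$table3 <- run_stage("stratified", {
    if (counts_only) need_individuals("stratified")
    sc <- config$stratify %||% list()
    snp <- sc$snp_id %||% counts$snp_id[which.min(
      allelic_test(counts, m = m)$p)]
    vars <- sc$vars %||% c("sex", "age", "hla_b27", "basdai", "basfi")
    t3 <- bind_rows(lapply(vars, function(v) {
      stratified_test(src$genotypes, src$phenotypes, snp, v)
    }))
    readr::write_tsv(t3, file.path(out_dir, "table3.tsv"), progress = FALSE)
    t3
  })
  haplo_stage <- run_stage("haplo", {
    if (counts_only) need_individuals("haplo")
    blocks <- config$blocks %||% list()
    t4 <- list(); ld <- list()
    for (b in blocks) {
      em <- em_haplotypes(src$genotypes, b, pheno = src$phenotypes)
      t4[[paste(b, collapse = "-")]] <- haplotype_association(em) %>%
        mutate(block = paste(b, collapse = "-"), .before = 1)
      ld[[paste(b, collapse = "-")]] <- ld_matrix(src$genotypes, b,
                                                  pheno = src$phenotypes)
    }
    t4 <- bind_rows(t4); ld <- bind_rows(ld)
    readr::write_tsv(t4, file.path(out_dir, "table4.tsv"), progress = FALSE)
    readr::write_tsv(ld, file.path(out_dir, "ld.tsv"), progress = FALSE)
    list(table4 = t4, ld = ld)
  })
  if (!is.null(haplo_stage)) {
    results$table4 <- haplo_stage$table4
    results$ld <- haplo_stage$ld
  }
  results$grs <- run_stage("grs", {
    if (counts_only) need_individuals("grs")
    prof <- wgrs_analysis(src$genotypes, src$phenotypes,
                          snps = config$wgrs_snps)
    readr::write_tsv(prof$scores, file.path(out_dir, "grs.tsv"),
                     progress = FALSE)
    jsonlite::write_json(as.list(glance(prof)),
                         file.path(out_dir, "grs_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    prof
  })
  results$mdr <- run_stage("mdr", {
    if (counts_only) need_individuals("mdr")
    mc <- config$mdr %||% list()
    fit <- mdr_search(src$genotypes, src$phenotypes,
                      k_range = mc$k_range %||% 1:2,
                      n_folds = mc$n_folds %||% 10L,
                      n_perm = mc$n_perm %||% 1000L,
                      seed = config$seed %||% 1L)
    readr::write_tsv(tidy(fit), file.path(out_dir, "mdr.tsv"),
                     progress = FALSE)
    fit
  })
  manifest$completed <- done
  jsonlite::write_json(manifest, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

load_cohort <- function(config) {
  sources <- c(!is.null(config$counts),
               !is.null(config$simulate),
               !is.null(config$genotypes))
  if (sum(sources) != 1L) {
    abort("config must name exactly one of counts, simulate, genotypes(+phenotypes)")
  }
  if (!is.null(config$counts)) {
    cts <- config$counts
    if (identical(cts, "published")) cts <- published_panel_counts()
    if (is.character(cts)) {
      cts <- readr::read_tsv(cts, col_types = readr::cols(
        snp_id = "c", gene = "c", allele_major = "c", allele_minor = "c",
        .default = "i"), progress = FALSE)
      cts <- mutate(cts,
        case_major = 2L * .data$case_hom_major + .data$case_het,
        case_minor = 2L * .data$case_hom_minor + .data$case_het,
        control_major = 2L * .data$control_hom_major + .data$control_het,
        control_minor = 2L * .data$control_hom_minor + .data$control_het)
    }
    return(list(counts = as_tibble(cts)))
  }
  if (!is.null(config$simulate)) {
    cfg <- config$simulate
    if (!inherits(cfg, "cohort_config")) {
      abort("config$simulate must be a cohort_config object")
    }
    sim <- simulate_cohort(cfg)
    return(list(genotypes = sim$genotypes, phenotypes = sim$phenotypes))
  }
  geno <- config$genotypes
  pheno <- config$phenotypes
  if (is.null(pheno)) abort("genotypes input needs phenotypes too")
  if (is.character(geno)) geno <- read_genotypes(geno)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  list(genotypes = geno, phenotypes = pheno)
}

cohort_description <- function(src) {
  if (is.null(src$phenotypes)) {
    cts <- src$counts
    n_case <- max(cts$case_hom_major + cts$case_het + cts$case_hom_minor +
                    cts$case_n_missing)
    n_control <- max(cts$control_hom_major + cts$control_het +
                       cts$control_hom_minor + cts$control_n_missing)
    return(tibble(characteristic = c("n_case", "n_control"),
                  case = c(n_case, NA), control = c(NA, n_control)))
  }
  p <- src$phenotypes
  by_group <- function(f) {
    c(case = f(p[p$status == "case", ]), control = f(p[p$status == "control", ]))
  }
  fmt <- function(v) {
    tibble(case = v[["case"]], control = v[["control"]])
  }
  rows <- list(
    n = by_group(nrow),
    male = if ("sex" %in% names(p))
      by_group(function(d) sum(d$sex == "male", na.rm = TRUE)),
    age_mean = if ("age" %in% names(p))
      by_group(function(d) mean(d$age, na.rm = TRUE)),
    age_sd = if ("age" %in% names(p))
      by_group(function(d) sd(d$age, na.rm = TRUE)),
    hla_b27_positive = if ("hla_b27" %in% names(p))
      by_group(function(d) sum(d$hla_b27 == "positive", na.rm = TRUE)),
    basdai_median = if ("basdai" %in% names(p))
      by_group(function(d) median(d$basdai, na.rm = TRUE)),
    basfi_median = if ("basfi" %in% names(p))
      by_group(function(d) median(d$basfi, na.rm = TRUE))
  )
  rows <- rows[!vapply(rows, is.null, TRUE)]
  bind_rows(lapply(names(rows), function(nm) {
    mutate(fmt(rows[[nm]]), characteristic = nm, .before = 1)
  }))
}
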