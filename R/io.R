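#' Read an unphased biallelic genotype matrix
#'
#' Reads genotype calls for a panel of biallelic SNPs into a tibble with one
#' row per individual and one column per SNP. Two dialects are supported:
#'
#' * `"tsv"` — a tab-separated file whose header row holds rsIDs (first column
#'   `individual_id`), with cells like `"CT"`, `"CC"`; `"NN"`, `"00"`, `"--"`
#'   or an empty cell mark a missing call.
#' * `"pedmap"` — a white-space separated PLINK-style PED file (six leading
#'   columns, then two allele columns per SNP, `0` = missing) together with the
#'   matching MAP file naming the SNPs. Only biallelic autosomal rows with
#'   base-letter alleles are accepted.
#'
#' Calls are stored order-free: `"TC"` and `"CT"` are the same heterozygote and
#' both are normalised to the alphabetically sorted string `"CT"`. Row and
#' column order follow the file. Per-SNP alleles are inferred from the observed
#' calls unless a `snp_info` sidecar is supplied; observing more than two
#' alleles at a SNP is an error.
#'
#' @param path Path to the genotype TSV (or the PED file for `format =
#'   "pedmap"`).
#' @param format `"tsv"` or `"pedmap"`.
#' @param map_path Path to the MAP file (required for `"pedmap"`).
#' @param snp_info Optional tibble with columns `snp_id`, `allele_major`,
#'   `allele_minor` (and optionally `gene`, `chrom`, `bp`) declaring the panel;
#'   calls are validated against it.
#' @return A tibble with column `individual_id` followed by one character
#'   column per SNP; the panel description is attached as attribute
#'   `"snp_info"` (see [snp_info()]).
#' @seealso [read_phenotypes()], [count_genotypes()], [write_genotypes()]
#' @export
read_genotypes <- function(path, format = c("tsv", "pedmap"), map_path = NULL,
                           snp_info = NULL) {
  format <- arg_match(format)
  if (!file.exists(path)) abort(paste0("genotype file not found: ", path))
  geno <- switch(format,
    tsv = read_genotypes_tsv(path),
    pedmap = read_genotypes_pedmap(path, map_path)
  )
  validate_genotypes(geno, snp_info = snp_info)
}

read_genotypes_tsv <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) {
    abort("genotype TSV needs an ID column plus >= 1 SNP column")
  }
  check_ragged(path, length(header))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  names(raw)[1] <- "individual_id"
  raw
}

check_ragged <- function(path, expected) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != expected)
  if (length(bad) > 0L) {
    abort(paste0("ragged genotype file: line ", bad[1], " has ", nfield[bad[1]],
                 " fields, expected ", expected))
  }
  invisible(TRUE)
}

read_genotypes_pedmap <- function(ped_path, map_path) {
  if (is.null(map_path)) abort("format = \"pedmap\" requires `map_path`")
  if (!file.exists(map_path)) abort(paste0("MAP file not found: ", map_path))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) < 4L) abort("MAP file must have 4 columns: chrom, snp_id, cM, bp")
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "bp")
  ped <- utils::read.table(ped_path, header = FALSE, colClasses = "character")
  n_snp <- nrow(map)
  if (ncol(ped) != 6L + 2L * n_snp) {
    abort(paste0("PED has ", ncol(ped), " columns; MAP implies ",
                 6L + 2L * n_snp))
  }
  calls <- vapply(seq_len(n_snp), function(j) {
    a1 <- ped[[6L + 2L * j - 1L]]
    a2 <- ped[[6L + 2L * j]]
    bad <- !(a1 %in% c("A", "C", "G", "T", "0")) |
           !(a2 %in% c("A", "C", "G", "T", "0"))
    if (any(bad)) {
      abort(paste0("PED: non-base allele code at SNP ", map$snp_id[j],
                   " (only A/C/G/T and 0 accepted)"))
    }
    miss <- a1 == "0" | a2 == "0"
    out <- normalise_call(paste0(a1, a2))
    out[miss] <- NA_character_
    out
  }, character(nrow(ped)))
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = nrow(ped))
  colnames(calls) <- map$snp_id
  dplyr::bind_cols(tibble(individual_id = ped[[2]]), as_tibble(calls))
}

MISSING_CODES <- c("NN", "00", "--", "", "NA", "..")

normalise_call <- function(x) {
  x <- toupper(trimws(x))
  x[x %in% MISSING_CODES] <- NA_character_
  ok <- !is.na(x)
  split <- strsplit(x[ok], "", fixed = TRUE)
  bad <- lengths(split) != 2L
  if (any(bad)) {
    abort(paste0("malformed genotype call(s): ",
                 paste(unique(x[ok][bad]), collapse = ", ")))
  }
  x[ok] <- vapply(split, function(a) paste(sort(a), collapse = ""), "")
  x
}

#' @rdname read_genotypes
#' @param geno A genotype tibble as returned by [read_genotypes()].
#' @export
snp_info <- function(geno) {
  info <- attr(geno, "snp_info", exact = TRUE)
  if (is.null(info)) info <- infer_snp_info(geno)
  info
}

snp_cols <- function(geno) setdiff(names(geno), "individual_id")

#' Infer per-SNP major/minor alleles from observed calls
#'
#' The minor allele is the rarer allele in the pooled sample; frequency ties
#' break toward the lexicographically smaller base being minor. Monomorphic
#' SNPs get `allele_minor = NA`.
#' @noRd
infer_snp_info <- function(geno) {
  ids <- snp_cols(geno)
  rows <- lapply(ids, function(id) {
    alle <- unlist(strsplit(geno[[id]][!is.na(geno[[id]])], "", fixed = TRUE))
    if (length(alle) == 0L) {
      return(tibble(snp_id = id, allele_major = NA_character_,
                    allele_minor = NA_character_))
    }
    tab <- sort(table(alle))
    if (length(tab) > 2L) {
      abort(paste0(">2 alleles observed at ", id, ": {",
                   paste(sort(names(tab)), collapse = ","), "}"))
    }
    if (length(tab) == 1L) {
      return(tibble(snp_id = id, allele_major = names(tab),
                    allele_minor = NA_character_))
    }
    nm <- names(tab)
    if (tab[[1]] == tab[[2]]) nm <- sort(nm)  # tie: smaller base is minor
    tibble(snp_id = id, allele_major = nm[2], allele_minor = nm[1])
  })
  bind_rows(rows)
}

validate_genotypes <- function(geno, snp_info = NULL) {
  stopifnot(is.data.frame(geno), "individual_id" %in% names(geno))
  if (anyDuplicated(geno$individual_id)) {
    abort(paste0("duplicate individual_id in genotype file: ",
                 paste(unique(geno$individual_id[duplicated(geno$individual_id)]),
                       collapse = ", ")))
  }
  for (id in snp_cols(geno)) {
    geno[[id]] <- normalise_call(geno[[id]])
  }
  inferred <- infer_snp_info(geno)   # errors on >2 alleles
  if (!is.null(snp_info)) {
    req <- c("snp_id", "allele_major", "allele_minor")
    if (!all(req %in% names(snp_info))) {
      abort("snp_info sidecar needs columns snp_id, allele_major, allele_minor")
    }
    missing_snps <- setdiff(snp_cols(geno), snp_info$snp_id)
    if (length(missing_snps) > 0L) {
      abort(paste0("snp_info lacks rows for: ", paste(missing_snps, collapse = ", ")))
    }
    info <- as_tibble(snp_info)[match(snp_cols(geno), snp_info$snp_id), ]
    for (j in seq_len(nrow(info))) {
      declared <- c(info$allele_major[j], info$allele_minor[j])
      seen <- stats::na.omit(c(inferred$allele_major[j], inferred$allele_minor[j]))
      extra <- setdiff(seen, declared)
      if (length(extra) > 0L) {
        abort(paste0("calls at ", info$snp_id[j], " use allele(s) ",
                     paste(extra, collapse = ","),
                     " not among declared {", paste(declared, collapse = ","), "}"))
      }
    }
    attr(geno, "snp_info") <- info
  } else {
    attr(geno, "snp_info") <- inferred
  }
  geno
}

#' Write a genotype matrix to the package TSV dialect
#'
#' Missing calls are written as `NN`. `write_genotypes()` followed by
#' [read_genotypes()] round-trips calls and ordering exactly.
#'
#' @param geno Genotype tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- geno
  for (id in snp_cols(out)) out[[id]][is.na(out[[id]])] <- "NN"
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with mandatory columns `individual_id` and `status`
#' (`case`/`control`, case-insensitive) and optional `sex` (`male`/`female`),
#' `age` (years), `hla_b27` (`positive`/`negative`; empty = unknown), `basdai`
#' and `basfi` (Bath AS disease-activity and functional indices, each on the
#' 0-10 scale; out-of-range values are rejected). Clinical fields may be
#' missing, typically for controls.
#'
#' @param path Path to the phenotype TSV.
#' @return A typed tibble; `status`, `sex` and `hla_b27` become factors with
#'   levels `control`/`case`, `male`/`female`, `negative`/`positive`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(paste0("phenotype file not found: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  validate_phenotypes(raw)
}

validate_phenotypes <- function(raw) {
  if (!all(c("individual_id", "status") %in% names(raw))) {
    abort("phenotype table needs columns individual_id and status")
  }
  if (anyDuplicated(raw$individual_id)) {
    abort(paste0("duplicate individual_id in phenotype table: ",
                 paste(unique(raw$individual_id[duplicated(raw$individual_id)]),
                       collapse = ", ")))
  }
  status <- tolower(trimws(as.character(raw$status)))
  if (anyNA(status) || any(!status %in% c("case", "control"))) {
    bad <- unique(raw$status[is.na(status) | !status %in% c("case", "control")])
    abort(paste0("status must be case/control for every individual; got: ",
                 paste(bad, collapse = ", ")))
  }
  out <- tibble(
    individual_id = as.character(raw$individual_id),
    status = factor(status, levels = c("control", "case"))
  )
  if ("sex" %in% names(raw)) {
    sex <- tolower(trimws(as.character(raw$sex)))
    sex[sex %in% c("", "na")] <- NA
    if (any(!is.na(sex) & !sex %in% c("male", "female"))) {
      abort("sex must be male/female (or missing)")
    }
    out$sex <- factor(sex, levels = c("male", "female"))
  }
  if ("age" %in% names(raw)) out$age <- as.numeric(raw$age)
  if ("hla_b27" %in% names(raw)) {
    h <- tolower(trimws(as.character(raw$hla_b27)))
    h[h %in% c("", "na", "unknown")] <- NA
    if (any(!is.na(h) & !h %in% c("positive", "negative"))) {
      abort("hla_b27 must be positive/negative (or missing)")
    }
    out$hla_b27 <- factor(h, levels = c("negative", "positive"))
  }
  for (col in c("basdai", "basfi")) {
    if (col %in% names(raw)) {
      v <- as.numeric(raw[[col]])
      bad <- !is.na(v) & (v < 0 | v > 10)
      if (any(bad)) {
        abort(paste0(col, " out of the 0-10 scale for individual(s): ",
                     paste(out$individual_id[bad], collapse = ", ")))
      }
      out[[col]] <- v
    }
  }
  out
}
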