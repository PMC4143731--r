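#' Read genotype dosages from VCF or a TSV dosage matrix
#'
#' VCF: only the GT field is used; the dosage is the count of alternate
#' alleles (`0/0` -> 0, `0/1` or `1/0` -> 1, `1/1` -> 2; any missing allele
#' -> `NA`). Multi-allelic sites are skipped with a warning. Parsing is
#' delegated to `VariantAnnotation::readVcf`.
#'
#' TSV: rows are SNPs and columns individuals; the first column holds SNP
#' ids, cells are 0/1/2 or `NA`.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"tsv"`.
#' @return Integer matrix SNPs x individuals with dimnames.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_tsv(path)
}

read_genotypes_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("VCF input needs the VariantAnnotation package", call. = FALSE)
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field", call. = FALSE)
  alt <- VariantAnnotation::alt(vcf)
  multi <- lengths(alt) > 1L
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
    gt <- gt[!multi, , drop = FALSE]
  }
  dos <- gt_to_dosage(gt)
  rownames(dos) <- rownames(gt)
  colnames(dos) <- colnames(gt)
  dos
}

# "0/0"->0, "0/1"/"1/0"->1, "1/1"->2; any '.' allele or ploidy != 2 -> NA
gt_to_dosage <- function(gt) {
  map <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L,
           "0|1" = 1L, "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  dos <- map[gt]
  dim(dos) <- dim(gt)
  bad <- !is.na(gt) & !gt %in% c(names(map), ".", "./.", ".|.",
                                 "0/.", "./0", "1/.", "./1",
                                 "0|.", ".|0", "1|.", ".|1")
  if (any(bad))
    stop("unparseable GT value(s), e.g. '", gt[bad][1L], "'", call. = FALSE)
  dos
}

read_genotypes_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = 1L))
  if (ncol(dt) < 2L)
    stop("dosage TSV needs an id column plus individuals", call. = FALSE)
  ids <- dt[[1L]]
  m <- as.matrix(dt[, -1L])
  if (!all(m[!is.na(m)] %in% 0:2))
    stop("dosage TSV cells must be 0, 1, 2 or NA", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a dosage matrix as TSV
#'
#' @param geno integer matrix SNPs x individuals.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(geno, path) {
  dt <- data.table::data.table(snp_id = rownames(geno))
  dt <- cbind(dt, data.table::as.data.table(geno))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a covariate/phenotype table
#'
#' Expects a TSV with (by default) columns `ID`, `SEX`, `SMOKE`, `AGE`,
#' `PEDIGREE`, `HTN`; the mapping is configurable. Rows with a missing
#' outcome are dropped with a message.
#'
#' @param path file path.
#' @param col_map named character vector mapping internal names (`id`,
#'   `sex`, `smoke`, `age`, `pedigree`, `outcome`) to file columns.
#' @return A [cohort_table].
#' @export
read_covariates <- function(path,
                            col_map = c(id = "ID", sex = "SEX",
                                        smoke = "SMOKE", age = "AGE",
                                        pedigree = "PEDIGREE",
                                        outcome = "HTN")) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  miss <- setdiff(col_map, names(dt))
  if (length(miss))
    stop("covariate file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(dt)[, col_map]
  names(df) <- names(col_map)
  if (!is.numeric(df$age))
    stop("non-numeric AGE values in covariate file", call. = FALSE)
  cohort_table(df)
}

#' Write a cohort table as covariate TSV
#'
#' @param cohort a [cohort_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates <- function(cohort, path) {
  out <- data.frame(ID = cohort$id, SEX = cohort$sex, SMOKE = cohort$smoke,
                    AGE = cohort$age, PEDIGREE = as.character(cohort$pedigree),
                    HTN = cohort$outcome)
  data.table::fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a run configuration (YAML)
#'
#' @param path YAML file with keys among: `genotypes`, `covariates`,
#'   `strategies`, `age_cutoff`, `n0`, `s_pct`, `i_pct`, `k`,
#'   `ce_keep`, `be_upper`, `ce_lower`, `permutations`, `seed`, `out_dir`.
#' @return Named list of configuration values merged over defaults.
#' @export
read_run_config <- function(path) {
  defaults <- list(strategies = c("NO_ATTR", "SEX", "SMOKE", "AGE",
                                  "PEDIGREE", "ALL_ATTR"),
                   age_cutoff = 60, n0 = 10, s_pct = 15, i_pct = 15,
                   k = 0.45,
                   ce_keep = list(SEX = 0.8, SMOKE = 0.8, AGE = 0.8,
                                  PEDIGREE = 0.4),
                   permutations = 99, seed = 1, out_dir = ".")
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  utils::modifyList(defaults, cfg)
}
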