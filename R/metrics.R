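#' Per-SNP entropy metrics under one or more blocking strategies
#'
#' Computes, for every SNP (row of the dosage matrix), the block entropy,
#' entropy gains and consistency entropy of the main genotype under each
#' requested blocking strategy. This is the workhorse behind both the
#' selection rules and the command-line `compute` subcommand; it is fully
#' vectorised across SNPs.
#'
#' @param geno integer matrix of dosages, SNPs x individuals (rownames =
#'   SNP ids, colnames = individual ids); `NA` = missing call (excluded per
#'   SNP).
#' @param cohort a [cohort_table]; individuals are matched to `geno`
#'   columns by id.
#' @param strategies character vector of strategy labels (see
#'   [build_partition()]); default the six used on the real data.
#' @param age_cutoff,n0 see [partition_by_attribute()] and
#'   [standardized_proportions()].
#' @param gains if `TRUE` also report entropy gains I and II per strategy.
#' @return A data.frame with one row per SNP: `snp_id`, then per strategy
#'   `BE_<s>`, `CE_<s>`, `MG_<s>` (main genotype) and optionally
#'   `GA1_<s>`, `GA2_<s>`.
#' @examples
#' sim <- simulate_cohort_data(sim_config(n_individuals = 60, n_snps = 5,
#'                                        seed = 1))
#' compute_snp_metrics(sim$genotypes, sim$cohort,
#'                     strategies = c("NO_ATTR", "SEX"))
#' @export
compute_snp_metrics <- function(geno, cohort,
                                strategies = c("NO_ATTR", "SEX", "SMOKE",
                                               "AGE", "PEDIGREE", "ALL_ATTR"),
                                age_cutoff = 60, n0 = 10, gains = FALSE) {
  cohort <- stopifnot_cohort(cohort)
  geno <- align_genotypes(geno, cohort)
  out <- data.frame(snp_id = rownames(geno), row.names = NULL)
  for (s in strategies) {
    p <- build_partition(cohort, s, age_cutoff)
    es <- entropy_stats_matrix(geno, cohort$outcome, p$block)
    out[[paste0("BE_", s)]] <- es$be
    if (gains) {
      out[[paste0("GA1_", s)]] <- es$gain1
      out[[paste0("GA2_", s)]] <- es$gain2
    }
    cs <- consistency_matrix(geno, cohort$outcome, p$block, n0 = n0)
    out[[paste0("CE_", s)]] <- cs$ce
    out[[paste0("MG_", s)]] <- cs$main_genotype
  }
  out
}

align_genotypes <- function(geno, cohort) {
  if (!is.matrix(geno))
    stop("'geno' must be a SNPs x individuals matrix", call. = FALSE)
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("snp_%05d", seq_len(nrow(geno)))
  if (!is.null(colnames(geno))) {
    missing <- setdiff(cohort$id, colnames(geno))
    if (length(missing))
      stop(length(missing), " cohort individual(s) absent from the ",
           "genotype matrix (first: ", missing[1L], ")", call. = FALSE)
    geno <- geno[, cohort$id, drop = FALSE]
  } else if (ncol(geno) != nrow(cohort)) {
    stop("unnamed genotype columns do not align with the cohort",
         call. = FALSE)
  }
  geno
}
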