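#' Permute the outcome of a cohort
#'
#' Shuffles outcome labels uniformly at random, leaving covariates and
#' genotypes untouched — the null in which the outcome is unrelated to
#' genotype. With `within_blocks = TRUE` labels are shuffled only inside
#' the blocks of `partition`, preserving each block's outcome count
#' \eqn{q_i} (useful when pedigree structure confounds a global null).
#'
#' @param cohort a [cohort_table].
#' @param within_blocks logical; permute within blocks of `partition`.
#' @param partition a `block_partition`, required when `within_blocks`.
#' @return The cohort with a permuted `outcome` column. Deterministic given
#'   the RNG state; seed with `set.seed()` or pass `seed` to the callers.
#' @export
permute_outcome <- function(cohort, within_blocks = FALSE, partition = NULL) {
  cohort <- stopifnot_cohort(cohort)
  if (within_blocks) {
    if (is.null(partition))
      stop("within-block permutation needs a partition", call. = FALSE)
    for (lev in levels(partition$block)) {
      idx <- which(partition$block == lev)
      cohort$outcome[idx] <- cohort$outcome[sample(idx)]
    }
  } else {
    cohort$outcome <- cohort$outcome[sample.int(nrow(cohort))]
  }
  cohort
}

#' Permutation p-values for per-SNP entropy statistics
#'
#' Recomputes the chosen statistic under `B` outcome permutations and
#' reports, per SNP, a one-sided p-value with the add-one convention
#' \eqn{p = (1 + \#\{\mathrm{null\ at\ least\ as\ extreme}\})/(B + 1)}.
#' For block entropy, small values are extreme (low entropy = informative);
#' for the gains, large values are extreme.
#'
#' @inheritParams compute_snp_metrics
#' @param strategy a blocking-strategy label (see [build_partition()]).
#' @param statistic one of `"be"`, `"gain1"`, `"gain2"`.
#' @param B number of permutations, at least 19.
#' @param seed integer seed; the run is bit-reproducible given it.
#' @param within_blocks permute within blocks instead of globally.
#' @return data.frame: `snp_id`, `observed`, `p_value`, `B`, `scheme`, with
#'   the null statistic matrix (SNPs x B) in attribute `"null_values"`.
#' @export
permutation_pvalues <- function(geno, cohort, strategy = "ALL_ATTR",
                                statistic = c("be", "gain1", "gain2"),
                                B = 99, seed = 1, age_cutoff = 60,
                                within_blocks = FALSE) {
  statistic <- match.arg(statistic)
  if (B < 19) stop("'B' must be at least 19", call. = FALSE)
  cohort <- stopifnot_cohort(cohort)
  geno <- align_genotypes(geno, cohort)
  p <- build_partition(cohort, strategy, age_cutoff)
  stat <- function(y) entropy_stats_matrix(geno, y, p$block)[[statistic]]
  observed <- stat(cohort$outcome)
  null_values <- matrix(NA_real_, nrow(geno), B)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (b in seq_len(B)) {
    perm <- permute_outcome(cohort, within_blocks = within_blocks,
                            partition = p)
    null_values[, b] <- stat(perm$outcome)
  }
  extreme <- if (statistic == "be") null_values <= observed
             else null_values >= observed
  pv <- (1 + rowSums(extreme)) / (B + 1)
  structure(
    data.frame(snp_id = rownames(geno), statistic = statistic,
               observed = observed, p_value = pv, B = B,
               scheme = if (within_blocks) "within_block" else "global",
               row.names = NULL),
    null_values = null_values
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
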