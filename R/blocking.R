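#' Block partitions of a cohort
#'
#' The screening method stratifies individuals into disjoint blocks sharing
#' covariate values and computes entropies within blocks. Six strategies
#' are supported:
#'
#' * `NO_ATTR` — all individuals in a single block;
#' * `SEX`, `SMOKE` — one block per covariate value;
#' * `AGE` — two blocks, age below / at-or-above `age_cutoff`;
#' * `PEDIGREE` — one block per pedigree;
#' * `ALL_ATTR` — occupied cells of the sex x smoke x age-band x pedigree
#'   cross-product;
#' * any custom cross-product via `partition_cross()` (e.g. sex x smoke x
#'   age band, the "SSA" blocking of the simulated-data evaluation).
#'
#' Empty blocks are dropped; block order is deterministic (sorted by
#' covariate values), so downstream output is reproducible.
#'
#' @param cohort a [cohort_table] (or coercible data.frame).
#' @param attr one of `"SEX"`, `"SMOKE"`, `"AGE"`, `"PEDIGREE"`.
#' @param attrs character vector of attributes to cross (subset of the
#'   above, for `partition_cross`).
#' @param age_cutoff years; individuals with `age >= age_cutoff` form the
#'   upper age block. Default 60.
#' @return A `block_partition`: list with `strategy` (label), `block`
#'   (factor of block membership aligned with `cohort$id`), `ids`, and `m`
#'   (number of non-empty blocks).
#' @examples
#' coh <- cohort_table(data.frame(id = letters[1:4], sex = c(1, 1, 2, 2),
#'                                smoke = c(0, 1, 0, 1), age = c(40, 70, 55, 65),
#'                                pedigree = "P1", outcome = c(0, 1, 0, 1)))
#' partition_by_attribute(coh, "AGE")$m  # 2
#' partition_all_attr(coh)$m             # 4
#' @name blocking
NULL

new_partition <- function(strategy, block, ids) {
  block <- droplevels(as.factor(block))
  structure(list(strategy = strategy, block = block, ids = ids,
                 m = nlevels(block)),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> strategy %s: %d block(s) over %d individuals\n",
              x$strategy, x$m, length(x$ids)))
  print(table(x$block))
  invisible(x)
}

#' @rdname blocking
#' @export
partition_no_attr <- function(cohort) {
  cohort <- stopifnot_cohort(cohort)
  new_partition("NO_ATTR", rep("all", nrow(cohort)), cohort$id)
}

#' @rdname blocking
#' @export
partition_by_attribute <- function(cohort, attr, age_cutoff = 60) {
  cohort <- stopifnot_cohort(cohort)
  attr <- match.arg(toupper(attr), c("SEX", "SMOKE", "AGE", "PEDIGREE"))
  key <- attr_key(cohort, attr, age_cutoff)
  if (anyNA(key))
    stop("missing values in covariate used by strategy ", attr, call. = FALSE)
  new_partition(attr, key, cohort$id)
}

#' @rdname blocking
#' @export
partition_all_attr <- function(cohort, age_cutoff = 60) {
  p <- partition_cross(cohort, c("SEX", "SMOKE", "AGE", "PEDIGREE"),
                       age_cutoff = age_cutoff)
  p$strategy <- "ALL_ATTR"
  p
}

#' @rdname blocking
#' @export
partition_cross <- function(cohort, attrs, age_cutoff = 60) {
  cohort <- stopifnot_cohort(cohort)
  attrs <- match.arg(toupper(attrs), c("SEX", "SMOKE", "AGE", "PEDIGREE"),
                     several.ok = TRUE)
  keys <- lapply(attrs, function(a) attr_key(cohort, a, age_cutoff))
  if (anyNA(unlist(keys)))
    stop("missing values in covariates used by cross-product blocking",
         call. = FALSE)
  key <- do.call(paste, c(keys, sep = "|"))
  block <- factor(key, levels = sort(unique(key)))
  new_partition(paste(attrs, collapse = "x"), block, cohort$id)
}

attr_key <- function(cohort, attr, age_cutoff) {
  switch(attr,
    SEX      = paste0("sex", cohort$sex),
    SMOKE    = paste0("smoke", cohort$smoke),
    AGE      = ifelse(cohort$age < age_cutoff,
                      paste0("age<", age_cutoff), paste0("age>=", age_cutoff)),
    PEDIGREE = paste0("ped", as.character(cohort$pedigree)))
}

#' Build a partition for a named strategy
#'
#' Convenience dispatcher mapping a strategy label to its partition
#' constructor. `"SSA"` is the sex x smoke x age cross-product used in the
#' simulated-phenotype evaluation.
#'
#' @inheritParams blocking
#' @param strategy one of `"NO_ATTR"`, `"SEX"`, `"SMOKE"`, `"AGE"`,
#'   `"PEDIGREE"`, `"ALL_ATTR"`, `"SSA"`.
#' @return A `block_partition`.
#' @export
build_partition <- function(cohort, strategy, age_cutoff = 60) {
  strategy <- match.arg(toupper(strategy),
                        c("NO_ATTR", "SEX", "SMOKE", "AGE", "PEDIGREE",
                          "ALL_ATTR", "SSA"))
  switch(strategy,
    NO_ATTR  = partition_no_attr(cohort),
    ALL_ATTR = partition_all_attr(cohort, age_cutoff),
    SSA      = { p <- partition_cross(cohort, c("SEX", "SMOKE", "AGE"),
                                      age_cutoff)
                 p$strategy <- "SSA"; p },
    partition_by_attribute(cohort, strategy, age_cutoff))
}

#' Tabulate one SNP into a count table
#'
#' Cross-tabulates a dosage vector against a block partition and the
#' outcome, producing the [count_table] the entropy statistics consume.
#' Individuals with a missing dosage are excluded from this SNP only
#' (complete case per SNP); blocks emptied by the exclusion are dropped.
#'
#' @param dosage named integer vector of 0/1/2 dosages (names = individual
#'   ids) or an unnamed vector aligned with `cohort$id`; `NA` = missing.
#' @param cohort a [cohort_table].
#' @param partition a `block_partition` built from the same cohort.
#' @return A [count_table]; error if no individual has a genotype call.
#' @examples
#' coh <- cohort_table(data.frame(id = letters[1:4], sex = 1, smoke = 0,
#'                                age = 50, pedigree = "P1",
#'                                outcome = c(1, 0, 0, 0)))
#' tabulate_counts(c(a = 0, b = 0, c = 1, d = 1), coh, partition_no_attr(coh))
#' @export
tabulate_counts <- function(dosage, cohort, partition) {
  cohort <- stopifnot_cohort(cohort)
  if (!inherits(partition, "block_partition"))
    stop("'partition' must be a block_partition", call. = FALSE)
  if (!is.null(names(dosage))) dosage <- dosage[cohort$id]
  if (length(dosage) != nrow(cohort))
    stop("dosage vector does not align with the cohort", call. = FALSE)
  keep <- !is.na(dosage)
  if (!any(keep))
    stop("no individuals with a genotype call for this SNP", call. = FALSE)
  if (any(!dosage[keep] %in% 0:2))
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  blk <- droplevels(partition$block[keep])
  g <- factor(dosage[keep], levels = 0:2)
  n <- table(blk, g)
  q <- table(blk[cohort$outcome[keep] == 1], g[cohort$outcome[keep] == 1])
  count_table(unclass(n), unclass(q))
}
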