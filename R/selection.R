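#' Rank SNPs by block entropy and split into sensitive / insensitive sets
#'
#' Orders block entropies ascending and returns the upper `s_pct`% of SNPs
#' (lowest entropy: association with the outcome is modified by the
#' covariates — the "sensitive" candidates) and the lower `i_pct`% (highest
#' entropy: insensitive to the covariates). Ties break by SNP id.
#'
#' @param be named numeric vector of block entropies (names = SNP ids).
#' @param s_pct,i_pct percentages in (0, 100); the sets have
#'   `ceiling(s_pct * N / 100)` and `ceiling(i_pct * N / 100)` members.
#' @return List with `sensitive` and `insensitive` character vectors of SNP
#'   ids (in ascending / descending entropy order respectively).
#' @export
rank_partition <- function(be, s_pct = 15, i_pct = 15) {
  if (!length(be)) stop("'be' is empty", call. = FALSE)
  if (s_pct <= 0 || s_pct >= 100 || i_pct <= 0 || i_pct >= 100)
    stop("'s_pct' and 'i_pct' must lie in (0, 100)", call. = FALSE)
  ids <- names(be) %||% as.character(seq_along(be))
  ord <- order(be, ids)
  n_s <- ceiling(s_pct * length(be) / 100)
  n_i <- ceiling(i_pct * length(be) / 100)
  if (n_s + n_i > length(be))
    warning("sensitive and insensitive sets overlap (s_pct + i_pct too ",
            "large for N = ", length(be), ")")
  list(sensitive = ids[ord][seq_len(n_s)],
       insensitive = ids[rev(ord)][seq_len(n_i)])
}

#' Block-entropy threshold VBE
#'
#' `VBE = BEmin + k * (BEmax - BEmin)`: the selection bound interpolated
#' between the smallest and largest block entropy observed for a strategy.
#' `k = 0.45` matches the value used on chromosome 9; 0.5-0.7 was used on
#' chromosome 3.
#'
#' @param be numeric vector of block entropies.
#' @param k interpolation factor in \[0, 1\].
#' @return The threshold value.
#' @export
vbe_threshold <- function(be, k = 0.45) {
  if (!length(be)) stop("'be' is empty", call. = FALSE)
  if (k < 0 || k > 1) stop("'k' must lie in [0, 1]", call. = FALSE)
  rng <- range(be, na.rm = TRUE)
  rng[1L] + k * (rng[2L] - rng[1L])
}

#' Consistency-entropy threshold VCE
#'
#' The `(1 - keep_fraction)` empirical quantile of the consistency-entropy
#' distribution, so that approximately `keep_fraction` of SNPs satisfy
#' `CE > VCE`. Missing CEs are excluded from the quantile (and always fail
#' the rule).
#'
#' @param ce numeric vector of consistency entropies (may contain `NA`).
#' @param keep_fraction fraction of SNPs to keep, in (0, 1\]; e.g. 0.8
#'   removes around 20% of inconsistent SNPs, 0.4 keeps around 40%.
#' @return The threshold value.
#' @export
vce_threshold <- function(ce, keep_fraction = 0.8) {
  ce <- ce[!is.na(ce)]
  if (!length(ce)) stop("all consistency entropies are missing", call. = FALSE)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("'keep_fraction' must lie in (0, 1]", call. = FALSE)
  unname(stats::quantile(ce, probs = 1 - keep_fraction, type = 7))
}

#' Selection rule: BE upper bounds and CE lower bounds
#'
#' A conjunction of strict constraints `BE_<strategy> < be_upper` and
#' `CE_<strategy> > ce_lower`, as in rule sets like
#' `BE_ALL_ATTR < 0.36 & CE_PEDIGREE > 0.29 & CE_SEX > 0.9`. Thresholds
#' can be given directly (fixed mode) or derived with [vbe_threshold()] /
#' [vce_threshold()].
#'
#' @param be_upper named numeric vector: strategy label -> BE upper bound.
#' @param ce_lower named numeric vector: strategy label -> CE lower bound.
#' @return A `selection_rule` object.
#' @export
selection_rule <- function(be_upper = numeric(), ce_lower = numeric()) {
  if (length(be_upper) && is.null(names(be_upper)))
    stop("'be_upper' must be named by strategy", call. = FALSE)
  if (length(ce_lower) && is.null(names(ce_lower)))
    stop("'ce_lower' must be named by strategy", call. = FALSE)
  structure(list(be_upper = be_upper, ce_lower = ce_lower),
            class = "selection_rule")
}

#' Apply a selection rule to a metrics table
#'
#' A SNP is selected iff every `BE < threshold` constraint and every
#' `CE > threshold` constraint holds strictly. A missing metric for a
#' constrained strategy fails that constraint. An attrition table reports
#' how many SNPs pass each constraint individually.
#'
#' @param metrics data.frame from [compute_snp_metrics()] (columns
#'   `snp_id`, `BE_<s>`, `CE_<s>`).
#' @param rule a [selection_rule()].
#' @return List with `selected` (character SNP ids), `keep` (logical vector
#'   along `metrics`), and `attrition` (data.frame constraint/passing).
#' @export
apply_rules <- function(metrics, rule) {
  stopifnot(inherits(rule, "selection_rule"))
  keep <- rep(TRUE, nrow(metrics))
  attrition <- data.frame(constraint = character(), passing = integer())
  check <- function(col, thr, op, label) {
    if (!col %in% names(metrics))
      stop("metrics table lacks column '", col, "' required by the rule",
           call. = FALSE)
    v <- metrics[[col]]
    ok <- !is.na(v) & op(v, thr)
    attrition <<- rbind(attrition,
                        data.frame(constraint = label, passing = sum(ok)))
    keep <<- keep & ok
  }
  for (s in names(rule$be_upper))
    check(paste0("BE_", s), rule$be_upper[[s]], `<`,
          sprintf("BE_%s < %.4g", s, rule$be_upper[[s]]))
  for (s in names(rule$ce_lower))
    check(paste0("CE_", s), rule$ce_lower[[s]], `>`,
          sprintf("CE_%s > %.4g", s, rule$ce_lower[[s]]))
  list(selected = metrics$snp_id[keep], keep = keep, attrition = attrition)
}

#' Evaluate SNPs under the eight screening situations
#'
#' Runs the evaluation harness used on simulated phenotypes: per-SNP values
#' and a top-`top_fraction` membership flag under eight situations —
#' block entropy with (1) no blocking, (2) sex, (3) age, (4) pedigree,
#' (5) the full sex x smoke x age-band x pedigree cross-product,
#' (6) situation 5 restricted to SNPs whose pedigree consistency entropy
#' exceeds the average, (7) the sex x smoke x age cross-product, and
#' (8) entropy gain II under blocking (7). "Top" means lowest block
#' entropy (most informative) and highest gain II.
#'
#' @inheritParams compute_snp_metrics
#' @param top_fraction fraction flagged per situation; default 0.05.
#' @return List with `values` and `top` (logical) data.frames, one column
#'   per situation (`S1`..`S8`) plus `snp_id`, and `ce_ped` used by S6.
#' @export
run_situations <- function(geno, cohort, age_cutoff = 60, n0 = 10,
                           top_fraction = 0.05) {
  cohort <- stopifnot_cohort(cohort)
  geno <- align_genotypes(geno, cohort)
  specs <- list(S1 = "NO_ATTR", S2 = "SEX", S3 = "AGE", S4 = "PEDIGREE",
                S5 = "ALL_ATTR", S7 = "SSA")
  values <- data.frame(snp_id = rownames(geno), row.names = NULL)
  for (nm in names(specs)) {
    p <- build_partition(cohort, specs[[nm]], age_cutoff)
    values[[nm]] <- entropy_stats_matrix(geno, cohort$outcome, p$block)$be
  }
  ssa <- build_partition(cohort, "SSA", age_cutoff)
  values$S8 <- entropy_stats_matrix(geno, cohort$outcome, ssa$block)$gain2
  ped <- build_partition(cohort, "PEDIGREE", age_cutoff)
  ce_ped <- consistency_matrix(geno, cohort$outcome, ped$block, n0 = n0)$ce
  values$S6 <- values$S5

  n_top <- ceiling(top_fraction * nrow(values))
  flag_low <- function(v, eligible = rep(TRUE, length(v))) {
    ord <- order(v, values$snp_id)
    ord <- ord[eligible[ord] & !is.na(v[ord])]
    out <- rep(FALSE, length(v))
    out[ord[seq_len(min(n_top, length(ord)))]] <- TRUE
    out
  }
  top <- data.frame(snp_id = values$snp_id, row.names = NULL)
  for (nm in c("S1", "S2", "S3", "S4", "S5")) top[[nm]] <- flag_low(values[[nm]])
  top$S6 <- flag_low(values$S5, eligible = !is.na(ce_ped) &
                                  ce_ped > mean(ce_ped, na.rm = TRUE))
  top$S7 <- flag_low(values$S7)
  top$S8 <- flag_low(-values$S8)  # gain: large is informative
  values <- values[, c("snp_id", paste0("S", 1:8))]
  top <- top[, c("snp_id", paste0("S", 1:8))]
  list(values = values, top = top, ce_ped = ce_ped)
}
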