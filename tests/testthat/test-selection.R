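test_that("rank_partition sizes, ordering and tie-breaks", {
  be <- setNames(seq(0.01, 1, length.out = 100), sprintf("s%03d", 100:1))
  rp <- rank_partition(be, s_pct = 15, i_pct = 15)
  expect_length(rp$sensitive, 15)
  expect_length(rp$insensitive, 15)
  expect_equal(rp$sensitive[1], "s100")      # lowest entropy
  expect_equal(rp$insensitive[1], "s001")    # highest entropy
  expect_length(intersect(rp$sensitive, rp$insensitive), 0)

  # ties broken by snp id
  tied <- setNames(c(0.5, 0.5, 0.9), c("b", "a", "c"))
  expect_equal(rank_partition(tied, 33, 33)$sensitive, "a")

  # degenerate N = 1: the single SNP lands in both sets, with a warning
  expect_warning(rp1 <- rank_partition(c(x = 0.4), 15, 15), "overlap")
  expect_equal(rp1$sensitive, "x")
  expect_equal(rp1$insensitive, "x")
  expect_error(rank_partition(numeric(0)), "empty")
  expect_error(rank_partition(be, s_pct = 0), "\\(0, 100\\)")
})

test_that("VBE and VCE thresholds", {
  expect_equal(vbe_threshold(c(0.2, 0.6, 0.4), k = 0.45), 0.38)
  expect_equal(vbe_threshold(c(0.2, 0.6), k = 0), 0.2)
  expect_equal(vbe_threshold(c(0.2, 0.6), k = 1), 0.6)
  expect_error(vbe_threshold(c(0.2), k = 2), "\\[0, 1\\]")

  ce <- seq(0, 1, length.out = 101)  # uniform grid
  thr <- vce_threshold(ce, keep_fraction = 0.4)
  expect_equal(thr, unname(quantile(ce, 0.6)))
  expect_equal(mean(ce > thr), 0.4, tolerance = 0.01)
  thr8 <- vce_threshold(ce, keep_fraction = 0.8)
  expect_equal(mean(ce <= thr8), 0.2, tolerance = 0.015)
  expect_equal(vce_threshold(ce, keep_fraction = 1), min(ce))
  expect_equal(vce_threshold(c(NA, 0.5, 0.7), 0.5), 0.6)
  expect_error(vce_threshold(c(NA_real_, NA_real_)), "missing")
})

test_that("apply_rules equals a brute-force row filter", {
  set.seed(77)
  n <- 1000
  metrics <- data.frame(
    snp_id = sprintf("s%04d", 1:n),
    BE_ALL_ATTR = runif(n, 0.1, 0.9),
    BE_NO_ATTR = runif(n, 0.4, 1.0),
    CE_PEDIGREE = ifelse(runif(n) < 0.05, NA, runif(n)),
    CE_SEX = runif(n))
  rule <- selection_rule(
    be_upper = c(ALL_ATTR = 0.36, NO_ATTR = 0.67),
    ce_lower = c(PEDIGREE = 0.29, SEX = 0.9))
  res <- apply_rules(metrics, rule)
  brute <- with(metrics, !is.na(CE_PEDIGREE) &
                  BE_ALL_ATTR < 0.36 & BE_NO_ATTR < 0.67 &
                  CE_PEDIGREE > 0.29 & CE_SEX > 0.9)
  expect_equal(res$keep, brute)
  expect_equal(res$selected, metrics$snp_id[brute])
  expect_equal(nrow(res$attrition), 4)

  # monotone in thresholds: loosening one bound never drops a SNP
  looser <- selection_rule(be_upper = c(ALL_ATTR = 0.5, NO_ATTR = 0.67),
                           ce_lower = c(PEDIGREE = 0.29, SEX = 0.9))
  expect_true(all(res$selected %in% apply_rules(metrics, looser)$selected))

  expect_error(apply_rules(metrics, selection_rule(be_upper = c(AGE = 0.5))),
               "lacks column")
})

test_that("run_situations emits eight situations with correct flags", {
  sim <- simulate_cohort_data(sim_config(n_individuals = 200, n_snps = 40,
                                         n_pedigrees = 8, n_sensitive = 2,
                                         n_main_only = 2, seed = 9))
  rs <- run_situations(sim$genotypes, sim$cohort)
  expect_named(rs$values, c("snp_id", paste0("S", 1:8)))
  n_top <- ceiling(0.05 * 40)

  # situation 1 is the unblocked entropy
  p1 <- partition_no_attr(sim$cohort)
  es <- blockentropy:::entropy_stats_matrix(sim$genotypes,
                                            sim$cohort$outcome, p1$block)
  expect_equal(rs$values$S1, es$be)

  for (s in paste0("S", c(1:5, 7, 8)))
    expect_equal(sum(rs$top[[s]]), n_top)
  # S6 only flags SNPs above the average pedigree consistency entropy
  expect_true(all(rs$ce_ped[rs$top$S6] > mean(rs$ce_ped, na.rm = TRUE)))
  expect_lte(sum(rs$top$S6), n_top)
  # the flagged BE sets are the lowest values
  expect_equal(which(rs$top$S5), sort(order(rs$values$S5)[seq_len(n_top)]))
  expect_equal(which(rs$top$S8), sort(order(-rs$values$S8)[seq_len(n_top)]))
})
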