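test_that("binary_entropy matches closed form and rejects bad input", {
  expect_identical(binary_entropy(0.5), 1)
  expect_identical(binary_entropy(0), 0)
  expect_identical(binary_entropy(1), 0)
  expect_equal(binary_entropy(0.25), -0.25 * log2(0.25) - 0.75 * log2(0.75))
  p <- runif(20)
  expect_equal(binary_entropy(p), binary_entropy(1 - p))
  expect_error(binary_entropy(-0.1), "\\[0, 1\\]")
  expect_error(binary_entropy(1.1), "\\[0, 1\\]")
})

test_that("per-block entropy follows the mixed-denominator formula", {
  # hand evaluation: each geno-0 term is 0.25, geno-1 terms vanish
  expect_equal(per_block_entropy(nij = c(4, 4, 0), qij = c(2, 0, 0)), 0.5)
  # outcome-pure genotype classes contribute nothing
  expect_equal(per_block_entropy(nij = c(3, 5, 2), qij = c(0, 5, 2)), 0)
  # a single genotype class reduces to the marginal binary entropy
  expect_equal(per_block_entropy(nij = c(0, 6, 0), qij = c(0, 2, 0)),
               binary_entropy(2 / 6))
  expect_error(per_block_entropy(nij = c(0, 0, 0), qij = c(0, 0, 0)),
               "empty block")
  expect_error(per_block_entropy(nij = c(1, 1, 1), qij = c(2, 0, 0)))
})

test_that("count_table validates its invariants", {
  expect_error(count_table(rbind(c(1, 2)), rbind(c(0, 1))), "3 genotype")
  expect_error(count_table(rbind(c(1, 1, 1)), rbind(c(2, 0, 0))),
               "must not exceed")
  expect_error(count_table(rbind(c(-1, 1, 1)), rbind(c(0, 0, 0))),
               "non-negative")
  expect_error(count_table(rbind(c(1, 1, 1), c(0, 0, 0)),
                           rbind(c(0, 0, 0), c(0, 0, 0))), "empty blocks")
})

test_that("table-level statistics agree with spec examples", {
  ct <- count_table(n = rbind(c(4, 4, 0)), q = rbind(c(2, 0, 0)))
  expect_equal(block_entropy(ct), 0.5)
  expect_equal(no_snp_entropy(ct), binary_entropy(0.25))
  expect_equal(entropy_gain1(ct), binary_entropy(0.25) - 0.5)
  expect_equal(entropy_gain2(ct), 0)  # m = 1: inner and outer sums cancel

  # duplicating a block leaves the weighted averages unchanged
  ct2 <- count_table(rbind(c(4, 4, 0), c(4, 4, 0)),
                     rbind(c(2, 0, 0), c(2, 0, 0)))
  expect_equal(block_entropy(ct2), block_entropy(ct))
  expect_equal(no_snp_entropy(ct2), no_snp_entropy(ct))

  # two outcome-pure single-genotype blocks: gain II = 1 bit
  pure <- count_table(rbind(c(4, 0, 0), c(4, 0, 0)),
                      rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(entropy_gain2(pure), 1)
  expect_equal(block_entropy(pure), 0)

  # two blocks, n = 4, q = 2 each: G* = 1
  half <- count_table(rbind(c(4, 0, 0), c(0, 4, 0)),
                      rbind(c(2, 0, 0), c(0, 2, 0)))
  expect_equal(no_snp_entropy(half), 1)
})

test_that("statistics match the joint-distribution oracle on random tables", {
  set.seed(101)
  for (rep in 1:300) {
    t <- random_count_table()
    o <- oracle_stats(t)
    expect_equal(block_entropy(t), o$G, tolerance = 1e-12)
    expect_equal(no_snp_entropy(t), o$Gstar, tolerance = 1e-12)
    expect_equal(entropy_gain1(t), o$Ga, tolerance = 1e-12)
    expect_equal(entropy_gain2(t), o$Ga2, tolerance = 1e-12)
  }
})

test_that("invariance: genotype relabeling, block order, count scaling", {
  set.seed(202)
  stats5 <- function(t) c(block_entropy(t), no_snp_entropy(t),
                          entropy_gain1(t), entropy_gain2(t),
                          per_block_entropy(t$n[1, ], t$q[1, ]))
  for (rep in 1:50) {
    t <- random_count_table()
    perm_g <- sample(3)
    perm_b <- sample(t$m)
    t_g <- count_table(t$n[, perm_g, drop = FALSE], t$q[, perm_g, drop = FALSE])
    t_b <- count_table(t$n[perm_b, , drop = FALSE], t$q[perm_b, , drop = FALSE])
    t_s <- count_table(t$n * 3L, t$q * 3L)
    base <- stats5(t)
    expect_equal(stats5(t_g)[1:4], base[1:4])
    expect_equal(stats5(t_b)[1:4], base[1:4])
    expect_equal(stats5(t_s), base)
  }
})

test_that("vectorised engine agrees with the per-table path", {
  coh <- tiny_cohort()
  g <- tiny_geno()
  for (strat in c("NO_ATTR", "SEX", "PEDIGREE", "ALL_ATTR")) {
    p <- build_partition(coh, strat)
    es <- blockentropy:::entropy_stats_matrix(g, coh$outcome, p$block)
    for (i in seq_len(nrow(g))) {
      ct <- tabulate_counts(g[i, ], coh, p)
      expect_equal(es$be[i], block_entropy(ct), tolerance = 1e-12)
      expect_equal(es$gstar[i], no_snp_entropy(ct), tolerance = 1e-12)
      expect_equal(es$gain2[i], entropy_gain2(ct), tolerance = 1e-12)
    }
  }
})
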