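test_that("standardized proportions follow the two-branch definition", {
  # single block at or above n0: the scaling ratio is 1
  ct <- count_table(rbind(c(4, 4, 0)), rbind(c(2, 1, 0)))
  s <- standardized_proportions(ct, n0 = 3)
  expect_equal(unname(s$F[1, ]), c(2 / 4, 1 / 4, 0))

  # two blocks n = 4 each (n0 = 3), q_1 = 2, q_2 = 1:
  # maxprop = 0.5, p_2 = 0.25, so F(2, j) = 2 * q_2j / n_2j
  ct2 <- count_table(rbind(c(2, 2, 0), c(2, 2, 0)),
                     rbind(c(1, 1, 0), c(1, 0, 0)))
  s2 <- standardized_proportions(ct2, n0 = 3)
  expect_equal(unname(s2$F[2, ]), 2 * c(1 / 2, 0, 0))
  expect_equal(unname(s2$F[1, ]), c(1 / 2, 1 / 2, 0))

  # absent genotype class -> F = 0; small blocks use the raw proportion
  expect_warning(standardized_proportions(ct2, n0 = 10), "n0")
  expect_equal(unname(suppressWarnings(
    standardized_proportions(ct2, n0 = 10))$F[2, ]), c(1 / 2, 0, 0))
})

test_that("proportional blocks give constant F across large blocks", {
  # p_1 : p_2 = p_1j : p_2j for every j -> F(i, j) constant in i
  ct <- count_table(rbind(c(10, 10, 0), c(10, 10, 0)),
                    rbind(c(4, 2, 0), c(2, 1, 0)))
  s <- standardized_proportions(ct, n0 = 5)
  expect_equal(s$F[1, 1:2], s$F[2, 1:2])
})

test_that("totals, main genotype and tie-breaks", {
  ct <- count_table(rbind(c(4, 4, 0)), rbind(c(2, 1, 0)))
  s <- standardized_proportions(ct, n0 = 3)
  expect_equal(unname(total_standardized_proportion(s)), c(0.5, 0.25, 0))
  expect_equal(main_genotype(c(0.2, 0.5, 0.1)), 1L)
  expect_equal(main_genotype(c(0.3, 0.3, 0.1)), 0L)
  expect_error(main_genotype(c(0, 0, 0)), "uninformative")

  set.seed(5)
  for (rep in 1:20) {  # brute-force weighted sum
    t <- random_count_table()
    s <- suppressWarnings(standardized_proportions(t, n0 = 3))
    manual <- colSums(s$F * (t$n_i / t$n_total))
    expect_equal(unname(total_standardized_proportion(s)), unname(manual))
  }
})

test_that("consistency entropy: closed forms and invariances", {
  mk <- function(m) {  # m equal blocks, identical counts
    s <- standardized_proportions(
      count_table(matrix(rep(c(10, 10, 0), each = m), m),
                  matrix(rep(c(4, 2, 0), each = m), m)), n0 = 5)
    s
  }
  expect_equal(consistency_entropy(mk(2), 0), 1)
  expect_equal(consistency_entropy(mk(4), 0), binary_entropy(1 / 4))
  expect_equal(consistency_entropy(mk(20), 0), binary_entropy(1 / 20))
  expect_equal(consistency_entropy(mk(20), 0), 0.28640, tolerance = 1e-4)

  # m = 1 -> zero; rescaling F leaves CE unchanged
  one <- standardized_proportions(count_table(rbind(c(4, 4, 0)),
                                              rbind(c(2, 1, 0))), n0 = 3)
  expect_equal(consistency_entropy(one, 0), 0)
  s <- mk(3)
  s2 <- s
  s2$F <- s$F * 7.3
  expect_equal(consistency_entropy(s2, 0), consistency_entropy(s, 0))

  # absent genotype -> undefined CE
  expect_true(is.na(consistency_entropy(s, 2)))
})

test_that("two equal blocks: CE is maximized at equal F", {
  base <- count_table(rbind(c(10, 10, 0), c(10, 10, 0)),
                      rbind(c(4, 2, 0), c(4, 2, 0)))
  s <- standardized_proportions(base, n0 = 5)
  ce_equal <- consistency_entropy(s, 0)
  for (f1 in seq(0.05, 0.95, by = 0.09)) {
    s$F[1, 1] <- f1
    s$F[2, 1] <- 1 - f1 + 0.1  # unequal split of the same mass
    if (abs(s$F[1, 1] - s$F[2, 1]) < 1e-9) next
    expect_lt(consistency_entropy(s, 0), ce_equal)
  }
})

test_that("vectorised consistency agrees with the scalar path", {
  coh <- tiny_cohort()
  g <- tiny_geno()
  for (strat in c("SEX", "PEDIGREE", "ALL_ATTR")) {
    p <- build_partition(coh, strat)
    cm <- blockentropy:::consistency_matrix(g, coh$outcome, p$block, n0 = 2)
    for (i in seq_len(nrow(g))) {
      ct <- tabulate_counts(g[i, ], coh, p)
      s <- suppressWarnings(standardized_proportions(ct, n0 = 2))
      tot <- total_standardized_proportion(s)
      if (all(tot == 0)) {
        expect_true(is.na(cm$main_genotype[i]))
      } else {
        mg <- main_genotype(tot)
        expect_equal(cm$main_genotype[i], mg)
        expect_equal(cm$ce[i], consistency_entropy(s, mg), tolerance = 1e-12)
      }
    }
  }
})
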