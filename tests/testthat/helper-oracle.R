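# Independent oracle: build the full joint distribution over
# (block, genotype, outcome) from a count_table and compute conditional
# entropies / conditional mutual informations from first principles.
# Deliberately shares no code with the package kernel.

oracle_H <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_stats <- function(t) {
  n <- t$n_total
  # joint cells p(block, geno, outcome)
  p_bg1 <- as.vector(t$q) / n
  p_bg0 <- as.vector(t$n - t$q) / n
  H_BGY <- oracle_H(c(p_bg0, p_bg1))
  H_BG <- oracle_H(as.vector(t$n) / n)
  H_B <- oracle_H(t$n_i / n)
  H_BY <- oracle_H(c(t$q_i / n, (t$n_i - t$q_i) / n))
  H_G <- oracle_H(colSums(t$n) / n)
  H_GY <- oracle_H(c(colSums(t$q) / n, colSums(t$n - t$q) / n))
  G <- H_BGY - H_BG              # H(Y | block, genotype)
  Gstar <- H_BY - H_B            # H(Y | block)
  list(G = G, Gstar = Gstar,
       Ga = Gstar - G,                       # I(Y; genotype | block)
       Ga2 = (H_GY - H_G) - (H_BGY - H_BG))  # I(Y; block | genotype)
}

# random valid count tables, small (m <= max_m, block cells <= max_cell)
random_count_table <- function(max_m = 4, max_cell = 5) {
  repeat {
    m <- sample.int(max_m, 1)
    n <- matrix(sample(0:max_cell, m * 3, replace = TRUE), m, 3)
    if (all(rowSums(n) > 0)) break
  }
  q <- matrix(rbinom(m * 3, as.vector(n), runif(m * 3)), m, 3)
  count_table(n, q)
}
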