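#' Entropy statistics over block-by-genotype contingency counts
#'
#' The numeric kernel of the package. All quantities are Shannon entropies
#' in bits (base-2 logarithms) of a binary outcome, computed from the
#' counts in a [count_table]:
#'
#' * `per_block_entropy()` — the within-block entropy of the outcome given
#'   genotype, \eqn{G_i = \sum_j [-(q_{ij}/n_i)\log_2(q_{ij}/n_{ij}) -
#'   ((n_{ij}-q_{ij})/n_i)\log_2((n_{ij}-q_{ij})/n_{ij})]}.
#' * `block_entropy()` — the block entropy
#'   \eqn{G = \sum_i (n_i/n) G_i}, the empirical conditional entropy of the
#'   outcome given block and genotype. Low values flag SNPs that are
#'   informative jointly with the covariates defining the blocks.
#' * `no_snp_entropy()` — \eqn{G^* = \sum_i (n_i/n) H(q_i/n_i)}, the
#'   entropy of the outcome given blocks only.
#' * `entropy_gain1()` — gain (I), \eqn{Ga = G^* - G}: information about
#'   the outcome contributed by genotype within blocks.
#' * `entropy_gain2()` — gain (II), \eqn{Ga'}: information about the
#'   outcome contributed by the blocks within genotype classes (the
#'   conditional mutual information between outcome and block given
#'   genotype).
#'
#' Conventions: \eqn{0 \log_2 0 \equiv 0}; genotype classes with
#' \eqn{n_{ij} = 0} contribute nothing.
#'
#' @param t a [count_table].
#' @return A single non-negative numeric value in bits. `block_entropy` and
#'   `no_snp_entropy` lie in \[0, 1\] for a binary outcome.
#' @seealso [binary_entropy()], [tabulate_counts()]
#' @examples
#' ct <- count_table(n = rbind(c(4, 4, 0)), q = rbind(c(2, 0, 0)))
#' block_entropy(ct)   # 0.5
#' no_snp_entropy(ct)  # binary_entropy(0.25)
#' entropy_gain1(ct)   # their difference
#' @name entropy-statistics
NULL

#' Binary Shannon entropy
#'
#' \eqn{H(p) = -p \log_2 p - (1-p)\log_2(1-p)} in bits, with the
#' convention \eqn{0 \log_2 0 = 0}. Vectorised over `p`.
#'
#' @param p probability (or vector of probabilities) in \[0, 1\].
#' @return Entropy in bits, in \[0, 1\]; symmetric in `p` and `1 - p`.
#' @examples
#' binary_entropy(0.5)   # 1
#' binary_entropy(0.25)  # 0.8112781
#' @export
binary_entropy <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1))
    stop("'p' must lie in [0, 1]", call. = FALSE)
  -xlog2x(p) - xlog2x(1 - p)
}

# x * log2(x) with the 0 log 0 = 0 convention
xlog2x <- function(x) {
  out <- x * log2(x)
  out[x == 0] <- 0
  out
}

# a * log2(a / b); 0 when a == 0 (which covers b == 0 under q <= n)
xlog2r <- function(a, b) {
  out <- a * (log2(a) - log2(b))
  out[a == 0] <- 0
  out
}

#' @rdname entropy-statistics
#' @param nij,qij integer vectors of length 3: per-genotype group sizes and
#'   outcome counts of a single block (for `per_block_entropy`).
#' @export
per_block_entropy <- function(nij, qij) {
  if (inherits(nij, "count_table")) {
    if (nij$m != 1L)
      stop("pass one block (or use block_entropy on the table)", call. = FALSE)
    qij <- nij$q[1L, ]
    nij <- nij$n[1L, ]
  }
  ni <- sum(nij)
  if (ni == 0) stop("empty block: n_i must be positive", call. = FALSE)
  if (any(qij > nij) || any(nij < 0) || any(qij < 0))
    stop("need 0 <= q_ij <= n_ij", call. = FALSE)
  sum(-xlog2r(qij, nij) - xlog2r(nij - qij, nij)) / ni
}

#' @rdname entropy-statistics
#' @export
block_entropy <- function(t) {
  stopifnot_count_table(t)
  sum(-xlog2r(t$q, t$n) - xlog2r(t$n - t$q, t$n)) / t$n_total
}

#' @rdname entropy-statistics
#' @export
no_snp_entropy <- function(t) {
  stopifnot_count_table(t)
  sum(-xlog2r(t$q_i, t$n_i) - xlog2r(t$n_i - t$q_i, t$n_i)) / t$n_total
}

#' @rdname entropy-statistics
#' @export
entropy_gain1 <- function(t) {
  no_snp_entropy(t) - block_entropy(t)
}

#' @rdname entropy-statistics
#' @export
entropy_gain2 <- function(t) {
  stopifnot_count_table(t)
  n_j <- colSums(t$n)
  q_j <- colSums(t$q)
  marg <- sum(-xlog2r(q_j, n_j) - xlog2r(n_j - q_j, n_j))
  cond <- sum(xlog2r(t$q, t$n) + xlog2r(t$n - t$q, t$n))
  (marg + cond) / t$n_total
}

# ---- vectorised engine over many SNPs ---------------------------------------
#
# Counts for all SNPs at once: for genotype j, the snp-by-block matrices
#   N_j = [G == j] %*% B      and      Q_j = [G == j] %*% (B * y)
# where B is the individual-by-block indicator. Missing dosages drop the
# individual from that SNP only (complete case per SNP), so n_i and q_i are
# per-SNP quantities. Returns 3-d arrays snp x block x genotype.
tabulate_counts_matrix <- function(geno, outcome, block) {
  if (!is.matrix(geno)) geno <- matrix(geno, nrow = 1L)
  block <- as.factor(block)
  m <- nlevels(block)
  B <- matrix(0, ncol(geno), m)
  B[cbind(seq_along(block), as.integer(block))] <- 1
  By <- B * outcome
  N <- array(0, dim = c(nrow(geno), m, 3L),
             dimnames = list(rownames(geno), levels(block), 0:2))
  Q <- N
  for (j in 0:2) {
    Ij <- (geno == j)
    Ij[is.na(Ij)] <- FALSE
    storage.mode(Ij) <- "double"
    N[, , j + 1L] <- Ij %*% B
    Q[, , j + 1L] <- Ij %*% By
  }
  list(N = N, Q = Q)
}

# extract genotype slab j as an snp x block matrix without dropping dims
slab <- function(A, j) matrix(A[, , j], nrow = dim(A)[1L])

# Block entropy, no-SNP entropy and both gains for every SNP (rows of geno),
# from the arrays above. Used by the metrics/permutation layers; agrees with
# the per-table scalar path (tested).
entropy_stats_matrix <- function(geno, outcome, block) {
  tab <- tabulate_counts_matrix(geno, outcome, block)
  N <- tab$N; Q <- tab$Q
  Ni <- slab(N, 1L) + slab(N, 2L) + slab(N, 3L)  # snp x block
  Qi <- slab(Q, 1L) + slab(Q, 2L) + slab(Q, 3L)
  n <- rowSums(Ni)                               # per-SNP included count
  if (any(n == 0))
    warning(sum(n == 0), " SNP(s) have no individuals after missing-data ",
            "exclusion; their statistics are NaN")
  inner <- -xlog2r(Q, N) - xlog2r(N - Q, N)      # snp x block x geno
  be <- rowSums(inner, dims = 1L) / n
  gstar <- rowSums(-xlog2r(Qi, Ni) - xlog2r(Ni - Qi, Ni)) / n
  # gain II marginals over blocks, per genotype
  Nj <- apply(N, c(1L, 3L), sum)
  Qj <- apply(Q, c(1L, 3L), sum)
  marg <- rowSums(-xlog2r(Qj, Nj) - xlog2r(Nj - Qj, Nj))
  gain2 <- (marg - rowSums(inner, dims = 1L)) / n
  data.frame(snp_id = rownames(geno) %||% as.character(seq_along(be)),
             be = be, gstar = gstar, gain1 = gstar - be, gain2 = gain2,
             n_used = n, row.names = NULL)
}
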