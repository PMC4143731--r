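#' Per-SNP block-by-genotype contingency counts
#'
#' A `count_table` holds, for one SNP, the 3-way contingency counts that
#' every entropy statistic in this package is computed from: for each block
#' \eqn{B_i} of individuals and each genotype class \eqn{j \in \{0,1,2\}},
#' the group size \eqn{n_{ij}} and the number of outcome carriers
#' \eqn{q_{ij}}.
#'
#' @param n integer matrix, blocks x 3 genotype classes: group sizes
#'   \eqn{n_{ij}}. Columns correspond to genotype dosages 0, 1, 2.
#' @param q integer matrix of the same shape: outcome-carrier counts
#'   \eqn{q_{ij}}, with \eqn{0 \le q_{ij} \le n_{ij}}.
#'
#' @return An object of class `count_table`: a list with elements `n`, `q`
#'   (the two matrices), `n_i`, `q_i` (block row sums), `n_total` and `m`.
#'   Every block must be non-empty (drop empty blocks before construction).
#' @examples
#' ct <- count_table(n = rbind(c(4, 4, 0)), q = rbind(c(2, 0, 0)))
#' block_entropy(ct)
#' @export
count_table <- function(n, q) {
  n <- as.matrix(n)
  q <- as.matrix(q)
  if (!is.numeric(n) || !is.numeric(q))
    stop("'n' and 'q' must be numeric matrices", call. = FALSE)
  if (ncol(n) != 3L || ncol(q) != 3L)
    stop("count matrices must have 3 genotype columns", call. = FALSE)
  if (nrow(n) < 1L)
    stop("a count_table needs at least one block", call. = FALSE)
  if (!identical(dim(n), dim(q)))
    stop("'n' and 'q' must have identical dimensions", call. = FALSE)
  if (any(n < 0) || any(q < 0) || any(n != round(n)) || any(q != round(q)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (any(q > n))
    stop("q_ij must not exceed n_ij", call. = FALSE)
  n_i <- rowSums(n)
  if (any(n_i == 0))
    stop("empty blocks are not allowed; drop them before tabulation",
         call. = FALSE)
  structure(
    list(n = n, q = q, n_i = n_i, q_i = rowSums(q),
         n_total = sum(n_i), m = nrow(n)),
    class = "count_table"
  )
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("<count_table> %d block(s), %d individuals, %d with outcome\n",
              x$m, x$n_total, sum(x$q_i)))
  tab <- cbind(x$n, x$q)
  colnames(tab) <- c("n_j0", "n_j1", "n_j2", "q_j0", "q_j1", "q_j2")
  rownames(tab) <- rownames(x$n) %||% paste0("B", seq_len(x$m))
  print(tab)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_count_table <- function(t) {
  if (!inherits(t, "count_table"))
    stop("expected a 'count_table' object", call. = FALSE)
  invisible(t)
}
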