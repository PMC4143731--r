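#' Per-individual covariate and outcome table
#'
#' Validates and normalises the covariate/phenotype table used throughout
#' the package: one row per individual with sex (1/2), smoking status
#' (0/1), age in years, pedigree membership, and a binary outcome (e.g.
#' baseline hypertension status).
#'
#' @param x a data.frame with columns `id`, `sex`, `smoke`, `age`,
#'   `pedigree`, `outcome` (extra columns are kept).
#' @param require_complete character vector of covariate columns that must
#'   be non-missing; defaults to all of them. Rows with a missing outcome
#'   are always dropped (with a message).
#' @return A data.frame of class `cohort_table` with `id` coerced to
#'   character and `pedigree` to factor.
#' @examples
#' cohort_table(data.frame(id = c("a", "b"), sex = c(1, 2),
#'                         smoke = c(0, 1), age = c(45, 70),
#'                         pedigree = c("P1", "P1"), outcome = c(0, 1)))
#' @export
cohort_table <- function(x,
                         require_complete = c("sex", "smoke", "age",
                                              "pedigree")) {
  need <- c("id", "sex", "smoke", "age", "pedigree", "outcome")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("cohort table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  x <- as.data.frame(x)
  x$id <- as.character(x$id)
  if (anyDuplicated(x$id))
    stop("individual ids must be unique", call. = FALSE)
  drop <- is.na(x$outcome)
  if (any(drop)) {
    message(sum(drop), " individual(s) dropped for missing outcome")
    x <- x[!drop, , drop = FALSE]
  }
  if (nrow(x) == 0L) stop("cohort is empty", call. = FALSE)
  if (!all(x$outcome %in% c(0, 1)))
    stop("outcome must be binary 0/1", call. = FALSE)
  if (any(!is.na(x$sex) & !x$sex %in% c(1, 2)))
    stop("sex must be coded 1/2", call. = FALSE)
  if (any(!is.na(x$smoke) & !x$smoke %in% c(0, 1)))
    stop("smoke must be coded 0/1", call. = FALSE)
  if (any(!is.na(x$age) & x$age < 0))
    stop("age must be non-negative", call. = FALSE)
  for (col in require_complete)
    if (anyNA(x[[col]]))
      stop("missing values in required covariate '", col, "'", call. = FALSE)
  x$pedigree <- factor(x$pedigree)
  class(x) <- c("cohort_table", "data.frame")
  x
}

stopifnot_cohort <- function(c) {
  if (!inherits(c, "cohort_table")) c <- cohort_table(c)
  c
}
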