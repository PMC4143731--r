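#' Configuration for the synthetic family-cohort simulator
#'
#' Bundles and validates the parameters of the generator that emulates a
#' family-based hypertension cohort: ~20 pedigrees, dichotomous sex and
#' smoking, continuous age, a binary baseline outcome with prevalence near
#' 0.27, and SNP dosages with within-pedigree allele-frequency correlation.
#' A subset of SNPs carries a genotype main effect, and a further subset an
#' age-modified (genotype x covariate) effect — the "sensitive" SNPs the
#' screening method is designed to flag.
#'
#' @param n_individuals cohort size.
#' @param n_pedigrees number of pedigrees (default 20).
#' @param n_snps number of SNPs.
#' @param maf_range interval in (0, 0.5\] for per-SNP minor-allele
#'   frequencies (drawn uniformly).
#' @param n_sensitive SNPs with a genotype x age-band interaction effect.
#' @param n_main_only SNPs with a genotype main effect only.
#' @param beta_main,beta_gx log-odds per dosage unit for main and
#'   interaction effects.
#' @param beta_age,beta_sex,beta_smoke covariate log-odds (age >= 60,
#'   sex = 2, smoke = 1).
#' @param sd_pedigree standard deviation of the pedigree random intercept.
#' @param baseline_prevalence target outcome prevalence (default 0.27).
#' @param age_cutoff years; the age band boundary used by the interaction.
#' @param seed integer seed; every draw is deterministic given it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 1000, n_pedigrees = 20, n_snps = 500,
                       maf_range = c(0.05, 0.5), n_sensitive = 10,
                       n_main_only = 10, beta_main = 0.5, beta_gx = 1.0,
                       beta_age = 1.0, beta_sex = 0.3, beta_smoke = 0.4,
                       sd_pedigree = 0.5, baseline_prevalence = 0.27,
                       age_cutoff = 60, seed = 1) {
  cfg <- as.list(environment())
  if (n_individuals < n_pedigrees)
    stop("need at least one individual per pedigree", call. = FALSE)
  if (n_sensitive + n_main_only > n_snps)
    stop("n_sensitive + n_main_only must not exceed n_snps", call. = FALSE)
  if (length(maf_range) != 2L || maf_range[1L] <= 0 || maf_range[2L] > 0.5 ||
      maf_range[1L] > maf_range[2L])
    stop("'maf_range' must be an interval within (0, 0.5]", call. = FALSE)
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1)
    stop("'baseline_prevalence' must lie in (0, 1)", call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Generate the covariate table of a synthetic cohort
#'
#' Individuals are assigned to pedigrees multinomially (re-drawn, bounded,
#' until every pedigree is occupied); sex is Bernoulli(0.5) coded 1/2,
#' smoking Bernoulli(0.3), age uniform on \[30, 85\] years. The outcome
#' column is initialised to 0 and filled by [generate_outcome()].
#'
#' @param cfg a [sim_config()].
#' @return A [cohort_table] with `n_individuals` rows.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  for (try in 1:100) {
    ped <- sample.int(cfg$n_pedigrees, cfg$n_individuals, replace = TRUE)
    if (length(unique(ped)) == cfg$n_pedigrees) break
    if (try == 100) stop("could not occupy every pedigree", call. = FALSE)
  }
  cohort_table(data.frame(
    id = sprintf("ind_%05d", seq_len(cfg$n_individuals)),
    sex = stats::rbinom(cfg$n_individuals, 1, 0.5) + 1L,
    smoke = stats::rbinom(cfg$n_individuals, 1, 0.3),
    age = stats::runif(cfg$n_individuals, 30, 85),
    pedigree = sprintf("ped_%02d", ped),
    outcome = 0L))
}

#' Generate pedigree-correlated SNP dosages
#'
#' Per SNP, a minor-allele frequency is drawn uniformly from
#' `cfg$maf_range`; each pedigree then receives a perturbed allele
#' frequency from a Beta distribution with mean MAF and concentration 30
#' (beta-binomial family correlation), and dosages are drawn as
#' Binomial(2, pedigree frequency) — Hardy-Weinberg within pedigree. No
#' explicit Mendelian transmission is simulated: the method uses pedigree
#' only as a blocking factor, so frequency-level correlation suffices.
#'
#' @param cfg a [sim_config()].
#' @param cohort the [generate_cohort()] output.
#' @return Integer matrix SNPs x individuals with dimnames; attributes
#'   `maf` (per-SNP frequency), `sensitive_snps` and `main_only_snps`
#'   (SNP ids carrying the effects, assigned by [generate_outcome()]'s
#'   convention: the first `n_sensitive` SNPs are sensitive, the next
#'   `n_main_only` main-effect-only).
#' @export
generate_genotypes <- function(cfg, cohort) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- nrow(cohort)
  ped <- as.integer(cohort$pedigree)
  maf <- stats::runif(cfg$n_snps, cfg$maf_range[1L], cfg$maf_range[2L])
  theta <- 30  # concentration of the pedigree frequency perturbation
  geno <- matrix(0L, cfg$n_snps, n,
                 dimnames = list(sprintf("snp_%05d", seq_len(cfg$n_snps)),
                                 cohort$id))
  npED <- max(ped)
  for (s in seq_len(cfg$n_snps)) {
    pk <- stats::rbeta(npED, maf[s] * theta, (1 - maf[s]) * theta)
    geno[s, ] <- stats::rbinom(n, 2L, pk[ped])
  }
  snp_ids <- rownames(geno)
  attr(geno, "maf") <- stats::setNames(maf, snp_ids)
  attr(geno, "sensitive_snps") <-
    snp_ids[seq_len(cfg$n_sensitive)]
  attr(geno, "main_only_snps") <-
    snp_ids[cfg$n_sensitive + seq_len(cfg$n_main_only)]
  geno
}

#' Generate the binary outcome from a logistic model
#'
#' The outcome follows
#' \deqn{\mathrm{logit}\,p = \beta_0 + \beta_{age} 1[age \ge c] +
#'   \beta_{sex} 1[sex = 2] + \beta_{smoke}\,smoke + u_{ped} +
#'   \sum_{\mathrm{main}} \beta_g d + \sum_{\mathrm{sens}} \beta_{gx}
#'   d \cdot 1[age \ge c]}
#' with pedigree random intercepts \eqn{u_{ped} \sim N(0, sd^2)}. The
#' intercept \eqn{\beta_0} is calibrated by root-finding so the expected
#' prevalence equals `baseline_prevalence`; the Bernoulli draw is repeated
#' (deterministically under the seed) until the realized prevalence is
#' within 0.02 of the target.
#'
#' @inheritParams generate_genotypes
#' @param geno the [generate_genotypes()] output.
#' @return The cohort with its `outcome` column filled; attributes
#'   `beta0` and `prevalence` record the calibration.
#' @export
generate_outcome <- function(cfg, cohort, geno) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  old_age <- cohort$age >= cfg$age_cutoff
  u <- stats::rnorm(nlevels(cohort$pedigree), 0, cfg$sd_pedigree)
  eta <- cfg$beta_age * old_age + cfg$beta_sex * (cohort$sex == 2) +
    cfg$beta_smoke * cohort$smoke + u[as.integer(cohort$pedigree)]
  sens <- attr(geno, "sensitive_snps")
  main <- attr(geno, "main_only_snps")
  if (length(main))
    eta <- eta + cfg$beta_main * colSums(geno[main, , drop = FALSE])
  if (length(sens))
    eta <- eta + cfg$beta_gx *
      colSums(geno[sens, , drop = FALSE]) * old_age
  f <- function(b0) mean(stats::plogis(b0 + eta)) - cfg$baseline_prevalence
  b0 <- tryCatch(stats::uniroot(f, c(-30, 30), tol = 1e-8)$root,
                 error = function(e)
                   stop("prevalence calibration did not converge",
                        call. = FALSE))
  p <- stats::plogis(b0 + eta)
  for (try in 1:50) {
    y <- stats::rbinom(length(p), 1L, p)
    if (abs(mean(y) - cfg$baseline_prevalence) <= 0.02) break
    if (try == 50)
      stop("realized prevalence did not reach the target within 0.02",
           call. = FALSE)
  }
  cohort$outcome <- y
  attr(cohort, "beta0") <- b0
  attr(cohort, "prevalence") <- mean(y)
  cohort
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper chaining [generate_cohort()],
#' [generate_genotypes()] and [generate_outcome()].
#'
#' @param cfg a [sim_config()].
#' @return List with `cohort`, `genotypes`, and `truth` (the sensitive and
#'   main-effect-only SNP ids plus the config).
#' @examples
#' sim <- simulate_cohort_data(sim_config(n_individuals = 100, n_snps = 20,
#'                                        seed = 7))
#' dim(sim$genotypes)
#' @export
simulate_cohort_data <- function(cfg = sim_config()) {
  cohort <- generate_cohort(cfg)
  geno <- generate_genotypes(cfg, cohort)
  cohort <- generate_outcome(cfg, cohort, geno)
  list(cohort = cohort, genotypes = geno,
       truth = list(sensitive = attr(geno, "sensitive_snps"),
                    main_only = attr(geno, "main_only_snps"),
                    config = cfg))
}
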