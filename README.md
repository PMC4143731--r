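# blockentropy

Entropy-based screening of SNPs whose association with a binary outcome is
**sensitive or insensitive to covariates** (sex, smoking status, age band,
pedigree membership), for analysts working with family-based case-control
cohorts such as hypertension pedigree studies.

## The method

Individuals are partitioned into blocks $B_1,\dots,B_m$ sharing covariate
values. With $n_{ij}$ individuals of genotype $j \in \{0,1,2\}$ in block
$i$ ($q_{ij}$ of them carrying the outcome), the package computes, in
bits:

- **block entropy** $G = \sum_{i,j}\big[-\tfrac{q_{ij}}{n}\log_2
  \tfrac{q_{ij}}{n_{ij}} - \tfrac{n_{ij}-q_{ij}}{n}\log_2
  \tfrac{n_{ij}-q_{ij}}{n_{ij}}\big]$ — the conditional entropy
  $H(Y\mid \mathrm{block}, \mathrm{genotype})$; low values flag SNPs
  informative jointly with the covariates;
- **no-SNP entropy** $G^* = H(Y\mid \mathrm{block})$ and **gain I**
  $Ga = G^* - G \ge 0$;
- **gain II** $Ga' = I(Y;\mathrm{block}\mid \mathrm{genotype})$;
- **consistency entropy** $G(j)$ of the *main genotype* — a
  size-weighted entropy of the across-block distribution of standardized
  genotype-outcome proportions $F(i,j)$; high values mean the association
  is homogeneous across blocks.

Screening ranks SNPs by ascending block entropy under six blocking
strategies (none, sex, smoke, age<60/≥60, pedigree, full cross-product)
and selects covariate-sensitive SNPs by the strict rule conjunction
`BE < VBE` and `CE > VCE`, with `VBE = BEmin + k·(BEmax − BEmin)`
(default `k = 0.45`) and `VCE` an empirical quantile of the CE
distribution. Significance comes from outcome-permutation p-values with
the add-one convention. A synthetic family-cohort generator (20 pedigrees,
logistic outcome with planted genotype×age interactions) makes the whole
pipeline testable end to end.

## Worked example

```r
library(blockentropy)

sim <- simulate_cohort_data(sim_config(n_individuals = 500, n_snps = 100,
                                       n_sensitive = 3, n_main_only = 3,
                                       beta_gx = 2.0, seed = 101))
m <- compute_snp_metrics(sim$genotypes, sim$cohort)
head(m[, c("snp_id", "BE_NO_ATTR", "BE_AGE", "BE_ALL_ATTR",
           "CE_SEX", "CE_PEDIGREE")], 4)
#>      snp_id BE_NO_ATTR BE_AGE BE_ALL_ATTR CE_SEX CE_PEDIGREE
#> 1 snp_00001      0.821  0.450       0.206  0.958       0.235
#> 2 snp_00002      0.811  0.445       0.208  0.943       0.279
#> 3 snp_00003      0.825  0.469       0.184  1.000       0.258
#> 4 snp_00004      0.838  0.484       0.215  1.000       0.277

rank_partition(setNames(m$BE_AGE, m$snp_id), s_pct = 10, i_pct = 10)$sensitive
#>  [1] "snp_00002" "snp_00001" "snp_00003" "snp_00065" ...
```

The three planted interaction SNPs (`snp_00001..3`, age-modified log-odds
2.0) hold the three lowest age-blocked entropies: conditioning on the age
band makes their genotypes predictive, dropping BE from ≈0.82 bits
(unblocked) to ≈0.45. Their consistency entropies sit near the
theoretical homogeneity ceilings (≈1 bit for 2-block strategies,
H(1/20) ≈ 0.286 for 20 pedigrees), so a rule like
`BE_AGE < VBE & CE_PEDIGREE > VCE` retains them. Permutation confirms:

```r
permutation_pvalues(sim$genotypes[1:3, ], sim$cohort, strategy = "AGE",
                    statistic = "be", B = 99, seed = 7)$p_value
#> [1] 0.01 0.01 0.01    # the minimum attainable at B = 99
```

## Command line

```sh
Rscript -e 'blockentropy::be_cli()' simulate --n-individuals 500 --n-snps 200 --out-dir sim
Rscript -e 'blockentropy::be_cli()' compute  --genotypes sim/genotypes.tsv \
        --covariates sim/covariates.tsv --out metrics.tsv
Rscript -e 'blockentropy::be_cli()' select   --metrics metrics.tsv --out selected.tsv
Rscript -e 'blockentropy::be_cli()' permute  --genotypes sim/genotypes.tsv \
        --covariates sim/covariates.tsv --strategy AGE --out pvalues.tsv
```

Genotypes are read from a TSV dosage matrix (SNPs × individuals, cells
0/1/2/NA) or a VCF (GT field; multi-allelic sites skipped). Covariates are
a TSV with columns `ID SEX SMOKE AGE PEDIGREE HTN`. Every run writes a
reproducibility log; reruns are byte-identical given the seed.

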