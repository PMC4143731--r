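# Small in-code fixtures shared across test files.

tiny_cohort <- function() {
  cohort_table(data.frame(
    id = sprintf("i%02d", 1:8),
    sex = c(1, 1, 1, 1, 2, 2, 2, 2),
    smoke = c(0, 0, 1, 1, 0, 0, 1, 1),
    age = c(40, 70, 45, 65, 50, 75, 55, 80),
    pedigree = rep(c("P1", "P2"), 4),
    outcome = c(1, 0, 0, 0, 1, 1, 0, 0)))
}

# dosage matrix aligned with tiny_cohort(), with one missing call
tiny_geno <- function() {
  g <- rbind(snpA = c(0, 0, 1, 1, 2, 2, 0, 1),
             snpB = c(1, 1, 1, 1, 0, 0, 0, 0),
             snpC = c(0, NA, 2, 1, 0, 2, 1, 0))
  colnames(g) <- sprintf("i%02d", 1:8)
  g
}

write_tiny_vcf <- function(path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##contig=<ID=1>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("i%02d", 1:4)), collapse = "\t"))
  rows <- c(
    paste(c("1", "100", "rs1", "A", "G", ".", ".", ".", "GT",
            "0/0", "0/1", "1/0", "1/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "C", "T", ".", ".", ".", "GT",
            "./.", "0|1", "1|1", "0/0"), collapse = "\t"),
    paste(c("1", "300", "rs3", "G", "A,T", ".", ".", ".", "GT",
            "0/1", "0/2", "0/0", "1/1"), collapse = "\t"))
  writeLines(c(header, rows), path)
  path
}
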