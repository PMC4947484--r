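# Shared fixtures built in code at test time.

# The published 3x3 training-set agreement table (truth rows, predicted
# columns) used throughout the agreement tests.
table3_confusion <- function() {
  del_confusion(rbind(
    c(119, 2, 0),
    c(10, 127, 3),
    c(0, 3, 45)
  ))
}

# Genotype counts of the three study populations (totals column).
study_population_counts <- function() {
  genotype_counts(
    population = c("West-Africans", "East-Africans", "West-African children"),
    n_wtwt = c(316, 329, 110),
    n_wtdel = c(363, 156, 100),
    n_deldel = c(108, 24, 16)
  )
}

# Write a small hand-authored VCF exercising the dosage rules; returns the
# path. 10 usable biallelic SNP records + 1 multi-allelic + 1 indel.
write_toy_vcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=12>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "12\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./.",
    "12\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t1|1\t0|0\t0/1",
    "12\t300\trs3\tG\tA\t.\tPASS\t.\tGT\t0/1\t1/1\t1/1",
    "12\t400\trs4\tT\tC\t.\tPASS\t.\tGT\t0/0\t0/0\t0/1",
    "12\t500\trs5\tA\tC\t.\tPASS\t.\tGT\t1/0\t0/0\t0/0",
    "12\t600\trs6\tC\tG\t.\tPASS\t.\tGT\t0/.\t1/1\t0/0",
    "12\t700\trs7\tG\tT\t.\tPASS\t.\tGT\t0/1\t0/1\t0/1",
    "12\t800\trs8\tT\tA\t.\tPASS\t.\tGT\t1/1\t1/1\t0/0",
    "12\t900\trs9\tA\tT\t.\tPASS\t.\tGT\t0/0\t1/1\t0/1",
    "12\t1000\trs10\tC\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t1/1",
    "12\t1100\trsMulti\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "12\t1200\trsIndel\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"
  )
  writeLines(lines, path)
  path
}

write_tsv_lines <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

# A small simulated cohort shared by model tests (memoised per session).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_samples = 800, n_noise = 30, seed = 101)
      cache <<- suppressMessages(simulate_cohort(cfg))
    }
    cache
  }
})

# deletion-call tibble from a dosage vector
calls_from_dosage <- function(dosage, ids = sprintf("S%04d", seq_along(dosage))) {
  tibble::tibble(sample_id = ids, genotype = deletion_label(dosage),
                 dosage = as.integer(dosage))
}

# multinomial log-likelihood of a 3x3 genotype table given f11 and fixed
# allele frequencies: the independent grid-search oracle for the EM.
genotype_loglik <- function(tab, f11, px, py) {
  f10 <- px - f11; f01 <- py - f11; f00 <- 1 - px - py + f11
  if (min(f10, f01, f00, f11) < 0) return(-Inf)
  gp <- matrix(0, 3, 3)
  gp[1, 1] <- f00^2;        gp[1, 2] <- 2 * f00 * f01; gp[1, 3] <- f01^2
  gp[2, 1] <- 2 * f00 * f10; gp[2, 2] <- 2 * (f11 * f00 + f10 * f01)
  gp[2, 3] <- 2 * f01 * f11
  gp[3, 1] <- f10^2;        gp[3, 2] <- 2 * f10 * f11; gp[3, 3] <- f11^2
  ok <- tab > 0
  sum(tab[ok] * log(gp[ok]))
}

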