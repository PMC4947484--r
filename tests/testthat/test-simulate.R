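# Two-locus haplotype algebra and the synthetic-cohort generator.

test_that("haplotype table obeys marginals and rejects bound violations", {
  # independence
  f0 <- haplotype_table(0.3, 0.4, 0)
  expect_equal(unname(f0["del_alt"]), 0.12, tolerance = 1e-12)
  expect_equal(sum(f0), 1, tolerance = 1e-12)
  # perfect LD with equal frequencies
  f1 <- haplotype_table(0.3, 0.3, 1)
  expect_equal(unname(f1), c(0.3, 0, 0, 0.7), tolerance = 1e-12)
  # marginals always exact
  f <- haplotype_table(0.36, 0.25, 0.5)
  expect_equal(unname(f["del_alt"] + f["del_ref"]), 0.36, tolerance = 1e-12)
  expect_equal(unname(f["del_alt"] + f["wt_alt"]), 0.25, tolerance = 1e-12)
  # spec violating the Lewontin bounds is rejected with the offending cell
  expect_error(haplotype_table(0.35, 0.40, 0.9),
               class = "deltag_config_error")
  expect_error(sim_config(tags = tibble::tibble(
    snp_id = "bad", p_alt = 0.40, r = 0.9, pos = 1L), p_del = 0.35),
    class = "deltag_config_error")
})

test_that("simulated allele frequencies match their targets", {
  cfg <- sim_config(n_samples = 5000, p_del = 0.36, n_noise = 0, seed = 12)
  co <- simulate_genotypes(cfg)
  freq <- mean(attr(co, "truth")$true_dosage) / 2
  expect_lt(abs(freq - 0.36), 0.02)
})

test_that("realized tag LD lands near its target", {
  cfg <- sim_config(
    n_samples = 2000, n_noise = 0,
    tags = tibble::tibble(snp_id = "t", p_alt = 0.36, r = 0.97, pos = 1L),
    seed = 13)
  co <- simulate_genotypes(cfg)
  r2 <- attr(co, "truth")$tag_r2$realized_r2
  expect_gte(r2, 0.89); expect_lte(r2, 0.97)
})

test_that("missingness masks are applied exactly as configured", {
  cfg0 <- sim_config(n_samples = 300, n_noise = 10, seed = 14)
  expect_false(anyNA(simulate_genotypes(cfg0)$dosages))
  cfg <- sim_config(n_samples = 300, n_noise = 10, miss_snp = 0.1,
                    miss_del = 0.1, seed = 14)
  co <- simulate_genotypes(cfg)
  expect_gt(sum(is.na(co$dosages)), 0)
  expect_gt(sum(is.na(co$deletion$dosage)), 0)
  # truth record keeps unmasked dosages
  expect_false(anyNA(attr(co, "truth")$true_dosage))
})

test_that("deletion genotypes drawn by haplotype union are in HWE", {
  set.seed(15)
  reject <- vapply(seq_len(1000), function(i) {
    g <- rbinom(500, 1, 0.36) + rbinom(500, 1, 0.36)  # union of 2 haplotypes
    counts <- genotype_counts("sim", sum(g == 0), sum(g == 1), sum(g == 2))
    hwe_lrt(counts)$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(reject) - 0.05), 0.02)
})

test_that("phenotype model recovers its planted age slope", {
  cfg <- sim_config(n_samples = 10000, n_noise = 0, seed = 16)
  co <- simulate_cohort(cfg)
  y <- as.integer(co$phenotypes$phenotype == "case")
  fit <- glm(y ~ co$phenotypes$age, family = binomial())
  expect_lt(abs(coef(fit)[2] - log(1.07)) / log(1.07), 0.2)
})

test_that("balanced null phenotype model yields ~50% cases", {
  cfg <- sim_config(n_samples = 5000, n_noise = 0, intercept_odds = 1,
                    or_age = 1, or_female = 1, seed = 17)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$phenotypes$phenotype == "case") - 0.5), 0.02)
})

test_that("planted genotype effect is recovered within its CI", {
  cfg <- sim_config(n_samples = 10000, n_noise = 0, or_deldel = 3, seed = 18)
  co <- simulate_cohort(cfg)
  td <- tidy(genotype_association(co))
  row <- td[td$term == "genotypedel/del", ]
  expect_gt(row$or, 2.4); expect_lt(row$or, 3.7)
})

test_that("fixture files round-trip through the cohort readers", {
  cfg <- sim_config(n_samples = 150, n_noise = 8, seed = 19)
  co <- simulate_cohort(cfg)
  dir <- tempfile()
  paths <- write_fixture(co, dir)
  m <- read_snp_vcf(paths$vcf)
  expect_equal(nrow(m$snps), ncol(co$dosages))
  # VCF is emitted position-sorted; compare after aligning columns
  ord <- colnames(co$dosages)[order(co$snps$pos)]
  expect_identical(m$dosages[rownames(co$dosages), ord],
                   co$dosages[, ord])
  calls <- read_deletion_calls(paths$deletion)
  expect_equal(calls$dosage, co$deletion$dosage)
  ph <- read_phenotypes(paths$phenotypes)
  expect_equal(ph$age, co$phenotypes$age, tolerance = 1e-6)
  cohort2 <- assemble_cohort(m, calls, ph)
  expect_equal(n_samples(cohort2), 150)
  # truth JSON agrees with a fresh scan of the written files within 1e-9
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  scan <- scan_ld(cohort2, threshold = 0)
  for (k in seq_len(nrow(truth$tag_r2))) {
    expect_equal(scan$r2[scan$snp_id == truth$tag_r2$snp_id[k]],
                 truth$tag_r2$realized_r2[k], tolerance = 1e-9)
  }
})

test_that("config validation and file round-trip work", {
  cfg <- sim_config(n_samples = 50, seed = 20)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_samples = 50, p_del = 0.3, n_noise = 5,
                            seed = 20),
                       path, auto_unbox = TRUE)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$p_del, 0.3)
  jsonlite::write_json(list(n_samples = 50, bogus_key = 1), path,
                       auto_unbox = TRUE)
  expect_error(read_sim_config(path), class = "deltag_config_error")
})

test_that("imputation concordance rises with planted tag LD", {
  conc <- vapply(c(0.5, 0.75, 0.94), function(r2) {
    vals <- vapply(1:3, function(s) {
      cfg <- sim_config(
        n_samples = 800, n_noise = 0,
        tags = tibble::tibble(snp_id = "t", p_alt = 0.36, r = sqrt(r2),
                              pos = 1L),
        seed = 9000 + round(100 * r2) + s)
      co <- simulate_genotypes(cfg)
      p <- forest_params(n_trees = 150, seed = s)
      forest <- train_tag_forest(co, "t", p)
      report <- evaluate_topk_models(co, forest$importance, k_max = 1,
                                     params = p)
      model <- suppressMessages(select_best_model(report))
      calls <- impute_genotypes(model, co)$calls
      mean(calls$dosage == attr(co, "truth")$true_dosage[calls$sample_id])
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(conc) > 0))
})
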