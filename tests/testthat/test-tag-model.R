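# Forest training, importance ranking, top-k model selection, imputation.

test_that("a perfectly predictive SNP separates the classes", {
  set.seed(1)
  d <- sample(0:2, 300, replace = TRUE)
  cohort <- structure(list(
    snps = tibble::tibble(snp_id = c("perfect", "junk"), chrom = "12",
                          pos = c(1L, 2L), ref = "A", alt = "G"),
    dosages = cbind(perfect = d, junk = sample(0:2, 300, TRUE)) |>
      (\(m) {rownames(m) <- sprintf("S%03d", 1:300); m})(),
    deletion = calls_from_dosage(d, sprintf("S%03d", 1:300)),
    phenotypes = NULL,
    dropped = c(snp_matrix = 0L, deletion_calls = 0L, phenotypes = 0L)
  ), class = "del_cohort")
  forest <- train_tag_forest(cohort, c("perfect", "junk"),
                             forest_params(n_trees = 100, seed = 3))
  expect_equal(forest$importance$snp_id[1], "perfect")
  expect_gt(forest$importance$importance[1], 0)
  # noise importance ~ 0 relative to the predictive SNP
  expect_lt(forest$importance$importance[2],
            forest$importance$importance[1] / 10)
  report <- evaluate_topk_models(cohort, forest$importance, k_max = 1,
                                 params = forest_params(n_trees = 100, seed = 3))
  expect_equal(report$accuracy[1], 1)
  expect_equal(report$kappa[1], 1)
})

test_that("planted tags dominate the importance ranking", {
  co <- small_cohort()
  scan <- scan_ld(co)
  forest <- train_tag_forest(co, scan$snp_id,
                             forest_params(n_trees = 300, seed = 11))
  expect_setequal(forest$importance$snp_id[1:3], c("tagA", "tagB", "tagC"))
})

test_that("training is deterministic given the seed", {
  co <- small_cohort()
  scan <- scan_ld(co)
  p <- forest_params(n_trees = 100, seed = 17)
  f1 <- train_tag_forest(co, scan$snp_id, p)
  f2 <- train_tag_forest(co, scan$snp_id, p)
  expect_identical(f1$importance, f2$importance)
  r1 <- evaluate_topk_models(co, f1$importance, k_max = 2, params = p)
  r2 <- evaluate_topk_models(co, f2$importance, k_max = 2, params = p)
  expect_identical(dplyr::select(tibble::as_tibble(r1), -fit),
                   dplyr::select(tibble::as_tibble(r2), -fit))
  m1 <- select_best_model(r1); m2 <- select_best_model(r2)
  i1 <- impute_genotypes(m1, co); i2 <- impute_genotypes(m2, co)
  expect_identical(i1$calls, i2$calls)
})

test_that("top-k accuracy is non-decreasing to k = 3 on planted tags", {
  co <- small_cohort()
  scan <- scan_ld(co)
  p <- forest_params(n_trees = 300, seed = 23)
  forest <- train_tag_forest(co, scan$snp_id, p)
  report <- evaluate_topk_models(co, forest$importance, k_max = 3, params = p)
  expect_true(all(diff(report$accuracy) >= -0.01))
  expect_true(all(report$n_correct <= report$n_total))
  expect_equal(report$accuracy, report$n_correct / report$n_total)
})

test_that("model selection prefers fewest misclassifications, then kappa, then parsimony", {
  # synthesise a report with known orderings
  fake_report <- function(k, n_correct, kappa) {
    tibble::tibble(k = k, snp_ids = purrr::map(k, ~letters[seq_len(.x)]),
                   n_correct = n_correct, n_total = 309,
                   accuracy = n_correct / 309, kappa = kappa,
                   kappa_ci_low = kappa - .02, kappa_ci_high = kappa + .02,
                   kappa_weighted = kappa, kappa_weighted_ci_low = kappa - .02,
                   kappa_weighted_ci_high = kappa + .02,
                   evaluation = "resubstitution",
                   fit = purrr::map(k, ~list(params = list())))
  }
  # published selection: 289 correct at k=1 vs 292 at k=3 -> k=3 wins
  r <- fake_report(c(1, 3), c(289, 292), c(0.90, 0.91))
  expect_equal(suppressMessages(select_best_model(r))$k, 3)
  # equal misclassifications and kappa -> smaller k
  r2 <- fake_report(c(2, 4), c(290, 290), c(0.90, 0.90))
  expect_equal(suppressMessages(select_best_model(r2))$k, 2)
  # tie on misclassifications broken by kappa
  r3 <- fake_report(c(2, 3), c(290, 290), c(0.89, 0.93))
  expect_equal(suppressMessages(select_best_model(r3))$k, 3)
  # single row -> that row
  r4 <- fake_report(1, 300, 0.95)
  expect_equal(suppressMessages(select_best_model(r4))$k, 1)
})

test_that("imputation excludes samples with missing model SNPs and reconciles", {
  cfg <- sim_config(n_samples = 500, n_noise = 5, miss_snp = 0.05, seed = 41)
  co <- suppressMessages(simulate_cohort(cfg))
  scan <- scan_ld(co)
  p <- forest_params(n_trees = 200, seed = 41)
  forest <- suppressMessages(train_tag_forest(co, scan$snp_id[1:3], p))
  report <- suppressMessages(
    evaluate_topk_models(co, forest$importance, k_max = 3, params = p))
  model <- suppressMessages(select_best_model(report))
  res <- impute_genotypes(model, co)
  expect_equal(nrow(res$calls) + length(res$excluded), n_samples(co))
  incomplete <- rowSums(is.na(co$dosages[, model$snp_ids, drop = FALSE])) > 0
  expect_setequal(res$excluded, rownames(co$dosages)[incomplete])
  expect_true(all(res$calls$source == "imputed"))
  # class counts reconcile
  expect_equal(sum(table(res$calls$dosage)), n_samples(co) - length(res$excluded))
  # absent model SNP -> error naming it
  co_small <- co
  co_small$dosages <- co_small$dosages[, setdiff(colnames(co$dosages),
                                                 model$snp_ids[1])]
  co_small$snps <- co_small$snps[co_small$snps$snp_id != model$snp_ids[1], ]
  expect_error(impute_genotypes(model, co_small), regexp = model$snp_ids[1],
               class = "deltag_validation_error")
})

test_that("training-set re-imputation agrees with the resubstitution report", {
  co <- small_cohort()
  scan <- scan_ld(co)
  p <- forest_params(n_trees = 300, seed = 29)
  forest <- train_tag_forest(co, scan$snp_id, p)
  report <- evaluate_topk_models(co, forest$importance, k_max = 3, params = p)
  model <- suppressMessages(select_best_model(report))
  res <- impute_genotypes(model, co)
  agree <- mean(res$calls$dosage ==
                  co$deletion$dosage[match(res$calls$sample_id,
                                           co$deletion$sample_id)])
  expect_equal(agree, report$accuracy[report$k == model$k], tolerance = 1e-12)
})

test_that("imputed genotypes stay in HWE when the simulator draws HWE", {
  pvals <- vapply(1:10, function(s) {
    cfg <- sim_config(n_samples = 2000, n_noise = 0, seed = 5000 + s)
    co <- simulate_genotypes(cfg)
    p <- forest_params(n_trees = 150, seed = s)
    forest <- train_tag_forest(co, cfg$tags$snp_id, p)
    report <- evaluate_topk_models(co, forest$importance, k_max = 3, params = p)
    model <- suppressMessages(select_best_model(report))
    calls <- impute_genotypes(model, co)$calls
    counts <- genotype_counts("sim", sum(calls$dosage == 0),
                              sum(calls$dosage == 1), sum(calls$dosage == 2))
    hwe_lrt(counts)$p
  }, numeric(1))
  expect_true(all(pvals > 0.01))
})

test_that("a noise-only forest cannot beat the majority class", {
  cfg <- sim_config(n_samples = 600, n_noise = 30, tags = default_tags()[0, ],
                    seed = 71)
  co <- simulate_genotypes(cfg)
  forest <- train_tag_forest(co, colnames(co$dosages),
                             forest_params(n_trees = 200, seed = 71))
  majority <- max(table(co$deletion$dosage)) / n_samples(co)
  oob_acc <- 1 - forest$oob_error
  expect_lt(abs(oob_acc - majority), 0.05)
})

test_that("model serialization round-trips with format versioning", {
  co <- small_cohort()
  scan <- scan_ld(co)
  p <- forest_params(n_trees = 100, seed = 13)
  forest <- train_tag_forest(co, scan$snp_id[1:2], p)
  report <- evaluate_topk_models(co, forest$importance, k_max = 2, params = p)
  model <- suppressMessages(select_best_model(report))
  path <- tempfile(fileext = ".rds")
  write_tag_model(model, path)
  model2 <- read_tag_model(path)
  expect_identical(model2$snp_ids, model$snp_ids)
  i1 <- impute_genotypes(model, co)
  i2 <- impute_genotypes(model2, co)
  expect_identical(i1$calls, i2$calls)
  # version check
  saveRDS(list(format_version = "0.0", model = model), path)
  expect_error(read_tag_model(path), class = "deltag_validation_error")
})
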