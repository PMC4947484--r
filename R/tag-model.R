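# Tree-ensemble classifier of deletion genotype from candidate SNPs:
# permutation-importance ranking, reduction to a minimal 1-4 tag-SNP
# model selected by misclassifications and Cohen's kappa, and imputation
# into new cohorts. Forests are grown with ranger.

#' Random-forest hyperparameters
#'
#' @param n_trees Number of trees (default 500).
#' @param mtry Candidate features per split; default
#'   `floor(sqrt(p))` chosen at fit time.
#' @param min_node_size Minimum terminal node size (default 1,
#'   classification convention).
#' @param importance `"permutation"` (out-of-bag permutation importance,
#'   default) or `"impurity"` (Gini).
#' @param seed Integer seed; every fit with the same seed, data and
#'   parameters is identical.
#' @return A `forest_params` list.
#' @export
forest_params <- function(n_trees = 500, mtry = NULL, min_node_size = 1,
                          importance = c("permutation", "impurity"),
                          seed = 1) {
  importance <- match.arg(importance)
  stopifnot(n_trees >= 1, min_node_size >= 1)
  structure(
    list(n_trees = as.integer(n_trees), mtry = mtry,
         min_node_size = as.integer(min_node_size),
         importance = importance, seed = as.integer(seed)),
    class = "forest_params"
  )
}

# Feature frame (samples with non-missing label x candidate SNPs) with
# per-SNP median imputation of missing dosages.
forest_frame <- function(cohort, candidate_ids) {
  missing_snps <- setdiff(candidate_ids, colnames(cohort$dosages))
  if (length(missing_snps)) {
    abort(sprintf("Candidate SNP(s) absent from cohort: %s",
                  paste(missing_snps, collapse = ", ")),
          class = "deltag_validation_error")
  }
  keep <- !is.na(cohort$deletion$dosage)
  x <- cohort$dosages[keep, candidate_ids, drop = FALSE]
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- median(x[!nas, j])
    }
    inform(sprintf("train: median-imputed %d missing feature value(s)",
                   n_imputed))
  }
  df <- as.data.frame(x)
  names(df) <- make.names(candidate_ids)
  df$.label <- factor(deletion_label(cohort$deletion$dosage[keep]),
                      levels = DELETION_LEVELS)
  attr(df, "snp_ids") <- candidate_ids
  df
}

#' Train a random forest of deletion genotype on candidate SNPs
#'
#' Grows a classification forest (bootstrap resamples, random feature
#' subset per split, Gini splitting, majority vote) on the candidate
#' SNPs and computes variable importance. Samples with missing deletion
#' calls are excluded; missing feature dosages are median-imputed per
#' SNP with a reported count.
#'
#' @param cohort A `del_cohort`.
#' @param candidate_ids SNP ids to use as features (typically
#'   `scan_ld(cohort)$snp_id`).
#' @param params A [forest_params()].
#' @return A `tag_forest`: list with `fit` (the ranger object),
#'   `importance` (descending tibble of `snp_id`, `importance`),
#'   `oob_error`, `snp_ids`, `params`.
#' @export
train_tag_forest <- function(cohort, candidate_ids, params = forest_params()) {
  stopifnot(inherits(cohort, "del_cohort"), inherits(params, "forest_params"))
  if (length(candidate_ids) == 0) {
    abort("No candidate SNPs supplied", class = "deltag_validation_error")
  }
  df <- forest_frame(cohort, candidate_ids)
  if (length(unique(df$.label)) < 2) {
    abort("Deletion labels are single-class; cannot train a classifier",
          class = "deltag_validation_error")
  }
  mtry <- params$mtry %||% max(1L, floor(sqrt(length(candidate_ids))))
  fit <- ranger::ranger(
    dependent.variable.name = ".label",
    data = df,
    num.trees = params$n_trees,
    mtry = min(mtry, length(candidate_ids)),
    min.node.size = params$min_node_size,
    importance = params$importance,
    seed = params$seed,
    num.threads = 1,
    respect.unordered.factors = "order"
  )
  imp <- fit$variable.importance
  snp_ids <- attr(df, "snp_ids")
  ranking <- tibble::tibble(
    snp_id = snp_ids[match(names(imp), make.names(snp_ids))],
    importance = as.numeric(imp)
  )
  ranking <- dplyr::arrange(ranking, dplyr::desc(.data$importance))
  structure(
    list(fit = fit, importance = ranking,
         oob_error = fit$prediction.error,
         snp_ids = candidate_ids, params = params),
    class = "tag_forest"
  )
}

#' @export
print.tag_forest <- function(x, ...) {
  cat(sprintf("<tag_forest> %d SNPs, %d trees, OOB error %.4f\n",
              length(x$snp_ids), x$params$n_trees, x$oob_error))
  print(head(x$importance, 5))
  invisible(x)
}

# Predictions of a fitted forest on a cohort's feature frame.
forest_predict_dosage <- function(fit, df) {
  pred <- predict(fit, data = df, num.threads = 1)$predictions
  deletion_dosage(as.character(pred))
}

#' Evaluate nested top-k tag-SNP models
#'
#' For each `k` in `1..k_max`, retrains the forest on the `k`
#' highest-importance SNPs and records accuracy and Cohen's kappa
#' (unweighted and quadratic-weighted) against the experimental calls,
#' either on resubstituted predictions (how published training-set
#' cross-tabulations are built) or
#' on out-of-bag predictions (internally unbiased).
#'
#' @param cohort A `del_cohort`.
#' @param ranking Importance tibble from [train_tag_forest()] (or any
#'   tibble with `snp_id` in rank order).
#' @param k_max Largest panel size to evaluate (default 4).
#' @param params A [forest_params()].
#' @param evaluation `"resubstitution"` (default) or `"oob"`.
#' @return A `tag_selection_report` tibble: one row per `k` with
#'   `snp_ids` (list-column), `n_correct`, `n_total`, `accuracy`,
#'   `kappa`, `kappa_ci_low`, `kappa_ci_high`, `kappa_weighted`,
#'   `kappa_weighted_ci_low`, `kappa_weighted_ci_high` and a `fit`
#'   list-column holding each trained `tag_forest`.
#' @export
evaluate_topk_models <- function(cohort, ranking, k_max = 4,
                                 params = forest_params(),
                                 evaluation = c("resubstitution", "oob")) {
  evaluation <- match.arg(evaluation)
  stopifnot(k_max >= 1)
  if (k_max > nrow(ranking)) {
    abort(sprintf("k_max (%d) exceeds ranking length (%d)", k_max,
                  nrow(ranking)),
          class = "deltag_validation_error")
  }
  rows <- purrr::map(seq_len(k_max), function(k) {
    ids <- ranking$snp_id[seq_len(k)]
    forest <- train_tag_forest(cohort, ids, params)
    df <- forest_frame(cohort, ids)
    pred <- if (evaluation == "resubstitution") {
      forest_predict_dosage(forest$fit, df)
    } else {
      deletion_dosage(as.character(forest$fit$predictions))
    }
    truth <- deletion_dosage(as.character(df$.label))
    cm <- cross_tabulate(truth, pred)
    ku <- cohen_kappa(cm, "none")
    kw <- cohen_kappa(cm, "quadratic")
    acc <- overall_accuracy(cm)
    tibble::tibble(
      k = k,
      snp_ids = list(ids),
      n_correct = acc$n_correct,
      n_total = acc$n,
      accuracy = acc$accuracy,
      kappa = ku$kappa,
      kappa_ci_low = ku$ci_low, kappa_ci_high = ku$ci_high,
      kappa_weighted = kw$kappa,
      kappa_weighted_ci_low = kw$ci_low,
      kappa_weighted_ci_high = kw$ci_high,
      evaluation = evaluation,
      fit = list(forest)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tag_selection_report", class(out))
  out
}

#' Select the best tag-SNP model from a selection report
#'
#' Picks the row with the fewest misclassifications; ties are broken by
#' higher unweighted kappa, then by smaller panel size (parsimony).
#'
#' @param report A `tag_selection_report` from [evaluate_topk_models()].
#' @return A `tag_snp_model`: list with `snp_ids`, `fit` (the trained
#'   `tag_forest`), `k`, `report` (fit columns dropped), `params`.
#' @export
select_best_model <- function(report) {
  if (nrow(report) == 0) {
    abort("Empty selection report", class = "deltag_validation_error")
  }
  miscls <- report$n_total - report$n_correct
  ord <- order(miscls, -report$kappa, report$k)
  best <- ord[1]
  inform(sprintf(
    "select_best_model: k = %d (%d misclassification(s), kappa %.3f)",
    report$k[best], miscls[best], report$kappa[best]))
  structure(
    list(
      snp_ids = report$snp_ids[[best]],
      fit = report$fit[[best]],
      k = report$k[best],
      report = dplyr::select(tibble::as_tibble(report), -"fit"),
      params = report$fit[[best]]$params
    ),
    class = "tag_snp_model"
  )
}

#' @export
print.tag_snp_model <- function(x, ...) {
  cat(sprintf("<tag_snp_model> %d tag SNP(s): %s\n", x$k,
              paste(x$snp_ids, collapse = ", ")))
  invisible(x)
}

#' Impute deletion genotypes in a new cohort with a tag-SNP model
#'
#' Applies the trained classifier to every sample with complete dosages
#' at the model SNPs; samples missing any model-SNP dosage are excluded
#' and listed, mirroring the complete-data restriction used when a panel
#' is deployed. Model SNPs are matched by id, falling back to
#' `chrom:pos`.
#'
#' @param model A `tag_snp_model`.
#' @param snp_matrix A `snp_matrix` (or `del_cohort`) holding the target
#'   cohort's SNP dosages.
#' @return List with `calls` (tibble `sample_id`, `genotype`, `dosage`,
#'   `source = "imputed"`) and `excluded` (character vector of sample
#'   ids dropped for missingness).
#' @export
impute_genotypes <- function(model, snp_matrix) {
  stopifnot(inherits(model, "tag_snp_model"))
  dosages <- snp_matrix$dosages
  snps <- snp_matrix$snps
  idx <- match(model$snp_ids, colnames(dosages))
  if (anyNA(idx)) {
    # fall back to chrom:pos matching for SNPs trained under another id
    model_snps <- model$fit$snp_ids[is.na(idx)]
    key <- paste0(snps$chrom, ":", snps$pos)
    alt_idx <- match(model_snps, key)
    idx[is.na(idx)] <- alt_idx
  }
  if (anyNA(idx)) {
    abort(sprintf("Model SNP(s) absent from target matrix: %s",
                  paste(model$snp_ids[is.na(idx)], collapse = ", ")),
          class = "deltag_validation_error")
  }
  x <- dosages[, idx, drop = FALSE]
  complete <- rowSums(is.na(x)) == 0
  excluded <- rownames(dosages)[!complete]
  if (sum(complete) == 0) {
    abort("No samples with complete model-SNP dosages",
          class = "deltag_validation_error")
  }
  df <- as.data.frame(x[complete, , drop = FALSE])
  names(df) <- make.names(model$snp_ids)
  dosage <- forest_predict_dosage(model$fit$fit, df)
  list(
    calls = tibble::tibble(
      sample_id = rownames(dosages)[complete],
      genotype = deletion_label(dosage),
      dosage = as.integer(dosage),
      source = "imputed"
    ),
    excluded = excluded
  )
}

MODEL_FORMAT_VERSION <- "1.0"

#' Serialize / restore a tag-SNP model
#'
#' The model is written as a single self-describing, format-versioned
#' file (RDS) containing the SNP panel, hyperparameters, selection
#' report and trees.
#'
#' @param model A `tag_snp_model`.
#' @param path File path.
#' @return `write_tag_model()`: `path` invisibly; `read_tag_model()`:
#'   the restored `tag_snp_model`.
#' @export
write_tag_model <- function(model, path) {
  stopifnot(inherits(model, "tag_snp_model"))
  saveRDS(list(format_version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname write_tag_model
#' @export
read_tag_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path), class = "deltag_io_error")
  }
  obj <- readRDS(path)
  if (!identical(obj$format_version, MODEL_FORMAT_VERSION)) {
    abort(sprintf("Unsupported model format version: %s",
                  obj$format_version %||% "<missing>"),
          class = "deltag_validation_error")
  }
  obj$model
}

#' Write a model-selection report to TSV
#'
#' @param report A `tag_selection_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(report, path) {
  flat <- dplyr::mutate(
    dplyr::select(tibble::as_tibble(report), -dplyr::any_of("fit")),
    snp_ids = purrr::map_chr(.data$snp_ids, paste, collapse = "+")
  )
  readr::write_tsv(flat, path, progress = FALSE)
  invisible(path)
}
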