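# Cross-tabulation of experimental vs imputed deletion genotypes and
# chance-corrected agreement (Cohen's kappa, unweighted and weighted).

#' Cross-tabulate true and predicted deletion genotypes
#'
#' Builds the 3x3 confusion matrix over samples with both calls
#' non-missing. Category order is fixed as wt/wt, wt/del, del/del; rows
#' are truth, columns are predictions.
#'
#' @param truth,predicted Deletion-call tibbles (`sample_id` + `dosage`)
#'   or plain dosage vectors of equal length.
#' @return A `del_confusion` object: list with `counts` (3x3 integer
#'   matrix) and `n`.
#' @export
cross_tabulate <- function(truth, predicted) {
  pair <- align_calls(truth, predicted)
  if (nrow(pair) == 0) {
    abort("No samples with both truth and predicted calls non-missing",
          class = "deltag_validation_error")
  }
  counts <- table(
    factor(deletion_label(pair$t), levels = DELETION_LEVELS),
    factor(deletion_label(pair$p), levels = DELETION_LEVELS)
  )
  counts <- matrix(as.integer(counts), 3, 3,
                   dimnames = list(truth = DELETION_LEVELS,
                                   predicted = DELETION_LEVELS))
  new_del_confusion(counts)
}

align_calls <- function(truth, predicted) {
  get <- function(x) {
    if (is.data.frame(x)) x else
      tibble::tibble(sample_id = seq_along(x), dosage = as.integer(x))
  }
  t <- get(truth); p <- get(predicted)
  ids <- intersect(t$sample_id, p$sample_id)
  if (length(ids) == 0) {
    abort("No overlapping sample ids between truth and predicted calls",
          class = "deltag_validation_error")
  }
  td <- t$dosage[match(ids, t$sample_id)]
  pd <- p$dosage[match(ids, p$sample_id)]
  ok <- !is.na(td) & !is.na(pd)
  tibble::tibble(sample_id = ids[ok], t = td[ok], p = pd[ok])
}

#' Construct a confusion matrix from counts
#'
#' @param counts 3x3 non-negative integer matrix, rows = truth, columns =
#'   predicted, category order wt/wt, wt/del, del/del.
#' @return A `del_confusion` object.
#' @examples
#' # published training-set agreement table for a 3-genotype classifier
#' cm <- del_confusion(rbind(c(119, 2, 0), c(10, 127, 3), c(0, 3, 45)))
#' overall_accuracy(cm)
#' @export
del_confusion <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3)) || any(counts < 0) ||
      any(counts != round(counts))) {
    abort("counts must be a 3x3 non-negative integer matrix",
          class = "deltag_validation_error")
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(truth = DELETION_LEVELS,
                           predicted = DELETION_LEVELS)
  new_del_confusion(counts)
}

new_del_confusion <- function(counts) {
  n <- sum(counts)
  if (n < 1) {
    abort("Confusion matrix must contain at least one observation",
          class = "deltag_validation_error")
  }
  structure(list(counts = counts, n = as.integer(n)),
            class = "del_confusion")
}

#' @export
print.del_confusion <- function(x, ...) {
  cat(sprintf("<del_confusion> n = %d\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A `del_confusion`.
#' @return Tibble with `n_correct`, `n`, `accuracy` (trace/n) and
#'   `percent` (rendered to two decimals).
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "del_confusion"))
  correct <- sum(diag(cm$counts))
  tibble::tibble(
    n_correct = correct,
    n = cm$n,
    accuracy = correct / cm$n,
    percent = sprintf("%.2f%%", 100 * correct / cm$n)
  )
}

kappa_weights <- function(weighting, k = 3) {
  d <- abs(outer(seq_len(k), seq_len(k), "-"))
  switch(weighting,
    none = (d == 0) * 1,
    linear = 1 - d / (k - 1),
    quadratic = 1 - (d / (k - 1))^2
  )
}

#' Cohen's kappa (unweighted or weighted) with asymptotic CI
#'
#' Chance-corrected agreement between the truth and predicted axes of a
#' confusion matrix. Weights are identity (`"none"`), linear
#' (`1 - |i-j|/(k-1)`) or quadratic Fleiss-Cohen (`1 - (i-j)^2/(k-1)^2`).
#' The standard error is the large-sample (Fleiss-Cohen-Everitt)
#' asymptotic for the estimate, and the 95% CI is `kappa +/- 1.96 SE`.
#'
#' @param cm A `del_confusion`.
#' @param weighting One of `"none"`, `"linear"`, `"quadratic"`.
#' @return A `kappa_estimate` object with fields `kappa`, `weighting`,
#'   `se`, `ci_low`, `ci_high`, `po`, `pe`, `n`. Has [tidy()] and
#'   [glance()] methods.
#' @examples
#' cm <- del_confusion(rbind(c(119, 2, 0), c(10, 127, 3), c(0, 3, 45)))
#' cohen_kappa(cm, "none")
#' cohen_kappa(cm, "quadratic")
#' @export
cohen_kappa <- function(cm, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(cm, "del_confusion"))
  if (cm$n < 2) {
    abort("Kappa requires n >= 2", class = "deltag_validation_error")
  }
  k <- nrow(cm$counts)
  w <- kappa_weights(weighting, k)
  p <- cm$counts / cm$n
  r <- rowSums(p); c_ <- colSums(p)
  po <- sum(w * p)
  pe <- sum(w * outer(r, c_))
  if (abs(1 - pe) < 1e-12) {
    abort("Kappa undefined: expected agreement is 1 (degenerate marginals)",
          class = "deltag_validation_error")
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss, Cohen & Everitt asymptotic variance of the weighted kappa
  wbar_i <- as.vector(w %*% c_)   # row-conditional expected weight
  wbar_j <- as.vector(r %*% w)    # column-conditional expected weight
  pen <- outer(wbar_i, wbar_j, "+") * (1 - kappa)
  v <- (sum(p * (w - pen)^2) - (kappa - pe * (1 - kappa))^2) /
    (cm$n * (1 - pe)^2)
  se <- sqrt(max(v, 0))
  structure(
    list(kappa = kappa, weighting = weighting, se = se,
         ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
         po = po, pe = pe, n = cm$n),
    class = "kappa_estimate"
  )
}

#' @export
print.kappa_estimate <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s): %.3f (95%% CI %.3f-%.3f), SE %.4f, n = %d\n",
              x$weighting, x$kappa, x$ci_low, x$ci_high, x$se, x$n))
  invisible(x)
}

#' @rdname cohen_kappa
#' @param x A `kappa_estimate`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.kappa_estimate <- function(x, ...) {
  tibble::tibble(
    weighting = x$weighting, kappa = x$kappa, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, n = x$n
  )
}

#' @rdname cohen_kappa
#' @exportS3Method generics::glance
glance.kappa_estimate <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, po = x$po, pe = x$pe, n = x$n)
}

#' Full agreement report for a pair of call sets
#'
#' Convenience wrapper producing the agreement summary written by the
#' `evaluate` CLI subcommand: accuracy plus unweighted and weighted kappa.
#'
#' @inheritParams cross_tabulate
#' @param weightings Weightings to report (default unweighted and
#'   quadratic).
#' @return Tibble with one row per weighting: `weighting`, `kappa`, `se`,
#'   `ci_low`, `ci_high`, `accuracy`, `n`.
#' @export
agreement_report <- function(truth, predicted,
                             weightings = c("none", "quadratic")) {
  cm <- cross_tabulate(truth, predicted)
  acc <- overall_accuracy(cm)
  purrr::map_dfr(weightings, function(wt) {
    dplyr::mutate(tidy(cohen_kappa(cm, wt)),
                  accuracy = acc$accuracy, .before = "n")
  })
}
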