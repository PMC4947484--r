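# ggplot2 presentations of scan, importance and selection results.

#' Plot an LD scan across the region
#'
#' Position against r-squared for every SNP in the scan (full scan when
#' available), coloured by the conventional LD bins (0.2-0.4, 0.4-0.6,
#' 0.6-0.8, >0.8), with the candidate threshold drawn as a dashed line.
#'
#' @param object An `ld_scan` tibble from [scan_ld()].
#' @param threshold Threshold line to draw (default 0.2).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ld_scan <- function(object, threshold = 0.2, ...) {
  full <- attr(object, "full_scan") %||% object
  full <- dplyr::mutate(
    tibble::as_tibble(full),
    ld_bin = cut(.data$r2, breaks = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                 labels = c("<0.2", "0.2-0.4", "0.4-0.6", "0.6-0.8", ">0.8"),
                 include.lowest = TRUE)
  )
  ggplot2::ggplot(full, ggplot2::aes(x = .data$pos / 1e6, y = .data$r2,
                                     colour = .data$ld_bin)) +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::scale_colour_viridis_d(name = expression(r^2 ~ "bin"),
                                    drop = FALSE) +
    ggplot2::labs(x = "Position (Mb)",
                  y = expression(r^2 ~ "with deletion"),
                  title = "LD between region SNPs and the deletion variant") +
    ggplot2::theme_minimal()
}

#' Plot random-forest variable importance
#'
#' Lollipop chart of per-SNP importance, highest first.
#'
#' @param object A `tag_forest` from [train_tag_forest()].
#' @param top_n Show only the `top_n` most important SNPs (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tag_forest <- function(object, top_n = 30, ...) {
  imp <- head(object$importance, top_n)
  imp$snp_id <- factor(imp$snp_id, levels = rev(imp$snp_id))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$snp_id)) +
    ggplot2::geom_segment(ggplot2::aes(xend = 0, yend = .data$snp_id),
                          colour = "grey60") +
    ggplot2::geom_point(colour = "steelblue", size = 2) +
    ggplot2::labs(x = "Permutation importance", y = NULL,
                  title = "Variable importance in deletion-genotype forest") +
    ggplot2::theme_minimal()
}

#' Plot a model-selection report
#'
#' Accuracy and kappa (with CIs) against panel size `k`.
#'
#' @param object A `tag_selection_report` from [evaluate_topk_models()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tag_selection_report <- function(object, ...) {
  df <- dplyr::select(tibble::as_tibble(object), -dplyr::any_of("fit"))
  long <- tidyr::pivot_longer(
    df[, c("k", "accuracy", "kappa", "kappa_weighted")],
    cols = c("accuracy", "kappa", "kappa_weighted"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = df$k) +
    ggplot2::labs(x = "Tag SNPs in model (k)", y = NULL,
                  title = "Tag-SNP panel selection") +
    ggplot2::theme_minimal()
}
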