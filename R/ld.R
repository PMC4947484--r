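# Pairwise LD (r^2) between the deletion variant and SNP dosages, and the
# region scan that selects candidate tag SNPs.

#' Squared dosage correlation between two genotype vectors
#'
#' The composite (genotype-dosage) LD estimate: the squared Pearson
#' correlation of the two 0/1/2 dosage vectors over pairwise-complete
#' samples. Symmetric in its arguments and invariant under allele-label
#' flips (`dosage -> 2 - dosage`).
#'
#' @param x,y Integer dosage vectors of equal length (values 0/1/2 or NA).
#' @return r-squared in `[0, 1]`, with attribute `n_used` (number of
#'   pairwise-complete samples).
#' @examples
#' dosage_r2(c(0, 1, 2, 0, 1, 2, 0, 0), c(0, 1, 2, 0, 1, 1, 0, 0))
#' @export
dosage_r2 <- function(x, y) {
  if (length(x) != length(y)) {
    abort("Dosage vectors must have equal length",
          class = "deltag_validation_error")
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) {
    abort("Fewer than 2 pairwise-complete samples",
          class = "deltag_undefined_ld")
  }
  xs <- x[ok]; ys <- y[ok]
  vx <- stats::var(xs); vy <- stats::var(ys)
  if (vx == 0 || vy == 0) {
    abort("LD undefined: constant dosage vector on the complete pairs",
          class = "deltag_undefined_ld")
  }
  r <- stats::cov(xs, ys) / sqrt(vx * vy)
  structure(min(r^2, 1), n_used = n)
}

#' EM haplotype-frequency r-squared for two unphased loci
#'
#' Maximises the two-locus multinomial likelihood over the four haplotype
#' frequencies by expectation-maximisation (double heterozygotes are split
#' between cis and trans configurations at each iteration) and returns
#' `r^2 = D^2 / (pA qA pB qB)` at the fixed point. The maximum-likelihood
#' haplotype margins equal the sample allele frequencies, so the EM has a
#' single effective free parameter.
#'
#' @inheritParams dosage_r2
#' @param tol Convergence tolerance on the maximum absolute change in any
#'   haplotype frequency (default 1e-10).
#' @param max_iter Maximum EM iterations (default 1000); non-convergence
#'   raises a warning and returns the last iterate with attribute
#'   `converged = FALSE`.
#' @return r-squared in `[0, 1]` with attributes `n_used`, `converged` and
#'   `haplotypes` (the four estimated frequencies, order 11, 10, 01, 00
#'   with 1 = alt/deletion allele at that locus).
#' @export
em_haplotype_r2 <- function(x, y, tol = 1e-10, max_iter = 1000) {
  if (length(x) != length(y)) {
    abort("Dosage vectors must have equal length",
          class = "deltag_validation_error")
  }
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 2) {
    abort("Fewer than 2 pairwise-complete samples",
          class = "deltag_undefined_ld")
  }
  xs <- x[ok]; ys <- y[ok]
  px <- mean(xs) / 2; py <- mean(ys) / 2
  if (px %in% c(0, 1) || py %in% c(0, 1)) {
    abort("LD undefined: monomorphic locus on the complete pairs",
          class = "deltag_undefined_ld")
  }
  # 3x3 genotype count table, dosage 0..2 each axis
  tab <- table(factor(xs, levels = 0:2), factor(ys, levels = 0:2))
  tab <- matrix(as.numeric(tab), 3, 3)

  # haplotype freqs h[ab]: a = x allele (1 alt), b = y allele
  h11 <- px * py; h10 <- px * (1 - py); h01 <- (1 - px) * py
  h00 <- (1 - px) * (1 - py)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    denom <- h11 * h00 + h10 * h01
    p_cis <- if (denom > 0) h11 * h00 / denom else 0.5
    ndh <- tab[2, 2]
    c11 <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3] + ndh * p_cis
    c10 <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1] + ndh * (1 - p_cis)
    c01 <- 2 * tab[1, 3] + tab[2, 3] + tab[1, 2] + ndh * (1 - p_cis)
    c00 <- 2 * tab[1, 1] + tab[2, 1] + tab[1, 2] + ndh * p_cis
    tot <- c11 + c10 + c01 + c00
    new <- c(c11, c10, c01, c00) / tot
    delta <- max(abs(new - c(h11, h10, h01, h00)))
    h11 <- new[1]; h10 <- new[2]; h01 <- new[3]; h00 <- new[4]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn(sprintf("em_haplotype_r2: EM did not converge in %d iterations",
                 max_iter))
  }
  pa <- h11 + h10; pb <- h11 + h01
  D <- h11 - pa * pb
  r2 <- D^2 / (pa * (1 - pa) * pb * (1 - pb))
  structure(min(r2, 1), n_used = n, converged = converged,
            haplotypes = c(h11 = h11, h10 = h10, h01 = h01, h00 = h00))
}

#' Scan a region for SNPs in LD with the deletion variant
#'
#' Estimates r-squared between the deletion-allele dosage and every SNP in
#' the cohort, and returns the candidates exceeding a threshold, sorted by
#' descending r-squared (ties broken by ascending genomic position). SNPs
#' with undefined LD (monomorphic on the complete pairs) are excluded.
#'
#' @param cohort A `del_cohort` with deletion calls.
#' @param threshold Minimum r-squared for a candidate (default 0.2, the
#'   conventional candidate cut-off); rows with `r2 > threshold` are kept.
#' @param method LD estimator: `"dosage"` (default; squared genotype
#'   correlation) or `"em"` (haplotype EM).
#' @return An `ld_scan` tibble with columns `snp_id`, `chrom`, `pos`,
#'   `r2`, `n_used`, `method`. The unthresholded scan (for plotting or TSV
#'   dump) is attached as attribute `"full_scan"`.
#' @export
scan_ld <- function(cohort, threshold = 0.2, method = c("dosage", "em")) {
  method <- match.arg(method)
  stopifnot(inherits(cohort, "del_cohort"))
  if (ncol(cohort$dosages) < 1) {
    abort("Cohort contains no SNPs", class = "deltag_validation_error")
  }
  if (all(is.na(cohort$deletion$dosage))) {
    abort("Cohort has no non-missing deletion calls",
          class = "deltag_validation_error")
  }
  y <- cohort$deletion$dosage
  est <- if (method == "dosage") dosage_r2 else em_haplotype_r2
  res <- purrr::map(seq_len(ncol(cohort$dosages)), function(j) {
    r2 <- tryCatch(est(cohort$dosages[, j], y),
                   deltag_undefined_ld = function(e) NULL)
    if (is.null(r2)) return(NULL)
    n_used <- attr(r2, "n_used")
    tibble::tibble(
      snp_id = cohort$snps$snp_id[j],
      chrom = cohort$snps$chrom[j],
      pos = cohort$snps$pos[j],
      r2 = as.numeric(r2),
      n_used = n_used,
      method = method
    )
  })
  full <- dplyr::arrange(dplyr::bind_rows(res), dplyr::desc(.data$r2),
                         .data$pos)
  out <- dplyr::filter(full, .data$r2 > threshold)
  attr(out, "full_scan") <- full
  class(out) <- c("ld_scan", class(out))
  out
}

#' Write an LD scan to TSV
#'
#' @param scan An `ld_scan` tibble from [scan_ld()].
#' @param path Output path.
#' @param full Write the unthresholded scan instead of the candidate set.
#' @return `path`, invisibly.
#' @export
write_ld_scan <- function(scan, path, full = FALSE) {
  x <- if (full) attr(scan, "full_scan") else scan
  readr::write_tsv(as.data.frame(x), path, progress = FALSE)
  invisible(path)
}
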