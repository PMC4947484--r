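# Allele frequencies, Hardy-Weinberg likelihood-ratio test,
# cross-population allele-frequency comparison, case-control logistic
# association with covariates, and a Monte-Carlo power calculator.

#' Construct a genotype-count table
#'
#' One row per population: counts of the three deletion genotypes.
#'
#' @param population Character vector of population labels.
#' @param n_wtwt,n_wtdel,n_deldel Non-negative integer genotype counts.
#' @return Tibble with those four columns.
#' @examples
#' genotype_counts("East-Africans", 155, 76, 13)
#' @export
genotype_counts <- function(population, n_wtwt, n_wtdel, n_deldel) {
  out <- tibble::tibble(
    population = as.character(population),
    n_wtwt = as.integer(n_wtwt),
    n_wtdel = as.integer(n_wtdel),
    n_deldel = as.integer(n_deldel)
  )
  if (any(out$n_wtwt < 0 | out$n_wtdel < 0 | out$n_deldel < 0)) {
    abort("Genotype counts must be non-negative",
          class = "deltag_validation_error")
  }
  if (any(out$n_wtwt + out$n_wtdel + out$n_deldel < 1)) {
    abort("Each population must have at least one genotyped sample",
          class = "deltag_validation_error")
  }
  out
}

#' Read a genotype-count table from TSV
#'
#' Columns: `population`, `n_wtwt`, `n_wtdel`, `n_deldel`. This format
#' lets published count tables be analysed without raw data.
#'
#' @param path Path to the TSV file.
#' @return Tibble as from [genotype_counts()].
#' @export
read_genotype_counts <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Genotype-count file not found: %s", path),
          class = "deltag_io_error")
  }
  df <- readr::read_tsv(path, col_types = "ciii", progress = FALSE)
  genotype_counts(df$population, df$n_wtwt, df$n_wtdel, df$n_deldel)
}

#' Deletion-allele frequency from genotype counts
#'
#' @param counts Tibble from [genotype_counts()].
#' @return Input with added columns `n` (samples) and `freq_del`
#'   (`(n_wtdel + 2 n_deldel) / 2n`).
#' @examples
#' allele_frequency(genotype_counts("East-Africans", 155, 76, 13))
#' @export
allele_frequency <- function(counts) {
  dplyr::mutate(
    counts,
    n = .data$n_wtwt + .data$n_wtdel + .data$n_deldel,
    freq_del = (.data$n_wtdel + 2 * .data$n_deldel) / (2 * .data$n)
  )
}

#' Hardy-Weinberg likelihood-ratio (G) test
#'
#' Tests each population's genotype counts against Hardy-Weinberg
#' proportions: expected counts `(q^2 n, 2pq n, p^2 n)` with `p` the
#' deletion-allele frequency, `G = 2 sum O log(O/E)` over cells with
#' `O > 0`, compared to a chi-square with one degree of freedom. When one
#' allele is absent the observed table equals its expectation and `G = 0`.
#'
#' @param counts Tibble from [genotype_counts()].
#' @return Tibble with one row per population: `freq_del`, expected
#'   counts `e_wtwt`, `e_wtdel`, `e_deldel`, `G`, `df`, `p`.
#' @examples
#' hwe_lrt(genotype_counts("pop", 329, 156, 24))
#' @export
hwe_lrt <- function(counts) {
  counts <- allele_frequency(counts)
  purrr::pmap_dfr(counts, function(population, n_wtwt, n_wtdel, n_deldel,
                                   n, freq_del, ...) {
    p <- freq_del; q <- 1 - p
    e <- c(q^2, 2 * p * q, p^2) * n
    o <- c(n_wtwt, n_wtdel, n_deldel)
    if (p == 0 || p == 1) {
      G <- 0
    } else {
      nz <- o > 0
      G <- 2 * sum(o[nz] * log(o[nz] / e[nz]))
      G <- max(G, 0)
    }
    tibble::tibble(
      population = population, n = n, freq_del = p,
      e_wtwt = e[1], e_wtdel = e[2], e_deldel = e[3],
      G = G, df = 1L, p = pchisq(G, df = 1, lower.tail = FALSE)
    )
  })
}

# del/wt allele counts for a one-row genotype-count table
allele_counts <- function(row) {
  del <- row$n_wtdel + 2 * row$n_deldel
  n2 <- 2 * (row$n_wtwt + row$n_wtdel + row$n_deldel)
  c(del = del, wt = n2 - del)
}

#' Allele-level odds ratio between two groups
#'
#' The 2x2 odds ratio of carrying the deletion allele in group `a` versus
#' group `b`. With genotype counts available a Wald confidence interval
#' `exp(log OR +/- 1.96 sqrt(sum 1/cell))` and Wald p-value are computed;
#' with frequencies only, just the point estimate.
#'
#' @param a,b Either one-row tibbles from [genotype_counts()], or scalar
#'   deletion-allele frequencies in `(0, 1)`.
#' @return Tibble with `freq_a`, `freq_b`, `or`, `ci_low`, `ci_high`,
#'   `p_wald` (CI and p `NA` when only frequencies are supplied or a
#'   frequency is 0 or 1).
#' @examples
#' allelic_odds_ratio(0.332, 0.209)
#' @export
allelic_odds_ratio <- function(a, b) {
  from_counts <- is.data.frame(a) && is.data.frame(b)
  if (from_counts) {
    ca <- allele_counts(a); cb <- allele_counts(b)
    fa <- ca["del"] / sum(ca); fb <- cb["del"] / sum(cb)
  } else {
    fa <- as.numeric(a); fb <- as.numeric(b)
  }
  degenerate <- fa %in% c(0, 1) || fb %in% c(0, 1)
  if (degenerate) {
    warn("Allelic OR degenerate: a group frequency is 0 or 1; no CI reported")
    or <- if (fa %in% c(1) || fb %in% c(0)) Inf else 0
    return(tibble::tibble(freq_a = fa, freq_b = fb, or = or,
                          ci_low = NA_real_, ci_high = NA_real_,
                          p_wald = NA_real_))
  }
  or <- (fa / (1 - fa)) / (fb / (1 - fb))
  if (from_counts) {
    se <- sqrt(sum(1 / c(ca, cb)))
    z <- log(or) / se
    tibble::tibble(
      freq_a = unname(fa), freq_b = unname(fb), or = unname(or),
      ci_low = unname(exp(log(or) - 1.96 * se)),
      ci_high = unname(exp(log(or) + 1.96 * se)),
      p_wald = unname(2 * stats::pnorm(-abs(z)))
    )
  } else {
    tibble::tibble(freq_a = fa, freq_b = fb, or = or,
                   ci_low = NA_real_, ci_high = NA_real_, p_wald = NA_real_)
  }
}

#' Allele-level logistic regression of deletion frequency on population
#'
#' Expands each sample's genotype into two allele observations (0 =
#' wild-type, 1 = deletion) and regresses allele state on population
#' membership by logistic regression. For this saturated model each
#' group's odds ratio versus the reference equals the closed-form 2x2
#' allelic odds ratio. Alleles within an individual are treated as
#' independent, which understates within-individual correlation; the
#' construction is conventional for published count tables.
#'
#' @param counts Tibble from [genotype_counts()], at least two rows.
#' @param reference Population label used as the OR reference.
#' @return Tibble with one row per non-reference population: `freq_del`,
#'   `or`, `ci_low`, `ci_high`, `p_wald`, `monomorphic` (flagged groups
#'   have no Wald reporting). The overall likelihood-ratio test of any
#'   frequency difference is attached as attributes `"lrt_stat"`,
#'   `"lrt_df"`, `"lrt_p"`.
#' @export
population_freq_regression <- function(counts, reference) {
  if (nrow(counts) < 2) {
    abort("Need at least two populations", class = "deltag_validation_error")
  }
  if (!reference %in% counts$population) {
    abort(sprintf("Reference population '%s' not present", reference),
          class = "deltag_validation_error")
  }
  counts <- allele_frequency(counts)
  mono <- counts$freq_del %in% c(0, 1)
  if (any(mono)) {
    warn(sprintf("Monomorphic group(s) excluded from Wald reporting: %s",
                 paste(counts$population[mono], collapse = ", ")))
  }
  df <- tibble::tibble(
    population = factor(counts$population,
                        levels = c(reference,
                                   setdiff(counts$population, reference))),
    del = counts$n_wtdel + 2 * counts$n_deldel,
    wt = 2 * counts$n - (counts$n_wtdel + 2 * counts$n_deldel)
  )
  fit <- glm(cbind(del, wt) ~ population, family = binomial(), data = df,
             control = list(epsilon = 1e-10, maxit = 100))
  fit0 <- glm(cbind(del, wt) ~ 1, family = binomial(), data = df,
              control = list(epsilon = 1e-10, maxit = 100))
  lrt <- fit0$deviance - fit$deviance
  lrt_df <- fit0$df.residual - fit$df.residual
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  others <- setdiff(levels(df$population), reference)
  terms <- paste0("population", others)
  out <- tibble::tibble(
    population = others,
    freq_del = counts$freq_del[match(others, counts$population)],
    or = unname(exp(cf[terms])),
    ci_low = unname(exp(cf[terms] - 1.96 * se[terms])),
    ci_high = unname(exp(cf[terms] + 1.96 * se[terms])),
    p_wald = unname(2 * stats::pnorm(-abs(cf[terms] / se[terms]))),
    monomorphic = mono[match(others, counts$population)]
  )
  out$or[out$monomorphic] <- NA_real_
  out$ci_low[out$monomorphic] <- NA_real_
  out$ci_high[out$monomorphic] <- NA_real_
  out$p_wald[out$monomorphic] <- NA_real_
  attr(out, "lrt_stat") <- lrt
  attr(out, "lrt_df") <- lrt_df
  attr(out, "lrt_p") <- pchisq(lrt, lrt_df, lower.tail = FALSE)
  attr(out, "reference") <- reference
  out
}

#' Case-control logistic association of phenotype with deletion genotype
#'
#' Multivariable logistic regression of a binary phenotype on the
#' three-level deletion genotype (entered as wt/del and del/del indicators
#' with wt/wt as reference) plus covariates. Age and sex are the
#' conventional a-priori confounders; ethnicity enters as an indicator
#' set with the most frequent group as reference. Fitting is by IRLS
#' (`stats::glm`); complete cases only, with the dropped count recorded.
#' A joint 2-df likelihood-ratio test compares the full model against the
#' covariates-only model.
#'
#' @param data A `del_cohort` with phenotypes attached, or a data frame
#'   with columns `dosage` (deletion-allele count), `phenotype`
#'   (`case`/`control`) and the requested covariates.
#' @param covariates Subset of `c("age", "sex", "ethnicity")`.
#' @return A `del_assoc` object wrapping the two fits; use [tidy()] for
#'   the per-term OR table and [glance()] for model-level statistics.
#' @export
genotype_association <- function(data, covariates = c("age", "sex")) {
  covariates <- match.arg(covariates, c("age", "sex", "ethnicity"),
                          several.ok = TRUE)
  df <- if (inherits(data, "del_cohort")) {
    if (is.null(data$phenotypes)) {
      abort("Cohort has no phenotype table", class = "deltag_validation_error")
    }
    dplyr::bind_cols(
      tibble::tibble(dosage = data$deletion$dosage),
      data$phenotypes[, setdiff(names(data$phenotypes), "sample_id")]
    )
  } else {
    tibble::as_tibble(data)
  }
  need <- c("dosage", "phenotype", covariates)
  if (!all(need %in% names(df))) {
    abort(sprintf("Missing column(s): %s",
                  paste(setdiff(need, names(df)), collapse = ", ")),
          class = "deltag_validation_error")
  }
  df <- df[, need]
  n_in <- nrow(df)
  df <- df[complete.cases(df), ]
  n_dropped <- n_in - nrow(df)
  df$y <- as.integer(df$phenotype == "case")
  if (length(unique(df$y)) < 2) {
    abort("Outcome must have both cases and controls",
          class = "deltag_validation_error")
  }
  df$genotype <- factor(deletion_label(df$dosage), levels = DELETION_LEVELS)
  if ("sex" %in% covariates) {
    df$sex <- factor(df$sex, levels = c("male", "female"))
  }
  if ("ethnicity" %in% covariates) {
    ref <- names(sort(table(df$ethnicity), decreasing = TRUE))[1]
    df$ethnicity <- stats::relevel(factor(df$ethnicity), ref = ref)
  }
  rhs <- paste(c("genotype", covariates), collapse = " + ")
  rhs0 <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  n_par <- 3 + length(covariates)  # rough: intercept + 2 genotype + covariates
  if (nrow(df) < 10 * n_par) {
    warn(sprintf("Only %d complete cases for ~%d parameters", nrow(df), n_par))
  }
  fit <- glm(stats::as.formula(paste("y ~", rhs)), family = binomial(),
             data = df, control = list(epsilon = 1e-10, maxit = 100))
  fit0 <- glm(stats::as.formula(paste("y ~", rhs0)), family = binomial(),
              data = df, control = list(epsilon = 1e-10, maxit = 100))
  if (!fit$converged) {
    abort(sprintf("Logistic fit did not converge in %d iterations", fit$iter),
          class = "deltag_fit_error")
  }
  separated <- any(abs(coef(fit)) > 15)
  if (separated) warn("Possible separation: a fitted coefficient exceeds 15")
  lrt <- fit0$deviance - fit$deviance
  lrt_df <- fit0$df.residual - fit$df.residual
  structure(
    list(fit = fit, fit0 = fit0, n = nrow(df), n_dropped = n_dropped,
         covariates = covariates, lrt_stat = lrt, lrt_df = lrt_df,
         lrt_p = pchisq(lrt, lrt_df, lower.tail = FALSE),
         separated = separated),
    class = "del_assoc"
  )
}

#' @export
print.del_assoc <- function(x, ...) {
  cat(sprintf("<del_assoc> n = %d (%d dropped), joint genotype LRT p = %.3g\n",
              x$n, x$n_dropped, x$lrt_p))
  print(tidy(x))
  invisible(x)
}

#' @rdname genotype_association
#' @param x A `del_assoc`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.del_assoc <- function(x, ...) {
  cf <- coef(x$fit); se <- sqrt(diag(vcov(x$fit)))
  terms <- setdiff(names(cf), "(Intercept)")
  tibble::tibble(
    term = terms,
    or = exp(cf[terms]),
    ci_low = exp(cf[terms] - 1.96 * se[terms]),
    ci_high = exp(cf[terms] + 1.96 * se[terms]),
    p = 2 * stats::pnorm(-abs(cf[terms] / se[terms])),
    test = "wald"
  )
}

#' @rdname genotype_association
#' @exportS3Method generics::glance
glance.del_assoc <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_dropped = x$n_dropped, converged = x$fit$converged,
    separated = x$separated, lrt_stat = x$lrt_stat, lrt_df = x$lrt_df,
    lrt_genotype_p = x$lrt_p, deviance = x$fit$deviance,
    aic = x$fit$aic
  )
}

#' Monte-Carlo power for an additive case-control allele-dosage test
#'
#' Simulates case/control genotype dosages under an additive logistic
#' model (control genotypes Hardy-Weinberg at `freq`; case genotype
#' probabilities proportional to `HWE(g) * or_per_allele^g`), tests each
#' replicate with the Wald test on the dosage-trend coefficient of a
#' logistic regression, and reports the rejection fraction.
#'
#' @param n_cases,n_controls Arm sizes.
#' @param freq Deletion-allele frequency in controls, in `(0, 1)`.
#' @param or_per_allele Per-allele odds ratio (> 0).
#' @param alpha Significance level (default 0.05).
#' @param reps Monte-Carlo replicates (>= 100).
#' @param seed Integer RNG seed.
#' @return Tibble with `power`, binomial 95% CI (`ci_low`, `ci_high`),
#'   `reps`, `alpha`.
#' @export
power_additive <- function(n_cases, n_controls, freq, or_per_allele,
                           alpha = 0.05, reps = 1000, seed = 1) {
  stopifnot(freq > 0, freq < 1, or_per_allele > 0, reps >= 100)
  set.seed(seed)
  p_ctrl <- c((1 - freq)^2, 2 * freq * (1 - freq), freq^2)
  p_case <- p_ctrl * or_per_allele^(0:2)
  p_case <- p_case / sum(p_case)
  y <- c(rep(1L, n_cases), rep(0L, n_controls))
  rej <- vapply(seq_len(reps), function(i) {
    g <- c(sample(0:2, n_cases, replace = TRUE, prob = p_case),
           sample(0:2, n_controls, replace = TRUE, prob = p_ctrl))
    fit <- suppressWarnings(glm(y ~ g, family = binomial()))
    z <- coef(summary(fit))["g", "z value"]
    abs(z) > qnorm(1 - alpha / 2)
  }, logical(1))
  pw <- mean(rej)
  se <- sqrt(pw * (1 - pw) / reps)
  tibble::tibble(
    power = pw,
    ci_low = max(0, pw - 1.96 * se),
    ci_high = min(1, pw + 1.96 * se),
    reps = reps, alpha = alpha
  )
}
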