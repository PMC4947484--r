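# Synthetic-cohort generator: a deletion variant at specified population
# frequency, tag SNPs at specified LD with it, unlinked HWE noise SNPs,
# and a covariate-driven binary phenotype.

#' Two-locus haplotype frequencies for a target correlation
#'
#' Given the deletion-allele frequency, a tag-SNP alt-allele frequency
#' and a target allelic correlation `r`, returns the four haplotype
#' frequencies with `f(del, alt) = p_del p_alt + D`,
#' `D = r sqrt(p_del q_del p_alt q_alt)`. Specifications whose implied
#' `D` pushes any haplotype frequency below zero (Lewontin bound
#' violation) are rejected.
#'
#' @param p_del Deletion-allele frequency in `(0, 1)`.
#' @param p_alt Tag-SNP alt-allele frequency in `(0, 1)`.
#' @param r Target correlation in `[-1, 1]`.
#' @return Named numeric vector `c(del_alt, del_ref, wt_alt, wt_ref)`
#'   summing to 1 with marginals exactly `p_del` and `p_alt`.
#' @examples
#' haplotype_table(0.3, 0.3, 1)
#' @export
haplotype_table <- function(p_del, p_alt, r) {
  stopifnot(p_del > 0, p_del < 1, p_alt > 0, p_alt < 1, abs(r) <= 1)
  D <- r * sqrt(p_del * (1 - p_del) * p_alt * (1 - p_alt))
  f <- c(
    del_alt = p_del * p_alt + D,
    del_ref = p_del * (1 - p_alt) - D,
    wt_alt = (1 - p_del) * p_alt - D,
    wt_ref = (1 - p_del) * (1 - p_alt) + D
  )
  if (any(f < -1e-12)) {
    abort(sprintf(
      "Tag spec violates Lewontin bounds (p_del=%.3f, p_alt=%.3f, r=%.3f): haplotype frequency %s = %.4f < 0",
      p_del, p_alt, r, names(f)[which.min(f)], min(f)),
      class = "deltag_config_error")
  }
  pmax(f, 0)
}

#' Simulation configuration
#'
#' Defaults describe the study conditions the package is validated
#' against: a deletion at Gambian-adult frequency 0.36; three tag SNPs at
#' r-squared 0.937, 0.889 and 0.888 with the deletion (the observed LD of
#' the three best tags); 100 unlinked noise SNPs with alt frequency
#' uniform on (0.05, 0.5); adult ages uniform on 30-95; 71% female; age
#' odds ratio 1.07 per year and female odds ratio 1.68 with genotype odds
#' ratios of 1 (the null found for trachomatous scarring); intercept odds
#' 0.025, giving roughly balanced case/control arms at the cohort's mean
#' covariates.
#'
#' @param n_samples Cohort size.
#' @param p_del Deletion-allele frequency in `(0, 1)`.
#' @param tags Tibble with columns `snp_id`, `p_alt`, `r` (target
#'   correlation with the deletion allele; `r^2` is the target LD) and
#'   `pos`; validated against Lewontin bounds.
#' @param n_noise Number of unlinked noise SNPs.
#' @param noise_freq_range Length-2 range for noise alt frequencies.
#' @param intercept_odds Baseline odds of being a case.
#' @param or_age,or_female,or_wtdel,or_deldel Phenotype-model odds ratios.
#' @param age_range Length-2 range; ages drawn uniformly.
#' @param prop_female Proportion female.
#' @param miss_snp,miss_del Independent missingness rates in `[0, 1)` for
#'   SNP dosages and deletion calls.
#' @param chrom Chromosome label for the emitted records.
#' @param deletion_pos Position (bp) of the deletion midpoint; tags
#'   default to nearby positions and noise SNPs spread over a 2-Mb
#'   window around it.
#' @param seed Integer RNG seed.
#' @return Validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 2000,
                       p_del = 0.36,
                       tags = default_tags(p_del),
                       n_noise = 100,
                       noise_freq_range = c(0.05, 0.5),
                       intercept_odds = 0.025,
                       or_age = 1.07,
                       or_female = 1.68,
                       or_wtdel = 1,
                       or_deldel = 1,
                       age_range = c(30, 95),
                       prop_female = 0.71,
                       miss_snp = 0,
                       miss_del = 0,
                       chrom = "12",
                       deletion_pos = 10590000L,
                       seed = 20160616) {
  stopifnot(n_samples >= 2, p_del > 0, p_del < 1,
            n_noise >= 0, length(noise_freq_range) == 2,
            all(noise_freq_range > 0), all(noise_freq_range < 1),
            intercept_odds > 0, or_age > 0, or_female > 0,
            or_wtdel > 0, or_deldel > 0,
            length(age_range) == 2, age_range[1] >= 0,
            prop_female >= 0, prop_female <= 1,
            miss_snp >= 0, miss_snp < 1, miss_del >= 0, miss_del < 1)
  tags <- tibble::as_tibble(tags)
  stopifnot(all(c("snp_id", "p_alt", "r") %in% names(tags)))
  if (!"pos" %in% names(tags)) {
    tags$pos <- deletion_pos + 4000L * seq_len(nrow(tags))
  }
  # validate every tag spec against the Lewontin bounds now
  for (k in seq_len(nrow(tags))) {
    haplotype_table(p_del, tags$p_alt[k], tags$r[k])
  }
  structure(
    list(n_samples = as.integer(n_samples), p_del = p_del, tags = tags,
         n_noise = as.integer(n_noise), noise_freq_range = noise_freq_range,
         intercept_odds = intercept_odds, or_age = or_age,
         or_female = or_female, or_wtdel = or_wtdel, or_deldel = or_deldel,
         age_range = age_range, prop_female = prop_female,
         miss_snp = miss_snp, miss_del = miss_del, chrom = chrom,
         deletion_pos = as.integer(deletion_pos), seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_tags <- function(p_del = 0.36) {
  tibble::tibble(
    snp_id = c("tagA", "tagB", "tagC"),
    p_alt = p_del,
    r = sqrt(c(0.937, 0.889, 0.888))
  )
}

#' Read a simulation configuration from YAML/JSON-like key-value file
#'
#' Accepts a JSON file whose keys are [sim_config()] arguments (`tags` as
#' an array of objects with `snp_id`, `p_alt`, `r`, optional `pos`).
#' Unknown keys are rejected.
#'
#' @param path Path to the JSON config.
#' @return Validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "deltag_config_error")
  }
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "deltag_config_error")
  }
  if (!is.null(raw$tags)) raw$tags <- tibble::as_tibble(raw$tags)
  do.call(sim_config, raw)
}

#' Simulate genotypes for a synthetic cohort
#'
#' Each sample receives two haplotypes drawn independently. On each
#' haplotype the deletion allele is Bernoulli(`p_del`) and every tag-SNP
#' allele is drawn conditionally on that haplotype's deletion allele from
#' the two-locus table of [haplotype_table()] (tags are conditionally
#' independent given the deletion). Noise SNPs are drawn independently in
#' Hardy-Weinberg proportions. Missingness is applied by independent
#' masking; the truth record keeps the unmasked deletion dosages.
#'
#' @param config A `sim_config`.
#' @return A `del_cohort` (phenotypes `NULL`) with attribute `"truth"`: a
#'   list with `true_dosage` (named integer vector), `tag_r2` (realized
#'   dosage r-squared per tag, computed on the unmasked data) and
#'   `config`.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  ids <- sprintf("S%04d", seq_len(n))

  # two deletion haplotype alleles per sample
  hap_del <- matrix(rbinom(2 * n, 1, config$p_del), nrow = 2)
  del_dosage <- colSums(hap_del)

  tag_dosage <- NULL
  tags <- config$tags
  if (nrow(tags) > 0) {
    tag_dosage <- vapply(seq_len(nrow(tags)), function(k) {
      f <- haplotype_table(config$p_del, tags$p_alt[k], tags$r[k])
      p_alt_given_del <- f["del_alt"] / (f["del_alt"] + f["del_ref"])
      p_alt_given_wt <- f["wt_alt"] / (f["wt_alt"] + f["wt_ref"])
      p <- ifelse(hap_del == 1, p_alt_given_del, p_alt_given_wt)
      alleles <- matrix(rbinom(2 * n, 1, p), nrow = 2)
      as.integer(colSums(alleles))
    }, integer(n))
  }

  noise_dosage <- NULL
  noise_freqs <- numeric(0)
  if (config$n_noise > 0) {
    noise_freqs <- runif(config$n_noise, config$noise_freq_range[1],
                         config$noise_freq_range[2])
    noise_dosage <- vapply(noise_freqs, function(f) rbinom(n, 2, f),
                           integer(n))
  }

  dosages <- cbind(tag_dosage, noise_dosage)
  snp_ids <- c(tags$snp_id,
               if (config$n_noise > 0) sprintf("noise%03d", seq_len(config$n_noise)))
  colnames(dosages) <- snp_ids
  rownames(dosages) <- ids

  half_window <- 1e6
  noise_pos <- if (config$n_noise > 0) {
    sort(sample(seq(config$deletion_pos - half_window,
                    config$deletion_pos + half_window),
                config$n_noise))
  } else integer(0)
  bases <- c("A", "C", "G", "T")
  p_snps <- length(snp_ids)
  ref <- sample(bases, p_snps, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  snps <- tibble::tibble(
    snp_id = snp_ids,
    chrom = config$chrom,
    pos = as.integer(c(tags$pos, noise_pos)),
    ref = ref, alt = alt
  )

  # realized LD before masking
  tag_r2 <- if (nrow(tags) > 0) {
    tibble::tibble(
      snp_id = tags$snp_id,
      target_r2 = tags$r^2,
      realized_r2 = vapply(seq_len(nrow(tags)), function(k)
        as.numeric(dosage_r2(tag_dosage[, k], del_dosage)), numeric(1))
    )
  } else tibble::tibble(snp_id = character(), target_r2 = numeric(),
                        realized_r2 = numeric())

  obs_del <- del_dosage
  if (config$miss_del > 0) {
    obs_del[runif(n) < config$miss_del] <- NA_integer_
  }
  if (config$miss_snp > 0) {
    mask <- matrix(runif(length(dosages)) < config$miss_snp, nrow = n)
    dosages[mask] <- NA_integer_
  }

  cohort <- structure(
    list(
      snps = snps,
      dosages = dosages,
      deletion = tibble::tibble(
        sample_id = ids,
        genotype = deletion_label(obs_del),
        dosage = as.integer(obs_del)
      ),
      phenotypes = NULL,
      dropped = c(snp_matrix = 0L, deletion_calls = 0L, phenotypes = 0L)
    ),
    class = "del_cohort"
  )
  attr(cohort, "truth") <- list(
    true_dosage = setNames(as.integer(del_dosage), ids),
    tag_r2 = tag_r2,
    noise_freqs = noise_freqs,
    config = config
  )
  cohort
}

#' Simulate phenotypes and covariates onto a cohort
#'
#' Ages are uniform over the configured range, sex is
#' Bernoulli(`prop_female`), and case status follows
#' `logit P(case) = log(intercept_odds) + log(or_age) age +
#' log(or_female) [female] + log(or_wtdel) [dosage = 1] +
#' log(or_deldel) [dosage = 2]`, using the true (unmasked) deletion
#' dosage.
#'
#' @param cohort A `del_cohort` from [simulate_genotypes()].
#' @param config The `sim_config` used to generate it.
#' @param seed RNG seed for the phenotype draw (default `config$seed + 1`;
#'   kept separate so genotypes are unchanged by re-drawing phenotypes).
#' @return The cohort with its `phenotypes` tibble filled in.
#' @export
simulate_phenotypes <- function(cohort, config, seed = config$seed + 1L) {
  stopifnot(inherits(cohort, "del_cohort"), inherits(config, "sim_config"))
  truth <- attr(cohort, "truth")
  dosage <- if (!is.null(truth)) truth$true_dosage[cohort$deletion$sample_id]
            else cohort$deletion$dosage
  set.seed(seed)
  n <- n_samples(cohort)
  age <- runif(n, config$age_range[1], config$age_range[2])
  female <- rbinom(n, 1, config$prop_female)
  lp <- log(config$intercept_odds) + log(config$or_age) * age +
    log(config$or_female) * female +
    log(config$or_wtdel) * (dosage == 1) +
    log(config$or_deldel) * (dosage == 2)
  case <- rbinom(n, 1, stats::plogis(lp))
  cohort$phenotypes <- tibble::tibble(
    sample_id = cohort$deletion$sample_id,
    age = age,
    sex = ifelse(female == 1, "female", "male"),
    phenotype = ifelse(case == 1, "case", "control"),
    population = "simulated",
    ethnicity = NA_character_
  )
  cohort
}

#' Simulate a full cohort (genotypes + phenotypes)
#'
#' @param config A `sim_config`.
#' @return A `del_cohort` with phenotypes and a `"truth"` attribute.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 50, n_noise = 5))
#' cohort
#' @export
simulate_cohort <- function(config = sim_config()) {
  simulate_phenotypes(simulate_genotypes(config), config)
}

#' Write a simulated cohort as VCF + TSV + truth JSON fixture files
#'
#' Emits `genotypes.vcf` (VCF 4.2, unphased GT), `deletion_calls.tsv`,
#' `phenotypes.tsv` and `truth.json` (schema-versioned; true dosages,
#' realized tag LD and generating parameters).
#'
#' @param cohort A simulated `del_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture <- function(cohort, dir) {
  stopifnot(inherits(cohort, "del_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("Cannot create directory %s", dir),
                   class = "deltag_io_error")
  }
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    deletion = file.path(dir, "deletion_calls.tsv"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(cohort, paths$vcf)
  write_deletion_calls(cohort$deletion, paths$deletion)
  if (!is.null(cohort$phenotypes)) {
    write_phenotypes(cohort$phenotypes, paths$phenotypes)
  }
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    cfg <- truth$config
    jsonlite::write_json(
      list(
        schema_version = "1.0",
        true_dosage = as.list(truth$true_dosage),
        tag_r2 = truth$tag_r2,
        parameters = cfg[setdiff(names(cfg), "tags")],
        tags = truth$config$tags
      ),
      paths$truth, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(paths)
}

# Minimal VCF 4.2 writer for simulated dosage matrices. Dosage 0/1/2 is
# emitted as unphased GT 0/0, 0/1, 1/1; NA as ./.
write_vcf <- function(cohort, path) {
  snps <- cohort$snps
  ord <- order(snps$pos)
  gt_codes <- c("0/0", "0/1", "1/1")
  samples <- rownames(cohort$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=deltag-simulator",
    sprintf("##contig=<ID=%s>", unique(snps$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)
  for (j in ord) {
    d <- cohort$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1L])
    writeLines(paste(c(snps$chrom[j], snps$pos[j], snps$snp_id[j],
                       snps$ref[j], snps$alt[j], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}
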