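# Readers, writers and the cohort container joining SNP dosages, deletion
# calls and phenotypes on sample_id.

#' Read a biallelic-SNP dosage matrix from a VCF file
#'
#' Parses a VCF 4.x file and returns alt-allele dosages (0/1/2) per sample
#' and SNP. Only biallelic SNP records are kept; multi-allelic records and
#' records whose REF or ALT is not a single nucleotide are skipped with a
#' reported count. Genotypes are read from the GT field; phased and
#' unphased separators are treated identically; `./.` and half-calls
#' (any missing allele) become `NA`.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param region Optional region string `"chrom:start-end"` (1-based,
#'   inclusive) restricting the returned SNPs.
#' @return A `snp_matrix` object: a list with
#'   \describe{
#'     \item{snps}{tibble of `snp_id`, `chrom`, `pos`, `ref`, `alt`}
#'     \item{dosages}{integer matrix, samples in rows (rownames =
#'       sample ids), SNPs in columns (colnames = `snp_id`)}
#'     \item{n_skipped}{count of non-biallelic-SNP records dropped}
#'   }
#' @examples
#' cohort <- simulate_cohort(sim_config(n_samples = 20, n_noise = 3))
#' dir <- tempfile(); dir.create(dir)
#' files <- write_fixture(cohort, dir)
#' m <- read_snp_vcf(files$vcf)
#' dim(m$dosages)
#' @export
read_snp_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("VCF file not found: %s", path), class = "deltag_io_error")
  }
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) {
      abort(sprintf("Failed to parse VCF %s: %s", path, conditionMessage(e)),
            class = "deltag_parse_error", parent = e)
    }
  )
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    abort(sprintf("VCF %s contains no variant records", path),
          class = "deltag_parse_error")
  }
  is_snp <- !is.na(fix$REF) & !is.na(fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE) &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_skipped <- sum(!is_snp)
  if (n_skipped > 0) {
    inform(sprintf("read_snp_vcf: skipped %d non-biallelic-SNP record(s)",
                   n_skipped))
  }
  keep <- which(is_snp)

  if (!is.null(region)) {
    reg <- parse_region(region)
    pos <- as.integer(fix$POS)
    keep <- keep[fix$CHROM[keep] == reg$chrom &
                   pos[keep] >= reg$start & pos[keep] <= reg$end]
  }
  if (length(keep) == 0) {
    abort("No biallelic SNP records remain after filtering",
          class = "deltag_parse_error")
  }

  gt <- vcfR::extract.gt(v, element = "GT")        # SNPs x samples
  gt <- gt[keep, , drop = FALSE]
  dos <- gt_to_dosage(gt)                          # same shape
  snp_id <- fix$ID[keep]
  anon <- is.na(snp_id) | snp_id == "."
  snp_id[anon] <- paste0(fix$CHROM[keep][anon], ":", fix$POS[keep][anon])
  if (anyDuplicated(snp_id)) {
    abort("Duplicate SNP ids in VCF after id assignment",
          class = "deltag_validation_error")
  }
  snps <- tibble::tibble(
    snp_id = snp_id,
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = fix$REF[keep],
    alt = fix$ALT[keep]
  )
  dosages <- t(dos)
  dimnames(dosages) <- list(colnames(gt), snp_id)
  new_snp_matrix(snps, dosages, n_skipped = n_skipped)
}

# "chrom:start-end" -> list(chrom, start, end); inclusive 1-based.
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4) {
    abort(sprintf("Malformed region '%s' (expected chrom:start-end)", region),
          class = "deltag_validation_error")
  }
  list(chrom = m[2], start = as.integer(m[3]), end = as.integer(m[4]))
}

# GT character matrix -> integer alt-allele dosage; any missing allele -> NA.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(alleles))
    if (anyNA(ai)) return(NA_integer_)
    sum(ai > 0L)
  }, integer(1))
  out <- lut[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

new_snp_matrix <- function(snps, dosages, n_skipped = 0L) {
  stopifnot(nrow(snps) == ncol(dosages))
  if (anyDuplicated(rownames(dosages))) {
    abort("Duplicate sample ids in genotype matrix",
          class = "deltag_validation_error")
  }
  structure(
    list(snps = snps, dosages = dosages, n_skipped = as.integer(n_skipped)),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d samples x %d SNPs (%d record(s) skipped)\n",
              nrow(x$dosages), ncol(x$dosages), x$n_skipped))
  invisible(x)
}

#' Read three-state deletion genotype calls from TSV
#'
#' Expects a tab-separated file with header `sample_id<TAB>genotype` and
#' genotype values in `wt/wt`, `wt/del`, `del/del` or `NA`.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `sample_id`, `genotype`, `dosage`
#'   (deletion-allele count 0/1/2, `NA` for missing).
#' @export
read_deletion_calls <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Deletion-call file not found: %s", path),
          class = "deltag_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("NA", ""), progress = FALSE)
  if (!all(c("sample_id", "genotype") %in% names(df))) {
    abort("Deletion-call TSV must have columns sample_id and genotype",
          class = "deltag_validation_error")
  }
  bad <- !is.na(df$genotype) & !df$genotype %in% DELETION_LEVELS
  if (any(bad)) {
    abort(sprintf(
      "Unknown deletion genotype label(s) at row(s) %s: %s",
      paste(which(bad), collapse = ", "),
      paste(unique(df$genotype[bad]), collapse = ", ")
    ), class = "deltag_validation_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("Duplicated sample_id(s): %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", ")),
          class = "deltag_validation_error")
  }
  tibble::tibble(
    sample_id = df$sample_id,
    genotype = df$genotype,
    dosage = deletion_dosage(df$genotype)
  )
}

#' Write deletion genotype calls to TSV
#'
#' @param calls Tibble with `sample_id` and `genotype` (or `dosage`)
#'   columns, as returned by [read_deletion_calls()] or
#'   [impute_genotypes()].
#' @param path Output path.
#' @param source Optional string recorded in a `source` column (imputed
#'   calls are conventionally written with `source = "imputed"`).
#' @return `path`, invisibly.
#' @export
write_deletion_calls <- function(calls, path, source = NULL) {
  geno <- if ("genotype" %in% names(calls)) calls$genotype
          else deletion_label(calls$dosage)
  out <- tibble::tibble(sample_id = calls$sample_id, genotype = geno)
  if (!is.null(source)) out$source <- source
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table from TSV
#'
#' Expects columns `sample_id`, `age`, `sex`, `phenotype`, `population`,
#' `ethnicity`; empty fields and `"NA"` are missing. `sex` must be
#' `male`/`female`, `phenotype` must be `case`/`control`; age must be
#' non-negative.
#'
#' @param path Path to the TSV file.
#' @return Typed tibble; a per-column missingness count is attached as
#'   attribute `"missingness"`.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Phenotype file not found: %s", path),
          class = "deltag_io_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("NA", ""), progress = FALSE)
  need <- c("sample_id", "age", "sex", "phenotype", "population", "ethnicity")
  if (!all(need %in% names(df))) {
    abort(sprintf("Phenotype TSV must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "deltag_validation_error")
  }
  if (anyDuplicated(df$sample_id)) {
    abort("Duplicated sample_id in phenotype table",
          class = "deltag_validation_error")
  }
  age <- suppressWarnings(as.numeric(df$age))
  if (any(!is.na(df$age) & is.na(age))) {
    abort("Non-numeric age value(s) in phenotype table",
          class = "deltag_validation_error")
  }
  if (any(age < 0, na.rm = TRUE)) {
    abort(sprintf("Negative age at row(s): %s",
                  paste(which(!is.na(age) & age < 0), collapse = ", ")),
          class = "deltag_validation_error")
  }
  check_levels <- function(x, levels, what) {
    bad <- !is.na(x) & !x %in% levels
    if (any(bad)) {
      abort(sprintf("Invalid %s value(s): %s", what,
                    paste(unique(x[bad]), collapse = ", ")),
            class = "deltag_validation_error")
    }
    x
  }
  out <- tibble::tibble(
    sample_id = df$sample_id,
    age = age,
    sex = check_levels(df$sex, c("male", "female"), "sex"),
    phenotype = check_levels(df$phenotype, c("case", "control"), "phenotype"),
    population = df$population,
    ethnicity = df$ethnicity
  )
  attr(out, "missingness") <- vapply(out, function(x) sum(is.na(x)), integer(1))
  out
}

#' Write a phenotype table to TSV
#'
#' @param phenotypes Tibble as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, path) {
  cols <- c("sample_id", "age", "sex", "phenotype", "population", "ethnicity")
  readr::write_tsv(phenotypes[, cols], path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Assemble a cohort by joining genotypes, deletion calls and phenotypes
#'
#' Inner-joins the three components on `sample_id`; samples absent from any
#' component are dropped and the per-source drop counts are recorded.
#'
#' @param snp_matrix A `snp_matrix` from [read_snp_vcf()].
#' @param deletion_calls Tibble from [read_deletion_calls()].
#' @param phenotypes Optional tibble from [read_phenotypes()]; may be
#'   `NULL` for LD/model work that needs no covariates.
#' @return A `del_cohort` object: list with elements `snps`, `dosages`
#'   (samples x SNPs), `deletion` (tibble), `phenotypes` (tibble or NULL)
#'   and `dropped` (named drop counts).
#' @export
assemble_cohort <- function(snp_matrix, deletion_calls, phenotypes = NULL) {
  stopifnot(inherits(snp_matrix, "snp_matrix"))
  ids <- intersect(rownames(snp_matrix$dosages), deletion_calls$sample_id)
  if (!is.null(phenotypes)) ids <- intersect(ids, phenotypes$sample_id)
  if (length(ids) == 0) {
    abort("No samples shared by all cohort components",
          class = "deltag_validation_error")
  }
  dropped <- c(
    snp_matrix = nrow(snp_matrix$dosages) - length(ids),
    deletion_calls = nrow(deletion_calls) - length(ids),
    phenotypes = if (is.null(phenotypes)) 0L else nrow(phenotypes) - length(ids)
  )
  if (any(dropped > 0)) {
    inform(sprintf(
      "assemble_cohort: dropped %d/%d/%d samples from genotypes/deletion calls/phenotypes",
      dropped[1], dropped[2], dropped[3]))
  }
  del <- deletion_calls[match(ids, deletion_calls$sample_id), ]
  phe <- if (is.null(phenotypes)) NULL else
    phenotypes[match(ids, phenotypes$sample_id), ]
  structure(
    list(
      snps = snp_matrix$snps,
      dosages = snp_matrix$dosages[ids, , drop = FALSE],
      deletion = del,
      phenotypes = phe,
      dropped = dropped
    ),
    class = "del_cohort"
  )
}

#' @export
print.del_cohort <- function(x, ...) {
  cat(sprintf(
    "<del_cohort> %d samples, %d SNPs, deletion calls: %d non-missing%s\n",
    nrow(x$dosages), ncol(x$dosages), sum(!is.na(x$deletion$dosage)),
    if (is.null(x$phenotypes)) "" else ", phenotypes attached"))
  invisible(x)
}

#' Number of samples in a cohort
#' @param cohort A `del_cohort`.
#' @return Integer sample count.
#' @export
n_samples <- function(cohort) nrow(cohort$dosages)
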