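required_cohort_columns <- function() {
  c("id", "age", "sex", "centre", "qualification", "smoking_status",
    "cigarettes_per_day", "smoking_duration", "years_since_cessation",
    "height_m", "weight_kg")
}

#' Write / read a raw cohort table
#'
#' Cohort tables are delimited (comma or tab; auto-detected on read), UTF-8,
#' with a header row and empty strings for missing values. Unknown extra
#' columns are preserved and ignored by downstream stages.
#'
#' @param cohort Cohort tibble.
#' @param path File path; `.csv` writes comma-delimited, anything else tab.
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()` the
#'   cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  if (grepl("\\.csv$", path)) {
    readr::write_csv(cohort, path, na = "")
  } else {
    readr::write_tsv(cohort, path, na = "")
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else ","
  cohort <- readr::read_delim(path, delim = delim, na = "",
                              show_col_types = FALSE, progress = FALSE)
  assert_columns(cohort, required_cohort_columns(), "cohort file")
  cohort
}

#' Write / read a genotype panel
#'
#' The dosage matrix is written tab-delimited (individuals x SNPs, SNP ids as
#' header) with a sidecar SNP-metadata table (`snp chr pos ea oa maf`) at
#' `<path>.meta`.
#'
#' @param panel A `genotype_panel`.
#' @param path Dosage file path.
#' @return `write_genotypes()` returns `path` invisibly; `read_genotypes()`
#'   the reconstructed `genotype_panel`.
#' @export
write_genotypes <- function(panel, path) {
  readr::write_tsv(tibble::as_tibble(panel$dosages), path, progress = FALSE)
  meta <- panel$snp_meta[, c("snp", "chr", "pos", "ea", "oa", "maf")]
  readr::write_tsv(meta, paste0(path, ".meta"), progress = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  dos <- as.matrix(readr::read_tsv(path, show_col_types = FALSE,
                                   progress = FALSE))
  storage.mode(dos) <- "integer"
  meta <- readr::read_tsv(paste0(path, ".meta"), show_col_types = FALSE,
                          progress = FALSE)
  assert_columns(meta, c("snp", "chr", "pos", "ea", "oa", "maf"),
                 "SNP metadata")
  structure(list(dosages = dos, snp_meta = meta), class = "genotype_panel")
}

#' Read dosages from a VCF file
#'
#' Maps diploid GT calls of biallelic records to 0/1/2 counts of the ALT
#' allele (effect allele). Multi-allelic records are dropped with a warning.
#' Requires the `vcfR` package.
#'
#' @param path VCF file path.
#' @return A `genotype_panel`.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("read_vcf_dosages() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !grepl(",", fix$ALT %||% "") & nchar(fix$ALT) == 1 &
    nchar(fix$REF) == 1
  if (any(!biallelic)) {
    warn(sprintf("dropping %d non-biallelic record(s)", sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  count_alt <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = FALSE),
                  function(a) sum(a == "1"), 1L))
  }
  dos <- t(apply(gt, 1, count_alt))
  dos <- t(dos)  # individuals x SNPs
  snp_ids <- ifelse(fix$ID == "." | is.na(fix$ID),
                    paste0(fix$CHROM, ":", fix$POS), fix$ID)
  colnames(dos) <- snp_ids
  f <- colMeans(dos, na.rm = TRUE) / 2
  meta <- tibble::tibble(
    snp = snp_ids, chr = fix$CHROM, pos = as.integer(fix$POS),
    ea = fix$ALT, oa = fix$REF, maf = pmin(f, 1 - f)
  )
  structure(list(dosages = dos, snp_meta = meta), class = "genotype_panel")
}

#' Write / read a truth report
#'
#' Machine-readable flat `key=value` table of all realized true effects in a
#' `true_parameters` object: per-outcome risk differences
#' (`rd.<outcome>.<exposure>`), mediation truth
#' (`mediation.<set>.{total,direct,indirect,pm}`), interaction truth,
#' scaling units and structural coefficients.
#'
#' @param truth A `true_parameters` object.
#' @param path Output path.
#' @return `truth_report()` returns `path` invisibly; `read_truth_report()` a
#'   named numeric vector.
#' @export
truth_report <- function(truth, path) {
  stopifnot(inherits(truth, "true_parameters"))
  kv <- truth_flatten(truth)
  writeLines(sprintf("%s=%.10g", names(kv), kv), path)
  invisible(path)
}

truth_flatten <- function(truth) {
  kv <- c()
  for (i in seq_len(nrow(truth$rd))) {
    kv[sprintf("rd.%s.%s", truth$rd$outcome[i], truth$rd$exposure[i])] <-
      truth$rd$true_rd[i]
  }
  m <- truth$mediation
  for (i in seq_len(nrow(m))) {
    for (f in c("total", "direct", "indirect", "pm")) {
      kv[sprintf("mediation.%s.%s", m$mediators[i], f)] <- m[[f]][i]
    }
  }
  it <- truth$interactions
  for (i in seq_len(nrow(it))) {
    kv[sprintf("interaction.%s.%s", it$exposure_a[i], it$exposure_b[i])] <-
      it$true_rd_interaction[i]
  }
  for (nm in names(truth$scales)) kv[paste0("scale.", nm)] <- truth$scales[nm]
  for (nm in names(truth$lambda)) kv[paste0("lambda.", nm)] <- truth$lambda[nm]
  for (nm in names(truth$structural)) kv[nm] <- truth$structural[nm]
  kv
}

#' @rdname truth_report
#' @export
read_truth_report <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "=", fixed = TRUE)
  setNames(vapply(parts, function(p) as.numeric(p[2]), 1),
           vapply(parts, `[`, "", 1))
}
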