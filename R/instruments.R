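#' Random half-sample split
#'
#' Assigns individuals to two random halves (sizes differing by at most one),
#' reproducibly given the seed. Instruments discovered in one half are only
#' ever applied in the other, avoiding sample-overlap bias.
#'
#' @param ids Unique individual identifiers.
#' @param seed Integer seed.
#' @return Tibble with `id` and `split` (1 or 2).
#' @export
split_sample <- function(ids, seed) {
  if (length(ids) < 2) abort("need at least two individuals to split")
  if (anyDuplicated(ids)) abort("ids must be unique")
  n <- length(ids)
  perm <- with_seed(seed, sample.int(n))
  split <- integer(n)
  split[perm <= ceiling(n / 2)] <- 1L
  split[perm > ceiling(n / 2)] <- 2L
  tibble::tibble(id = ids, split = split)
}

covariate_matrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  df <- as.data.frame(covariates)
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  model.matrix(~., df)
}

#' Per-SNP covariate-adjusted GWAS
#'
#' Least-squares slope of the phenotype on each SNP's effect-allele dosage,
#' adjusting for covariates, with exact two-sided p-values from the t
#' distribution. Implemented by residualizing the phenotype and every dosage
#' column on the covariates (Frisch-Waugh), which reproduces the full
#' per-SNP multiple regression exactly and runs as two matrix operations.
#' SNPs with (residually) constant dosage are skipped with a warning.
#'
#' @param panel A `genotype_panel`.
#' @param phenotype Numeric vector, one value per panel row.
#' @param covariates Optional data frame of covariates (factors allowed).
#' @param rows Optional row indices restricting the analysis (e.g. one split).
#' @return Tibble: `snp chr pos ea oa eaf beta se p n`.
#' @export
run_gwas <- function(panel, phenotype, covariates = NULL, rows = NULL) {
  rows <- rows %||% seq_len(nrow(panel$dosages))
  y <- phenotype[rows]
  ok <- !is.na(y)
  if (!is.null(covariates)) {
    cov_df <- as.data.frame(covariates)[rows, , drop = FALSE]
    ok <- ok & complete.cases(cov_df)
  }
  rows <- rows[ok]
  y <- phenotype[rows]
  n <- length(rows)
  g <- panel$dosages[rows, , drop = FALSE]
  storage.mode(g) <- "double"
  cm <- covariate_matrix(if (is.null(covariates)) NULL else
    as.data.frame(covariates)[rows, , drop = FALSE], n)
  qrc <- qr(cm)
  p_cov <- qrc$rank
  y_r <- qr.resid(qrc, y)
  g_r <- qr.resid(qrc, g)
  sxx <- colSums(g_r^2)
  degenerate <- sxx < 1e-10
  if (any(degenerate)) {
    warn(sprintf("skipping %d SNP(s) with constant adjusted dosage",
                 sum(degenerate)))
  }
  sxy <- colSums(g_r * y_r)
  beta <- ifelse(degenerate, NA_real_, sxy / sxx)
  df <- n - p_cov - 1
  rss <- sum(y_r^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  eaf <- colMeans(g) / 2
  res <- tibble::tibble(
    snp = panel$snp_meta$snp,
    chr = panel$snp_meta$chr,
    pos = panel$snp_meta$pos,
    ea = panel$snp_meta$ea,
    oa = panel$snp_meta$oa,
    eaf = unname(eaf),
    beta = unname(beta),
    se = unname(se),
    p = unname(2 * pt(-abs(tval), df)),
    n = n
  )
  res[!degenerate, , drop = FALSE]
}

snp_r2 <- function(panel, snp_a, snp_b, rows = NULL) {
  rows <- rows %||% seq_len(nrow(panel$dosages))
  cor(panel$dosages[rows, snp_a], panel$dosages[rows, snp_b])^2
}

#' Select genome-wide-significant SNPs and greedily clump them
#'
#' Retains SNPs with p at or below `p_threshold`, iterating in order of
#' ascending p (ties broken by ascending id); a SNP is kept iff its squared
#' dosage correlation with every already-retained SNP on the same chromosome
#' within `window_kb` is below `r2_threshold`. Defaults follow genome-wide
#' convention: p <= 5e-8, r^2 < 0.001 within a 10,000 kb window. The panel
#' itself serves as the LD reference.
#'
#' @param summary GWAS summary tibble from [run_gwas()].
#' @param panel LD reference `genotype_panel`.
#' @param p_threshold,r2_threshold,window_kb Selection and clumping
#'   parameters.
#' @param rows Optional LD-reference row subset.
#' @return A `prs_model`: tibble `snp ea weight` with selection metadata
#'   attributes.
#' @export
select_and_clump <- function(summary, panel, p_threshold = 5e-8,
                             r2_threshold = 0.001, window_kb = 10000,
                             rows = NULL) {
  cand <- summary[!is.na(summary$p) & summary$p <= p_threshold, , drop = FALSE]
  if (nrow(cand) == 0) {
    abort("no SNP passes the p-value threshold",
          class = "splitmr_empty_model_error")
  }
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(cand))) {
    in_window <- kept[cand$chr[kept] == cand$chr[i] &
                        abs(cand$pos[kept] - cand$pos[i]) <= window_kb * 1000]
    indep <- TRUE
    for (j in in_window) {
      if (snp_r2(panel, cand$snp[i], cand$snp[j], rows) >= r2_threshold) {
        indep <- FALSE
        break
      }
    }
    if (indep) kept <- c(kept, i)
  }
  model <- tibble::tibble(snp = cand$snp[kept], ea = cand$ea[kept],
                          weight = cand$beta[kept])
  structure(model, class = c("prs_model", class(model)),
            p_threshold = p_threshold, r2_threshold = r2_threshold,
            window_kb = window_kb)
}

#' Find an LD proxy for a SNP
#'
#' Returns the SNP with the highest squared dosage correlation with
#' `snp_id` (itself excluded) on the same chromosome within the window,
#' provided r^2 is at least `min_r2`; ties are broken by smaller distance,
#' then lexicographic id.
#'
#' @param snp_id Target SNP id.
#' @param panel `genotype_panel` used as LD reference.
#' @param min_r2 Lower r^2 limit (default 0.8).
#' @param window_kb Search window.
#' @param rows Optional reference row subset.
#' @return Proxy SNP id, or `NA_character_` if none qualifies.
#' @export
find_proxy <- function(snp_id, panel, min_r2 = 0.8, window_kb = 10000,
                       rows = NULL) {
  meta <- panel$snp_meta
  k <- match(snp_id, meta$snp)
  if (is.na(k)) abort(sprintf("SNP %s not in panel", snp_id))
  cand <- which(meta$chr == meta$chr[k] &
                  abs(meta$pos - meta$pos[k]) <= window_kb * 1000 &
                  meta$snp != snp_id)
  if (length(cand) == 0) return(NA_character_)
  r2 <- vapply(cand, function(j) snp_r2(panel, snp_id, meta$snp[j], rows), 1)
  qual <- which(r2 >= min_r2)
  if (length(qual) == 0) return(NA_character_)
  cand <- cand[qual]; r2 <- r2[qual]
  ord <- order(-r2, abs(meta$pos[cand] - meta$pos[k]), meta$snp[cand])
  meta$snp[cand[ord[1]]]
}

#' Score a standardized polygenic risk score
#'
#' Raw score is the weight-dosage inner product over the model SNPs, with
#' effect alleles aligned to the panel (allele-swapped SNPs are flipped:
#' dosage 2 - d). The score is then standardized to mean 0, SD 1 in the
#' scored sample.
#'
#' @param panel `genotype_panel` to score.
#' @param model `prs_model` from [select_and_clump()].
#' @param rows Optional row subset to score (standardization is within this
#'   subset).
#' @param use_proxies Replace SNPs missing from the panel by their best proxy
#'   in `proxy_panel` (r^2 >= `min_r2`)?
#' @param proxy_panel Panel used for proxy search (default `panel`).
#' @param min_r2 Proxy r^2 limit.
#' @return Numeric standardized scores (length = rows scored).
#' @export
score_prs <- function(panel, model, rows = NULL, use_proxies = FALSE,
                      proxy_panel = panel, min_r2 = 0.8) {
  rows <- rows %||% seq_len(nrow(panel$dosages))
  meta <- panel$snp_meta
  idx <- match(model$snp, meta$snp)
  if (anyNA(idx) && use_proxies) {
    for (i in which(is.na(idx))) {
      proxy <- find_proxy(model$snp[i], proxy_panel, min_r2 = min_r2)
      if (!is.na(proxy)) {
        model$snp[i] <- proxy
        model$ea[i] <- meta$ea[match(proxy, meta$snp)]
      }
    }
    idx <- match(model$snp, meta$snp)
  }
  if (anyNA(idx)) {
    abort(sprintf("model SNP(s) missing from panel without proxy: %s",
                  paste(model$snp[is.na(idx)], collapse = ", ")),
          class = "splitmr_missing_snp_error")
  }
  same <- model$ea == meta$ea[idx]
  flipped <- model$ea == meta$oa[idx]
  if (any(!same & !flipped)) {
    abort(sprintf("unharmonizable alleles for SNP(s): %s",
                  paste(model$snp[!same & !flipped], collapse = ", ")))
  }
  g <- panel$dosages[rows, idx, drop = FALSE]
  storage.mode(g) <- "double"
  g[, flipped] <- 2 - g[, flipped]
  raw <- as.numeric(g %*% model$weight)
  if (sd(raw) < 1e-12) {
    abort("PRS has zero variance in the scored sample",
          class = "splitmr_degenerate_error")
  }
  (raw - mean(raw)) / sd(raw)
}

#' Instrument-strength diagnostics
#'
#' R^2 and F statistic from the unadjusted simple linear regression of the
#' exposure on the PRS, plus sample size and the number of SNPs in the score.
#'
#' @param prs Standardized score vector.
#' @param exposure Exposure values (same length).
#' @param n_snps Number of SNPs in the scoring model (reported through).
#' @return One-row tibble: `r2`, `f_stat`, `n_snps`, `n`.
#' @export
instrument_diagnostics <- function(prs, exposure, n_snps = NA_integer_) {
  ok <- complete.cases(prs, exposure)
  n <- sum(ok)
  if (n < 3) abort("need at least 3 complete pairs")
  r2 <- cor(prs[ok], exposure[ok])^2
  tibble::tibble(r2 = r2, f_stat = r2 * (n - 2) / (1 - r2),
                 n_snps = as.integer(n_snps), n = as.integer(n))
}

#' Write / read GWAS summary statistics
#'
#' Tab-delimited with header `snp chr pos ea oa eaf beta se p n`.
#'
#' @param summary GWAS summary tibble.
#' @param path File path.
#' @export
write_gwas_summary <- function(summary, path) {
  assert_columns(summary, c("snp", "chr", "pos", "ea", "oa", "eaf",
                            "beta", "se", "p", "n"), "GWAS summary")
  readr::write_tsv(summary, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_gwas_summary
#' @export
read_gwas_summary <- function(path) {
  s <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(s, c("snp", "chr", "pos", "ea", "oa", "eaf",
                      "beta", "se", "p", "n"), "GWAS summary file")
  s
}

#' Write / read a PRS model
#'
#' Tab-delimited `snp ea weight` body preceded by a `#`-prefixed metadata
#' header block (p threshold, clumping r^2, window, source split).
#'
#' @param model A `prs_model`.
#' @param path File path.
#' @param source_split Optional split label recorded in the header.
#' @export
write_prs_model <- function(model, path, source_split = NA) {
  hdr <- c(
    sprintf("# p_threshold=%g", attr(model, "p_threshold") %||% NA),
    sprintf("# r2_threshold=%g", attr(model, "r2_threshold") %||% NA),
    sprintf("# window_kb=%g", attr(model, "window_kb") %||% NA),
    sprintf("# source_split=%s", source_split)
  )
  writeLines(hdr, path)
  suppressWarnings(
    utils::write.table(model, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, append = TRUE))
  invisible(path)
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- readr::read_tsv(I(lines[!startsWith(lines, "#")]),
                          show_col_types = FALSE, progress = FALSE)
  assert_columns(body, c("snp", "ea", "weight"), "PRS model file")
  get_meta <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (length(ln)) as.numeric(sub(".*=", "", ln[1])) else NA_real_
  }
  structure(body, class = c("prs_model", class(body)),
            p_threshold = get_meta("p_threshold"),
            r2_threshold = get_meta("r2_threshold"),
            window_kb = get_meta("window_kb"))
}
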