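canonical_exposures <- function() c("education", "bmi", "smoking", "alcohol")

#' Add analysis-scale exposure columns
#'
#' Effects are reported per SD of education years, per 5 kg/m^2 of BMI, per
#' SD of lifetime smoking index and per 5 alcohol units/week. This helper
#' appends the scaled columns (`education_std`, `bmi_per5`, `smoking_std`,
#' `alcohol_per5`) and records the scaling units.
#'
#' @param data Derived cohort (see [derive_exposures()]).
#' @return Data with scaled columns; attribute `scales` holds the units.
#' @export
add_scaled_exposures <- function(data) {
  scales <- c(education = sd(data$education_years, na.rm = TRUE),
              bmi = 5,
              smoking = sd(data$smoking_index, na.rm = TRUE),
              alcohol = 5)
  data$education_std <- data$education_years / scales[["education"]]
  data$bmi_per5 <- data$bmi / 5
  data$smoking_std <- data$smoking_index / scales[["smoking"]]
  data$alcohol_per5 <- data$alcohol_units / 5
  attr(data, "scales") <- scales
  data
}

scaled_column <- function(exposure) {
  c(education = "education_std", bmi = "bmi_per5",
    smoking = "smoking_std", alcohol = "alcohol_per5")[[exposure]]
}

scale_label <- function(exposure, scales) {
  switch(exposure,
    education = sprintf("per SD education (%.2f years)", scales[["education"]]),
    bmi = "per 5 kg/m^2 BMI",
    smoking = sprintf("per SD smoking index (%.3f)", scales[["smoking"]]),
    alcohol = "per 5 units/week alcohol")
}

panel_subset <- function(panel, snps) {
  idx <- match(snps, panel$snp_meta$snp)
  structure(list(dosages = panel$dosages[, idx, drop = FALSE],
                 snp_meta = panel$snp_meta[idx, , drop = FALSE]),
            class = "genotype_panel")
}

#' Build cross-split polygenic-score instruments
#'
#' For each exposure, runs a covariate-adjusted GWAS within each half of the
#' sample, selects and clumps genome-wide-significant SNPs, and scores the
#' resulting standardized PRS in the *other* half (scores discovered in
#' split s are only ever applied in split 3 - s). Scores land in
#' `prs_<exposure>` columns; instrument-strength diagnostics (R^2, F,
#' number of SNPs) are computed in the applied split. Exposures with no
#' genome-wide-significant SNP in a split are reported as skipped, not
#' errors.
#'
#' @param data Derived cohort with scaled exposure columns, aligned row-wise
#'   with `panel`.
#' @param panel The `genotype_panel`.
#' @param exposures Canonical exposure names to instrument.
#' @param covariates GWAS covariate columns (age, sex, principal
#'   components).
#' @param seed Seed for the split assignment.
#' @param p_threshold,r2_threshold,window_kb Selection/clumping parameters.
#' @return List: `data` (with `split` and score columns), `models`,
#'   `summaries` (per exposure x split GWAS), `diagnostics` tibble, and
#'   `log` lines recording the cross-split discipline.
#' @export
build_instruments <- function(data, panel,
                              exposures = canonical_exposures(),
                              covariates = c("age", "sex"),
                              seed = 1, p_threshold = 5e-8,
                              r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(nrow(data) == nrow(panel$dosages))
  sp <- split_sample(data$id, substream_seed(seed, "split"))
  data$split <- sp$split[match(data$id, sp$id)]
  models <- list()
  summaries <- list()
  diagnostics <- list()
  log <- character()
  for (e in exposures) {
    x <- data[[scaled_column(e)]]
    models[[e]] <- list()
    summaries[[e]] <- list()
    for (s in 1:2) {
      disc <- which(data$split == s)
      apply_rows <- which(data$split == 3 - s)
      gw <- run_gwas(panel, x, data[, covariates, drop = FALSE], rows = disc)
      summaries[[e]][[s]] <- gw
      model <- tryCatch(
        select_and_clump(gw, panel, p_threshold, r2_threshold, window_kb,
                         rows = disc),
        splitmr_empty_model_error = function(e_) NULL)
      models[[e]][[s]] <- model
      if (is.null(model)) {
        log <- c(log, sprintf(
          "prs_%s: no genome-wide-significant SNP in split %d; split %d unscored",
          e, s, 3 - s))
        diagnostics[[paste(e, s)]] <- tibble::tibble(
          exposure = e, discovery_split = s, applied_split = 3L - s,
          r2 = NA_real_, f_stat = NA_real_, n_snps = 0L,
          n = length(apply_rows), skipped = TRUE)
        next
      }
      score_col <- paste0("prs_", e)
      if (!score_col %in% names(data)) data[[score_col]] <- NA_real_
      scores <- score_prs(panel, model, rows = apply_rows)
      data[[score_col]][apply_rows] <- scores
      log <- c(log, sprintf(
        "prs_%s: split %d scored with weights discovered in split %d (%d SNPs)",
        e, 3 - s, s, nrow(model)))
      di <- instrument_diagnostics(scores, x[apply_rows],
                                   n_snps = nrow(model))
      diagnostics[[paste(e, s)]] <- dplyr::bind_cols(
        tibble::tibble(exposure = e, discovery_split = s,
                       applied_split = 3L - s),
        di, tibble::tibble(skipped = FALSE))
    }
  }
  list(data = data, models = models, summaries = summaries,
       diagnostics = dplyr::bind_rows(diagnostics), log = log)
}

#' Split-sample MR estimate for one exposure-outcome pair
#'
#' Two-stage least squares of the outcome on the scaled exposure,
#' instrumented by the cross-split PRS, within each half; the per-split
#' estimates are pooled by fixed-effects meta-analysis with I^2. Analyses
#' involving alcohol use the multimorbidity definition excluding the
#' alcohol-problems condition and drop excluded drinkers.
#'
#' @param data Output `data` of [build_instruments()].
#' @param exposure Canonical exposure name.
#' @param outcome Outcome stem (`mm2`, `mm3`, `mm4`, `cmms`).
#' @param covariates MR adjustment columns (age, sex, centre, PCs).
#' @return List with `per_split` estimates, `pooled` row and the outcome
#'   column used.
#' @export
split_mr_estimate <- function(data, exposure, outcome = "mm2",
                              covariates = c("age", "sex", "centre")) {
  score_col <- paste0("prs_", exposure)
  if (!score_col %in% names(data) || all(is.na(data[[score_col]]))) {
    return(list(per_split = NULL, pooled = NULL, outcome = outcome,
                skipped = TRUE))
  }
  an <- build_analysis_set(data, exposure, outcome,
                           covariates = c(covariates, score_col))
  outcome_used <- attr(an, "outcome")
  xcol <- scaled_column(exposure)
  per <- purrr::map_dfr(sort(unique(an$split)), function(s) {
    d <- an[an$split == s, , drop = FALSE]
    fit <- tsls(d, outcome_used, xcol, score_col, covariates)
    dplyr::mutate(tidy(fit), split = s,
                  f_stat = fit$first_stage$f_stat[1])
  })
  pooled <- fixed_effect_meta(per$beta, per$se)
  list(per_split = per, pooled = pooled, outcome = outcome_used,
       skipped = FALSE)
}

#' Per-split ratio-based sensitivity estimators, meta-analysed
#'
#' For each discovery split, harmonizes the discovery variant-exposure
#' associations of the clumped instrument SNPs with variant-outcome
#' associations estimated in the application split, and applies IVW,
#' MR-Egger, the unweighted median and the simple mode estimator; the two
#' splits are then pooled per method.
#'
#' @param inst Result of [build_instruments()].
#' @param panel The `genotype_panel`.
#' @param exposure Canonical exposure name.
#' @param outcome Outcome stem.
#' @param covariates Outcome-GWAS covariates.
#' @param seed Bootstrap seed for median/mode SEs.
#' @return Tibble of pooled estimates, one row per method, with `i2`;
#'   per-split rows in attribute `per_split`.
#' @export
mr_sensitivity <- function(inst, panel, exposure, outcome = "mm2",
                           covariates = c("age", "sex"), seed = 1) {
  data <- inst$data
  outcome_used <- analysis_outcome(exposure, outcome)
  y <- data[[outcome_used]]
  per <- list()
  for (s in 1:2) {
    model <- inst$models[[exposure]][[s]]
    if (is.null(model)) next
    app <- which(data$split == 3 - s &
                   !is.na(data[[exposure_column(exposure)]]))
    gx <- inst$summaries[[exposure]][[s]]
    gx <- gx[gx$snp %in% model$snp, , drop = FALSE]
    gy <- run_gwas(panel_subset(panel, gx$snp), y,
                   data[, covariates, drop = FALSE], rows = app)
    r <- make_ratios(gx, gy)
    ests <- dplyr::bind_rows(
      ivw(r)[, c("term", "beta", "se", "n")],
      if (nrow(r) >= 3) mr_egger(r)[, c("term", "beta", "se", "n")],
      if (nrow(r) >= 3) unweighted_median(
        r, seed = substream_seed(seed, paste0("med", s)))[
          , c("term", "beta", "se", "n")],
      if (nrow(r) >= 3) simple_mode(
        r, seed = substream_seed(seed, paste0("mode", s)))[
          , c("term", "beta", "se", "n")]
    )
    per[[s]] <- dplyr::mutate(ests, split = 3L - s)
  }
  per <- dplyr::bind_rows(per)
  if (nrow(per) == 0) return(per)
  pooled <- combine_split_estimates(per, labels = "term")
  attr(pooled, "per_split") <- per
  pooled
}
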