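interaction_pair_order <- function(pair) {
  # education is upstream of the behavioural exposures; otherwise the
  # first-listed exposure is treated as A (config-overridable by reordering)
  if ("education" %in% pair) c("education", setdiff(pair, "education")) else pair
}

default_interaction_pairs <- function() {
  list(c("bmi", "smoking"), c("bmi", "alcohol"), c("education", "bmi"),
       c("smoking", "alcohol"), c("education", "smoking"),
       c("education", "alcohol"))
}

#' Run the full synthetic split-sample MR study
#'
#' End-to-end orchestration: simulate genotypes and cohort, derive exposures
#' and outcomes, split the sample, run per-split GWAS and build cross-split
#' PRS instruments, estimate exposure-outcome effects by robust multivariable
#' regression and split-sample two-stage least squares (meta-analysed with
#' I^2), run ratio-based sensitivity estimators, mediation analyses (MVR and
#' MR difference method with bootstrap, plus a g-formula sensitivity) and
#' additive-interaction analyses (MVR product terms; MR with product-score
#' instruments). Every stage draws from a substream of the master seed, so a
#' repeated run is byte-identical.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (defaults to `config$seed`).
#' @param out_dir Optional directory: when given, [generate_report()] writes
#'   the result files there.
#' @param outcomes Outcome stems to analyse (default `"mm2"`).
#' @param n_boot Mediation bootstrap repeats.
#' @param include_sensitivity,include_gformula,include_interactions Toggles
#'   for the slower secondary analyses.
#' @param interaction_pairs List of exposure pairs for interaction analyses.
#' @param keep_data Keep the derived cohort (with scores) in the result?
#' @return A `splitmr_study` list of result tibbles plus the truth object.
#' @export
run_study <- function(config = sim_config(), seed = config$seed,
                      out_dir = NULL, outcomes = "mm2", n_boot = 200,
                      include_sensitivity = TRUE, include_gformula = TRUE,
                      include_interactions = TRUE,
                      interaction_pairs = default_interaction_pairs(),
                      keep_data = FALSE) {
  config$seed <- seed
  panel <- simulate_genotypes(config)
  sim <- simulate_cohort(panel, config)
  data <- add_scaled_exposures(derive_exposures(sim$cohort))
  scales <- attr(data, "scales")
  pcs <- paste0("pc", seq_len(config$n_pcs))
  covs_gwas <- c("age", "sex", pcs)
  covs_mr <- c("age", "sex", "centre", pcs)
  covs_mvr <- c("age", "sex", "centre")

  inst <- build_instruments(data, panel, covariates = covs_gwas, seed = seed)
  data <- inst$data

  ## exposure-outcome effects, MVR vs MR
  effects <- list()
  for (e in canonical_exposures()) {
    for (o in outcomes) {
      an <- build_analysis_set(data, e, o, covariates = covs_mvr)
      o_used <- attr(an, "outcome")
      mvr <- fit_linear_robust(an, o_used, scaled_column(e), covs_mvr)
      effects[[paste(e, o, "mvr")]] <- tibble::tibble(
        analysis = "mvr", exposure = e, outcome = o_used, method = "ols_robust",
        split = NA_integer_, beta = mvr$beta, se = mvr$se,
        ci_low = mvr$ci_low, ci_high = mvr$ci_high, p = mvr$p, n = mvr$n,
        i2 = NA_real_, scale = scale_label(e, scales))
      mr <- split_mr_estimate(data, e, o, covariates = covs_mr)
      if (mr$skipped) {
        effects[[paste(e, o, "mr")]] <- tibble::tibble(
          analysis = "mr", exposure = e, outcome = mr$outcome,
          method = "SKIPPED", split = NA_integer_, beta = NA_real_,
          se = NA_real_, ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
          n = NA_integer_, i2 = NA_real_, scale = scale_label(e, scales))
      } else {
        pooled_row <- tibble::tibble(
          analysis = "mr", exposure = e, outcome = mr$outcome,
          method = "2sls_meta", split = NA_integer_, beta = mr$pooled$beta,
          se = mr$pooled$se, ci_low = mr$pooled$ci_low,
          ci_high = mr$pooled$ci_high, p = mr$pooled$p,
          n = sum(mr$per_split$n), i2 = mr$pooled$i2,
          scale = scale_label(e, scales))
        split_rows <- dplyr::transmute(
          mr$per_split, analysis = "mr", exposure = e, outcome = mr$outcome,
          method = "2sls", split = .data$split, beta = .data$beta,
          se = .data$se, ci_low = .data$ci_low, ci_high = .data$ci_high,
          p = .data$p, n = .data$n, i2 = NA_real_,
          scale = scale_label(e, scales))
        effects[[paste(e, o, "mr")]] <- dplyr::bind_rows(pooled_row,
                                                         split_rows)
      }
    }
  }
  effects <- dplyr::bind_rows(effects)

  ## ratio-based sensitivity estimators (primary outcome only)
  sensitivity <- if (include_sensitivity) {
    purrr::map_dfr(canonical_exposures(), function(e) {
      out <- mr_sensitivity(inst, panel, e, outcomes[1],
                            covariates = covs_gwas,
                            seed = substream_seed(seed, paste0("sens_", e)))
      if (nrow(out) == 0) return(out)
      dplyr::mutate(out, exposure = e, .before = 1)
    })
  } else {
    tibble::tibble()
  }

  ## mediation of the education effect
  med_sets <- list(bmi = "bmi", smoking = "smoking", alcohol = "alcohol",
                   `bmi+smoking` = c("bmi", "smoking"))
  prs_map <- function(names_) {
    setNames(paste0("prs_", names_), vapply(names_, scaled_column, ""))
  }
  mediation <- purrr::map_dfr(names(med_sets), function(nm) {
    meds <- med_sets[[nm]]
    an <- build_analysis_set(data, c("education", meds), outcomes[1],
                             covariates = covs_mvr)
    o_used <- attr(an, "outcome")
    med_cols <- vapply(meds, scaled_column, "")
    rows <- list()
    rows$mvr <- mediation_analysis(
      an, "education_std", med_cols, o_used, covariates = covs_mvr,
      framework = "mvr", n_boot = n_boot,
      seed = substream_seed(seed, paste0("med_mvr_", nm)))
    inst_map <- prs_map(c("education", meds))
    if (all(unname(inst_map) %in% names(data))) {
      rows$mr <- mediation_analysis(
        an, "education_std", med_cols, o_used, covariates = covs_mr,
        framework = "mr", instruments = inst_map, n_boot = n_boot,
        seed = substream_seed(seed, paste0("med_mr_", nm)))
    }
    purrr::map_dfr(rows, function(r) {
      dplyr::mutate(tidy_mediation_row(r), mediators = nm, outcome = o_used,
                    .before = 1)
    })
  })

  ## g-formula sensitivity for the BMI-mediated path
  gform <- NULL
  if (include_gformula) {
    an <- build_analysis_set(data, c("education", "bmi"), outcomes[1],
                             covariates = covs_mvr)
    gform <- gformula_mediation(
      an, "education_std", "bmi_per5", attr(an, "outcome"),
      covariates = covs_mvr, delta = 1,
      seed = substream_seed(seed, "gformula"))
  }

  ## additive interactions
  interactions <- if (include_interactions) {
    purrr::map_dfr(interaction_pairs, function(pair) {
      pair <- interaction_pair_order(pair)
      an <- build_analysis_set(data, pair, outcomes[1],
                               covariates = covs_mvr)
      o_used <- attr(an, "outcome")
      a_col <- scaled_column(pair[1]); b_col <- scaled_column(pair[2])
      mvr <- interaction_mvr(an, a_col, b_col, o_used, covs_mvr)
      mr <- NULL
      prs_cols <- paste0("prs_", pair)
      if (all(prs_cols %in% names(an))) {
        mr <- interaction_mr(an, a_col, b_col, o_used,
                             prs_cols[1], prs_cols[2], covs_mr)
        mr <- dplyr::select(mr, "term", "beta", "se", "ci_low", "ci_high",
                            "p", "i2", "exposure_a", "exposure_b",
                            "framework")
      }
      res <- dplyr::bind_rows(
        dplyr::select(mvr, "term", "beta", "se", "ci_low", "ci_high", "p",
                      "i2", "exposure_a", "exposure_b", "framework"),
        mr)
      dplyr::mutate(res, pair_a = pair[1], pair_b = pair[2],
                    outcome = o_used)
    })
  } else {
    tibble::tibble()
  }

  study <- structure(list(
    seed = seed, config = config, config_hash = config_hash(config),
    scales = scales, truth = sim$truth,
    effects = effects, sensitivity = sensitivity, mediation = mediation,
    gformula = gform, interactions = interactions,
    diagnostics = inst$diagnostics, log = inst$log,
    data = if (keep_data) data else NULL,
    panel = if (keep_data) panel else NULL
  ), class = "splitmr_study")
  if (!is.null(out_dir)) generate_report(study, out_dir)
  study
}

tidy_mediation_row <- function(r) {
  tibble::tibble(
    framework = r$framework,
    total = r$total$beta, total_se = r$total$se,
    direct = r$direct$beta, direct_se = r$direct$se,
    indirect = r$indirect,
    indirect_ci_low = r$indirect_ci[1], indirect_ci_high = r$indirect_ci[2],
    pm = r$pm, pm_ci_low = r$pm_ci[1], pm_ci_high = r$pm_ci[2],
    inconsistent = r$inconsistent, n = r$total$n
  )
}

#' @export
print.splitmr_study <- function(x, ...) {
  cat(sprintf("<splitmr_study> seed %d, config %s\n", x$seed, x$config_hash))
  cat("MVR vs MR pooled effects (per scaled unit):\n")
  pooled <- x$effects[x$effects$method %in% c("ols_robust", "2sls_meta"), ]
  print(pooled[, c("analysis", "exposure", "outcome", "beta", "se", "i2")],
        n = Inf)
  invisible(x)
}

#' Write the study report files
#'
#' Writes five delimited/plain-text files to `out_dir`: the MVR-vs-MR
#' exposure-outcome estimate table, the mediation table (PM rendered as
#' `inconsistent` when flagged), the interaction table with per-term I^2,
#' the instrument-diagnostics table, and a run log with the config hash,
#' master seed and cross-split scoring record. Re-generation from the same
#' study object is byte-identical.
#'
#' @param study A `splitmr_study` from [run_study()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
generate_report <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(out_dir, c("effects.tsv", "mediation.tsv",
                                "interactions.tsv", "diagnostics.tsv",
                                "run_log.txt"))
  readr::write_tsv(study$effects, paths[1], progress = FALSE)
  med <- study$mediation
  if (nrow(med) > 0) {
    med$pm <- ifelse(med$inconsistent, "inconsistent",
                     format(med$pm, digits = 10))
  }
  readr::write_tsv(med, paths[2], progress = FALSE)
  inter <- study$interactions
  if (is.null(inter) || nrow(inter) == 0) {
    inter <- tibble::tibble(term = "SKIPPED")
  }
  readr::write_tsv(inter, paths[3], progress = FALSE)
  readr::write_tsv(study$diagnostics, paths[4], progress = FALSE)
  writeLines(c(
    sprintf("config_hash=%s", study$config_hash),
    sprintf("seed=%d", study$seed),
    sprintf("package_version=%s", as.character(utils::packageVersion("splitmr"))),
    study$log
  ), paths[5])
  invisible(paths)
}
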