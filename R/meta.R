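#' Fixed-effects inverse-variance meta-analysis
#'
#' Pools estimates with weights `1/se^2`: pooled beta is the weighted mean,
#' pooled SE `1/sqrt(sum w)`, Cochran's Q the weighted squared deviation, and
#' `I^2 = max(0, 100 (Q - df)/Q)` quantifies heterogeneity. With a single
#' estimate the input is returned with `I^2 = 0` and a `single_split` flag so
#' report schemas stay rectangular.
#'
#' @param betas Numeric estimates.
#' @param ses Their standard errors (all positive).
#' @return One-row tibble:
#'   `beta se ci_low ci_high p q df i2 k single_split`.
#' @export
fixed_effect_meta <- function(betas, ses) {
  k <- length(betas)
  if (k == 0) abort("no estimates to meta-analyse")
  if (length(ses) != k || any(is.na(ses)) || any(ses <= 0)) {
    abort("ses must be positive and match betas in length")
  }
  w <- 1 / ses^2
  pooled <- sum(w * betas) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- sum(w * (betas - pooled)^2)
  df <- k - 1L
  i2 <- if (k > 1 && q > 0) max(0, 100 * (q - df) / q) else 0
  out <- effect_row("pooled", pooled, se, NA)
  out$term <- NULL
  out$n <- NULL
  dplyr::bind_cols(out, tibble::tibble(q = q, df = df, i2 = i2, k = k,
                                       single_split = k == 1))
}

#' Meta-analyse matched per-split estimates
#'
#' Groups a long table of per-split effect estimates by analysis label and
#' pools each group with [fixed_effect_meta()]. Labels present in only one
#' split are pooled as single-split rows and flagged, never silently mixed;
#' with `strict = TRUE` a label missing from either split is an error.
#'
#' @param results Tibble with columns `split`, `beta`, `se` plus one or more
#'   label columns.
#' @param labels Character vector of label columns (default: everything
#'   except `split`, `beta`, `se` and other estimate columns).
#' @param strict Error on labels missing a split?
#' @return Tibble: label columns plus the [fixed_effect_meta()] columns.
#' @export
combine_split_estimates <- function(results, labels = NULL, strict = FALSE) {
  assert_columns(results, c("split", "beta", "se"), "results")
  labels <- labels %||% setdiff(names(results),
                                c("split", "beta", "se", "ci_low", "ci_high",
                                  "p", "n", "scale", "q", "term"))
  grouped <- dplyr::group_by(results, dplyr::across(dplyr::all_of(labels)))
  n_splits <- length(unique(results$split))
  if (strict) {
    bad <- dplyr::filter(dplyr::summarise(grouped, k = dplyr::n(),
                                          .groups = "drop"), .data$k < n_splits)
    if (nrow(bad) > 0) {
      abort(paste0("estimates missing for some split(s) in label(s): ",
                   paste(do.call(paste, c(bad[labels], sep = "/")),
                         collapse = "; ")),
            class = "splitmr_label_error")
    }
  }
  dplyr::summarise(grouped,
                   fixed_effect_meta(.data$beta, .data$se),
                   .groups = "drop")
}
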