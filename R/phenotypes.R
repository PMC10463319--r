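#' Default education qualification-to-years mapping
#'
#' The standard UK qualification to years-of-education table
#' (degree 20, NVQ/HND/HNC 19, other professional 15, A levels 13,
#' O levels/GCSEs 10, CSEs 10, none 7). The exact table is a configurable
#' input: supply your own two-column table to [map_education_years()] to
#' override it.
#'
#' @return Tibble with columns `qualification` and `years`.
#' @export
education_mapping <- function() {
  tibble::tribble(
    ~qualification, ~years,
    "College or University degree", 20,
    "NVQ or HND or HNC or equivalent", 19,
    "Other professional qualifications", 15,
    "A levels/AS levels or equivalent", 13,
    "O levels/GCSEs or equivalent", 10,
    "CSEs or equivalent", 10,
    "None of the above", 7
  )
}

#' Infer years of education from highest achieved qualification
#'
#' @param qualification Character vector of highest qualifications; `NA`
#'   propagates to `NA` years.
#' @param mapping Two-column table (`qualification`, `years`).
#' @return Numeric vector of years of education.
#' @export
map_education_years <- function(qualification, mapping = education_mapping()) {
  assert_columns(mapping, c("qualification", "years"), "education mapping")
  idx <- match(qualification, mapping$qualification)
  unmapped <- !is.na(qualification) & is.na(idx)
  if (any(unmapped)) {
    abort(sprintf("unmapped qualification category: %s",
                  paste(unique(qualification[unmapped]), collapse = ", ")),
          class = "splitmr_config_error")
  }
  mapping$years[idx]
}

#' Lifetime smoking index
#'
#' Continuous smoking score combining initiation, duration, heaviness and
#' cessation. Never smokers score 0; for ever-smokers the index is
#' `(1 - 0.5^(duration/tau)) * 0.5^(cessation/tau) * log(intensity + 1)`,
#' where `tau` is the half-life in years (default 18.9) capturing the decay
#' of smoking's impact with time smoked and time since quitting. With the
#' default half-life, a current smoker of 5 cigarettes/day for 12 years
#' scores 0.638, roughly one cohort SD.
#'
#' @param status Character: `"never"`, `"former"` or `"current"`.
#' @param intensity Cigarettes per day.
#' @param duration Years smoked.
#' @param cessation Years since stopping (0 for current smokers).
#' @param tau Half-life in years, must be positive.
#' @return Numeric index, 0 for never smokers.
#' @export
lifetime_smoking_index <- function(status, intensity, duration, cessation,
                                   tau = 18.9) {
  if (tau <= 0) abort("tau must be positive", class = "splitmr_domain_error")
  ok <- !is.na(status)
  if (any(ok & !status %in% c("never", "former", "current"))) {
    abort("status must be one of never/former/current",
          class = "splitmr_domain_error")
  }
  smoker <- ok & status != "never"
  if (any(smoker & (intensity < 0 | duration < 0 | cessation < 0), na.rm = TRUE)) {
    abort("intensity, duration and cessation must be non-negative",
          class = "splitmr_domain_error")
  }
  idx <- ifelse(status == "never", 0,
                (1 - 0.5^(duration / tau)) * 0.5^(cessation / tau) *
                  log(intensity + 1))
  idx[!ok] <- NA_real_
  idx
}

#' Default alcohol units-per-drink conversion table
#'
#' UK-unit conventions per typical serving: a glass of wine ~2 units, a pint
#' of beer/cider ~2 units, a single spirit measure ~1 unit, fortified wine
#' ~1 unit. These defaults are an assumption (the conversion applied to any
#' real questionnaire should be supplied explicitly).
#'
#' @return Tibble with columns `beverage` and `units_per_drink`.
#' @export
alcohol_units_table <- function() {
  tibble::tribble(
    ~beverage, ~units_per_drink,
    "red_wine", 2,
    "white_wine", 2,
    "beer_cider", 2,
    "spirits", 1,
    "fortified_wine", 1,
    "other", 1.5
  )
}

#' Weekly alcohol units from per-beverage drink counts
#'
#' Computes total units/week as the unit-weighted sum of weekly drink counts.
#' Never-drinkers are set to 0 units and retained; former drinkers are set to
#' missing and flagged for exclusion (their previous consumption is unknown);
#' totals above `max_units` (default 200 units/week) are excluded as
#' implausibly high current consumption.
#'
#' @param data Data frame with one `drinks_<beverage>` column per beverage in
#'   `units_table`, plus logical columns `never_drinker` and `former_drinker`
#'   (missing flag columns are treated as all-FALSE).
#' @param units_table Conversion table, see [alcohol_units_table()].
#' @param max_units Exclusion threshold in units/week.
#' @return Tibble with `alcohol_units` (NA where excluded) and logical
#'   `alcohol_excluded`.
#' @export
alcohol_units_per_week <- function(data, units_table = alcohol_units_table(),
                                   max_units = 200) {
  cols <- paste0("drinks_", units_table$beverage)
  assert_columns(data, cols, "cohort")
  counts <- as.matrix(data[cols])
  if (any(counts < 0, na.rm = TRUE)) {
    abort("drink counts must be non-negative", class = "splitmr_domain_error")
  }
  units <- as.numeric(counts %*% units_table$units_per_drink)
  never <- if ("never_drinker" %in% names(data)) data$never_drinker else FALSE
  former <- if ("former_drinker" %in% names(data)) data$former_drinker else FALSE
  units[never %in% TRUE] <- 0
  excluded <- (former %in% TRUE) | (!is.na(units) & units > max_units)
  units[excluded] <- NA_real_
  tibble::tibble(alcohol_units = units, alcohol_excluded = excluded)
}

#' Body mass index from height and weight
#'
#' @param height_m Height in metres (> 0).
#' @param weight_kg Weight in kilograms.
#' @return BMI in kg/m^2; missing inputs propagate.
#' @export
compute_bmi <- function(height_m, weight_kg) {
  if (any(height_m <= 0, na.rm = TRUE)) {
    abort("height must be positive", class = "splitmr_domain_error")
  }
  weight_kg / height_m^2
}

condition_cols <- function(data) {
  grep("^cond_", names(data), value = TRUE)
}

#' Multimorbidity outcomes from condition flags
#'
#' Counts conditions and defines multimorbidity as 2+, 3+ and 4+ conditions.
#' Because alcohol consumption appears as an exposure/mediator in some
#' models, each outcome can be computed excluding the alcohol-problems
#' condition from the definition.
#'
#' @param data Data frame with logical/0-1 condition columns named
#'   `cond_<label>`.
#' @param include_alcohol_condition Keep the alcohol-problems flag in the
#'   count?
#' @param alcohol_condition Column name of the alcohol-problems flag.
#' @param n_conditions Expected number of condition flags (validated).
#' @return Tibble with `condition_count`, `mm2`, `mm3`, `mm4` (integer 0/1).
#' @export
multimorbidity_outcomes <- function(data, include_alcohol_condition = TRUE,
                                    alcohol_condition = "cond_alcohol_problems",
                                    n_conditions = NULL) {
  cols <- condition_cols(data)
  if (length(cols) == 0) {
    abort("no cond_* columns found", class = "splitmr_format_error")
  }
  if (!is.null(n_conditions) && length(cols) != n_conditions) {
    abort(sprintf("expected %d condition flags, found %d",
                  n_conditions, length(cols)), class = "splitmr_format_error")
  }
  if (!include_alcohol_condition) cols <- setdiff(cols, alcohol_condition)
  flags <- as.matrix(data[cols]) * 1
  count <- as.integer(rowSums(flags))
  tibble::tibble(
    condition_count = count,
    mm2 = as.integer(count >= 2),
    mm3 = as.integer(count >= 3),
    mm4 = as.integer(count >= 4)
  )
}

#' Cambridge multimorbidity score
#'
#' Weighted sum of condition flags using general-outcome weights (one
#' non-negative weight per condition). Weights are an input table, never a
#' constant of the package; a synthetic default table ships in
#' `inst/extdata/cmms_weights_synthetic.tsv`.
#'
#' @param data Data frame with `cond_<label>` columns.
#' @param weights Two-column table `condition`, `weight` covering every flag
#'   (conditions are matched as `cond_<condition>`).
#' @param include_alcohol_condition,alcohol_condition As in
#'   [multimorbidity_outcomes()].
#' @return Numeric score vector.
#' @export
cmms_score <- function(data, weights,
                       include_alcohol_condition = TRUE,
                       alcohol_condition = "cond_alcohol_problems") {
  assert_columns(weights, c("condition", "weight"), "CMMS weights")
  cols <- condition_cols(data)
  if (!include_alcohol_condition) cols <- setdiff(cols, alcohol_condition)
  w <- weights$weight[match(sub("^cond_", "", cols), weights$condition)]
  if (anyNA(w)) {
    abort(sprintf("missing CMMS weight for condition(s): %s",
                  paste(sub("^cond_", "", cols)[is.na(w)], collapse = ", ")),
          class = "splitmr_config_error")
  }
  as.numeric(as.matrix(data[cols]) %*% w)
}

#' Synthetic default CMMS weight table
#'
#' A stand-in general-outcome weight table (label + non-negative weight per
#' condition) for synthetic runs; the weights are arbitrary but fixed, and
#' clearly synthetic - supply the published table for any real analysis.
#'
#' @param condition_labels Condition labels to cover.
#' @return Tibble `condition`, `weight`.
#' @export
cmms_weights_synthetic <- function(condition_labels = default_condition_labels()) {
  k <- length(condition_labels)
  # fixed pseudo-random but deterministic spread of weights in [0.1, 2.6]
  w <- round(0.1 + 2.5 * ((seq_len(k) * 7919) %% 97) / 96, 3)
  tibble::tibble(condition = condition_labels, weight = w)
}

#' Derive all exposures and outcomes from a raw cohort table
#'
#' Applies the four exposure derivations (years of education from highest
#' qualification, BMI from height/weight, lifetime smoking index, weekly
#' alcohol units with exclusions) and the multimorbidity outcomes (2+/3+/4+
#' and CMMS, each including and excluding the alcohol-problems condition).
#'
#' @param cohort Raw cohort tibble (see [simulate_cohort()] for the column
#'   dictionary).
#' @param mapping Education mapping table.
#' @param units_table Alcohol conversion table.
#' @param cmms_weights CMMS weight table.
#' @param tau Smoking-index half-life.
#' @return The cohort with derived columns appended: `education_years`,
#'   `bmi`, `smoking_index`, `alcohol_units`, `alcohol_excluded`,
#'   `condition_count`, `mm2`, `mm3`, `mm4`, `cmms` and `*_exalc` variants.
#' @export
derive_exposures <- function(cohort,
                             mapping = education_mapping(),
                             units_table = alcohol_units_table(),
                             cmms_weights = cmms_weights_synthetic(
                               sub("^cond_", "", condition_cols(cohort))),
                             tau = 18.9) {
  assert_columns(cohort, c("qualification", "height_m", "weight_kg",
                           "smoking_status"), "cohort")
  alc <- alcohol_units_per_week(cohort, units_table)
  out <- multimorbidity_outcomes(cohort)
  out_ex <- multimorbidity_outcomes(cohort, include_alcohol_condition = FALSE)
  names(out_ex) <- paste0(names(out_ex), "_exalc")
  dplyr::bind_cols(
    cohort,
    tibble::tibble(
      education_years = map_education_years(cohort$qualification, mapping),
      bmi = compute_bmi(cohort$height_m, cohort$weight_kg),
      smoking_index = lifetime_smoking_index(
        cohort$smoking_status, cohort$cigarettes_per_day,
        cohort$smoking_duration, cohort$years_since_cessation, tau = tau)
    ),
    alc, out, out_ex,
    tibble::tibble(
      cmms = cmms_score(cohort, cmms_weights),
      cmms_exalc = cmms_score(cohort, cmms_weights,
                              include_alcohol_condition = FALSE)
    )
  )
}

exposure_column <- function(exposure) {
  switch(exposure,
    education = "education_years",
    bmi = "bmi",
    smoking = "smoking_index",
    alcohol = "alcohol_units",
    abort(sprintf("unknown exposure '%s'", exposure),
          class = "splitmr_config_error")
  )
}

#' Build a per-exposure complete-case analysis set
#'
#' Restricts a derived cohort to rows with complete data for the outcome,
#' covariates and the named exposure(s). When alcohol is involved (as
#' exposure or mediator), former drinkers and implausibly high consumers are
#' removed (their `alcohol_units` is missing) and the requested outcome is
#' switched to its alcohol-excluded variant.
#'
#' @param data Derived cohort (see [derive_exposures()]).
#' @param exposure Exposure name(s): subset of
#'   `c("education", "bmi", "smoking", "alcohol")`.
#' @param outcome Outcome column (`mm2`, `mm3`, `mm4` or `cmms`).
#' @param covariates Covariate column names required complete.
#' @return Filtered tibble with an `outcome` attribute naming the column
#'   actually used.
#' @export
build_analysis_set <- function(data, exposure, outcome = "mm2",
                               covariates = c("age", "sex", "centre")) {
  cols <- vapply(exposure, exposure_column, "")
  use_exalc <- "alcohol" %in% exposure
  outcome_used <- if (use_exalc) paste0(outcome, "_exalc") else outcome
  assert_columns(data, c(cols, outcome_used, covariates), "analysis data")
  keep <- complete.cases(data[, c(cols, outcome_used, covariates)])
  res <- data[keep, , drop = FALSE]
  if (nrow(res) == 0) {
    abort("analysis set is empty after exclusions",
          class = "splitmr_empty_error")
  }
  attr(res, "outcome") <- outcome_used
  res
}
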