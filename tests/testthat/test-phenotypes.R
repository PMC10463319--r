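test_that("education years map from qualifications, missing propagates", {
  m <- education_mapping()
  expect_equal(map_education_years("College or University degree"), 20)
  expect_equal(map_education_years("None of the above"), 7)
  expect_true(is.na(map_education_years(NA_character_)))
  expect_equal(
    map_education_years(c("CSEs or equivalent", NA, "A levels/AS levels or equivalent")),
    c(10, NA, 13))
  expect_error(map_education_years("PhD by thesis"), "PhD by thesis",
               class = "splitmr_config_error")
  # custom mapping tables override the default
  custom <- tibble::tibble(qualification = "Degree", years = 17)
  expect_equal(map_education_years("Degree", custom), 17)
})

test_that("lifetime smoking index matches its closed form", {
  # independent re-derivation of the worked value: current smoker,
  # 5 cigarettes/day for 12 years, half-life 18.9 years
  tau <- 18.9
  expected <- (1 - 0.5^(12 / tau)) * 0.5^(0 / tau) * log(5 + 1)
  got <- lifetime_smoking_index("current", 5, 12, 0)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(round(got, 3), 0.638)

  expect_equal(lifetime_smoking_index("never", 0, 0, 0), 0)
  expect_equal(lifetime_smoking_index("never", 99, 99, 0), 0)
  # duration -> infinity, current smoker: index -> log(intensity + 1)
  expect_equal(lifetime_smoking_index("current", 10, 1e6, 0), log(11),
               tolerance = 1e-9)
  expect_error(lifetime_smoking_index("current", -1, 10, 0),
               class = "splitmr_domain_error")
  expect_error(lifetime_smoking_index("sometimes", 1, 1, 0),
               class = "splitmr_domain_error")
})

test_that("smoking index is continuous and increasing in its inputs", {
  dur <- seq(0.1, 60, length.out = 200)
  idx <- lifetime_smoking_index(rep("current", 200), 10, dur, 0)
  expect_true(all(diff(idx) > 0))
  expect_true(max(abs(diff(idx))) < 0.05)  # no jumps on a fine grid
  ints <- seq(0, 60, length.out = 200)
  idx2 <- lifetime_smoking_index(rep("current", 200), ints, 20, 0)
  expect_true(all(diff(idx2) > 0))
  ces <- seq(0, 40, length.out = 100)
  idx3 <- lifetime_smoking_index(rep("former", 100), 10, 20, ces)
  expect_true(all(diff(idx3) < 0))
})

test_that("alcohol units: never 0 and retained, former and >200 excluded", {
  d <- tibble::tibble(
    drinks_red_wine = c(2, 0, 0, 50),
    drinks_white_wine = c(1, 0, 0, 20),
    drinks_beer_cider = c(3, 0, 0, 10),
    drinks_spirits = c(2, 0, 0, 50),
    drinks_fortified_wine = c(0, 0, 0, 1),
    drinks_other = c(0, 0, 0, 0),
    never_drinker = c(FALSE, TRUE, FALSE, FALSE),
    former_drinker = c(FALSE, FALSE, TRUE, FALSE))
  res <- alcohol_units_per_week(d)
  expect_equal(res$alcohol_units[1], 2 * 2 + 1 * 2 + 3 * 2 + 2 * 1)
  expect_false(res$alcohol_excluded[1])
  expect_equal(res$alcohol_units[2], 0)       # never-drinker retained at 0
  expect_false(res$alcohol_excluded[2])
  expect_true(is.na(res$alcohol_units[3]))    # former drinker excluded
  expect_true(res$alcohol_excluded[3])
  expect_true(res$alcohol_excluded[4])        # 201 units/week excluded
  d$drinks_red_wine[1] <- -1
  expect_error(alcohol_units_per_week(d), class = "splitmr_domain_error")
})

test_that("BMI is weight over height squared with domain checks", {
  expect_equal(compute_bmi(1.70, 72.25), 25)
  expect_equal(compute_bmi(2.00, 100), 25)
  expect_true(is.na(compute_bmi(1.70, NA)))
  expect_error(compute_bmi(0, 70), class = "splitmr_domain_error")
})

test_that("multimorbidity outcomes count conditions with thresholds 2/3/4", {
  flags <- tibble::tibble(cond_a = c(1, 0, 0), cond_b = c(1, 0, 0),
                          cond_c = c(1, 0, 0), cond_alcohol_problems = c(0, 0, 1))
  out <- multimorbidity_outcomes(flags)
  expect_equal(out$condition_count, c(3L, 0L, 1L))
  expect_equal(out$mm2, c(1L, 0L, 0L))
  expect_equal(out$mm3, c(1L, 0L, 0L))
  expect_equal(out$mm4, c(0L, 0L, 0L))
  # alcohol-problems flag only, excluded from definition -> count 0
  out_ex <- multimorbidity_outcomes(flags, include_alcohol_condition = FALSE)
  expect_equal(out_ex$condition_count[3], 0L)
  expect_error(multimorbidity_outcomes(flags, n_conditions = 35),
               class = "splitmr_format_error")
})

test_that("outcome thresholds are monotone under added conditions", {
  set.seed(9)
  base <- matrix(rbinom(50 * 10, 1, 0.3), 50, 10,
                 dimnames = list(NULL, paste0("cond_", letters[1:10])))
  d0 <- tibble::as_tibble(base)
  d1 <- d0
  d1$cond_a <- pmin(d1$cond_a + 1, 1)   # add a condition where absent
  o0 <- multimorbidity_outcomes(d0)
  o1 <- multimorbidity_outcomes(d1)
  expect_true(all(o1$condition_count >= o0$condition_count))
  expect_true(all(o1$mm2 >= o0$mm2 & o1$mm3 >= o0$mm3 & o1$mm4 >= o0$mm4))
  expect_true(all(o0$mm2 >= o0$mm3 & o0$mm3 >= o0$mm4))
})

test_that("CMMS is the weight-flag dot product", {
  d <- tibble::tibble(cond_x = c(1, 0, 1), cond_y = c(1, 0, 0))
  w <- tibble::tibble(condition = c("x", "y"), weight = c(0.2, 0.5))
  expect_equal(cmms_score(d, w), c(0.7, 0, 0.2))
  expect_equal(cmms_score(tibble::tibble(cond_x = 0, cond_y = 0), w), 0)
  w1 <- tibble::tibble(condition = "x", weight = 1.5)
  expect_equal(cmms_score(tibble::tibble(cond_x = 1), w1), 1.5)
  expect_error(cmms_score(d, w1), "y", class = "splitmr_config_error")
})

test_that("analysis sets drop incomplete rows and apply alcohol rules", {
  d <- small_derived()
  a_edu <- build_analysis_set(d, "education", "mm2")
  expect_equal(nrow(a_edu), nrow(d))   # education complete by construction
  a_alc <- build_analysis_set(d, "alcohol", "mm2")
  expect_equal(attr(a_alc, "outcome"), "mm2_exalc")
  expect_equal(nrow(a_alc), sum(!is.na(d$alcohol_units)))
  expect_true(nrow(a_alc) < nrow(d))   # former drinkers removed
  # idempotence
  a_twice <- build_analysis_set(a_alc, "alcohol", "mm2")
  expect_equal(nrow(a_twice), nrow(a_alc))
  # missing weight drops that row for BMI
  d2 <- d
  d2$weight_kg[1] <- NA
  d2$bmi[1] <- NA
  expect_equal(nrow(build_analysis_set(d2, "bmi", "mm2")), nrow(d) - 1)
  expect_error(build_analysis_set(d[0, ], "bmi", "mm2"),
               class = "splitmr_empty_error")
})
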