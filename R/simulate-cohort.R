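#' Simulate a biobank-like cohort from a genotype panel
#'
#' Generates questionnaire-like raw phenotype fields with known structural
#' parameters. Education has a polygenic component; BMI, lifetime smoking and
#' alcohol consumption each have their own polygenic component plus a causal
#' effect of education (so education's effect on multimorbidity is partly
#' mediated); a single standard-normal latent confounder U loads on every
#' exposure and every condition liability. Each of the binary chronic
#' conditions arises from a probit (liability-threshold) model whose
#' threshold is solved from its prevalence target.
#'
#' Smoking is generated as raw behaviour fields (status, cigarettes/day,
#' duration, years since cessation) constructed by inverting the lifetime
#' smoking index formula, so the *derived* index carries the intended
#' polygenic and education structure. Condition liabilities are driven by the
#' exposures exactly as an analyst would derive them.
#'
#' The condition liability loadings are calibrated so that the implied true
#' risk differences for multimorbidity (2+ conditions) per scaled exposure
#' unit equal `config$target_rd`; true effects are defined as counterfactual
#' contrasts computed exactly from the probit condition probabilities
#' (Poisson-binomial tail over conditions) averaged over the generated
#' sample, and recorded in the returned `true_parameters` object.
#'
#' @param panel A `genotype_panel` from [simulate_genotypes()].
#' @param config The [sim_config()] used to build the panel.
#' @return List with `cohort` (raw-field tibble, one row per individual) and
#'   `truth` (a `true_parameters` object).
#' @export
simulate_cohort <- function(panel, config) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(config, "sim_config"))
  n <- nrow(panel$dosages)
  if (n < config$n_individuals) {
    abort("panel has fewer rows than config$n_individuals",
          class = "splitmr_config_error")
  }

  exposures <- c("education", "bmi", "smoking", "alcohol")

  ## --- covariates (independent of genotype: no population structure) -----
  covars <- with_seed(substream_seed(config$seed, "covariates"), {
    tibble::tibble(
      id = sprintf("id%06d", seq_len(n)),
      age = round(runif(n, config$age_range[1], config$age_range[2]), 1),
      sex = ifelse(runif(n) < config$female_frac, "female", "male"),
      centre = sprintf("centre_%02d", sample.int(config$n_centres, n, TRUE))
    )
  })
  pcs <- with_seed(substream_seed(config$seed, "pcs"),
                   matrix(rnorm(n * config$n_pcs), n,
                          dimnames = list(NULL, paste0("pc", seq_len(config$n_pcs)))))

  ## --- true polygenic scores --------------------------------------------
  prs <- make_true_prs(panel, config)

  u <- with_seed(substream_seed(config$seed, "confounder"), rnorm(n))
  conf <- config$confounding

  ## --- education ---------------------------------------------------------
  ve_e <- config$architecture$education$variance_explained
  c_e <- unname(conf["education"]) %|na|% 0
  noise_var <- 1 - ve_e - c_e^2
  e_lat <- scale_to_var(prs$education, ve_e) + c_e * u +
    with_seed(substream_seed(config$seed, "edu_noise"),
              rnorm(n, 0, sqrt(max(noise_var, 0))))
  qual <- education_from_latent(e_lat)
  edu_years <- map_education_years(qual)

  edu_c <- edu_years - mean(edu_years)

  ## --- BMI ---------------------------------------------------------------
  bmi <- structured_exposure(
    prs$bmi, u, edu_c, config, "bmi", config$bmi_mean, config$bmi_sd,
    config$edu_bmi, "bmi_noise")
  hw <- with_seed(substream_seed(config$seed, "height"), {
    h <- pmax(rnorm(n, 1.69, 0.09), 1.40)
    list(height_m = round(h, 2), weight_kg = round(bmi * round(h, 2)^2, 1))
  })

  ## --- smoking (latent index -> raw behaviour fields) --------------------
  s_lat <- structured_exposure(
    prs$smoking, u, edu_c, config, "smoking", 0, config$smoking_latent_sd,
    config$edu_smoking, "smoking_noise")
  smoke <- smoking_fields_from_latent(s_lat, config)

  ## --- alcohol (latent units -> beverage counts) -------------------------
  a_lat <- structured_exposure(
    prs$alcohol, u, edu_c, config, "alcohol", config$alcohol_mean,
    config$alcohol_sd, config$edu_alcohol, "alcohol_noise")
  drink <- drink_fields_from_latent(a_lat, config)

  cohort_raw <- dplyr::bind_cols(
    covars, tibble::as_tibble(pcs),
    tibble::tibble(qualification = qual),
    smoke$fields, drink$fields,
    tibble::as_tibble(hw)
  )

  ## --- exposures as the analyst would derive them ------------------------
  smoking_index <- lifetime_smoking_index(
    smoke$fields$smoking_status, smoke$fields$cigarettes_per_day,
    smoke$fields$smoking_duration, smoke$fields$years_since_cessation,
    tau = config$tau)
  alcohol_units <- drink$realized_units      # former drinkers: latent value
  bmi_derived <- compute_bmi(hw$height_m, hw$weight_kg)

  scales <- c(education = sd(edu_years), bmi = 5,
              smoking = sd(smoking_index), alcohol = 5)
  xs <- cbind(
    education = (edu_years - mean(edu_years)) / scales["education"],
    bmi = (bmi_derived - mean(bmi_derived)) / scales["bmi"],
    smoking = (smoking_index - mean(smoking_index)) / scales["smoking"],
    alcohol = (alcohol_units - mean(alcohol_units)) / scales["alcohol"]
  )

  ## mediator response to one year of education (linearized; exact for BMI)
  med_resp <- c(
    bmi = config$edu_bmi,
    smoking = config$edu_smoking * mean(smoking_index > 0),
    alcohol = config$edu_alcohol * mean(alcohol_units > 0)
  )

  ## --- liability machinery -----------------------------------------------
  k <- config$n_conditions
  w_cond <- with_seed(substream_seed(config$seed, "condition_weights"),
                      runif(k, 0.5, 1.5))
  agez <- (covars$age - mean(covars$age)) / sd(covars$age)
  fixed <- config$confounder_liability * u +
    config$age_liability * agez +
    config$sex_liability * (covars$sex == "female") +
    config$former_drinker_liability * drink$former
  lia <- list(w = w_cond, fixed = fixed, prevalence = config$prevalence,
              xs = xs, scales = scales, med_resp = med_resp,
              alc_idx = which(config$condition_labels == "alcohol_problems"))

  cal <- calibrate_loadings(lia, config)
  lambda <- cal$lambda
  kappa <- cal$kappa

  ## exact thresholds, then draw condition flags
  s <- liability_score(xs, lambda, kappa)
  thr <- solve_thresholds_exact(s, lia)
  eta <- tcrossprod(s, w_cond) + fixed
  eta <- sweep(eta, 2, thr, "-")
  flags <- with_seed(substream_seed(config$seed, "conditions"),
                     (eta + matrix(rnorm(n * k), n, k)) > 0)
  colnames(flags) <- paste0("cond_", config$condition_labels)

  cohort <- dplyr::bind_cols(cohort_raw, tibble::as_tibble(flags * 1L))

  truth <- build_truth(lia, lambda, kappa, thr, config, flags)
  list(cohort = cohort, truth = truth)
}

## --- internal generator helpers -------------------------------------------

scale_to_var <- function(x, target_var) {
  x <- as.vector(x) - mean(x)
  if (target_var <= 0 || sd(x) == 0) return(x * 0)
  x * sqrt(target_var) / sd(x)
}

make_true_prs <- function(panel, config) {
  blocks <- panel$snp_meta$block %||%
    rep(seq_len(ceiling(config$n_snps / config$ld_block_size)),
        each = config$ld_block_size)[seq_len(config$n_snps)]
  exposures <- names(config$architecture)
  n_blocks <- max(blocks)
  prs <- list()
  signs_seed <- substream_seed(config$seed, "causal_signs")
  for (i in seq_along(exposures)) {
    e <- exposures[i]
    nc <- config$architecture[[e]]$n_causal_snps
    # one causal SNP (block centre) per block; blocks interleaved across
    # exposures so causal variants for different exposures never share LD
    my_blocks <- seq(i, by = length(exposures), length.out = nc)
    if (max(my_blocks) > n_blocks) {
      abort("not enough LD blocks for causal SNP placement",
            class = "splitmr_config_error")
    }
    snp_idx <- vapply(my_blocks, function(b) {
      in_b <- which(blocks == b)
      in_b[ceiling(length(in_b) / 2)]
    }, 1L)
    signs <- with_seed(signs_seed + i, sample(c(-1, 1), nc, TRUE))
    g <- panel$dosages[, snp_idx, drop = FALSE]
    # equal variance contribution per causal SNP before empirical rescaling
    v <- pmax(apply(g, 2, var), 1e-12)
    beta <- signs / sqrt(v)
    prs[[e]] <- as.numeric(g %*% beta)
    attr(prs[[e]], "snps") <- panel$snp_meta$snp[snp_idx]
  }
  prs
}

structured_exposure <- function(prs_raw, u, edu_c, config, name, mean_x, sd_x,
                                edu_coef, noise_stream) {
  ve <- config$architecture[[name]]$variance_explained
  cf <- unname(config$confounding[name]) %|na|% 0
  total_var <- sd_x^2
  edu_var <- edu_coef^2 * var(edu_c)
  noise_var <- total_var * (1 - ve - cf^2) - edu_var
  if (noise_var < 0) {
    abort(sprintf("inconsistent variance budget for %s", name),
          class = "splitmr_config_error")
  }
  mean_x + scale_to_var(prs_raw, ve * total_var) + cf * sd_x * u +
    edu_coef * edu_c +
    with_seed(substream_seed(config$seed, noise_stream),
              rnorm(length(u), 0, sqrt(noise_var)))
}

education_from_latent <- function(e_lat) {
  # low-to-high qualification fractions, UK-like
  frac <- c(0.16, 0.06, 0.22, 0.12, 0.05, 0.07, 0.32)
  labels <- c("None of the above", "CSEs or equivalent",
              "O levels/GCSEs or equivalent", "A levels/AS levels or equivalent",
              "Other professional qualifications",
              "NVQ or HND or HNC or equivalent", "College or University degree")
  cuts <- quantile(e_lat, cumsum(frac)[-length(frac)], names = FALSE)
  labels[findInterval(e_lat, cuts, left.open = TRUE) + 1]
}

smoking_fields_from_latent <- function(s_lat, config) {
  n <- length(s_lat)
  tau <- config$tau
  s0 <- quantile(s_lat, config$never_smoker_frac, names = FALSE)
  idx <- pmax(s_lat - s0, 0)
  smoker <- idx > 0
  draws <- with_seed(substream_seed(config$seed, "smoking_fields"), {
    list(former = runif(n) < config$former_smoker_frac,
         cess = runif(n, 1, 15))
  })
  status <- ifelse(!smoker, "never",
                   ifelse(draws$former, "former", "current"))
  cess <- ifelse(status == "former", draws$cess, 0)
  # duration increases with the index so inverted intensities stay plausible
  dur <- rep(0, n)
  dur[smoker] <- 10 + 25 * (rank(idx[smoker]) - 0.5) / sum(smoker)
  fac <- (1 - 0.5^(dur / tau)) * 0.5^(cess / tau)
  cigs <- rep(0, n)
  cigs[smoker] <- exp(idx[smoker] / fac[smoker]) - 1
  # extreme tail: make current and extend duration rather than exceed 80/day
  too_heavy <- smoker & cigs > 80
  cess[too_heavy] <- 0
  status[too_heavy] <- "current"
  dur[too_heavy] <- pmin(
    -tau * log2(pmax(1 - idx[too_heavy] / log(81), 2^(-60 / tau))), 60)
  fac <- (1 - 0.5^(dur / tau)) * 0.5^(cess / tau)
  cigs[too_heavy] <- pmin(exp(idx[too_heavy] / fac[too_heavy]) - 1, 80)
  tibble::tibble(
    smoking_status = status,
    cigarettes_per_day = round(cigs, 1),
    smoking_duration = round(dur, 1),
    years_since_cessation = round(cess, 1)
  ) -> fields
  list(fields = fields)
}

drink_fields_from_latent <- function(a_lat, config) {
  n <- length(a_lat)
  units <- pmax(a_lat, 0)
  drinker <- units > 0
  former <- with_seed(substream_seed(config$seed, "former_drinker"),
                      runif(n) < config$former_drinker_frac) & drinker
  tab <- alcohol_units_table()
  share <- c(0.25, 0.20, 0.30, 0.15, 0.05, 0.05)
  counts <- round(outer(units, share) /
                    matrix(tab$units_per_drink, n, nrow(tab), byrow = TRUE))
  counts[former | !drinker, ] <- 0
  colnames(counts) <- paste0("drinks_", tab$beverage)
  realized <- as.numeric(counts %*% tab$units_per_drink)
  # former drinkers' liability reflects their (unobserved) prior consumption
  realized[former] <- units[former]
  fields <- dplyr::bind_cols(
    tibble::as_tibble(counts),
    tibble::tibble(never_drinker = !drinker & !former,
                   former_drinker = former)
  )
  list(fields = fields, realized_units = realized, former = former)
}

## --- probit / Poisson-binomial truth machinery -----------------------------

liability_score <- function(xs, lambda, kappa = NULL) {
  s <- as.numeric(xs %*% lambda[colnames(xs)])
  if (!is.null(kappa) && length(kappa)) {
    for (nm in names(kappa)) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      s <- s + kappa[[nm]] * xs[, pair[1]] * xs[, pair[2]]
    }
  }
  s
}

cond_prob_matrix <- function(s, lia, thresholds) {
  eta <- tcrossprod(s, lia$w) + lia$fixed
  eta <- sweep(eta, 2, thresholds, "-")
  p <- pnorm(eta)
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

# P(count >= 2 .. 4) per individual from per-condition probabilities
pb_tail_probs <- function(p) {
  lp0 <- rowSums(log1p(-p))
  p0 <- exp(lp0)
  r <- p / (1 - p)
  s1 <- rowSums(r); s2 <- rowSums(r^2); s3 <- rowSums(r^3)
  e1 <- s1
  e2 <- (s1^2 - s2) / 2
  e3 <- (s1^3 - 3 * s1 * s2 + 2 * s3) / 6
  list(
    mm2 = pmin(pmax(1 - p0 * (1 + e1), 0), 1),
    mm3 = pmin(pmax(1 - p0 * (1 + e1 + e2), 0), 1),
    mm4 = pmin(pmax(1 - p0 * (1 + e1 + e2 + e3), 0), 1),
    count = rowSums(p)
  )
}

# fast normal-approximation thresholds used inside calibration loops
solve_thresholds_approx <- function(s, lia) {
  mu_s <- mean(s); v_s <- var(s)
  mu_f <- mean(lia$fixed); v_f <- var(lia$fixed)
  cv <- cov(s, lia$fixed)
  mu <- lia$w * mu_s + mu_f
  sig2 <- lia$w^2 * v_s + v_f + 2 * lia$w * cv
  mu + sqrt(1 + sig2) * qnorm(1 - lia$prevalence)
}

solve_thresholds_exact <- function(s, lia) {
  approx <- solve_thresholds_approx(s, lia)
  vapply(seq_along(lia$w), function(i) {
    eta <- lia$w[i] * s + lia$fixed
    uniroot(function(t) mean(pnorm(eta - t)) - lia$prevalence[i],
            interval = approx[i] + c(-2, 2), extendInt = "yes",
            tol = 1e-8)$root
  }, 1)
}

# mean outcome probability under a counterfactual shift of the scaled
# exposures; "*_exalc" outcomes drop the alcohol-problems condition
mm2_mean <- function(xs, lambda, kappa, lia, thresholds, outcome = "mm2") {
  s <- liability_score(xs, lambda, kappa)
  p <- cond_prob_matrix(s, lia, thresholds)
  if (grepl("_exalc$", outcome) && length(lia$alc_idx)) {
    p <- p[, -lia$alc_idx, drop = FALSE]
    outcome <- sub("_exalc$", "", outcome)
  }
  mean(pb_tail_probs(p)[[outcome]])
}

# the outcome an analyst would use for an analysis involving this exposure
analysis_outcome <- function(exposures, outcome = "mm2") {
  if ("alcohol" %in% exposures) paste0(outcome, "_exalc") else outcome
}

shift_xs <- function(xs, shifts) {
  for (nm in names(shifts)) xs[, nm] <- xs[, nm] + shifts[[nm]]
  xs
}

# shift sets defining the estimands (scaled units)
direct_shift <- function(e) setNames(list(1), e)
total_shift <- function(lia, held_fixed = character()) {
  sc <- lia$scales
  shifts <- list(education = 1)
  for (m in setdiff(names(lia$med_resp), held_fixed)) {
    shifts[[m]] <- unname(lia$med_resp[m] * sc["education"] /
                            sc[c(bmi = "bmi", smoking = "smoking",
                                 alcohol = "alcohol")[m]])
  }
  shifts
}

true_rd <- function(lia, lambda, kappa, thresholds, shifts, outcome = "mm2") {
  base <- mm2_mean(lia$xs, lambda, kappa, lia, thresholds, outcome)
  shifted <- mm2_mean(shift_xs(lia$xs, shifts), lambda, kappa, lia,
                      thresholds, outcome)
  shifted - base
}

calibrate_loadings <- function(lia, config) {
  exposures <- colnames(lia$xs)
  lambda <- setNames(rep(0, length(exposures)), exposures)
  kappa <- list()
  if (!is.null(config$interactions)) {
    for (it in config$interactions) {
      kappa[[paste(it$pair, collapse = ":")]] <- 0
    }
  }
  target <- config$target_rd
  pm_target <- config$target_pm

  rd_fun <- function(lam, shifts, outcome) {
    thr <- solve_thresholds_approx(liability_score(lia$xs, lam, kappa), lia)
    true_rd(lia, lam, kappa, thr, shifts, outcome)
  }
  solve_one <- function(lam, e, shifts, tgt) {
    out <- analysis_outcome(e)
    f <- function(l) { lam[e] <- l; rd_fun(lam, shifts, out) - tgt }
    lam[e] <- uniroot(f, c(-2, 2), extendInt = "yes", tol = 1e-4)$root
    lam
  }
  solve_edu <- function(lam) {
    if (is.na(target["education"])) return(lam)
    solve_one(lam, "education", total_shift(lia), target[["education"]])
  }

  for (sweep_i in 1:3) {
    for (e in c("bmi", "smoking", "alcohol")) {
      if (!is.null(pm_target) && names(pm_target) == e) next
      if (is.na(target[e])) next
      lambda <- solve_one(lambda, e, direct_shift(e), target[[e]])
    }
    if (!is.null(pm_target)) {
      med <- names(pm_target)
      pm_of <- function(l) {
        lam <- lambda; lam[med] <- l
        lam <- solve_edu(lam)
        thr <- solve_thresholds_approx(liability_score(lia$xs, lam, kappa), lia)
        tot <- true_rd(lia, lam, kappa, thr, total_shift(lia))
        dir <- true_rd(lia, lam, kappa, thr,
                       total_shift(lia, held_fixed = med))
        100 * (tot - dir) / tot - unname(pm_target)
      }
      lambda[med] <- uniroot(pm_of, c(0, 1.5), extendInt = "yes",
                             tol = 1e-3)$root
    }
    lambda <- solve_edu(lambda)
    if (length(kappa)) {
      for (it in config$interactions) {
        nm <- paste(it$pair, collapse = ":")
        f <- function(kv) {
          kappa[[nm]] <- kv
          thr <- solve_thresholds_approx(
            liability_score(lia$xs, lambda, kappa), lia)
          interaction_rd(lia, lambda, kappa, thr, it$pair,
                         analysis_outcome(it$pair)) - it$target_rd
        }
        kappa[[nm]] <- uniroot(f, c(-1, 1), extendInt = "yes", tol = 1e-4)$root
      }
    }
  }
  list(lambda = lambda, kappa = kappa)
}

interaction_rd <- function(lia, lambda, kappa, thresholds, pair,
                           outcome = "mm2") {
  f <- function(sh) mm2_mean(shift_xs(lia$xs, sh), lambda, kappa, lia,
                             thresholds, outcome)
  both <- setNames(list(1, 1), pair)
  f(both) - f(both[1]) - f(both[2]) + f(setNames(list(0), pair[1]))
}

build_truth <- function(lia, lambda, kappa, thresholds, config, flags) {
  outcomes <- c("mm2", "mm3", "mm4", "count", "mm2_exalc")
  rd <- purrr::map_dfr(colnames(lia$xs), function(e) {
    shifts <- if (e == "education") total_shift(lia) else direct_shift(e)
    tibble::tibble(
      exposure = e,
      outcome = outcomes,
      true_rd = unname(vapply(outcomes, function(o)
        true_rd(lia, lambda, kappa, thresholds, shifts, o), 1))
    )
  })

  med_sets <- list(bmi = "bmi", smoking = "smoking", alcohol = "alcohol",
                   `bmi+smoking` = c("bmi", "smoking"))
  mediation <- purrr::map_dfr(names(med_sets), function(nm) {
    out <- analysis_outcome(med_sets[[nm]])
    tot <- true_rd(lia, lambda, kappa, thresholds, total_shift(lia), out)
    dir <- true_rd(lia, lambda, kappa, thresholds,
                   total_shift(lia, held_fixed = med_sets[[nm]]), out)
    tibble::tibble(mediators = nm, outcome = out, total = tot, direct = dir,
                   indirect = tot - dir, pm = 100 * (tot - dir) / tot)
  })

  inter <- if (length(kappa)) {
    purrr::map_dfr(names(kappa), function(nm) {
      pair <- strsplit(nm, ":", fixed = TRUE)[[1]]
      rd_int <- interaction_rd(lia, lambda, kappa, thresholds, pair,
                               analysis_outcome(pair))
      tibble::tibble(exposure_a = pair[1], exposure_b = pair[2],
                     kappa = kappa[[nm]], true_rd_interaction = rd_int)
    })
  } else {
    tibble::tibble(exposure_a = character(), exposure_b = character(),
                   kappa = numeric(), true_rd_interaction = numeric())
  }

  structure(list(
    lambda = lambda,
    kappa = unlist(kappa) %||% numeric(),
    structural = c(edu_bmi = config$edu_bmi, edu_smoking = config$edu_smoking,
                   edu_alcohol = config$edu_alcohol),
    mediator_response = lia$med_resp,
    confounding = config$confounding,
    confounder_liability = config$confounder_liability,
    scales = lia$scales,
    thresholds = thresholds,
    condition_weights = lia$w,
    prevalence_target = lia$prevalence,
    prevalence_realized = colMeans(flags),
    rd = rd,
    mediation = mediation,
    interactions = inter
  ), class = "true_parameters")
}

#' @export
print.true_parameters <- function(x, ...) {
  cat("<true_parameters>\n")
  cat("  true risk differences (mm2, per scaled unit):\n")
  mm2 <- dplyr::filter(x$rd, .data$outcome == "mm2")
  for (i in seq_len(nrow(mm2))) {
    cat(sprintf("    %-10s %+.4f\n", mm2$exposure[i], mm2$true_rd[i]))
  }
  cat("  proportion mediated (%):\n")
  for (i in seq_len(nrow(x$mediation))) {
    cat(sprintf("    %-12s %.1f\n", x$mediation$mediators[i],
                x$mediation$pm[i]))
  }
  invisible(x)
}
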