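#' Simulation configuration for the synthetic biobank generator
#'
#' Builds and validates the configuration object consumed by
#' [simulate_genotypes()] and [simulate_cohort()]. The generator emulates a
#' biobank-style cohort: LD-blocked biallelic SNPs, education with a polygenic
#' component, BMI / lifetime smoking / alcohol consumption each with polygenic
#' components plus causal effects of education (a mediation structure),
#' optional pairwise additive interactions, a latent confounder of all
#' phenotype-outcome pairs, and a configurable number of binary chronic
#' conditions generated from probit (liability-threshold) models.
#'
#' Effect targets are expressed as risk differences for the primary
#' multimorbidity outcome (two or more conditions) per *scaled* exposure unit:
#' one SD of education years, 5 kg/m^2 of BMI, one SD of lifetime smoking
#' index, and 5 alcohol units/week. The generator calibrates the condition
#' liability loadings so that the implied true risk differences (computed
#' exactly from the probit condition probabilities) equal these targets.
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of SNPs (a multiple of `ld_block_size` is tidiest).
#' @param maf_range Length-2 numeric, minor-allele-frequency range in (0, 0.5].
#' @param ld_block_size SNPs per exchangeable-correlation LD block.
#' @param ld_rho Within-block haplotype correlation in [0, 1).
#' @param snp_spacing_kb Distance between adjacent SNPs on a chromosome (kb).
#' @param n_chromosomes Number of chromosomes blocks are spread across.
#' @param architecture Named list (education, bmi, smoking, alcohol), each with
#'   `n_causal_snps` and `variance_explained` (fraction of exposure variance).
#' @param edu_bmi,edu_smoking,edu_alcohol Structural effects of one year of
#'   education on BMI (kg/m^2), latent smoking index, and latent alcohol
#'   units/week.
#' @param target_rd Named numeric: target true risk difference on the mm2
#'   scale per scaled unit of each exposure (education entry is the *total*
#'   effect, mediators included).
#' @param target_pm Optional single named value, e.g. `c(bmi = 30)`: calibrate
#'   the BMI liability loading so the true proportion mediated through BMI
#'   equals this percentage (education total still matches `target_rd`).
#' @param interactions Optional list of `list(pair = c("a","b"), target_rd = x)`
#'   additive interactions on the mm2 risk-difference scale (per scaled unit
#'   of each exposure in the pair).
#' @param confounding Named numeric: effect of the standard-normal latent
#'   confounder U on each exposure, in exposure-SD units per SD of U.
#' @param confounder_liability Loading of U on every condition liability.
#' @param n_conditions Number of binary conditions (default 35).
#' @param prevalence Numeric vector of condition prevalence targets
#'   (length `n_conditions`); defaults to [default_prevalences()].
#' @param condition_labels Character labels, one per condition.
#' @param n_pcs Number of genetic principal-component covariates (independent
#'   of genotype by design; no population structure is simulated).
#' @param n_centres Number of assessment centres.
#' @param age_range Length-2 numeric, uniform age range in years.
#' @param female_frac Fraction female.
#' @param age_liability,sex_liability Liability-scale effects of age (per SD)
#'   and female sex on every condition.
#' @param never_smoker_frac Fraction of never smokers.
#' @param former_smoker_frac Fraction of ever-smokers who have quit.
#' @param former_drinker_frac Fraction of drinkers flagged as former drinkers
#'   (excluded from alcohol analyses downstream).
#' @param former_drinker_liability Extra liability for former drinkers.
#' @param bmi_mean,bmi_sd Target BMI mean/SD (kg/m^2).
#' @param alcohol_mean,alcohol_sd Latent alcohol units/week mean/SD.
#' @param smoking_latent_sd SD of the latent lifetime-smoking index.
#' @param tau Smoking-index half-life parameter (years).
#' @param seed Master seed; every stage derives an independent substream.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_snps = 2000,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10,
                       ld_rho = 0.8,
                       snp_spacing_kb = 50,
                       n_chromosomes = 10,
                       architecture = default_architecture(),
                       edu_bmi = -0.2,
                       edu_smoking = -0.05,
                       edu_alcohol = 0.3,
                       target_rd = c(education = -0.090, bmi = 0.092,
                                     smoking = 0.068, alcohol = 0.013),
                       target_pm = NULL,
                       interactions = NULL,
                       confounding = c(education = -0.3, bmi = 0.3,
                                       smoking = 0.3, alcohol = 0.2),
                       confounder_liability = 0.3,
                       n_conditions = 35,
                       prevalence = default_prevalences(n_conditions),
                       condition_labels = default_condition_labels(n_conditions),
                       n_pcs = 10,
                       n_centres = 10,
                       age_range = c(40, 73),
                       female_frac = 0.538,
                       age_liability = 0.1,
                       sex_liability = 0.05,
                       never_smoker_frac = 0.55,
                       former_smoker_frac = 0.35,
                       former_drinker_frac = 0.04,
                       former_drinker_liability = 0.2,
                       bmi_mean = 27.4,
                       bmi_sd = 4.8,
                       alcohol_mean = 18.8,
                       alcohol_sd = 16.5,
                       smoking_latent_sd = 0.9,
                       tau = 18.9,
                       seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_architecture <- function() {
  one <- list(n_causal_snps = 30, variance_explained = 0.15)
  list(education = one, bmi = one, smoking = one, alcohol = one)
}

#' Default condition prevalence targets
#'
#' A 35-condition prevalence profile with a handful of common conditions
#' (hearing loss 37%, depression/anxiety 35%, painful condition 29%) and a
#' geometric tail, chosen so that the expected prevalence of multimorbidity
#' (2+ conditions) is close to 55% in a middle-aged cohort.
#'
#' @param n_conditions Number of conditions.
#' @return Numeric vector of prevalences.
#' @export
default_prevalences <- function(n_conditions = 35) {
  head_p <- c(0.37, 0.35, 0.29, 0.15, 0.12, 0.10)
  if (n_conditions <= length(head_p)) return(head_p[seq_len(n_conditions)])
  k <- n_conditions - length(head_p)
  tail_p <- 0.09 * 0.92^(seq_len(k) - 1)
  pmax(c(head_p, tail_p), 0.005)
}

#' @rdname default_prevalences
#' @export
default_condition_labels <- function(n_conditions = 35) {
  base <- c("hearing_loss", "depression_anxiety", "painful_condition",
            "hypertension", "asthma", "diabetes", "alcohol_problems")
  if (n_conditions < length(base)) return(base[seq_len(n_conditions)])
  c(base, sprintf("condition_%02d", seq_len(n_conditions - length(base))))
}

validate_sim_config <- function(cfg) {
  err <- function(...) abort(sprintf(...), class = "splitmr_config_error")
  with(cfg, {
    if (n_individuals < 2 || n_snps < 1 || ld_block_size < 1) {
      err("counts (n_individuals, n_snps, ld_block_size) must be positive")
    }
    if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
        maf_range[1] > maf_range[2]) {
      err("maf_range must be within (0, 0.5] and non-decreasing")
    }
    if (ld_rho < 0 || ld_rho >= 1) err("ld_rho must be in [0, 1)")
    if (n_conditions < 1) err("n_conditions must be positive")
    if (length(prevalence) != n_conditions ||
        any(prevalence <= 0) || any(prevalence >= 1)) {
      err("prevalence must have one entry in (0,1) per condition")
    }
    if (length(condition_labels) != n_conditions) {
      err("condition_labels must have one label per condition")
    }
    for (e in names(architecture)) {
      a <- architecture[[e]]
      ve <- a$variance_explained
      cf <- unname(confounding[e]) %|na|% 0
      if (a$n_causal_snps < 1) err("n_causal_snps must be positive for %s", e)
      if (ve < 0 || ve > 1) err("variance_explained must be in [0,1] for %s", e)
      if (ve + cf^2 > 1) {
        err("inconsistent variance budget for %s: variance_explained + confounding^2 > 1", e)
      }
    }
    if (sum(vapply(architecture, function(a) a$n_causal_snps, 1)) >
        floor(n_snps / ld_block_size)) {
      err("not enough LD blocks for the requested causal SNPs (one causal SNP per block)")
    }
  })
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d individuals, %d SNPs (blocks of %d, rho = %.2f)\n",
              x$n_individuals, x$n_snps, x$ld_block_size, x$ld_rho))
  cat(sprintf("  %d conditions, seed %d\n", x$n_conditions, x$seed))
  invisible(x)
}
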