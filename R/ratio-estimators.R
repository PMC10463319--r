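#' Harmonize variant-exposure and variant-outcome associations into ratios
#'
#' Joins two GWAS summaries on shared variants, harmonizes alleles (flipping
#' the outcome beta when effect/other alleles are swapped; unharmonizable
#' variants are dropped with a warning), orients every variant-exposure beta
#' to be non-negative (flipping the outcome beta in tandem), and computes the
#' per-variant Wald ratio with its first-order standard error.
#'
#' @param gx Variant-exposure summary (`snp ea oa beta se ...`).
#' @param gy Variant-outcome summary (same schema).
#' @return Tibble: `snp beta_gx se_gx beta_gy se_gy ratio ratio_se`.
#' @export
make_ratios <- function(gx, gy) {
  assert_columns(gx, c("snp", "ea", "oa", "beta", "se"), "exposure summary")
  assert_columns(gy, c("snp", "ea", "oa", "beta", "se"), "outcome summary")
  m <- dplyr::inner_join(
    dplyr::select(gx, snp = "snp", ea_x = "ea", oa_x = "oa",
                  beta_gx = "beta", se_gx = "se"),
    dplyr::select(gy, snp = "snp", ea_y = "ea", oa_y = "oa",
                  beta_gy = "beta", se_gy = "se"),
    by = "snp")
  same <- m$ea_y == m$ea_x & m$oa_y == m$oa_x
  swapped <- m$ea_y == m$oa_x & m$oa_y == m$ea_x
  bad <- !same & !swapped
  if (any(bad)) {
    warn(sprintf("dropping %d variant(s) with unharmonizable alleles: %s",
                 sum(bad), paste(m$snp[bad], collapse = ", ")))
    m <- m[!bad, , drop = FALSE]
    same <- same[!bad]; swapped <- swapped[!bad]
  }
  m$beta_gy <- ifelse(swapped, -m$beta_gy, m$beta_gy)
  zero <- m$beta_gx == 0
  if (any(zero)) {
    warn(sprintf("dropping %d variant(s) with zero exposure beta", sum(zero)))
    m <- m[!zero, , drop = FALSE]
  }
  flip <- m$beta_gx < 0
  m$beta_gy[flip] <- -m$beta_gy[flip]
  m$beta_gx <- abs(m$beta_gx)
  tibble::tibble(
    snp = m$snp, beta_gx = m$beta_gx, se_gx = m$se_gx,
    beta_gy = m$beta_gy, se_gy = m$se_gy,
    ratio = m$beta_gy / m$beta_gx,
    ratio_se = m$se_gy / abs(m$beta_gx)
  )
}

assert_ratios <- function(r, min_k = 1, caller = "estimator") {
  assert_columns(r, c("beta_gx", "beta_gy", "se_gy", "ratio", "ratio_se"),
                 "ratio set")
  if (nrow(r) < min_k) {
    abort(sprintf("%s requires at least %d variant(s)", caller, min_k))
  }
  invisible(r)
}

#' Inverse-variance-weighted estimator
#'
#' Slope of the zero-intercept regression of variant-outcome on
#' variant-exposure betas, weighted by `1/se_gy^2`. With more than one
#' variant the standard error uses multiplicative random-effects scaling
#' (inflated by the residual scale when it exceeds 1); heterogeneity never
#' shrinks the SE below its fixed-effect value.
#'
#' @param r Ratio set from [make_ratios()].
#' @return One-row effect-estimate tibble with a `q` heterogeneity column.
#' @export
ivw <- function(r) {
  assert_ratios(r, 1, "IVW")
  w <- 1 / r$se_gy^2
  est <- sum(w * r$beta_gx * r$beta_gy) / sum(w * r$beta_gx^2)
  se_fe <- 1 / sqrt(sum(w * r$beta_gx^2))
  k <- nrow(r)
  q <- sum(w * (r$beta_gy - est * r$beta_gx)^2)
  phi <- if (k > 1) q / (k - 1) else 1
  out <- effect_row("ivw", est, se_fe * sqrt(max(1, phi)), k)
  out$q <- q
  out
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome on variant-exposure betas *with*
#' an intercept (weights `1/se_gy^2`, exposure betas oriented non-negative).
#' The intercept estimates directional pleiotropy; the slope is the
#' pleiotropy-adjusted causal effect. Standard errors use multiplicative
#' random-effects scaling floored at the fixed-effect value.
#'
#' @param r Ratio set from [make_ratios()] (at least 3 variants).
#' @return Two-row effect-estimate tibble, terms `egger_slope` and
#'   `egger_intercept`.
#' @export
mr_egger <- function(r) {
  assert_ratios(r, 3, "MR-Egger")
  if (sd(r$beta_gx) < 1e-12) {
    abort("degenerate design: identical variant-exposure betas",
          class = "splitmr_degenerate_error")
  }
  w <- 1 / r$se_gy^2
  fit <- lm(beta_gy ~ beta_gx, data = r, weights = w)
  sm <- summary(fit)
  scale_fix <- max(1, sm$sigma) / sm$sigma
  se <- sm$coefficients[, 2] * scale_fix
  dplyr::bind_rows(
    effect_row("egger_slope", coef(fit)[["beta_gx"]], se[["beta_gx"]], nrow(r)),
    effect_row("egger_intercept", coef(fit)[["(Intercept)"]],
               se[["(Intercept)"]], nrow(r))
  )
}

ratio_bootstrap_se <- function(r, stat, n_boot, seed) {
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      stat(rnorm(nrow(r), r$ratio, r$ratio_se))
    }, 1)
  })
  sd(draws)
}

#' Unweighted median estimator
#'
#' Sample median of the per-variant Wald ratios; robust to up to half the
#' variants being invalid. The standard error comes from a parametric
#' bootstrap (ratios resampled from normal(ratio, ratio_se)).
#'
#' @param r Ratio set (at least 3 variants).
#' @param n_boot Bootstrap draws (default 1000).
#' @param seed Seed for the bootstrap substream.
#' @return One-row effect-estimate tibble.
#' @export
unweighted_median <- function(r, n_boot = 1000, seed = 1) {
  assert_ratios(r, 3, "median estimator")
  est <- median(r$ratio)
  se <- ratio_bootstrap_se(r, median, n_boot, substream_seed(seed, "median"))
  effect_row("unweighted_median", est, se, nrow(r))
}

mode_of <- function(x, phi = 1) {
  if (length(unique(x)) == 1) return(x[1])
  spread <- min(sd(x), stats::mad(x))
  if (spread == 0) spread <- sd(x)
  bw <- phi * 0.9 * spread * length(x)^(-1 / 5)
  d <- density(x, bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

#' Simple mode-based estimator
#'
#' Mode of a normal-kernel density over the unweighted per-variant ratios,
#' bandwidth `phi` times the modified Silverman rule
#' (`0.9 min(sd, mad) k^(-1/5)`). Consistent when the largest group of
#' variants sharing a ratio value is valid. SE by parametric bootstrap.
#'
#' @param r Ratio set (at least 3 variants).
#' @param phi Bandwidth factor (default 1).
#' @param n_boot Bootstrap draws.
#' @param seed Seed for the bootstrap substream.
#' @return One-row effect-estimate tibble.
#' @export
simple_mode <- function(r, phi = 1, n_boot = 1000, seed = 1) {
  assert_ratios(r, 3, "mode estimator")
  est <- mode_of(r$ratio, phi)
  se <- ratio_bootstrap_se(r, function(x) mode_of(x, phi), n_boot,
                           substream_seed(seed, "mode"))
  effect_row("simple_mode", est, se, nrow(r))
}
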