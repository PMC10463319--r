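new_mediation_result <- function(total, direct, indirect, indirect_ci, pm,
                                 pm_ci, mediators, framework, n_boot,
                                 per_split = NULL) {
  inconsistent <- abs(direct$beta) > abs(total$beta) ||
    sign(direct$beta) != sign(total$beta)
  structure(list(
    total = total, direct = direct,
    indirect = indirect, indirect_ci = indirect_ci,
    pm = if (inconsistent) NA_real_ else pm,
    pm_ci = if (inconsistent) c(NA_real_, NA_real_) else pm_ci,
    mediators = mediators, framework = framework,
    inconsistent = inconsistent, n_boot = n_boot, per_split = per_split
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("<mediation_result> %s, mediator(s): %s\n",
              toupper(x$framework), paste(x$mediators, collapse = " + ")))
  cat(sprintf("  total    %+.4f (se %.4f)\n", x$total$beta, x$total$se))
  cat(sprintf("  direct   %+.4f (se %.4f)\n", x$direct$beta, x$direct$se))
  cat(sprintf("  indirect %+.4f (95%% CI %.4f, %.4f)\n",
              x$indirect, x$indirect_ci[1], x$indirect_ci[2]))
  if (x$inconsistent) {
    cat("  proportion mediated: suppressed (inconsistent mediation)\n")
  } else {
    cat(sprintf("  proportion mediated %.1f%% (95%% CI %.1f, %.1f)\n",
                x$pm, x$pm_ci[1], x$pm_ci[2]))
  }
  invisible(x)
}

mvr_total_direct <- function(data, exposure, mediators, outcome, covariates) {
  total <- fit_linear_robust(data, outcome, exposure, covariates)
  direct <- fit_linear_robust(data, outcome, exposure,
                              c(mediators, covariates))
  list(total = total, direct = direct)
}

mr_total_direct <- function(data, exposure, mediators, outcome, covariates,
                            instruments, split_col = "split") {
  splits <- sort(unique(data[[split_col]]))
  per <- purrr::map_dfr(splits, function(s) {
    d <- data[data[[split_col]] == s, , drop = FALSE]
    tot <- suppressWarnings(
      tidy(tsls(d, outcome, exposure, instruments[exposure], covariates)))
    dir <- suppressWarnings(
      tidy(tsls(d, outcome, c(exposure, mediators),
                instruments[c(exposure, mediators)], covariates)))
    dplyr::bind_rows(
      dplyr::mutate(tot[tot$term == exposure, ], which = "total", split = s),
      dplyr::mutate(dir[dir$term == exposure, ], which = "direct", split = s))
  })
  pool <- function(which) {
    rows <- per[per$which == which, ]
    mt <- fixed_effect_meta(rows$beta, rows$se)
    effect_row(which, mt$beta, mt$se, sum(rows$n))
  }
  list(total = pool("total"), direct = pool("direct"), per_split = per)
}

#' Mediation analysis by the difference method
#'
#' Estimates how much of the exposure's effect on the outcome operates
#' through the given mediator(s). The total effect is the exposure
#' coefficient with no mediators; the direct effect is the exposure
#' coefficient with the mediator(s) added - as covariates in a robust linear
#' regression (`framework = "mvr"`), or as additional instrumented exposures
#' in a multivariable two-stage least squares model (`framework = "mr"`,
#' which requires a genetic score column per exposure/mediator and a split
#' column; estimates are pooled across splits by fixed-effects
#' meta-analysis before the difference is formed, and per-split estimates
#' are retained). The indirect effect is total minus direct; the proportion
#' mediated (PM) is 100 x indirect / total.
#'
#' Percentile confidence intervals for the indirect effect and PM come from
#' a bootstrap over individuals (within split for MR). Mediation is flagged
#' inconsistent when the direct effect exceeds the total in magnitude or
#' differs in sign, in which case PM is suppressed (it is not interpretable
#' as a proportion).
#'
#' @param data Analysis tibble (complete cases are used).
#' @param exposure Exposure column name.
#' @param mediators Character vector of mediator column names (non-empty).
#' @param outcome Outcome column name.
#' @param covariates Adjustment column names.
#' @param framework `"mvr"` or `"mr"`.
#' @param instruments For MR: named character vector mapping each of
#'   `c(exposure, mediators)` to its score column.
#' @param split_col For MR: split label column.
#' @param n_boot Bootstrap repeats (default 200).
#' @param seed Bootstrap seed.
#' @return A `mediation_result`; see [tidy.mediation_result()].
#' @export
mediation_analysis <- function(data, exposure, mediators, outcome,
                               covariates = NULL,
                               framework = c("mvr", "mr"),
                               instruments = NULL, split_col = "split",
                               n_boot = 200, seed = 1) {
  framework <- match.arg(framework)
  if (length(mediators) == 0) abort("mediator set must be non-empty")
  need <- c(exposure, mediators, outcome, covariates,
            if (framework == "mr") c(unname(instruments), split_col))
  if (framework == "mr") {
    missing_inst <- setdiff(c(exposure, mediators), names(instruments))
    if (length(missing_inst)) {
      abort(sprintf("no instrument column mapped for: %s",
                    paste(missing_inst, collapse = ", ")))
    }
  }
  dat <- data[complete.cases(data[, need, drop = FALSE]), , drop = FALSE]

  point <- if (framework == "mvr") {
    mvr_total_direct(dat, exposure, mediators, outcome, covariates)
  } else {
    mr_total_direct(dat, exposure, mediators, outcome, covariates,
                    instruments, split_col)
  }
  total <- point$total
  direct <- point$direct
  if (total$beta == 0) {
    abort("total effect is exactly zero; proportion mediated undefined",
          class = "splitmr_degenerate_error")
  }
  indirect <- total$beta - direct$beta
  pm <- 100 * indirect / total$beta

  ## bootstrap over individuals (within split for MR) on prebuilt design
  ## matrices -- same estimators as the point fits, minus the bookkeeping
  y <- dat[[outcome]]
  xt <- build_design(dat, c(exposure, covariates))
  xd <- build_design(dat, c(exposure, mediators, covariates))
  et <- match_terms(colnames(xt), exposure)
  ed <- match_terms(colnames(xd), exposure)
  boot_stat <- if (framework == "mvr") {
    function(idx) {
      tot <- fast_ols_beta(y[idx], xt[idx, , drop = FALSE], et)
      dir <- fast_ols_beta(y[idx], xd[idx, , drop = FALSE], ed)
      c(tot, dir)
    }
  } else {
    zt <- build_design(dat, c(unname(instruments[exposure]), covariates))
    zd <- build_design(dat, c(unname(instruments[c(exposure, mediators)]),
                              covariates))
    split_idx <- split(seq_len(nrow(dat)), dat[[split_col]])
    function(idx) {
      per <- vapply(split_idx, function(rows) {
        i <- idx[idx %in% rows]
        tot <- fast_tsls(y[i], xt[i, , drop = FALSE], zt[i, , drop = FALSE], et)
        dir <- fast_tsls(y[i], xd[i, , drop = FALSE], zd[i, , drop = FALSE], ed)
        c(tot, dir)
      }, c(0, 0, 0, 0))
      # fixed-effects pool of (beta, se) rows: total then direct
      c(sum(per[1, ] / per[2, ]^2) / sum(1 / per[2, ]^2),
        sum(per[3, ] / per[4, ]^2) / sum(1 / per[4, ]^2))
    }
  }
  boot <- with_seed(substream_seed(seed, "mediation_boot"), {
    strata <- if (framework == "mr") {
      split(seq_len(nrow(dat)), dat[[split_col]])
    }
    vapply(seq_len(n_boot), function(b) {
      idx <- if (framework == "mr") {
        unlist(lapply(strata, function(i) sample(i, replace = TRUE)),
               use.names = FALSE)
      } else {
        sample.int(nrow(dat), replace = TRUE)
      }
      td <- boot_stat(idx)
      ind <- td[1] - td[2]
      c(ind, 100 * ind / td[1])
    }, c(0, 0))
  })
  indirect_ci <- unname(quantile(boot[1, ], c(0.025, 0.975)))
  pm_ci <- unname(quantile(boot[2, ], c(0.025, 0.975)))

  new_mediation_result(total, direct, indirect, indirect_ci, pm, pm_ci,
                       mediators, framework, n_boot,
                       per_split = point$per_split)
}

#' Parametric g-formula mediation for a binary outcome
#'
#' Sensitivity analysis to the difference method: fits a logistic outcome
#' model (exposure, mediator, covariates) and a linear-Gaussian mediator
#' model (exposure, covariates), then Monte-Carlo standardizes over the
#' empirical covariate distribution to obtain natural direct and indirect
#' effects on the risk-difference scale for a `delta`-unit exposure
#' increase. PM is indirect / total x 100.
#'
#' @param data Analysis tibble.
#' @param exposure,mediator,outcome Column names (outcome binary 0/1).
#' @param covariates Adjustment columns.
#' @param delta Exposure contrast (default 1 unit).
#' @param n_mc Monte-Carlo draws (default 10000).
#' @param seed Seed for the Monte-Carlo substream.
#' @return A `mediation_result` (framework `"gformula"`; no bootstrap CIs).
#' @export
gformula_mediation <- function(data, exposure, mediator, outcome,
                               covariates = NULL, delta = 1,
                               n_mc = 10000, seed = 1) {
  need <- c(exposure, mediator, outcome, covariates)
  dat <- data[complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  if (!all(dat[[outcome]] %in% c(0, 1))) {
    abort("g-formula requires a binary 0/1 outcome")
  }
  ofml <- stats::as.formula(paste(outcome, "~",
                                  paste(c(exposure, mediator, covariates),
                                        collapse = "+")))
  mfml <- stats::as.formula(paste(mediator, "~",
                                  paste(c(exposure, covariates),
                                        collapse = "+")))
  ofit <- glm(ofml, data = dat, family = binomial())
  if (!ofit$converged) abort("outcome model did not converge")
  if (anyNA(coef(ofit))) {
    abort("outcome model is rank deficient (collinear exposure/mediator?)",
          class = "splitmr_rank_error")
  }
  mfit <- lm(mfml, data = dat)
  if (anyNA(coef(mfit))) {
    abort("mediator model is rank deficient", class = "splitmr_rank_error")
  }
  msd <- summary(mfit)$sigma

  with_seed(substream_seed(seed, "gformula"), {
    rows <- dat[sample.int(nrow(dat), n_mc, replace = TRUE), , drop = FALSE]
    eps <- rnorm(n_mc, 0, msd)  # common random numbers across scenarios
    mediator_at <- function(x) {
      d <- rows; d[[exposure]] <- x
      predict(mfit, newdata = d) + eps
    }
    risk <- function(x, m) {
      d <- rows; d[[exposure]] <- x; d[[mediator]] <- m
      mean(predict(ofit, newdata = d, type = "response"))
    }
    x0 <- rows[[exposure]]
    m0 <- mediator_at(x0)
    m1 <- mediator_at(x0 + delta)
    y00 <- risk(x0, m0)
    y10 <- risk(x0 + delta, m0)
    y11 <- risk(x0 + delta, m1)
    total <- y11 - y00
    direct <- y10 - y00
    indirect <- total - direct
    new_mediation_result(
      total = effect_row("total", total, NA_real_, nrow(dat)),
      direct = effect_row("direct", direct, NA_real_, nrow(dat)),
      indirect = indirect, indirect_ci = c(NA_real_, NA_real_),
      pm = 100 * indirect / total, pm_ci = c(NA_real_, NA_real_),
      mediators = mediator, framework = "gformula", n_boot = 0L
    )
  })
}
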