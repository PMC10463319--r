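#' Multivariable regression with robust standard errors
#'
#' The MVR engine: linear-probability (identity link) least squares with
#' heteroskedasticity-consistent (HC1 sandwich) standard errors, or
#' maximum-likelihood logistic regression with robust sandwich standard
#' errors. Linear regression of a binary outcome yields coefficients on the
#' risk-difference scale, the common currency of all estimates here.
#'
#' @param data Data frame.
#' @param outcome Outcome column name.
#' @param predictors Character vector of predictor columns (effects
#'   reported); interactions may be given as `"a:b"`.
#' @param covariates Character vector of adjustment columns (not reported).
#' @param link `"identity"` (linear) or `"logit"`.
#' @return Tibble of effect estimates, one row per predictor term:
#'   `term beta se ci_low ci_high p n scale`.
#' @export
fit_linear_robust <- function(data, outcome, predictors,
                              covariates = NULL, link = "identity") {
  link <- match.arg(link, c("identity", "logit"))
  rhs <- paste(c(predictors, covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  base_cols <- unique(c(outcome, unlist(strsplit(c(predictors, covariates), ":"))))
  dat <- data[complete.cases(data[, base_cols, drop = FALSE]), , drop = FALSE]
  fit <- if (link == "identity") {
    lm(fml, data = dat)
  } else {
    glm(fml, data = dat, family = binomial())
  }
  if (anyNA(coef(fit))) {
    abort(sprintf("rank-deficient design; collinear term(s): %s",
                  paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "splitmr_rank_error")
  }
  vc <- if (link == "identity") {
    sandwich::vcovHC(fit, type = "HC1")
  } else {
    sandwich::sandwich(fit)
  }
  ct <- lmtest::coeftest(fit, vcov. = vc)
  keep <- match_terms(rownames(ct), predictors)
  effect_row(names(keep), ct[keep, 1], ct[keep, 2], nrow(dat))
}

# model.matrix writes "a:b" terms in its own column order; match either
match_terms <- function(have, want) {
  idx <- vapply(want, function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    alt <- paste(rev(parts), collapse = ":")
    m <- match(tm, have)
    if (is.na(m)) m <- match(alt, have)
    m
  }, 1L)
  if (anyNA(idx)) {
    abort(sprintf("term(s) not in fitted model: %s",
                  paste(want[is.na(idx)], collapse = ", ")))
  }
  setNames(idx, want)
}

build_design <- function(data, cols) {
  if (length(cols) == 0) {
    return(matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)")))
  }
  df <- as.data.frame(data[, unique(unlist(strsplit(cols, ":"))), drop = FALSE])
  df[] <- lapply(df, function(x) if (is.character(x)) factor(x) else x)
  mm <- model.matrix(stats::as.formula(paste("~", paste(cols, collapse = "+"))),
                     df)
  mm
}

#' Two-stage least squares (single- or multi-exposure MR)
#'
#' Standard 2SLS: exposures are projected on the instruments plus covariates,
#' and the outcome regressed on the projections plus covariates. Standard
#' errors are the instrumental-variable sandwich computed from the IV
#' residuals `y - X beta` (not the second-stage OLS residuals), with an HC1
#' small-sample factor. With several exposures this is multivariable MR and
#' the coefficient on each exposure is a direct effect.
#'
#' A first-stage partial F statistic below 10 for any exposure triggers a
#' weak-instrument warning (never an error).
#'
#' @param data Data frame.
#' @param outcome Outcome column.
#' @param exposures Character vector of exposure columns; products may be
#'   written `"a:b"`.
#' @param instruments Character vector of instrument columns (`"a:b"`
#'   products allowed); must be at least as many as exposures.
#' @param covariates Optional adjustment columns, included in both stages.
#' @return A `tsls_fit` object; [tidy()] extracts the per-exposure effect
#'   estimates, [glance()] the fit summary.
#' @export
tsls <- function(data, outcome, exposures, instruments, covariates = NULL) {
  if (length(instruments) < length(exposures)) {
    abort("under-identified: fewer instruments than exposures",
          class = "splitmr_identification_error")
  }
  cols <- unique(unlist(strsplit(c(outcome, exposures, instruments,
                                   covariates), ":")))
  dat <- data[complete.cases(data[, cols, drop = FALSE]), , drop = FALSE]
  n <- nrow(dat)
  y <- dat[[outcome]]
  xm <- build_design(dat, c(exposures, covariates))
  zm <- build_design(dat, c(instruments, covariates))
  x_terms <- match_terms(colnames(xm), exposures)
  if (qr(zm)$rank < ncol(zm)) {
    abort("instrument matrix is rank deficient",
          class = "splitmr_identification_error")
  }
  if (qr(xm)$rank < ncol(xm)) {
    abort("exposure/covariate design is rank deficient",
          class = "splitmr_rank_error")
  }
  qz <- qr(zm)
  xhat <- qr.fitted(qz, xm)
  k <- ncol(xm)
  xtx <- crossprod(xhat, xm)
  beta <- drop(solve(xtx, crossprod(xhat, y)))
  u <- y - drop(xm %*% beta)
  bread <- solve(xtx)
  meat <- crossprod(xhat * u)
  vc <- bread %*% meat %*% t(bread) * n / (n - k)
  se <- sqrt(diag(vc))

  # first-stage partial F of the excluded instruments, per exposure
  cvm <- build_design(dat, covariates %||% character(0))
  qc <- qr(cvm)
  fs <- purrr::map_dfr(seq_along(exposures), function(i) {
    x <- xm[, x_terms[i]]
    rss_r <- sum(qr.resid(qc, x)^2)
    rss_f <- sum(qr.resid(qz, x)^2)
    q_ex <- qz$rank - qc$rank
    df2 <- n - qz$rank
    fstat <- ((rss_r - rss_f) / q_ex) / (rss_f / df2)
    tibble::tibble(exposure = exposures[i], f_stat = fstat)
  })
  if (any(fs$f_stat < 10)) {
    warn(sprintf("weak instrument(s): first-stage F < 10 for %s",
                 paste(fs$exposure[fs$f_stat < 10], collapse = ", ")))
  }

  est <- effect_row(exposures, beta[x_terms], se[x_terms], n)
  structure(list(estimates = est, first_stage = fs, n = n,
                 n_instruments = length(instruments),
                 coefficients = setNames(beta, colnames(xm)),
                 vcov = vc, outcome = outcome),
            class = "tsls_fit")
}

#' @export
print.tsls_fit <- function(x, ...) {
  cat(sprintf("<tsls_fit> outcome %s, n = %d, %d instrument(s)\n",
              x$outcome, x$n, x$n_instruments))
  print(x$estimates)
  invisible(x)
}

# minimal matrix-level estimators used inside bootstrap loops: identical
# point estimates to fit_linear_robust()/tsls(), no bookkeeping
fast_ols_beta <- function(y, x, col) {
  drop(solve(crossprod(x), crossprod(x, y)))[col]
}

fast_tsls <- function(y, x, z, col) {
  xhat <- z %*% solve(crossprod(z), crossprod(z, x))
  xtx <- crossprod(xhat, x)
  beta <- drop(solve(xtx, crossprod(xhat, y)))
  u <- y - drop(x %*% beta)
  bread <- solve(xtx)
  vc <- bread %*% crossprod(xhat * u) %*% t(bread) *
    length(y) / (length(y) - ncol(x))
  c(beta[col], sqrt(diag(vc))[col])
}

#' Rescale an effect estimate
#'
#' Multiplies beta, SE and CI by a constant (e.g. per-unit to per-5-units);
#' the p-value is scale-invariant.
#'
#' @param est Effect-estimate tibble (rows from [fit_linear_robust()],
#'   [tidy()] of a `tsls_fit`, ...).
#' @param factor Non-zero scaling factor.
#' @param scale Optional new scale descriptor string.
#' @return Rescaled estimate tibble.
#' @export
rescale_effect <- function(est, factor, scale = NULL) {
  if (length(factor) != 1 || factor == 0) {
    abort("factor must be a single non-zero number")
  }
  est$beta <- est$beta * factor
  est$se <- est$se * abs(factor)
  est$ci_low <- est$beta - 1.96 * est$se
  est$ci_high <- est$beta + 1.96 * est$se
  if (!is.null(scale)) est$scale <- scale
  est
}
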