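#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a two-stage least squares fit
#'
#' @param x A `tsls_fit`.
#' @param ... Unused.
#' @return Tibble of per-exposure effect estimates
#'   (`term beta se ci_low ci_high p n scale`).
#' @method tidy tsls_fit
#' @export
tidy.tsls_fit <- function(x, ...) x$estimates

#' @rdname tidy.tsls_fit
#' @return For `glance()`: one-row tibble with `n`, `n_instruments` and the
#'   minimum first-stage F statistic.
#' @method glance tsls_fit
#' @export
glance.tsls_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_instruments = x$n_instruments,
                 min_f_stat = min(x$first_stage$f_stat))
}

#' Tidy a mediation result
#'
#' @param x A `mediation_result`.
#' @param ... Unused.
#' @return Tibble with one row per quantity (total, direct, indirect,
#'   proportion_mediated) and percentile-bootstrap CIs where available; the
#'   PM row is `NA` when mediation is inconsistent.
#' @method tidy mediation_result
#' @export
tidy.mediation_result <- function(x, ...) {
  tibble::tibble(
    term = c("total", "direct", "indirect", "proportion_mediated"),
    estimate = c(x$total$beta, x$direct$beta, x$indirect, x$pm),
    se = c(x$total$se, x$direct$se, NA_real_, NA_real_),
    ci_low = c(x$total$ci_low, x$direct$ci_low, x$indirect_ci[1], x$pm_ci[1]),
    ci_high = c(x$total$ci_high, x$direct$ci_high, x$indirect_ci[2],
                x$pm_ci[2])
  )
}

#' @rdname tidy.mediation_result
#' @method glance mediation_result
#' @export
glance.mediation_result <- function(x, ...) {
  tibble::tibble(
    framework = x$framework,
    mediators = paste(x$mediators, collapse = "+"),
    inconsistent = x$inconsistent,
    n = x$total$n,
    n_boot = x$n_boot
  )
}
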