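#' @importFrom rlang %||% abort warn
#' @importFrom stats pnorm qnorm pt quantile sd var cor cov median rnorm
#'   runif rbinom lm glm binomial coef residuals fitted predict mad
#'   model.matrix setNames complete.cases density uniroot
#' @importFrom utils head
NULL

# Deterministic substream seed: master seed + stage name -> integer in
# [1, 2^31 - 2]. Uses a small string hash so stages are mutually independent
# and reproducible across platforms (pure double arithmetic, no overflow).
substream_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, prime
  h <- abs(as.numeric(master)) %% m
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h %% (m - 1) + 1)
}

# djb2-style hash of a configuration object, for run logs.
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 4294967296
  sprintf("%08x", as.integer(h %% 2147483648))
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Wald-style effect-estimate row: the common currency of MVR, MR and meta.
effect_row <- function(term, beta, se, n, scale = NA_character_) {
  beta <- unname(beta)
  se <- unname(se)
  tibble::tibble(
    term = term,
    beta = beta,
    se = se,
    ci_low = beta - 1.96 * se,
    ci_high = beta + 1.96 * se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    n = as.integer(n),
    scale = scale
  )
}

`%|na|%` <- function(x, y) ifelse(is.na(x), y, x)

assert_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ), class = "splitmr_format_error")
  }
  invisible(data)
}
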