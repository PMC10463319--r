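sim_iv_data <- function(n = 2000, effect = 0.5, conf = 0.8, seed = 1) {
  set.seed(seed)
  u <- rnorm(n)
  z <- rnorm(n)
  x <- 0.5 * z + conf * u + rnorm(n)
  y <- effect * x - conf * u + rnorm(n)
  tibble::tibble(z = z, x = x, y = y, u = u)
}

test_that("robust linear fit recovers slopes; robust SE sane when homoskedastic", {
  set.seed(2)
  n <- 10000
  d <- tibble::tibble(x = rnorm(n), w = rnorm(n))
  d$y <- 2 * d$x + 0.5 * d$w + rnorm(n)
  est <- fit_linear_robust(d, "y", "x", "w")
  expect_equal(est$beta, 2, tolerance = 0.05)
  cl <- summary(lm(y ~ x + w, d))$coefficients["x", 2]
  expect_lt(abs(est$se / cl - 1), 0.10)   # sandwich ~ classical
  # near-exact fit: slope 2, se -> 0
  d$y2 <- 2 * d$x + rnorm(n, 0, 1e-8)
  est2 <- fit_linear_robust(d, "y2", "x")
  expect_equal(est2$beta, 2, tolerance = 1e-6)
  expect_lt(est2$se, 1e-8)
})

test_that("linear-probability coefficient equals the risk difference", {
  set.seed(3)
  x <- rbinom(5000, 1, 0.4)
  y <- rbinom(5000, 1, 0.3 + 0.2 * x)
  d <- tibble::tibble(x = x, y = y)
  est <- fit_linear_robust(d, "y", "x")
  expect_equal(est$beta, mean(y[x == 1]) - mean(y[x == 0]), tolerance = 1e-12)
  # logistic variant returns a log-odds coefficient with robust SE
  est_l <- fit_linear_robust(d, "y", "x", link = "logit")
  or <- (mean(y[x == 1]) / (1 - mean(y[x == 1]))) /
    (mean(y[x == 0]) / (1 - mean(y[x == 0])))
  expect_equal(est_l$beta, log(or), tolerance = 1e-6)
})

test_that("collinear designs error with the offending column named", {
  d <- tibble::tibble(x = rnorm(50))
  d$x2 <- d$x
  d$y <- d$x + rnorm(50)
  expect_error(fit_linear_robust(d, "y", c("x", "x2")), "x2",
               class = "splitmr_rank_error")
})

test_that("2SLS equals the IV closed form and the explicit two-stage build", {
  d <- sim_iv_data()
  fit <- tsls(d, "y", "x", "z")
  wald <- cov(d$z, d$y) / cov(d$z, d$x)
  expect_equal(tidy(fit)$beta, wald, tolerance = 1e-8)
  # explicit two-stage construction
  xhat <- fitted(lm(x ~ z, d))
  beta2 <- coef(lm(d$y ~ xhat))[[2]]
  expect_equal(tidy(fit)$beta, beta2, tolerance = 1e-8)
  # instrumenting x with itself reproduces OLS
  fit_ols <- tsls(d, "y", "x", "x")
  expect_equal(tidy(fit_ols)$beta, coef(lm(y ~ x, d))[["x"]],
               tolerance = 1e-8)
  expect_error(tsls(d, "y", c("x", "u"), "z"),
               class = "splitmr_identification_error")
})

test_that("2SLS removes confounding bias that OLS suffers", {
  d <- sim_iv_data(n = 20000, effect = 0.5, conf = 0.8, seed = 5)
  ols <- fit_linear_robust(d, "y", "x")
  iv <- tidy(tsls(d, "y", "x", "z"))
  expect_gt(abs(ols$beta - 0.5) / ols$se, 3)    # OLS biased
  expect_lt(abs(iv$beta - 0.5) / iv$se, 3)      # 2SLS consistent
  expect_lt(abs(iv$beta - 0.5), abs(ols$beta - 0.5))
})

test_that("estimators are outcome-scale equivariant", {
  d <- sim_iv_data(n = 3000, seed = 7)
  d$y10 <- 10 * d$y
  f1 <- tidy(tsls(d, "y", "x", "z"))
  f10 <- tidy(tsls(d, "y10", "x", "z"))
  expect_equal(f10$beta, 10 * f1$beta, tolerance = 1e-10)
  expect_equal(f10$se, 10 * f1$se, tolerance = 1e-10)
  expect_equal(f10$p, f1$p, tolerance = 1e-10)
})

test_that("weak instruments warn, strong ones do not", {
  d <- sim_iv_data(n = 500, seed = 11)
  d$z_weak <- rnorm(500)
  expect_warning(tsls(d, "y", "x", "z_weak"), "weak")
  expect_silent(tsls(d, "y", "x", "z"))
})

test_that("rescaling multiplies beta/se/CI and keeps p", {
  est <- effect_row("x", 0.0184, 0.004, 100)
  r5 <- rescale_effect(est, 5, scale = "per 5 units")
  expect_equal(r5$beta, 0.092)
  expect_equal(r5$se, 0.02)
  expect_equal(r5$ci_low, r5$beta - 1.96 * r5$se)
  expect_equal(r5$p, est$p)
  expect_equal(rescale_effect(est, 1)$beta, est$beta)
  expect_error(rescale_effect(est, 0))
})

test_that("ratio harmonization aligns alleles and orients beta_gx >= 0", {
  gx <- tibble::tibble(snp = c("a", "b", "c"), ea = "A", oa = "G",
                       beta = c(0.5, -0.4, 0), se = 0.01)
  gy <- tibble::tibble(snp = c("a", "b", "c"), ea = "A", oa = "G",
                       beta = c(0.1, 0.08, 0.3), se = 0.02)
  r <- suppressWarnings(make_ratios(gx, gy))
  expect_equal(nrow(r), 2)                 # zero-beta variant dropped
  expect_true(all(r$beta_gx >= 0))
  expect_equal(r$ratio[r$snp == "a"], 0.2)
  expect_equal(r$ratio_se[r$snp == "a"], 0.04)
  expect_equal(r$ratio[r$snp == "b"], 0.08 / -0.4)  # orientation flip
  # allele-swapped outcome summary gives the identical ratio set
  gy_sw <- gy
  gy_sw$ea <- "G"; gy_sw$oa <- "A"; gy_sw$beta <- -gy$beta
  expect_equal(suppressWarnings(make_ratios(gx, gy_sw)), r)
  # unharmonizable variant dropped with warning
  gy_bad <- gy
  gy_bad$ea[1] <- "T"
  w <- capture_warnings(make_ratios(gx, gy_bad))
  expect_match(w, "unharmonizable", all = FALSE)
})

test_that("IVW reduces to the Wald ratio and matches its algebraic form", {
  r1 <- make_ratio_fixture(k = 1, se_gy = 0.01)
  expect_equal(ivw(r1)$beta, r1$ratio)
  expect_equal(ivw(r1)$se, r1$ratio_se)
  r <- make_ratio_fixture(k = 20, effect = 0.3, seed = 2)
  w <- 1 / r$se_gy^2
  direct <- sum(w * r$beta_gx * r$beta_gy) / sum(w * r$beta_gx^2)
  expect_equal(ivw(r)$beta, direct, tolerance = 1e-10)
  # all ratios equal c -> estimate c with zero heterogeneity
  rc <- r
  rc$beta_gy <- 0.25 * rc$beta_gx
  rc$ratio <- 0.25
  expect_equal(ivw(rc)$beta, 0.25, tolerance = 1e-12)
  expect_lt(ivw(rc)$q, 1e-20)
})

test_that("MR-Egger finds directional pleiotropy and keeps the slope", {
  r0 <- make_ratio_fixture(k = 40, effect = 0.2, intercept = 0, seed = 3)
  e0 <- mr_egger(r0)
  int0 <- e0[e0$term == "egger_intercept", ]
  expect_lt(abs(int0$beta / int0$se), 3)    # no pleiotropy simulated
  # constant offset c added to every outcome beta
  rc <- r0
  rc$beta_gy <- rc$beta_gy + 0.02
  rc$ratio <- rc$beta_gy / rc$beta_gx
  ec <- mr_egger(rc)
  intc <- ec[ec$term == "egger_intercept", ]
  slc <- ec[ec$term == "egger_slope", ]
  expect_lt(abs(intc$beta - 0.02) / intc$se, 3)
  expect_lt(abs(slc$beta - 0.2) / slc$se, 3)
  # degenerate design: identical beta_gx
  rd <- r0
  rd$beta_gx <- 0.1
  expect_error(mr_egger(rd), class = "splitmr_degenerate_error")
  expect_error(mr_egger(r0[1:2, ]))
})

test_that("median and mode estimators resist invalid variants", {
  r <- make_ratio_fixture(k = 3, seed = 4)
  r$ratio <- c(1, 2, 100)
  expect_equal(unweighted_median(r)$beta, 2)
  # <= 50% invalid variants with inflated ratios, truth 0.2
  set.seed(8)
  k <- 11
  rk <- tibble::tibble(
    snp = sprintf("v%02d", 1:k), beta_gx = runif(k, 0.1, 0.2), se_gx = 0.01,
    se_gy = 0.004)
  rk$beta_gy <- 0.2 * rk$beta_gx + rnorm(k, 0, rk$se_gy)
  rk$beta_gy[1:5] <- rk$beta_gy[1:5] + 0.1   # 5 of 11 pleiotropic
  rk$ratio <- rk$beta_gy / rk$beta_gx
  rk$ratio_se <- rk$se_gy / rk$beta_gx
  med <- unweighted_median(rk, seed = 42)
  expect_lt(abs(med$beta - 0.2) / med$se, 3)
  # mode: tight cluster at 0.2 beats a stray ratio
  rm_ <- make_ratio_fixture(k = 4, seed = 5)
  rm_$ratio <- c(0.2, 0.2, 0.2, 0.9)
  rm_$ratio_se <- rep(0.02, 4)
  grid_mode <- {
    xs <- seq(0, 1, by = 1e-4)
    spread <- min(sd(rm_$ratio), mad(rm_$ratio))
    if (spread == 0) spread <- sd(rm_$ratio)
    bw <- 0.9 * spread * 4^(-1 / 5)
    dens <- vapply(xs, function(g)
      sum(dnorm((g - rm_$ratio) / bw)), 1)
    xs[which.max(dens)]
  }
  sm <- simple_mode(rm_, seed = 42)
  expect_equal(sm$beta, grid_mode, tolerance = 5e-3)
  expect_equal(sm$beta, 0.2, tolerance = 0.02)
  # invariant to variant order
  expect_equal(simple_mode(rm_[4:1, ], seed = 42)$beta, sm$beta)
  # all equal -> that value
  req <- rm_
  req$ratio <- rep(0.3, 4)
  expect_equal(simple_mode(req, seed = 1)$beta, 0.3)
})
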