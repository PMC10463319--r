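test_that("sample splits are balanced, complementary and reproducible", {
  s10 <- split_sample(letters[1:10], 1)
  expect_equal(sort(table(s10$split)), sort(c(`1` = 5, `2` = 5)),
               ignore_attr = TRUE)
  s11 <- split_sample(letters[1:11], 1)
  expect_lte(abs(diff(table(s11$split))), 1)
  expect_identical(split_sample(letters[1:11], 99),
                   split_sample(letters[1:11], 99))
  expect_false(identical(s11$split, split_sample(letters[1:11], 98)$split))
  expect_error(split_sample("a", 1))
  expect_error(split_sample(c("a", "a"), 1))
})

test_that("per-SNP GWAS matches lm() and is calibrated under the null", {
  pan <- toy_panel(n = 800, m = 6, seed = 2)
  set.seed(3)
  covs <- tibble::tibble(age = rnorm(800), sex = rbinom(800, 1, 0.5))
  y <- 0.5 * pan$dosages[, 3] + 0.3 * covs$age + rnorm(800)
  gw <- run_gwas(pan, y, covs)
  ref <- lm(y ~ pan$dosages[, 3] + covs$age + covs$sex)
  sm <- summary(ref)$coefficients[2, ]
  expect_equal(gw$beta[3], sm[["Estimate"]], tolerance = 1e-10)
  expect_equal(gw$se[3], sm[["Std. Error"]], tolerance = 1e-10)
  expect_equal(gw$p[3], sm[["Pr(>|t|)"]], tolerance = 1e-10)
  expect_lt(abs(gw$beta[3] - 0.5) / gw$se[3], 3)
  # covariate equal to the phenotype wipes out every association
  gw0 <- run_gwas(pan, y, tibble::tibble(y = y))
  expect_true(all(abs(gw0$beta) < 1e-8))
})

test_that("null phenotype gives uniform p-values", {
  pan <- small_panel()
  set.seed(4)
  y <- rnorm(nrow(pan$dosages))
  gw <- run_gwas(pan, y)
  frac <- mean(gw$p < 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("constant dosage columns are skipped with a warning", {
  pan <- toy_panel(n = 200, m = 4, seed = 5)
  pan$dosages[, 2] <- 1L
  set.seed(6)
  y <- rnorm(200)
  expect_warning(gw <- run_gwas(pan, y), "constant")
  expect_equal(nrow(gw), 3)
  expect_false("s02" %in% gw$snp)
})

test_that("greedy clumping matches the brute-force oracle", {
  # two perfectly correlated significant SNPs 100 kb apart: keep smaller p
  pan <- toy_panel(n = 500, m = 3, seed = 7, dup = TRUE)
  summ <- tibble::tibble(
    snp = pan$snp_meta$snp, chr = 1L, pos = pan$snp_meta$pos,
    ea = "A", oa = "G", eaf = 0.3,
    beta = 1, se = 0.1, p = c(1e-10, 1e-9, 0.5), n = 500L)
  model <- select_and_clump(summ, pan)
  expect_equal(model$snp, "s01")
  # two independent significant SNPs: both kept (r2 well below threshold)
  pan2 <- toy_panel(n = 500, m = 2, seed = 8)
  summ2 <- summ[1:2, ]
  summ2$pos <- pan2$snp_meta$pos
  expect_equal(nrow(select_and_clump(summ2, pan2, r2_threshold = 0.05)), 2)
  # no SNP passing the threshold is an explicit empty-model condition
  expect_error(select_and_clump(summ[3, ], pan),
               class = "splitmr_empty_model_error")
  # randomized panels against the independent oracle
  set.seed(9)
  for (rep_ in 1:20) {
    m <- sample(5:15, 1)
    pan_r <- toy_panel(n = 300, m = m, seed = 100 + rep_,
                       spacing = sample(c(3e6, 8e6), 1))
    summ_r <- tibble::tibble(
      snp = pan_r$snp_meta$snp, chr = 1L, pos = pan_r$snp_meta$pos,
      ea = "A", oa = "G", eaf = 0.3, beta = 1, se = 0.1,
      p = 10^-runif(m, 5, 12), n = 300L)
    thr <- 10^-sample(6:8, 1)
    got <- tryCatch(
      select_and_clump(summ_r, pan_r, p_threshold = thr,
                       r2_threshold = 0.01, window_kb = 10000)$snp,
      splitmr_empty_model_error = function(e) character(0))
    want <- clump_oracle(summ_r, pan_r, thr, 0.01, 10000)
    expect_identical(got, want)
  }
  # row order of the summary does not matter
  perm <- sample(nrow(summ))
  expect_identical(select_and_clump(summ[perm, ], pan)$snp, model$snp)
})

test_that("proxy search returns the best in-window correlate", {
  pan <- toy_panel(n = 400, m = 5, seed = 10, dup = TRUE)
  # s02 duplicates s01 (r2 = 1): proxy of s01 is s02, itself excluded
  expect_equal(find_proxy("s01", pan), "s02")
  # independent SNPs have no proxy at r2 >= 0.8
  expect_true(is.na(find_proxy("s03", pan)))
  # exhaustive-search oracle on a panel with graded correlations
  set.seed(11)
  base <- rbinom(600, 2, 0.4)
  mix <- function(w) ifelse(runif(600) < w, base,
                            rbinom(600, 2, 0.4))
  dos <- cbind(s1 = base, s2 = mix(0.9), s3 = mix(0.97), s4 = rbinom(600, 2, 0.4))
  pan2 <- structure(list(
    dosages = dos,
    snp_meta = tibble::tibble(snp = colnames(dos), chr = 1L,
                              pos = as.integer(1:4 * 1e5), ea = "A", oa = "G",
                              maf = 0.4)), class = "genotype_panel")
  r2s <- vapply(c("s2", "s3", "s4"),
                function(s) cor(dos[, "s1"], dos[, s])^2, 1)
  eligible <- r2s[r2s >= 0.5]
  expect_equal(find_proxy("s1", pan2, min_r2 = 0.5),
               names(eligible)[which.max(eligible)])
})

test_that("PRS scoring standardizes, aligns alleles and guards degeneracy", {
  pan <- toy_panel(n = 500, m = 4, seed = 12)
  model <- tibble::tibble(snp = "s01", ea = "A", weight = 1)
  sc <- score_prs(pan, model)
  expect_equal(mean(sc), 0, tolerance = 1e-10)
  expect_equal(sd(sc), 1, tolerance = 1e-10)
  expect_equal(sc, as.numeric(scale(pan$dosages[, 1])), tolerance = 1e-12)
  # allele-flipped model with negated weight scores identically
  model_fl <- tibble::tibble(snp = "s01", ea = "G", weight = -1)
  expect_equal(score_prs(pan, model_fl), sc, tolerance = 1e-12)
  expect_error(score_prs(pan, tibble::tibble(snp = "s01", ea = "A", weight = 0)),
               class = "splitmr_degenerate_error")
  expect_error(score_prs(pan, tibble::tibble(snp = "nope", ea = "A", weight = 1)),
               "nope", class = "splitmr_missing_snp_error")
  # a missing SNP with a perfect proxy scores through the proxy
  pan_dup <- toy_panel(n = 500, m = 4, seed = 12, dup = TRUE)
  pan_missing <- panel_drop <- structure(
    list(dosages = pan_dup$dosages[, -1], snp_meta = pan_dup$snp_meta[-1, ]),
    class = "genotype_panel")
  model1 <- tibble::tibble(snp = "s01", ea = "A", weight = 1)
  sc_proxy <- score_prs(pan_missing, model1, use_proxies = TRUE,
                        proxy_panel = pan_dup)
  expect_equal(sc_proxy, as.numeric(scale(pan_dup$dosages[, 2])),
               tolerance = 1e-12)
})

test_that("instrument diagnostics satisfy the F-R2 identity", {
  set.seed(13)
  prs <- rnorm(1000)
  x <- 0.3 * prs + rnorm(1000)
  d <- instrument_diagnostics(prs, x, n_snps = 7)
  expect_equal(d$f_stat, d$r2 * (d$n - 2) / (1 - d$r2), tolerance = 1e-8)
  expect_equal(d$n_snps, 7L)
  expect_equal(instrument_diagnostics(prs, prs)$r2, 1)
  # independent exposure: R2 near zero
  expect_lt(instrument_diagnostics(prs, rnorm(1000))$r2, 0.01)
  expect_error(instrument_diagnostics(1:2, 1:2))
})

test_that("GWAS summary and PRS model files round-trip", {
  dir <- withr::local_tempdir()
  pan <- toy_panel(n = 300, m = 5, seed = 14)
  set.seed(15)
  gw <- run_gwas(pan, rnorm(300))
  p1 <- file.path(dir, "gwas.tsv")
  write_gwas_summary(gw, p1)
  expect_equal(as.data.frame(read_gwas_summary(p1)), as.data.frame(gw),
               tolerance = 1e-12)
  summ <- dplyr::mutate(gw, p = 1e-10)
  model <- select_and_clump(summ, pan, r2_threshold = 2)  # keep all
  p2 <- file.path(dir, "prs.tsv")
  write_prs_model(model, p2, source_split = 1)
  back <- read_prs_model(p2)
  expect_equal(back$snp, model$snp)
  expect_equal(back$weight, model$weight, tolerance = 1e-12)
  expect_equal(attr(back, "r2_threshold"), 2)
  expect_equal(attr(back, "window_kb"), 10000)
})
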