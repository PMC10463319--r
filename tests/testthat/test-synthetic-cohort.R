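test_that("configuration validation catches bad inputs", {
  expect_error(small_config(n = 0), class = "splitmr_config_error")
  expect_error(sim_config(maf_range = c(0, 0.6)),
               class = "splitmr_config_error")
  expect_error(sim_config(ld_rho = 1), class = "splitmr_config_error")
  # variance budget: variance_explained + confounding^2 > 1
  arch <- small_architecture(ve = 0.9)
  expect_error(sim_config(architecture = arch,
                          confounding = c(education = -0.5, bmi = 0.5,
                                          smoking = 0.5, alcohol = 0.5)),
               "variance budget", class = "splitmr_config_error")
  expect_error(small_config(snps = 30), "blocks",
               class = "splitmr_config_error")
})

test_that("genotype simulation is deterministic and respects MAF targets", {
  cfg <- small_config(n = 2000, seed = 5)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1$dosages, p2$dosages)
  expect_identical(p1$snp_meta, p2$snp_meta)
  expect_true(all(p1$dosages %in% 0:2))
  expect_true(all(p1$snp_meta$maf > 0 & p1$snp_meta$maf <= 0.5))
  # positions strictly increasing within chromosome
  for (ch in unique(p1$snp_meta$chr)) {
    expect_true(all(diff(p1$snp_meta$pos[p1$snp_meta$chr == ch]) > 0))
  }
  # fixed-MAF panel: empirical frequency within binomial error
  cfg3 <- sim_config(n_individuals = 10000, n_snps = 40,
                     architecture = small_architecture(n_causal = 1),
                     maf_range = c(0.3, 0.3), seed = 6)
  p3 <- simulate_genotypes(cfg3)
  freq <- colMeans(p3$dosages) / 2
  tol <- 3 * sqrt(0.3 * 0.7 / 20000)
  expect_true(all(abs(freq - 0.3) < tol + 1e-9))
})

test_that("independent SNPs obey Hardy-Weinberg and near-zero LD", {
  cfg <- sim_config(n_individuals = 10000, n_snps = 40,
                    architecture = small_architecture(n_causal = 1),
                    ld_rho = 0, maf_range = c(0.2, 0.4), seed = 8)
  pan <- simulate_genotypes(cfg)
  # genotype frequencies match (1-p)^2, 2p(1-p), p^2 within 4 SE
  for (j in c(1, 17, 40)) {
    p <- mean(pan$dosages[, j]) / 2
    for (g in 0:2) {
      expected <- c((1 - p)^2, 2 * p * (1 - p), p^2)[g + 1]
      se <- sqrt(expected * (1 - expected) / 10000)
      expect_lt(abs(mean(pan$dosages[, j] == g) - expected), 4 * se + 1e-9)
    }
  }
  # mean pairwise r2 ~ 1/(n-1) under independence
  r2 <- cor(pan$dosages)^2
  mean_r2 <- mean(r2[upper.tri(r2)])
  expect_lt(mean_r2, 5 / 9999)
  # with LD, within-block r2 is substantial
  pan_ld <- small_panel()
  blk1 <- which(pan_ld$snp_meta$block == 1)
  r2b <- cor(pan_ld$dosages[, blk1])^2
  expect_gt(mean(r2b[upper.tri(r2b)]), 0.2)
})

test_that("cohort generation is deterministic and internally consistent", {
  sim <- small_sim()
  sim2 <- simulate_cohort(small_panel(), small_config())
  expect_identical(sim$cohort, sim2$cohort)
  co <- sim$cohort
  expect_true(all(co$age >= 40 & co$age <= 73))
  # never-smokers carry zero smoking quantities
  nev <- co$smoking_status == "never"
  expect_true(all(co$cigarettes_per_day[nev] == 0))
  expect_true(all(co$smoking_duration[nev] == 0))
  # current smokers have zero years since cessation
  cur <- co$smoking_status == "current"
  expect_true(all(co$years_since_cessation[cur] == 0))
  # condition flags are 0/1
  flags <- as.matrix(co[grep("^cond_", names(co))])
  expect_true(all(flags %in% 0:1))
  expect_equal(ncol(flags), 35)
})

test_that("prevalence targets and headline cohort stats are matched", {
  d <- small_derived()
  cfg <- small_config()
  tol <- 4 * sqrt(0.37 * 0.63 / nrow(d))
  expect_lt(abs(mean(d$cond_hearing_loss) - 0.37), tol + 0.01)
  realized <- small_sim()$truth$prevalence_realized
  expect_equal(unname(realized["cond_hearing_loss"]), mean(d$cond_hearing_loss))
  # education mapped through the qualification table
  expect_true(all(d$education_years %in% education_mapping()$years))
  # multimorbidity prevalence lands near the middle-aged cohort profile
  expect_gt(mean(d$mm2), 0.45)
  expect_lt(mean(d$mm2), 0.65)
})

test_that("structural coefficients are recovered by regression on the
           simulation's own draws when confounding is off", {
  cfg <- sim_config(
    n_individuals = 8000, n_snps = 320,
    architecture = small_architecture(),
    edu_bmi = -0.2, edu_smoking = 0, edu_alcohol = 0,
    confounding = c(education = 0, bmi = 0, smoking = 0, alcohol = 0),
    seed = 31)
  pan <- simulate_genotypes(cfg)
  sim <- simulate_cohort(pan, cfg)
  d <- derive_exposures(sim$cohort)
  fit <- summary(lm(bmi ~ education_years, d))$coefficients
  expect_lt(abs(fit[2, 1] - (-0.2)) / fit[2, 2], 3)
})

test_that("all-null structural coefficients give a null cohort", {
  cfg <- sim_config(
    n_individuals = 4000, n_snps = 320,
    architecture = small_architecture(),
    edu_bmi = 0, edu_smoking = 0, edu_alcohol = 0,
    target_rd = c(education = 0, bmi = 0, smoking = 0, alcohol = 0),
    confounding = c(education = 0, bmi = 0, smoking = 0, alcohol = 0),
    confounder_liability = 0, seed = 32)
  pan <- simulate_genotypes(cfg)
  sim <- simulate_cohort(pan, cfg)
  d <- derive_exposures(sim$cohort)
  expect_true(all(abs(sim$truth$lambda) < 1e-3))
  expect_lt(abs(cor(d$education_years, d$condition_count)), 3 / sqrt(4000))
  expect_lt(abs(cor(d$bmi, d$condition_count)), 3 / sqrt(4000))
})

test_that("truth object satisfies its accounting identities", {
  tr <- small_sim()$truth
  expect_equal(tr$mediation$indirect, tr$mediation$total - tr$mediation$direct,
               tolerance = 1e-12)
  ok <- tr$mediation$total != 0
  expect_equal(tr$mediation$pm[ok],
               100 * tr$mediation$indirect[ok] / tr$mediation$total[ok],
               tolerance = 1e-10)
  # calibrated true RDs hit the configured targets
  cfg <- small_config()
  mm2 <- tr$rd[tr$rd$outcome == "mm2", ]
  for (e in c("education", "bmi", "smoking")) {
    expect_equal(mm2$true_rd[mm2$exposure == e],
                 unname(cfg$target_rd[e]), tolerance = 5e-3)
  }
  exalc <- tr$rd[tr$rd$outcome == "mm2_exalc", ]
  expect_equal(exalc$true_rd[exalc$exposure == "alcohol"],
               unname(cfg$target_rd["alcohol"]), tolerance = 5e-3)
})

test_that("scaled exposures standardize exactly", {
  d <- small_derived()
  z <- (d$education_years - mean(d$education_years)) / sd(d$education_years)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  expect_equal(sd(d$education_std), 1, tolerance = 1e-8)
})

test_that("cohort files round-trip with validation and tolerance of extras", {
  dir <- withr::local_tempdir()
  co <- small_sim()$cohort[1:200, ]
  p <- file.path(dir, "cohort.tsv")
  write_cohort(co, p)
  back <- read_cohort(p)
  expect_equal(as.data.frame(back), as.data.frame(co), tolerance = 1e-12)
  # comma-delimited variant auto-detected
  pc <- file.path(dir, "cohort.csv")
  write_cohort(co, pc)
  expect_equal(as.data.frame(read_cohort(pc))$bmi, as.data.frame(co)$bmi %||% NULL)
  # unknown extra columns survive and downstream stages ignore them
  co_extra <- dplyr::mutate(co, mystery = "x")
  p2 <- file.path(dir, "extra.tsv")
  write_cohort(co_extra, p2)
  back2 <- read_cohort(p2)
  expect_true("mystery" %in% names(back2))
  expect_equal(derive_exposures(back2)$bmi, derive_exposures(co)$bmi)
  # a missing required column is named in the error
  co_bad <- co[, setdiff(names(co), "sex")]
  p3 <- file.path(dir, "bad.tsv")
  readr::write_tsv(co_bad, p3)
  expect_error(read_cohort(p3), "sex", class = "splitmr_format_error")
})

test_that("genotype files and VCF dosages round-trip", {
  dir <- withr::local_tempdir()
  pan <- toy_panel(n = 50, m = 4, seed = 20)
  p <- file.path(dir, "dosages.tsv")
  write_genotypes(pan, p)
  back <- read_genotypes(p)
  expect_identical(unname(back$dosages), unname(pan$dosages))
  expect_equal(back$snp_meta$snp, pan$snp_meta$snp)
  # VCF reader maps GT to ALT dosage on biallelic records
  vcf <- file.path(dir, "toy.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tI1\tI2\tI3",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0"), vcf)
  vp <- read_vcf_dosages(vcf)
  expect_equal(unname(vp$dosages[, "rs1"]), c(0L, 1L, 2L))
  expect_equal(unname(vp$dosages[, "rs2"]), c(1L, 2L, 0L))
  expect_equal(vp$snp_meta$ea, c("G", "T"))
})

test_that("truth reports round-trip as key=value tables", {
  dir <- withr::local_tempdir()
  tr <- small_sim()$truth
  p <- file.path(dir, "truth.txt")
  truth_report(tr, p)
  kv <- read_truth_report(p)
  expect_equal(unname(kv["rd.mm2.education"]),
               tr$rd$true_rd[tr$rd$exposure == "education" &
                               tr$rd$outcome == "mm2"], tolerance = 1e-8)
  expect_equal(unname(kv["mediation.bmi.pm"]),
               tr$mediation$pm[tr$mediation$mediators == "bmi"],
               tolerance = 1e-8)
  # report totals honour indirect = total - direct and the PM formula
  expect_equal(unname(kv["mediation.bmi.indirect"]),
               unname(kv["mediation.bmi.total"] - kv["mediation.bmi.direct"]),
               tolerance = 1e-8)
  expect_equal(unname(kv["mediation.bmi.pm"]),
               unname(100 * kv["mediation.bmi.indirect"] /
                        kv["mediation.bmi.total"]), tolerance = 1e-6)
})
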