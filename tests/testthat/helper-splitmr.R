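# shared fixtures: everything is generated in code at test time

small_architecture <- function(n_causal = 8, ve = 0.15) {
  one <- list(n_causal_snps = n_causal, variance_explained = ve)
  list(education = one, bmi = one, smoking = one, alcohol = one)
}

small_config <- function(n = 3000, snps = 320, seed = 42, ...) {
  sim_config(n_individuals = n, n_snps = snps,
             architecture = small_architecture(), seed = seed, ...)
}

# cache expensive fixtures across test files (one R session per test run)
.splitmr_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, .splitmr_cache)) {
    assign(key, force(expr), .splitmr_cache)
  }
  get(key, .splitmr_cache)
}

small_panel <- function() {
  cached("small_panel", simulate_genotypes(small_config()))
}

small_sim <- function() {
  cached("small_sim", simulate_cohort(small_panel(), small_config()))
}

small_derived <- function() {
  cached("small_derived",
         add_scaled_exposures(derive_exposures(small_sim()$cohort)))
}

# a tiny hand-rolled dosage panel with known LD structure (independent SNPs
# unless `dup` duplicates column 1)
toy_panel <- function(n = 400, m = 6, seed = 1, maf = 0.3, dup = FALSE,
                      spacing = 100e3) {
  set.seed(seed)
  dos <- matrix(rbinom(n * m, 2, maf), n, m)
  if (dup) dos[, 2] <- dos[, 1]
  colnames(dos) <- sprintf("s%02d", seq_len(m))
  f <- colMeans(dos) / 2
  meta <- tibble::tibble(
    snp = colnames(dos), chr = 1L,
    pos = as.integer(seq_len(m) * spacing),
    ea = "A", oa = "G", maf = pmin(f, 1 - f))
  structure(list(dosages = dos, snp_meta = meta), class = "genotype_panel")
}

# independent oracle for greedy clumping: full r2 matrix, plain loops
clump_oracle <- function(summary, panel, p_threshold, r2_threshold,
                         window_kb) {
  cand <- summary[summary$p <= p_threshold, ]
  cand <- cand[order(cand$p, cand$snp), ]
  r2 <- cor(panel$dosages[, cand$snp, drop = FALSE])^2
  kept <- character(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      ki <- match(k, cand$snp)
      if (cand$chr[ki] == cand$chr[i] &&
          abs(cand$pos[ki] - cand$pos[i]) <= window_kb * 1000 &&
          r2[cand$snp[i], k] >= r2_threshold) {
        ok <- FALSE
      }
    }
    if (ok) kept <- c(kept, cand$snp[i])
  }
  kept
}

# simulated ratio sets for the summary-statistic estimators
make_ratio_fixture <- function(k = 30, effect = 0.2, intercept = 0,
                               se_gy = 0.005, seed = 1) {
  set.seed(seed)
  beta_gx <- runif(k, 0.05, 0.2)
  beta_gy <- effect * beta_gx + intercept + rnorm(k, 0, se_gy)
  tibble::tibble(
    snp = sprintf("v%02d", seq_len(k)),
    ea = "A", oa = "G",
    beta_gx = beta_gx, se_gx = 0.01,
    beta_gy = beta_gy, se_gy = se_gy,
    ratio = beta_gy / beta_gx, ratio_se = se_gy / beta_gx)
}
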