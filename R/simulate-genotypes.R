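#' Simulate an LD-blocked genotype panel
#'
#' Draws two haplotypes per individual from block-exchangeable latent
#' Gaussians thresholded at the minor-allele-frequency quantile, so that SNPs
#' within a block are in linkage disequilibrium (haplotype correlation
#' `ld_rho`) while SNPs in different blocks are independent. Blocks are
#' spread round-robin across chromosomes with a fixed inter-SNP spacing, so
#' clumping-window logic operates on realistic positions.
#'
#' @param config A [sim_config()] object.
#' @return A `genotype_panel`: list with `dosages` (integer matrix,
#'   individuals x SNPs, entries 0/1/2, SNP ids as column names) and
#'   `snp_meta` (tibble: `snp`, `chr`, `pos`, `ea`, `oa`, `maf`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_snps
  bs <- config$ld_block_size
  rho <- config$ld_rho
  n_blocks <- ceiling(m / bs)

  meta <- genotype_meta_skeleton(config)
  maf <- with_seed(substream_seed(config$seed, "maf"),
                   runif(m, config$maf_range[1], config$maf_range[2]))
  thr <- qnorm(maf)

  dos <- matrix(0L, n, m, dimnames = list(NULL, meta$snp))
  with_seed(substream_seed(config$seed, "genotypes"), {
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1) * bs + 1):min(b * bs, m)
      k <- length(idx)
      for (hap in 1:2) {
        shared <- rnorm(n)
        z <- sqrt(rho) * matrix(shared, n, k) +
          sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
        alleles <- sweep(z, 2, thr[idx], "<")
        dos[, idx] <- dos[, idx] + alleles
      }
    }
  })
  storage.mode(dos) <- "integer"

  f <- colMeans(dos) / 2
  meta$maf <- pmin(f, 1 - f)
  structure(list(dosages = dos, snp_meta = meta), class = "genotype_panel")
}

genotype_meta_skeleton <- function(config) {
  m <- config$n_snps
  bs <- config$ld_block_size
  n_blocks <- ceiling(m / bs)
  block <- rep(seq_len(n_blocks), each = bs)[seq_len(m)]
  chr <- ((block - 1) %% config$n_chromosomes) + 1L
  # strictly increasing positions within chromosome, fixed spacing
  pos <- integer(m)
  for (c_ in unique(chr)) {
    on_c <- which(chr == c_)
    pos[on_c] <- 1L + (seq_along(on_c) - 1L) * as.integer(config$snp_spacing_kb * 1000)
  }
  tibble::tibble(
    snp = sprintf("rs%05d", seq_len(m)),
    chr = as.integer(chr),
    pos = pos,
    ea = "A",
    oa = "G",
    maf = NA_real_,
    block = block
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d SNPs, %d chromosome(s)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$snp_meta$chr))))
  invisible(x)
}
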