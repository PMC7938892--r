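#' Configuration for the synthetic SNP study generator
#'
#' Bundles every knob of the genotype/phenotype simulator into one validated
#' list. Defaults mirror the structure of a terminal-sire pig line feed-test
#' dataset: 5,708 animals, 9,523 analysis-ready SNPs with moderate block LD,
#' 46 farm-by-batch contemporary groups (each at least 10 animals), and an
#' RFI-like trait with heritability 0.3 riding on realistic component traits
#' (ADG around 900 g/day, backfat around 12 mm, test weights 31 to 130 kg).
#'
#' @param n_samples number of animals.
#' @param n_snps number of SNPs.
#' @param maf_range minor-allele-frequency range, each in (0, 0.5]; per-SNP
#'   MAFs are drawn uniformly from it.
#' @param ld_block_size SNPs per linkage-disequilibrium block (non-overlapping).
#' @param ld_rho within-block latent AR(1) correlation, in \[0, 1).
#' @param n_qtl number of causal SNPs.
#' @param h2 narrow-sense heritability of the simulated RFI signal, in \[0, 1\].
#' @param n_epistatic_pairs number of causal pairwise product (epistatic)
#'   terms; 0 disables epistasis.
#' @param n_farmbatch number of FarmBatch levels (>= 2); every level is
#'   guaranteed at least 10 records, so `n_samples >= 10 * n_farmbatch`.
#' @param sigma_batch standard deviation (g/day) of FarmBatch effects.
#' @param age_slope,length_slope fixed regression slopes (g/day per day) of
#'   the trait on age at test start and days on test.
#' @param sigma_rfi total (genetic + environmental) standard deviation of the
#'   RFI signal, g/day.
#' @param missing_rate fraction of genotype calls set missing, in \[0, 1).
#' @param seed integer seed; the whole simulation is deterministic given it.
#'
#' @return An object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_samples = 5708, n_snps = 9523,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 10, ld_rho = 0.3,
                       n_qtl = 100, h2 = 0.3,
                       n_epistatic_pairs = 0,
                       n_farmbatch = 46,
                       sigma_batch = 50,
                       age_slope = 2, length_slope = 1.5,
                       sigma_rfi = 150,
                       missing_rate = 0, seed = 1L) {
  stopifnot(n_samples >= 1, n_snps >= 1)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be an increasing pair within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1)
    stop("ld_rho must lie in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (n_farmbatch < 2) stop("n_farmbatch must be >= 2")
  if (n_samples < 10 * n_farmbatch)
    stop("each FarmBatch level needs >= 10 records: need n_samples >= 10 * n_farmbatch")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)")
  structure(list(
    n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
    maf_range = maf_range, ld_block_size = as.integer(ld_block_size),
    ld_rho = ld_rho, n_qtl = as.integer(n_qtl), h2 = h2,
    n_epistatic_pairs = as.integer(n_epistatic_pairs),
    n_farmbatch = as.integer(n_farmbatch), sigma_batch = sigma_batch,
    age_slope = age_slope, length_slope = length_slope,
    sigma_rfi = sigma_rfi, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate additive-coded SNP genotypes with block LD
#'
#' Generates an `n_samples x n_snps` matrix of genotype codes 0/1/2 (plus
#' `NA` at `missing_rate`). Each SNP's minor allele frequency is drawn from
#' `maf_range`. Linkage disequilibrium is induced by a latent
#' multivariate-Gaussian haplotype model: within each non-overlapping block
#' of `ld_block_size` SNPs, two latent Gaussian vectors per animal (one per
#' gamete) follow an AR(1) correlation `ld_rho` and are thresholded at the
#' MAF-matched quantile to yield alleles. The stored code counts copies of
#' the major allele, so 0 is the minor-allele homozygote and 2 the major
#' homozygote, and expected MAF equals the drawn frequency. With
#' `ld_rho = 0` genotype counts are Binomial(2, maf) and in Hardy-Weinberg
#' proportions by construction.
#'
#' @param config a [sim_config()].
#' @return numeric matrix with animal row names and SNP column names.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_snps
  maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
  thr <- stats::qnorm(maf)
  rho <- config$ld_rho
  bs <- config$ld_block_size
  geno <- matrix(0L, n, p)
  start <- 1L
  while (start <= p) {
    end <- min(start + bs - 1L, p)
    b <- end - start + 1L
    minor <- matrix(0L, n, b)
    for (gamete in 1:2) {
      z <- matrix(stats::rnorm(n * b), n, b)
      if (rho > 0 && b > 1) {
        for (j in 2:b) z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
      minor <- minor + (z < rep(thr[start:end], each = n))
    }
    geno[, start:end] <- 2L - minor  # count major alleles: 0 = minor homozygote
    start <- end + 1L
  }
  if (config$missing_rate > 0) {
    miss <- stats::runif(n * p) < config$missing_rate
    geno[miss] <- NA
  }
  dimnames(geno) <- list(sprintf("A%05d", seq_len(n)), sprintf("SNP%05d", seq_len(p)))
  storage.mode(geno) <- "double"
  geno
}

#' Simulate component traits and an RFI-like target with known genetic truth
#'
#' Builds per-animal component traits (start/end test weight, ADG, backfat,
#' metabolic weight), systematic effects (FarmBatch, age at start, days on
#' test) and a daily-feed-intake record composed as a linear combination of
#' ADG, BFT and MW plus a residual-feed-intake signal. That signal is the sum
#' of an additive genetic value over `n_qtl` causal SNPs (optionally plus
#' epistatic product terms), environmental noise, FarmBatch effects and
#' age/length slopes. QTL effects are drawn Normal(0,1) and rescaled so the
#' realized genetic variance is exactly `h2 * sigma_rfi^2` on this sample,
#' avoiding heritability drift at small N. Deriving RFI from `DFI` with
#' [derive_rfi()] and [adjust_rfi()] therefore recovers (an OLS projection
#' of) the genetic value plus noise.
#'
#' @param geno complete genotype matrix from [simulate_genotypes()]
#'   (no missing entries; impute first if `missing_rate > 0`).
#' @param config the same [sim_config()].
#' @return list with `phenotypes` (a data frame: animal_id, DFI, ADG, BFT,
#'   Wstart, Wend, MW, Age, Length, FarmBatch) and `truth` (class
#'   `sim_truth`: qtl_ids, qtl_effects, true_genetic_values,
#'   true_variances = c(sigma_u2, sigma_e2)).
#' @export
simulate_phenotypes <- function(geno, config) {
  stopifnot(inherits(config, "sim_config"))
  if (anyNA(geno)) stop("genotypes must be complete; impute missing entries first")
  if (config$n_qtl > ncol(geno)) stop("n_qtl must not exceed the number of SNPs")
  set.seed(config$seed + 1L)
  n <- nrow(geno)
  h2 <- config$h2
  sig2 <- config$sigma_rfi^2

  qtl_idx <- sort(sample.int(ncol(geno), config$n_qtl))
  qtl_ids <- colnames(geno)[qtl_idx]
  a <- stats::rnorm(config$n_qtl)
  Xq <- scale(geno[, qtl_idx, drop = FALSE], center = TRUE, scale = FALSE)
  g <- drop(Xq %*% a)
  if (config$n_epistatic_pairs > 0) {
    Zs <- scale(geno[, qtl_idx, drop = FALSE])
    for (k in seq_len(config$n_epistatic_pairs)) {
      pr <- sample.int(config$n_qtl, 2)
      g <- g + stats::rnorm(1) * Zs[, pr[1]] * Zs[, pr[2]]
    }
  }
  vg <- stats::var(g)
  if (h2 > 0 && vg > 0) {
    sc <- sqrt(h2 * sig2 / vg)
    g <- g * sc
    a <- a * sc
  } else {
    g <- rep(0, n)
    a <- a * 0
  }
  e <- stats::rnorm(n, 0, sqrt((1 - h2) * sig2))
  rfi_true <- g + e

  farmbatch <- factor(sample(rep(seq_len(config$n_farmbatch), length.out = n)))
  levels(farmbatch) <- sprintf("FB%02d", seq_len(config$n_farmbatch))
  batch_eff <- stats::rnorm(config$n_farmbatch, 0, config$sigma_batch)
  age <- round(stats::runif(n, 50, 105))
  len <- round(stats::runif(n, 60, 120))

  wstart <- stats::rnorm(n, 31, 4)
  wend <- wstart + stats::rnorm(n, 99, 8)
  adg <- stats::rnorm(n, 900, 90)
  bft <- stats::rnorm(n, 12, 2)
  mw <- compute_metabolic_weight(wstart, wend)

  dfi <- 1.5 * adg + 30 * bft + 20 * mw +
    batch_eff[as.integer(farmbatch)] +
    config$age_slope * (age - mean(age)) +
    config$length_slope * (len - mean(len)) +
    rfi_true

  phen <- data.frame(
    animal_id = rownames(geno), DFI = dfi, ADG = adg, BFT = bft,
    Wstart = wstart, Wend = wend, MW = mw, Age = age, Length = len,
    FarmBatch = farmbatch, stringsAsFactors = FALSE
  )
  truth <- structure(list(
    qtl_ids = qtl_ids, qtl_effects = a,
    true_genetic_values = stats::setNames(g, rownames(geno)),
    true_variances = c(sigma_u2 = h2 * sig2, sigma_e2 = (1 - h2) * sig2)
  ), class = "sim_truth")
  list(phenotypes = phen, truth = truth)
}

#' Write / read a PLINK .raw-style additive genotype table
#'
#' Whitespace-delimited text with the usual `FID IID PAT MAT SEX PHENOTYPE`
#' preamble columns followed by one additive-coded column per SNP; missing
#' calls are written as `NA`.
#'
#' @param geno genotype matrix with animal row names and SNP column names.
#' @param path file path.
#' @return `write_plink_raw` returns `path` invisibly; `read_plink_raw`
#'   returns the genotype matrix.
#' @export
write_plink_raw <- function(geno, path) {
  df <- data.frame(FID = rownames(geno), IID = rownames(geno),
                   PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L,
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(geno, check.names = FALSE))
  utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = " ")
  invisible(path)
}

#' @rdname write_plink_raw
#' @export
read_plink_raw <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  geno <- as.matrix(df[, -(1:6), drop = FALSE])
  rownames(geno) <- df$IID
  storage.mode(geno) <- "double"
  geno
}

#' Write the simulation truth as JSON
#' @param truth a `sim_truth` object.
#' @param path file path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
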