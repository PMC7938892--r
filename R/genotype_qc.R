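#' Per-SNP call rate and minor allele frequency
#'
#' Helpers on an additive-coded genotype matrix (0 = minor-allele homozygote,
#' 1 = heterozygote, 2 = major-allele homozygote, `NA` = missing call).
#'
#' @param geno genotype matrix, animals in rows, SNPs in columns.
#' @return numeric vector over SNPs.
#' @export
snp_call_rate <- function(geno) 1 - colMeans(is.na(geno))

#' @rdname snp_call_rate
#' @export
snp_maf <- function(geno) {
  f <- colMeans(geno, na.rm = TRUE) / 2   # frequency of the counted allele
  pmin(f, 1 - f)
}

#' Remove SNPs and samples failing call-rate / MAF thresholds
#'
#' SNPs with call rate below `snp_cr` or minor allele frequency below
#' `maf_min` are removed first, then samples with call rate below
#' `sample_cr`; MAF metadata is implicitly recomputed on the result by
#' [snp_maf()].
#'
#' @param geno genotype matrix.
#' @param snp_cr,sample_cr minimum call rates (defaults 0.90).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return filtered genotype matrix.
#' @export
filter_call_rate_maf <- function(geno, snp_cr = 0.90, maf_min = 0.05,
                                 sample_cr = 0.90) {
  keep_snp <- snp_call_rate(geno) >= snp_cr & snp_maf(geno) >= maf_min
  geno <- geno[, keep_snp, drop = FALSE]
  if (ncol(geno) == 0) stop("no SNPs pass the call-rate/MAF thresholds")
  keep_sample <- 1 - rowMeans(is.na(geno)) >= sample_cr
  geno <- geno[keep_sample, , drop = FALSE]
  if (nrow(geno) == 0) stop("no samples pass the call-rate threshold")
  geno
}

#' Mean-impute missing genotype calls
#'
#' Missing entries are replaced by the rounded per-SNP mean genotype; SNPs
#' with no observed calls at all are dropped with a warning.
#'
#' @param geno genotype matrix.
#' @return complete genotype matrix.
#' @export
impute_missing <- function(geno) {
  all_na <- colSums(!is.na(geno)) == 0
  if (any(all_na)) {
    warning(sprintf("dropping %d SNP(s) with all calls missing", sum(all_na)))
    geno <- geno[, !all_na, drop = FALSE]
  }
  if (!anyNA(geno)) return(geno)
  mu <- round(colMeans(geno, na.rm = TRUE))
  idx <- which(is.na(geno), arr.ind = TRUE)
  geno[idx] <- mu[idx[, 2]]
  geno
}

#' Remove zero- and near-zero-variance SNPs
#'
#' Drops constant SNPs, and SNPs for which the ratio of the most common to
#' the second most common genotype frequency exceeds `freq_ratio_cut`
#' (default 95/5 = 19) while the percentage of distinct values relative to
#' the number of samples is below `unique_cut`. Delegates to
#' `caret::nearZeroVar()`, the utility whose semantics these thresholds
#' follow.
#'
#' @param geno complete genotype matrix.
#' @param freq_ratio_cut frequency-ratio cutoff (default 95/5).
#' @param unique_cut percent-unique cutoff (default 10).
#' @return filtered genotype matrix.
#' @export
remove_near_zero_variance <- function(geno, freq_ratio_cut = 95 / 5,
                                      unique_cut = 10) {
  if (anyNA(geno)) stop("impute missing genotypes first")
  drop <- caret::nearZeroVar(geno, freqCut = freq_ratio_cut,
                             uniqueCut = unique_cut)
  if (length(drop)) geno <- geno[, -drop, drop = FALSE]
  geno
}

#' Prune highly correlated SNPs
#'
#' Greedily removes SNPs until no pairwise Pearson correlation exceeds
#' `cutoff` in absolute value; within an offending pair the SNP with the
#' larger mean absolute correlation to all others is removed (ties resolved
#' deterministically by column order). Delegates to
#' `caret::findCorrelation(exact = TRUE)`.
#'
#' @param geno complete genotype matrix (no constant columns).
#' @param cutoff absolute-correlation cutoff (default 0.8).
#' @return pruned genotype matrix with max pairwise |r| <= cutoff.
#' @export
prune_correlated <- function(geno, cutoff = 0.8) {
  if (anyNA(geno)) stop("impute missing genotypes first")
  if (ncol(geno) < 2) return(geno)
  cm <- stats::cor(geno)
  drop <- caret::findCorrelation(cm, cutoff = cutoff, exact = TRUE)
  if (length(drop)) geno <- geno[, -drop, drop = FALSE]
  geno
}

#' Full genotype quality control pipeline
#'
#' Fixed stage order: SNP call-rate/MAF filter, sample call-rate filter,
#' mean imputation, near-zero-variance removal, correlation pruning.
#' Re-running the pipeline on its own output changes nothing.
#'
#' @param geno genotype matrix.
#' @param snp_cr,maf_min,sample_cr see [filter_call_rate_maf()].
#' @param freq_ratio_cut,unique_cut see [remove_near_zero_variance()].
#' @param cor_cutoff see [prune_correlated()].
#' @return list with `geno` (analysis-ready matrix) and `report`, a data
#'   frame of SNP/sample counts after each stage.
#' @export
qc_genotypes <- function(geno, snp_cr = 0.90, maf_min = 0.05,
                         sample_cr = 0.90, freq_ratio_cut = 95 / 5,
                         unique_cut = 10, cor_cutoff = 0.8) {
  stages <- character(); nsnp <- integer(); nsam <- integer()
  log_stage <- function(stage, g) {
    stages <<- c(stages, stage); nsnp <<- c(nsnp, ncol(g)); nsam <<- c(nsam, nrow(g))
  }
  log_stage("input", geno)
  geno <- filter_call_rate_maf(geno, snp_cr, maf_min, sample_cr)
  log_stage("call_rate_maf", geno)
  geno <- impute_missing(geno)
  log_stage("imputation", geno)
  geno <- remove_near_zero_variance(geno, freq_ratio_cut, unique_cut)
  log_stage("near_zero_variance", geno)
  geno <- prune_correlated(geno, cor_cutoff)
  log_stage("correlation_pruning", geno)
  list(geno = geno,
       report = data.frame(stage = stages, n_snps = nsnp, n_samples = nsam))
}
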