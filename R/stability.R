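#' A system of feature subsets from repeated selection runs
#'
#' Wraps the `n` SNP subsets produced by running one feature-selection
#' configuration on `n` different training folds, together with the size
#' `p` of the feature universe they were drawn from. Subsets may have
#' unequal sizes (as produced by embedded selectors).
#'
#' @param subsets list of character (or integer) vectors of selected
#'   feature IDs.
#' @param p total number of candidate features.
#' @return object of class `subset_system`.
#' @export
subset_system <- function(subsets, p) {
  stopifnot(is.list(subsets), length(subsets) >= 1, p >= 1)
  sizes <- lengths(subsets)
  if (any(sizes > p)) stop("a subset is larger than the feature universe")
  if (any(vapply(subsets, anyDuplicated, integer(1)) > 0))
    stop("subsets must not contain duplicated features")
  structure(list(subsets = subsets, p = as.integer(p), n = length(subsets),
                 sizes = sizes),
            class = "subset_system")
}

# selection frequency per feature that appears in at least one subset;
# features never selected have frequency 0 and contribute no variance
selection_freq <- function(system) {
  tab <- table(unlist(lapply(system$subsets, unique)))
  as.numeric(tab)
}

#' Chance-corrected feature-selection stability (NOG)
#'
#' The frequency-based stability estimator
#' \deqn{\hat\Phi(S) = 1 - \frac{\frac1p \sum_i \sigma^2_{f_i}}
#'   {\frac{\bar d}{p}\left(1 - \frac{\bar d}{p}\right)}}
#' where \eqn{\sigma^2_{f_i} = \frac{n}{n-1}\hat p_{f_i}(1 - \hat p_{f_i})}
#' is the unbiased sample variance of the selection indicator of feature
#' \eqn{f_i}, \eqn{\hat p_{f_i}} its selection frequency across the `n`
#' subsets, and \eqn{\bar d} the mean subset size. The denominator is the
#' expected variance under selection uniformly at random, so the estimator
#' is corrected for chance: it equals 1 only when all subsets are
#' identical, and has expectation 0 under random selection.
#'
#' @param system a [subset_system()] with `n > 1` subsets.
#' @return the stability estimate (a scalar, at most 1).
#' @export
nog_stability <- function(system) {
  stopifnot(inherits(system, "subset_system"))
  if (system$n < 2) stop("stability needs n > 1 subsets")
  n <- system$n; p <- system$p
  dbar <- mean(system$sizes)
  if (dbar == 0 || dbar == p)
    stop("undefined: mean subset size is 0 or the whole universe")
  phat <- selection_freq(system) / n
  var_sum <- sum(n / (n - 1) * phat * (1 - phat))
  1 - (var_sum / p) / ((dbar / p) * (1 - dbar / p))
}

#' Asymptotic confidence interval for the population stability
#'
#' Normal-approximation interval \eqn{\hat\Phi \pm z_{1-\alpha/2}\,\hat\sigma}
#' with the variance estimated from the per-subset influence terms
#' \deqn{\phi_j = \frac{1}{v_{rand}}\Big[\frac1p \sum_i z_{ji}\hat p_{f_i}
#'  - \frac{d_j \bar d}{p^2} - \frac{\hat\Phi}{2}\Big(\frac{2 d_j \bar d}{p^2}
#'  - \frac{d_j}{p} - \frac{\bar d}{p} + 1\Big)\Big]}
#' where \eqn{z_{ji}} indicates selection of feature i in subset j and
#' \eqn{v_{rand} = \frac{\bar d}{p}(1 - \frac{\bar d}{p})};
#' \eqn{\hat\sigma^2 = \frac{4}{n^2}\sum_j(\phi_j - \bar\phi)^2}. Degenerate
#' fully stable systems yield a zero-width interval.
#'
#' @param system a [subset_system()] with at least 5 subsets for the
#'   approximation to be usable.
#' @param alpha significance level (default 0.05).
#' @return named vector `lower`, `upper`.
#' @export
nog_confidence_interval <- function(system, alpha = 0.05) {
  stopifnot(inherits(system, "subset_system"))
  n <- system$n; p <- system$p
  if (n < 5) warning("normal approximation is poor below n = 5 subsets")
  stab <- nog_stability(system)
  dbar <- mean(system$sizes)
  v_rand <- (dbar / p) * (1 - dbar / p)
  feats <- sort(unique(unlist(system$subsets)))
  phat <- vapply(feats, function(f)
    mean(vapply(system$subsets, function(s) f %in% s, logical(1))), numeric(1))
  phi <- vapply(seq_len(n), function(j) {
    zj <- feats %in% system$subsets[[j]]
    kj <- system$sizes[j]
    (1 / v_rand) * (sum(phat[zj]) / p - kj * dbar / p^2 -
      (stab / 2) * (2 * kj * dbar / p^2 - kj / p - dbar / p + 1))
  }, numeric(1))
  v <- 4 / n^2 * sum((phi - mean(phi))^2)
  z <- stats::qnorm(1 - alpha / 2)
  c(lower = stab - z * sqrt(v), upper = stab + z * sqrt(v))
}

#' Descriptive statistics of a subset system
#'
#' `nsnps` is the total number of selections over the n subsets, `pdf` the
#' proportion of distinct features among them (1/n when all subsets are
#' identical, 1 when pairwise disjoint), and `median_sel` / `iqr_sel` the
#' median and interquartile range of the subset sizes.
#'
#' @param system a [subset_system()].
#' @return named vector `nsnps`, `pdf`, `median_sel`, `iqr_sel`.
#' @export
subset_descriptives <- function(system) {
  stopifnot(inherits(system, "subset_system"))
  nsnps <- sum(system$sizes)
  c(nsnps = nsnps,
    pdf = length(unique(unlist(system$subsets))) / nsnps,
    median_sel = stats::median(system$sizes),
    iqr_sel = unname(stats::quantile(system$sizes, 0.75) -
                       stats::quantile(system$sizes, 0.25)))
}

#' Score stability across training folds
#'
#' Mean Pearson correlation between all pairs of per-fold score vectors,
#' and mean Spearman correlation between the corresponding rank vectors
#' (average ranks on ties). Pairs involving a constant vector are excluded
#' with a warning.
#'
#' @param scores list of n [filter_score()] tables (or named numeric
#'   vectors) covering the same SNP universe.
#' @return named vector `pearson`, `spearman`.
#' @export
score_stability <- function(scores) {
  stopifnot(length(scores) >= 2)
  vecs <- lapply(scores, function(s) {
    if (inherits(s, "filter_score")) stats::setNames(s$score, s$snp_id) else s
  })
  ids <- names(vecs[[1]])
  stopifnot(!is.null(ids))
  vecs <- lapply(vecs, function(v) {
    if (!setequal(names(v), ids)) stop("score vectors cover different SNPs")
    v[ids]
  })
  const <- vapply(vecs, function(v) stats::var(v) == 0, logical(1))
  pc <- c(); sc <- c()
  n_excl <- 0L
  for (i in seq_along(vecs)[-length(vecs)]) {
    for (j in (i + 1):length(vecs)) {
      if (const[i] || const[j]) { n_excl <- n_excl + 1L; next }
      pc <- c(pc, stats::cor(vecs[[i]], vecs[[j]]))
      sc <- c(sc, stats::cor(vecs[[i]], vecs[[j]], method = "spearman"))
    }
  }
  if (n_excl > 0)
    warning(sprintf("%d pair(s) excluded due to constant score vectors", n_excl))
  c(pearson = mean(pc), spearman = mean(sc))
}

#' Expected proportion of distinct features under random selection
#'
#' Closed form for the expected PDF of `n` independent uniform subsets of
#' size `d` from `p` features:
#' `p * (1 - ((p - d)/p)^n) / (n * d)`.
#'
#' @param p universe size.
#' @param d subset size (0 < d <= p).
#' @param n number of subsets.
#' @return expected PDF.
#' @export
expected_random_pdf <- function(p, d, n) {
  stopifnot(d > 0, d <= p, n >= 1)
  p * (1 - ((p - d) / p)^n) / (n * d)
}

#' Draw a random subset system (the chance-level benchmark)
#'
#' `n` independent uniform subsets of size `d` without replacement from a
#' universe of `p` integer feature IDs.
#'
#' @param p universe size.
#' @param d subset size.
#' @param n number of subsets.
#' @param seed integer seed.
#' @return a [subset_system()].
#' @export
random_subset_system <- function(p, d, n, seed = 1L) {
  set.seed(seed)
  subset_system(lapply(seq_len(n), function(i) sample.int(p, d)), p)
}

#' Stability report for one feature-selection configuration
#'
#' Bundles the chance-corrected stability with its confidence interval and
#' the subset descriptives into one row, mirroring the columns of a
#' stability results table (NSNPs, PDF, medianSel, IQRSel, NOG with CI).
#'
#' @param system a [subset_system()].
#' @param alpha significance level for the interval.
#' @return one-row data frame.
#' @export
stability_report <- function(system, alpha = 0.05) {
  d <- subset_descriptives(system)
  ci <- nog_confidence_interval(system, alpha)
  data.frame(nsnps = d[["nsnps"]], pdf = d[["pdf"]],
             median_sel = d[["median_sel"]], iqr_sel = d[["iqr_sel"]],
             nog = nog_stability(system),
             nog_lo = ci[["lower"]], nog_hi = ci[["upper"]])
}
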