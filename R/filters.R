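#' Construct a per-SNP filter score table
#'
#' A `filter_score` is a data frame with columns `snp_id`, `score` (higher =
#' more relevant) and `rank` (1 = best, average ranks on ties), carrying the
#' filter name as an attribute. All filter methods return this type so their
#' outputs are interchangeable for top-k selection and score-stability
#' estimation.
#'
#' @param filter_name name of the producing filter.
#' @param snp_ids character vector of SNP identifiers.
#' @param scores numeric relevance scores, one per SNP.
#' @return a `filter_score` data frame.
#' @export
filter_score <- function(filter_name, snp_ids, scores) {
  stopifnot(length(snp_ids) == length(scores))
  out <- data.frame(snp_id = snp_ids, score = scores,
                    rank = rank(-scores, ties.method = "average"),
                    stringsAsFactors = FALSE)
  attr(out, "filter_name") <- filter_name
  class(out) <- c("filter_score", "data.frame")
  out
}

#' Spearman rank-correlation filter
#'
#' Scores each SNP by the absolute Spearman rank correlation between its
#' genotypes and the target; sign-blind so relevance does not depend on
#' allele coding, and invariant to monotone transformations of either
#' variable. Constant SNPs score 0 with a warning.
#'
#' @param X genotype matrix of the training fold (animals x SNPs).
#' @param y numeric target (adjusted RFI).
#' @return a [filter_score()].
#' @export
score_spearcor <- function(X, y) {
  stopifnot(nrow(X) == length(y))
  rho <- suppressWarnings(abs(stats::cor(X, y, method = "spearman")))[, 1]
  if (anyNA(rho)) {
    warning(sprintf("%d constant SNP(s) scored 0", sum(is.na(rho))))
    rho[is.na(rho)] <- 0
  }
  filter_score("spearcor", colnames(X), unname(rho))
}

#' Univariate decision-tree filter
#'
#' Fits a small regression tree on each SNP individually and scores it by
#' minus the repeated cross-validated mean squared error of that
#' single-feature tree, so SNPs whose genotype classes separate the target
#' well rank first. Fold assignment is a seeded shuffle, making scores a
#' pure function of (data, seed).
#'
#' @param X genotype matrix of the training fold.
#' @param y numeric target.
#' @param folds,repeats resampling scheme (default 5-fold, 2 repeats).
#' @param max_depth maximum tree depth (default 3).
#' @param seed integer seed for fold assignment.
#' @return a [filter_score()].
#' @export
score_univ_dtree <- function(X, y, folds = 5, repeats = 2, max_depth = 3,
                             seed = 1L) {
  n <- nrow(X)
  stopifnot(n >= 2 * folds, n == length(y))
  set.seed(seed)
  fold_sets <- lapply(seq_len(repeats), function(r)
    sample(rep(seq_len(folds), length.out = n)))
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, xval = 0,
                               minsplit = 10, minbucket = 5)
  mse <- vapply(seq_len(ncol(X)), function(j) {
    d <- data.frame(y = y, x = X[, j])
    errs <- unlist(lapply(fold_sets, function(fid) {
      vapply(seq_len(folds), function(f) {
        tr <- fid != f
        fit <- rpart::rpart(y ~ x, data = d[tr, ], control = ctrl)
        mean((d$y[!tr] - stats::predict(fit, d[!tr, , drop = FALSE]))^2)
      }, numeric(1))
    }))
    mean(errs)
  }, numeric(1))
  filter_score("univ.dtree", colnames(X), -mse)
}

# Gaussian mutual information from a Pearson correlation
mi_gaussian <- function(r) {
  r2 <- pmin(r^2, 1)
  ifelse(r2 >= 1, Inf, -0.5 * log(1 - r2))
}

#' Plug-in discretized mutual information estimator
#'
#' Histogram estimator of the mutual information between two variables,
#' discretizing each into (at most) `bins` quantile classes and computing
#' the plug-in MI of the contingency table (natural log). Used as the
#' independent cross-check for the Gaussian MI approximation inside the
#' mRMR filter, and available as an alternative estimator there.
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of quantile bins (default 4).
#' @return mutual information estimate in nats.
#' @export
mi_plugin <- function(x, y, bins = 4) {
  cutq <- function(v) {
    if (length(unique(v)) <= bins) return(factor(v))
    br <- unique(stats::quantile(v, probs = seq(0, 1, length.out = bins + 1)))
    cut(v, breaks = br, include.lowest = TRUE)
  }
  tab <- table(cutq(x), cutq(y))
  pj <- tab / sum(tab)
  px <- rowSums(pj); py <- colSums(pj)
  idx <- pj > 0
  sum(pj[idx] * log(pj[idx] / outer(px, py)[idx]))
}

#' Maximum-relevance minimum-redundancy (mRMR) filter
#'
#' Greedy forward selection on a mutual-information score: step 1 picks the
#' SNP with the highest MI with the target; each later step picks the
#' candidate maximizing (relevance MI with the target) minus (mean MI with
#' the already-selected set). By default MI is estimated under a Gaussian
#' approximation, `-0.5 * log(1 - r^2)` with `r` the Pearson correlation;
#' a discretized plug-in estimator is available via `mi`. A candidate
#' perfectly correlated with a selected SNP has infinite redundancy and is
#' never chosen while alternatives remain.
#'
#' @param X genotype matrix of the training fold.
#' @param y numeric target.
#' @param k number of SNPs to select (`k = ncol(X)` ranks all).
#' @param mi MI estimator: `"gaussian"` (default) or `"plugin"`.
#' @param bins quantile bins for the plug-in estimator.
#' @return list with `score` (a [filter_score()]: selected SNPs scored by
#'   reverse selection order, unselected 0) and `selected` (SNP IDs in
#'   selection order).
#' @export
score_mrmr <- function(X, y, k, mi = c("gaussian", "plugin"), bins = 4) {
  mi <- match.arg(mi)
  p <- ncol(X)
  stopifnot(k >= 1, k <= p, nrow(X) == length(y))
  pair_mi <- function(a, b) {
    if (mi == "gaussian") mi_gaussian(suppressWarnings(stats::cor(a, b)))
    else mi_plugin(a, b, bins)
  }
  if (mi == "gaussian") {
    rel <- mi_gaussian(suppressWarnings(stats::cor(X, y))[, 1])
  } else {
    rel <- vapply(seq_len(p), function(j) mi_plugin(X[, j], y, bins), numeric(1))
  }
  rel[is.na(rel)] <- 0
  selected <- integer(0)
  red_sum <- numeric(p)
  for (step in seq_len(k)) {
    if (step == 1) {
      sc <- rel
    } else {
      sc <- rel - red_sum / length(selected)
    }
    cand <- setdiff(seq_len(p), selected)
    # deterministic tie-break by column index; a candidate with infinite
    # redundancy (score -Inf) is only ever picked when no alternative remains
    pick <- cand[which.max(sc[cand])]
    selected <- c(selected, pick)
    if (step < k) {
      if (mi == "gaussian") {
        newr <- mi_gaussian(suppressWarnings(stats::cor(X, X[, pick]))[, 1])
        newr[is.na(newr)] <- 0
      } else {
        newr <- vapply(seq_len(p), function(j)
          mi_plugin(X[, j], X[, pick], bins), numeric(1))
      }
      red_sum <- red_sum + newr
    }
  }
  scores <- numeric(p)
  scores[selected] <- rev(seq_along(selected))
  list(score = filter_score("mrmr", colnames(X), scores),
       selected = colnames(X)[selected])
}

#' Conditional permutation importance from a random forest
#'
#' Fits a regression random forest (via \pkg{ranger}) and scores each SNP by
#' the mean increase in out-of-bag squared error across trees when its
#' values are permuted. To isolate a SNP's own contribution in the presence
#' of correlated markers, the permutation is conditional: it is carried out
#' within strata defined by the observed values of the predictors most
#' correlated with it (absolute Pearson correlation above `cond_threshold`,
#' capped at the `max_cond` strongest; genotype predictors take at most
#' three values, so strata are their value combinations). A SNP the forest
#' never splits on scores exactly 0. Deterministic given `seed`.
#'
#' @param X complete genotype matrix of the training fold.
#' @param y numeric target.
#' @param n_trees number of trees (default 100; fewer than 10 warns).
#' @param mtry variables tried per split (default `floor(p / 3)`).
#' @param cond_threshold correlation threshold for conditioning (default 0.2).
#' @param max_cond maximum number of conditioning predictors per SNP.
#' @param n_perm permutation replicates averaged per SNP.
#' @param seed integer seed.
#' @return a [filter_score()].
#' @export
score_cforest_cpi <- function(X, y, n_trees = 100, mtry = NULL,
                              cond_threshold = 0.2, max_cond = 2,
                              n_perm = 3, seed = 1L) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y))
  if (n_trees < 10) warning("fewer than 10 trees gives unstable importances")
  if (is.null(mtry)) mtry <- max(1L, floor(p / 3))
  df <- data.frame(y = y, X, check.names = FALSE)
  rf <- ranger::ranger(
    dependent.variable.name = "y", data = df, num.trees = n_trees,
    mtry = mtry, keep.inbag = TRUE, seed = seed, num.threads = 1
  )
  inbag <- do.call(cbind, rf$inbag.counts)           # n x trees
  oob <- inbag == 0
  pred0 <- stats::predict(rf, df, predict.all = TRUE,
                          num.threads = 1)$predictions  # n x trees
  err0 <- vapply(seq_len(n_trees), function(t) {
    o <- oob[, t]
    if (!any(o)) return(NA_real_)
    mean((y[o] - pred0[o, t])^2)
  }, numeric(1))
  cm <- suppressWarnings(stats::cor(X))
  cm[is.na(cm)] <- 0
  set.seed(seed + 1L)
  perm_within <- function(v, strata) {
    out <- v
    for (s in split(seq_along(v), strata)) out[s] <- v[sample(s, length(s))]
    out
  }
  scores <- vapply(seq_len(p), function(j) {
    r <- abs(cm[, j]); r[j] <- 0
    cond <- which(r > cond_threshold)
    if (length(cond) > max_cond) cond <- order(r, decreasing = TRUE)[seq_len(max_cond)]
    strata <- if (length(cond) == 0) rep(1L, n) else
      interaction(as.data.frame(X[, cond, drop = FALSE]), drop = TRUE)
    incs <- vapply(seq_len(n_perm), function(rep) {
      dperm <- df
      dperm[[colnames(X)[j]]] <- perm_within(X[, j], strata)
      predp <- stats::predict(rf, dperm, predict.all = TRUE,
                              num.threads = 1)$predictions
      errp <- vapply(seq_len(n_trees), function(t) {
        o <- oob[, t]
        if (!any(o)) return(NA_real_)
        mean((y[o] - predp[o, t])^2)
      }, numeric(1))
      mean(errp - err0, na.rm = TRUE)
    }, numeric(1))
    mean(incs)
  }, numeric(1))
  filter_score("cforest", colnames(X), scores)
}

#' Random benchmark selection of SNPs
#'
#' Uniform sample of `k` SNP IDs without replacement; the chance-level
#' baseline against which filter stability and accuracy are judged.
#'
#' @param snp_ids character vector of available SNP IDs.
#' @param k subset size.
#' @param seed integer seed.
#' @return character vector of `k` SNP IDs.
#' @export
select_random <- function(snp_ids, k, seed = 1L) {
  stopifnot(k >= 0, k <= length(snp_ids))
  set.seed(seed)
  if (k == 0) return(character(0))
  sample(snp_ids, k)
}

#' Select the k best-scoring SNPs
#'
#' Ties are broken by SNP position in the score table, so selection is
#' deterministic.
#'
#' @param score a [filter_score()].
#' @param k subset size (`k <=` number of scored SNPs).
#' @return character vector of `k` SNP IDs.
#' @export
select_top_k <- function(score, k) {
  stopifnot(inherits(score, "filter_score"), k >= 0, k <= nrow(score))
  if (k == 0) return(character(0))
  ord <- order(-score$score, seq_len(nrow(score)))
  score$snp_id[ord[seq_len(k)]]
}
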