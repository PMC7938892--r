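#' Nested cross-validation splits
#'
#' Seeded random partition of the animals into `outer` near-equal folds
#' (sizes differ by at most 1), plus, for each outer fold, a partition of
#' its training animals into `inner` folds used for hyper-parameter tuning.
#' One `cv_split` object is shared by every (filter, size, learner)
#' configuration of an experiment so all methods see identical data splits.
#'
#' @param animal_ids character vector of animal IDs.
#' @param outer,inner number of outer and inner folds (defaults 10 and 6).
#' @param seed integer seed.
#' @return object of class `cv_split`: `ids`, `outer` (named fold index per
#'   animal), `inner` (list per outer fold: named fold index per training
#'   animal), `outer_k`, `inner_k`, `seed`.
#' @export
make_nested_splits <- function(animal_ids, outer = 10, inner = 6, seed = 1L) {
  n <- length(animal_ids)
  stopifnot(n >= outer * inner)
  set.seed(seed)
  outer_assign <- stats::setNames(
    sample(rep(seq_len(outer), length.out = n)), animal_ids)
  inner_assign <- lapply(seq_len(outer), function(f) {
    tr <- animal_ids[outer_assign != f]
    stats::setNames(sample(rep(seq_len(inner), length.out = length(tr))), tr)
  })
  structure(list(ids = animal_ids, outer = outer_assign,
                 inner = inner_assign, outer_k = outer, inner_k = inner,
                 seed = as.integer(seed)),
            class = "cv_split")
}

#' Experiment configuration for the nested-CV benchmark
#'
#' @param filters filter methods to run: any of `"spearcor"`,
#'   `"univ.dtree"`, `"mrmr"`, `"cforest"`, `"random"`, `"none"` (no
#'   pre-selection; only learners that cope with all SNPs accept it).
#' @param sizes SNP subset sizes (the study grid is 50, 250, 500, 750,
#'   1000, 1500); ignored for `filter = "none"`.
#' @param learners any of `"enet"`, `"lasso"`, `"ridge"`, `"svm"`, `"gb"`,
#'   `"gblup"`, `"mean"` (constant benchmark predictor).
#' @param outer,inner fold counts (defaults 10 and 6).
#' @param seed integer master seed; per-fold seeds are derived from it.
#' @param keep_models store fitted model objects (for leakage audits).
#' @param filter_args,learner_args named lists of extra arguments passed to
#'   the filter scorers / learner fitters (e.g. `list(svm =
#'   list(feature_cap = 2000))`).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(filters = "spearcor", sizes = 50,
                              learners = "ridge", outer = 10, inner = 6,
                              seed = 1L, keep_models = FALSE,
                              filter_args = list(), learner_args = list()) {
  filters <- match.arg(filters, c("spearcor", "univ.dtree", "mrmr",
                                  "cforest", "random", "none"),
                       several.ok = TRUE)
  learners <- match.arg(learners, c("enet", "lasso", "ridge", "svm", "gb",
                                    "gblup", "mean"), several.ok = TRUE)
  structure(list(filters = filters, sizes = sizes, learners = learners,
                 outer = outer, inner = inner, seed = as.integer(seed),
                 keep_models = keep_models, filter_args = filter_args,
                 learner_args = learner_args),
            class = "experiment_config")
}

# fit one learner on an outer-training fold; sees training data only
fit_learner <- function(learner, X_tr, y_tr, foldid, seed, args) {
  a <- if (!is.null(args[[learner]])) args[[learner]] else list()
  switch(learner,
    enet  = do.call(fit_penalized_regression,
                    c(list(X = X_tr, y = y_tr, foldid = foldid, seed = seed), a)),
    lasso = do.call(fit_penalized_regression,
                    c(list(X = X_tr, y = y_tr, alpha = 1, foldid = foldid,
                           seed = seed), a)),
    ridge = do.call(fit_penalized_regression,
                    c(list(X = X_tr, y = y_tr, alpha = 0, foldid = foldid,
                           seed = seed), a)),
    svm   = do.call(fit_svm_rbf,
                    c(list(X = X_tr, y = y_tr, foldid = foldid, seed = seed), a)),
    gb    = do.call(fit_gradient_boosting,
                    c(list(X = X_tr, y = y_tr, foldid = foldid, seed = seed), a)),
    mean  = structure(list(mu = mean(y_tr)), class = "mean_fit"),
    stop("unknown learner: ", learner)
  )
}

#' @export
predict.mean_fit <- function(object, newdata, ...) rep(object$mu, nrow(newdata))

# filter scores on one outer-training fold
score_filter <- function(filter, X_tr, y_tr, k_max, seed, args) {
  a <- if (!is.null(args[[filter]])) args[[filter]] else list()
  switch(filter,
    spearcor     = score_spearcor(X_tr, y_tr),
    univ.dtree   = do.call(score_univ_dtree,
                           c(list(X = X_tr, y = y_tr, seed = seed), a)),
    mrmr         = do.call(score_mrmr,
                           c(list(X = X_tr, y = y_tr, k = k_max), a))$score,
    cforest      = do.call(score_cforest_cpi,
                           c(list(X = X_tr, y = y_tr, seed = seed), a)),
    stop("unknown filter: ", filter)
  )
}

#' Run the full nested-CV feature-selection / prediction benchmark
#'
#' For each outer fold: standardize features on the training animals, score
#' each filter on the training fold, select top-k subsets, tune each
#' learner by inner-CV on shared inner folds, refit on the whole outer
#' training set and predict the held-out animals. Records the per-fold
#' Spearman correlation between observed and predicted phenotypes, every
#' selected SNP subset (filter subsets, and nonzero-coefficient sets for
#' the embedded penalized learners), and the per-fold filter scores, which
#' together feed the stability estimators. A failing configuration is
#' marked failed and the rest continue. Everything is deterministic given
#' the configuration seed.
#'
#' @param geno QC'd complete genotype matrix (animals x SNPs).
#' @param y named numeric vector of adjusted phenotypes; names must match
#'   `rownames(geno)`.
#' @param config an [experiment_config()].
#' @param split optional [make_nested_splits()] result to reuse; by default
#'   built from `config`.
#' @return list of class `fs_experiment`:
#'   \item{results}{long data frame (filter, size, learner, fold, sc, status)}
#'   \item{accuracy}{summary data frame with median and IQR of SC per
#'     configuration}
#'   \item{filter_subsets}{`filter_subsets[[filter]][[size]]` = list of n
#'     outer-fold SNP subsets (a [subset_system()] input)}
#'   \item{embedded_subsets}{nonzero-coefficient subsets per
#'     filter_size_learner configuration (enet/lasso only)}
#'   \item{scores}{`scores[[filter]]` = list of per-fold [filter_score()]s}
#'   \item{split}{the shared `cv_split`}
#' @export
run_experiment <- function(geno, y, config, split = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  stopifnot(!is.null(rownames(geno)), !is.null(names(y)))
  y <- y[rownames(geno)]
  if (anyNA(y)) stop("phenotypes missing for some genotyped animals")
  if (is.null(split))
    split <- make_nested_splits(rownames(geno), config$outer, config$inner,
                                config$seed)
  p <- ncol(geno)
  sizes <- pmin(config$sizes, p)
  real_filters <- setdiff(config$filters, c("random", "none"))
  k_max <- if (length(sizes)) max(sizes) else p

  rows <- list(); models <- list()
  scores <- list(); filter_subsets <- list(); embedded_subsets <- list()
  G <- if ("gblup" %in% config$learners) compute_grm(geno) else NULL

  for (f in seq_len(config$outer)) {
    tr_ids <- names(split$outer)[split$outer != f]
    te_ids <- names(split$outer)[split$outer == f]
    foldid <- unname(split$inner[[f]][tr_ids])
    y_tr <- y[tr_ids]; y_te <- y[te_ids]
    std <- standardize_features(geno[tr_ids, , drop = FALSE],
                                geno[te_ids, , drop = FALSE])
    fold_seed <- config$seed * 1000L + f

    fold_scores <- list()
    for (fl in real_filters) {
      fold_scores[[fl]] <- score_filter(fl, std$train, y_tr, k_max,
                                        fold_seed, config$filter_args)
      scores[[fl]][[f]] <- fold_scores[[fl]]
    }

    for (fl in config$filters) {
      for (k in (if (fl == "none") p else sizes)) {
        sel <- switch(fl,
          none   = colnames(geno),
          random = select_random(colnames(geno), k, seed = fold_seed),
          select_top_k(fold_scores[[fl]], k))
        if (fl != "none")
          filter_subsets[[fl]][[as.character(k)]][[f]] <- sel
        for (lr in config$learners) {
          if (fl == "none" && !lr %in% c("enet", "lasso", "ridge", "gblup", "mean"))
            next
          if (lr == "gblup" && !(fl == "none" || k == p))
            next  # GBLUP benchmark uses the full SNP set
          key <- paste(fl, k, lr, sep = "_")
          res <- tryCatch({
            if (lr == "gblup") {
              a <- config$learner_args[["gblup"]]
              fit <- do.call(fit_gblup_gibbs,
                             c(list(y = y_tr, G = G[tr_ids, tr_ids],
                                    seed = fold_seed), a))
              pred <- predict(fit, G[te_ids, tr_ids, drop = FALSE])
            } else {
              fit <- fit_learner(lr, std$train[, sel, drop = FALSE], y_tr,
                                 foldid, fold_seed, config$learner_args)
              pred <- predict(fit, std$test[, sel, drop = FALSE])
            }
            sc <- if (stats::sd(pred) == 0) 0 else suppressWarnings(
              stats::cor(y_te, pred, method = "spearman"))
            if (lr %in% c("enet", "lasso"))
              embedded_subsets[[key]][[f]] <- fit$selected
            if (config$keep_models) models[[key]][[f]] <- fit
            list(sc = sc, status = "ok")
          }, error = function(e) list(sc = NA_real_,
                                      status = conditionMessage(e)))
          rows[[length(rows) + 1L]] <- data.frame(
            filter = fl, size = k, learner = lr, fold = f,
            sc = res$sc, status = res$status, stringsAsFactors = FALSE)
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  acc <- do.call(rbind, lapply(
    split(results, results[c("filter", "size", "learner")], drop = TRUE),
    function(d) {
      s <- tryCatch(summarize_accuracy(d$sc),
                    error = function(e) c(median = NA_real_, iqr = NA_real_))
      data.frame(filter = d$filter[1], size = d$size[1],
                 learner = d$learner[1], median_sc = unname(s["median"]),
                 iqr_sc = unname(s["iqr"]), n_folds = sum(!is.na(d$sc)),
                 row.names = NULL, stringsAsFactors = FALSE)
    }))
  structure(list(results = results, accuracy = acc,
                 filter_subsets = filter_subsets,
                 embedded_subsets = embedded_subsets,
                 scores = scores, split = split,
                 models = if (config$keep_models) models else NULL,
                 config = config),
            class = "fs_experiment")
}

#' Median and interquartile range of per-fold accuracies
#'
#' Quantiles use R's default type-7 (linear interpolation) convention.
#' Missing folds (failed configurations) are dropped and counted.
#'
#' @param per_fold_sc numeric vector of per-fold Spearman correlations.
#' @return named vector: `median`, `iqr`, `n_missing`.
#' @export
summarize_accuracy <- function(per_fold_sc) {
  ok <- per_fold_sc[!is.na(per_fold_sc)]
  if (length(ok) < 2) stop("need at least two folds with results")
  c(median = stats::median(ok),
    iqr = unname(stats::quantile(ok, 0.75) - stats::quantile(ok, 0.25)),
    n_missing = sum(is.na(per_fold_sc)))
}
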