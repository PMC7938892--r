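#' Standardize features with training-fold statistics
#'
#' Centers and scales each column of the training matrix to mean 0 and
#' standard deviation 1 (denominator N - 1), and applies the *training*
#' means and SDs to the test matrix, so no test information enters the
#' transformation.
#'
#' @param X_train training genotype matrix.
#' @param X_test optional test matrix with the same columns.
#' @return list with `train`, `test` (or `NULL`), `means`, `sds`.
#' @export
standardize_features <- function(X_train, X_test = NULL) {
  mu <- colMeans(X_train)
  sd <- apply(X_train, 2, stats::sd)
  if (any(sd == 0)) stop("constant training column(s); run QC first")
  tr <- sweep(sweep(X_train, 2, mu), 2, sd, "/")
  te <- if (!is.null(X_test)) sweep(sweep(X_test, 2, mu), 2, sd, "/") else NULL
  list(train = tr, test = te, means = mu, sds = sd)
}

#' Penalized linear regression (ridge / LASSO / elastic net)
#'
#' Solves the elastic-net objective
#' `argmin_b ||y - Xb||^2 + lambda * (alpha * sum|b| + (1 - alpha)/2 * sum b^2)`
#' (glmnet mixing convention: `alpha = 0` is ridge regression, `alpha = 1`
#' the LASSO) via \pkg{glmnet}'s coordinate descent. When `alpha` is a vector and `lambda = "auto"`, the
#' pair minimizing inner-cross-validation MSE is chosen, with ties broken
#' toward stronger regularization (larger lambda). Nonzero-coefficient SNPs
#' are reported as the embedded feature selection; variable importance is
#' `|beta|` on standardized predictors.
#'
#' Note on scale: glmnet minimizes `(1/2N)||y - b0 - Xb||^2` plus
#' `lambda * ((1-a)/2 ||b||^2 + a * sum|b|)` after internally standardizing
#' `y`, so the ridge solution at a given `lambda` equals the closed form
#' `(X'X + lambda' I)^{-1} X'y` on centered data with
#' `lambda' = N * lambda / sd_N(y)`, where `sd_N` uses the 1/N denominator.
#'
#' @param X standardized predictor matrix.
#' @param y numeric target.
#' @param alpha mixing value(s) in \[0, 1\]; default grid 0, 0.1, ..., 1
#'   (0 = ridge, 1 = LASSO).
#' @param lambda `"auto"` (inner-CV path per alpha) or a fixed value.
#' @param foldid optional inner-CV fold assignment (integer per row); if
#'   `NULL`, a seeded `nfolds`-fold split is drawn.
#' @param nfolds inner folds when `foldid` is `NULL` (default 6).
#' @param seed seed for the internal fold split.
#' @return object of class `penreg_fit` with elements `intercept`, `beta`
#'   (named vector), `alpha`, `lambda`, `selected` (nonzero-coefficient SNP
#'   IDs), `importance`.
#' @export
fit_penalized_regression <- function(X, y, alpha = seq(0, 1, by = 0.1),
                                     lambda = "auto", foldid = NULL,
                                     nfolds = 6, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (is.numeric(lambda)) {
    stopifnot(length(alpha) == 1)
    fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                          standardize = FALSE, thresh = 1e-14,
                          maxit = 10^7)
    if (fit$jerr != 0) stop(sprintf("glmnet did not converge at lambda=%g, alpha=%g",
                                    lambda, alpha))
    best <- list(alpha = alpha, lambda = lambda, fit = fit)
  } else {
    if (is.null(foldid)) {
      set.seed(seed)
      foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
    }
    best <- NULL
    for (a in alpha) {
      cv <- glmnet::cv.glmnet(X, y, alpha = a, foldid = foldid,
                              standardize = FALSE)
      cvm <- cv$cvm
      # ties toward stronger regularization: glmnet orders lambda decreasing,
      # so the first index attaining the minimum is the largest lambda
      i <- which(cvm <= min(cvm) + 1e-12)[1]
      if (is.null(best) || cvm[i] < best$cvm - 1e-12) {
        best <- list(alpha = a, lambda = cv$lambda[i], cvm = cvm[i],
                     fit = cv$glmnet.fit)
      }
    }
  }
  cf <- as.matrix(stats::coef(best$fit, s = best$lambda, exact = FALSE))
  beta <- stats::setNames(cf[-1, 1], rownames(cf)[-1])
  structure(list(
    intercept = cf[1, 1], beta = beta, alpha = best$alpha,
    lambda = best$lambda, selected = names(beta)[beta != 0],
    importance = abs(beta)
  ), class = "penreg_fit")
}

#' @export
predict.penreg_fit <- function(object, newdata, ...) {
  drop(newdata[, names(object$beta), drop = FALSE] %*% object$beta) +
    object$intercept
}

#' Epsilon-insensitive support vector regression with an RBF kernel
#'
#' Grid search over cost `C` and kernel width `gamma` by inner-CV mean
#' squared error, then refit on the full training fold (via \pkg{e1071}).
#' Defaults are the standard grids `C` in {0.001, 0.1, 1, 5, 10} and
#' `gamma` in {0.005, 0.05, 0.5, 5}; the tube width `epsilon` is fixed at
#' 0.1. Refuses to run above `feature_cap` predictors, where dense kernel
#' methods on SNP data become numerically fragile.
#'
#' @param X standardized predictor matrix.
#' @param y numeric target.
#' @param C_grid,gamma_grid hyper-parameter grids.
#' @param epsilon insensitivity tube width.
#' @param foldid optional inner-CV fold assignment.
#' @param nfolds inner folds when `foldid` is `NULL`.
#' @param feature_cap maximum allowed number of predictors.
#' @param seed seed for the internal fold split.
#' @return object of class `svm_fit` with the tuned `C`, `gamma` and the
#'   fitted model.
#' @export
fit_svm_rbf <- function(X, y, C_grid = c(0.001, 0.1, 1, 5, 10),
                        gamma_grid = c(0.005, 0.05, 0.5, 5),
                        epsilon = 0.1, foldid = NULL, nfolds = 6,
                        feature_cap = 2000, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (ncol(X) > feature_cap)
    stop(sprintf("feature cap exceeded: %d predictors > cap %d; pre-select SNPs first",
                 ncol(X), feature_cap))
  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
  }
  grid <- expand.grid(C = C_grid, gamma = gamma_grid)
  cvm <- vapply(seq_len(nrow(grid)), function(i) {
    errs <- vapply(sort(unique(foldid)), function(f) {
      tr <- foldid != f
      m <- e1071::svm(X[tr, , drop = FALSE], y[tr], type = "eps-regression",
                      kernel = "radial", cost = grid$C[i],
                      gamma = grid$gamma[i], epsilon = epsilon, scale = FALSE)
      mean((y[!tr] - stats::predict(m, X[!tr, , drop = FALSE]))^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  b <- which.min(cvm)
  model <- e1071::svm(X, y, type = "eps-regression", kernel = "radial",
                      cost = grid$C[b], gamma = grid$gamma[b],
                      epsilon = epsilon, scale = FALSE)
  structure(list(C = grid$C[b], gamma = grid$gamma[b], epsilon = epsilon,
                 cv_mse = cvm[b], model = model), class = "svm_fit")
}

#' @export
predict.svm_fit <- function(object, newdata, ...) {
  unname(stats::predict(object$model, newdata))
}

#' Least-squares gradient-boosted regression trees
#'
#' Grid search over tree depth, learning rate and number of trees by
#' inner-CV mean squared error (the validation error curve of a single run
#' at the maximum tree count supplies every candidate tree count), then
#' refit on the full training fold via \pkg{xgboost}. Defaults are the
#' standard grids: depth {10, 12, 15, 17}, learning rate {0.01, 0.02},
#' trees {500, 1000, 3000}. Ties are broken toward the smaller model.
#' Deterministic given `seed` (single-threaded).
#'
#' @param X predictor matrix.
#' @param y numeric target.
#' @param depth_grid,lr_grid,ntrees_grid hyper-parameter grids.
#' @param foldid optional inner-CV fold assignment.
#' @param nfolds inner folds when `foldid` is `NULL`.
#' @param feature_cap maximum allowed number of predictors.
#' @param seed integer seed.
#' @return object of class `gb_fit` with tuned `depth`, `learning_rate`,
#'   `n_trees` and the fitted booster.
#' @export
fit_gradient_boosting <- function(X, y, depth_grid = c(10, 12, 15, 17),
                                  lr_grid = c(0.01, 0.02),
                                  ntrees_grid = c(500, 1000, 3000),
                                  foldid = NULL, nfolds = 6,
                                  feature_cap = 2000, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (ncol(X) > feature_cap)
    stop(sprintf("feature cap exceeded: %d predictors > cap %d; pre-select SNPs first",
                 ncol(X), feature_cap))
  if (is.null(foldid)) {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(X)))
  }
  ntrees_grid <- sort(ntrees_grid)
  nmax <- max(ntrees_grid)
  base <- mean(y)
  folds <- sort(unique(foldid))
  grid <- expand.grid(depth = sort(depth_grid), lr = sort(lr_grid))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    val_curve <- matrix(0, nmax, length(folds))
    for (fi in seq_along(folds)) {
      tr <- foldid != folds[fi]
      dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr])
      dva <- xgboost::xgb.DMatrix(X[!tr, , drop = FALSE], label = y[!tr])
      bst <- xgboost::xgb.train(
        params = list(max_depth = grid$depth[i], eta = grid$lr[i],
                      objective = "reg:squarederror", nthread = 1,
                      lambda = 0, base_score = base, seed = seed),
        data = dtr, nrounds = nmax, evals = list(val = dva), verbose = 0
      )
      val_curve[, fi] <- attributes(bst)$evaluation_log$val_rmse^2
    }
    cvm <- rowMeans(val_curve)[ntrees_grid]
    j <- which(cvm <= min(cvm) + 1e-12)[1]   # tie toward fewer trees
    if (is.null(best) || cvm[j] < best$cvm - 1e-12) {
      best <- list(depth = grid$depth[i], lr = grid$lr[i],
                   n_trees = ntrees_grid[j], cvm = cvm[j])
    }
  }
  model <- xgboost::xgb.train(
    params = list(max_depth = best$depth, eta = best$lr,
                  objective = "reg:squarederror", nthread = 1,
                  lambda = 0, base_score = base, seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = best$n_trees,
    verbose = 0
  )
  structure(list(depth = best$depth, learning_rate = best$lr,
                 n_trees = best$n_trees, cv_mse = best$cvm, model = model),
            class = "gb_fit")
}

#' @export
predict.gb_fit <- function(object, newdata, ...) {
  stats::predict(object$model, newdata)
}

#' Genomic relationship matrix
#'
#' `G = (M - E)(M - E)' / (2 * sum_j q_j (1 - q_j))`, where `M` is the
#' additive-coded genotype matrix, `q_j` the frequency of the counted allele
#' of SNP `j` (computed from the data unless supplied) and `E` the matrix
#' whose column `j` equals `2 q_j`. The diagonal averages about 1 for data
#' in Hardy-Weinberg proportions.
#'
#' @param M complete genotype matrix (animals x SNPs).
#' @param q optional vector of allele frequencies; default `colMeans(M) / 2`.
#' @return symmetric N x N relationship matrix with animal dimnames.
#' @export
compute_grm <- function(M, q = NULL) {
  if (anyNA(M)) stop("genotypes must be complete")
  if (is.null(q)) q <- colMeans(M) / 2
  denom <- 2 * sum(q * (1 - q))
  if (denom <= 0) stop("zero denominator: all allele frequencies are 0 or 1")
  W <- sweep(M, 2, 2 * q)
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

# effective sample size from the autocorrelation function (initial positive
# sequence truncation)
ess <- function(x) {
  n <- length(x)
  v <- stats::var(x)
  if (n < 10 || !is.finite(v) || v == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  n / (1 + 2 * sum(ac))
}

#' Bayesian GBLUP via Gibbs sampling
#'
#' Fits `y = 1 mu + u + e` with `u ~ N(0, G sigma_u^2)` and
#' `e ~ N(0, I sigma_e^2)` by a Gibbs sampler: the breeding-value block is
#' sampled jointly in the eigenbasis of `G` (one eigendecomposition up
#' front makes each iteration O(N)), the intercept from its Gaussian full
#' conditional, and the variances from scaled inverse-chi-squared full
#' conditionals. Flat variance priors are the improper limit `df = -2`,
#' `scale = 0`. Defaults are a desk-scale chain (25,000 iterations, 2,500
#' burn-in, thinning 10); pass `n_iter = 250000, burn_in = 25000` for a
#' long chain. Either variance can be fixed for validation against the
#' known-variance mixed-model-equation BLUP.
#'
#' @param y named numeric vector of phenotypes.
#' @param G genomic relationship matrix for the training animals.
#' @param n_iter,burn_in,thin chain settings.
#' @param d_u,S_u,d_e,S_e scaled inverse-chi-squared prior df and scale for
#'   the genetic and residual variances.
#' @param fix_sigma_u,fix_sigma_e optional fixed variance values.
#' @param seed integer seed.
#' @param jitter ridge added to eigenvalues for numerical positive
#'   definiteness.
#' @param ess_floor warn when the effective sample size of a variance falls
#'   below this.
#' @return object of class `gblup_fit`: posterior means `mu`, `u`,
#'   `sigma_u2`, `sigma_e2`, posterior SDs `u_sd`, variance samples, ESS,
#'   and what `predict` needs for new animals.
#' @export
fit_gblup_gibbs <- function(y, G, n_iter = 25000, burn_in = 2500, thin = 10,
                            d_u = -2, S_u = 0, d_e = -2, S_e = 0,
                            fix_sigma_u = NULL, fix_sigma_e = NULL,
                            seed = 1L, jitter = 1e-8, ess_floor = 100) {
  n <- length(y)
  stopifnot(nrow(G) == n, ncol(G) == n, burn_in < n_iter, thin >= 1)
  set.seed(seed)
  eg <- eigen(G, symmetric = TRUE)
  D <- pmax(eg$values, 0) + jitter
  V <- eg$vectors
  sig_u <- if (is.null(fix_sigma_u)) max(stats::var(y) / 2, 1e-8) else fix_sigma_u
  sig_e <- if (is.null(fix_sigma_e)) max(stats::var(y) / 2, 1e-8) else fix_sigma_e
  mu <- mean(y)
  w <- numeric(n)                     # u in the eigenbasis: u = V w
  n_keep <- length(seq(burn_in + thin, n_iter, by = thin))
  u_sum <- numeric(n); u_sq <- numeric(n); mu_sum <- 0
  su_s <- numeric(n_keep); se_s <- numeric(n_keep)
  ki <- 0L
  yt <- drop(crossprod(V, y))
  one_t <- drop(crossprod(V, rep(1, n)))
  for (it in seq_len(n_iter)) {
    # w | rest: independent Gaussians in the eigenbasis
    prec <- 1 / sig_e + 1 / (D * sig_u)
    m <- ((yt - mu * one_t) / sig_e) / prec
    w <- m + stats::rnorm(n, 0, sqrt(1 / prec))
    u <- drop(V %*% w)
    # mu | rest
    mu <- stats::rnorm(1, mean(y - u), sqrt(sig_e / n))
    # variances | rest (scaled inv-chi-squared full conditionals)
    if (is.null(fix_sigma_u)) {
      ss <- sum(w^2 / D) + d_u * S_u
      sig_u <- max(ss / stats::rchisq(1, n + d_u), 1e-10)
    }
    if (is.null(fix_sigma_e)) {
      e <- y - mu - u
      ss <- sum(e^2) + d_e * S_e
      sig_e <- max(ss / stats::rchisq(1, n + d_e), 1e-10)
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      ki <- ki + 1L
      u_sum <- u_sum + u; u_sq <- u_sq + u^2; mu_sum <- mu_sum + mu
      su_s[ki] <- sig_u; se_s[ki] <- sig_e
    }
  }
  u_hat <- u_sum / n_keep
  u_sd <- sqrt(pmax(u_sq / n_keep - u_hat^2, 0))
  ess_u2 <- ess(su_s); ess_e2 <- ess(se_s)
  if (is.null(fix_sigma_u) && ess_u2 < ess_floor)
    warning(sprintf("effective sample size of sigma_u2 is %.0f (< %d); lengthen the chain",
                    ess_u2, ess_floor))
  names(u_hat) <- names(u_sd) <- rownames(G)
  # G^{-1} u_hat, for conditional-expectation prediction of new animals
  Ginv_u <- drop(V %*% (drop(crossprod(V, u_hat)) / D))
  structure(list(
    mu = mu_sum / n_keep, u = u_hat, u_sd = u_sd,
    sigma_u2 = mean(su_s), sigma_e2 = mean(se_s),
    samples = cbind(sigma_u2 = su_s, sigma_e2 = se_s),
    ess = c(sigma_u2 = ess_u2, sigma_e2 = ess_e2),
    Ginv_u = Ginv_u, train_ids = rownames(G)
  ), class = "gblup_fit")
}

#' Predict genetic values of new animals from a fitted GBLUP
#'
#' Uses the conditional expectation `u_new = G_cross G_train^{-1} u_hat`,
#' where `G_cross` holds the relationships between new and training
#' animals, and adds the posterior mean intercept.
#'
#' @param object a `gblup_fit`.
#' @param G_cross matrix of relationships, new animals in rows, training
#'   animals (in training order) in columns.
#' @param ... unused.
#' @return numeric vector of predicted phenotypes.
#' @export
predict.gblup_fit <- function(object, G_cross, ...) {
  stopifnot(ncol(G_cross) == length(object$u))
  drop(G_cross %*% object$Ginv_u) + object$mu
}
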