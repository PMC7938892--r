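test_that("standardization uses training statistics only", {
  X <- matrix(c(0, 1, 2, 2, 0, 1), 3, 2)
  colnames(X) <- c("a", "b")
  Xt <- matrix(c(2, 2, 0, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  std <- standardize_features(X, Xt)
  expect_equal(colMeans(std$train), c(a = 0, b = 0))
  expect_equal(apply(std$train, 2, sd), c(a = 1, b = 1))
  # column (0,1,2) maps to +/- 1/sd with the N-1 denominator
  expect_equal(std$train[, "a"], (c(0, 1, 2) - 1) / 1)
  # test columns use train means/sds, not their own
  expect_equal(std$test[, "a"], (c(2, 2) - 1) / 1)
  # already-standardized input is unchanged
  std2 <- standardize_features(std$train)
  expect_equal(std2$train, std$train)
  Xc <- cbind(X, cst = 1)
  expect_error(standardize_features(Xc), "constant")
})

test_that("penalized regression limits match closed-form oracles", {
  set.seed(42)
  n <- 60; p <- 10
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("S", 1:p)
  y <- 2 * X[, 1] - X[, 3] + rnorm(n)
  # lambda = 0: OLS by the normal equations
  f0 <- fit_penalized_regression(X, y, alpha = 0, lambda = 0)
  expect_equal(unname(f0$beta), unname(ols_oracle(X, y)[-1]), tolerance = 1e-6)
  # ridge at fixed lambda: (X'X + lambda' I)^{-1} X'y on centered data,
  # lambda' = N * lambda / sd_N(y) from glmnet's internal y-standardization
  lam <- 0.5
  fr <- fit_penalized_regression(X, y, alpha = 0, lambda = lam)
  Xc <- scale(X, scale = FALSE); yc <- y - mean(y)
  sdy <- sqrt(sum(yc^2) / n)
  br <- solve(crossprod(Xc) + n * (lam / sdy) * diag(p), crossprod(Xc, yc))
  expect_equal(unname(fr$beta), unname(drop(br)), tolerance = 1e-6)
  # LASSO at huge lambda shrinks everything to exactly zero
  fl <- fit_penalized_regression(X, y, alpha = 1, lambda = 1e4)
  expect_true(all(fl$beta == 0))
  expect_length(fl$selected, 0)
})

test_that("penalized regression tunes on inner folds and reports selection", {
  set.seed(43)
  n <- 120; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("S", 1:p)
  y <- 1.5 * X[, 2] + rnorm(n)
  foldid <- sample(rep(1:6, 20))
  f <- fit_penalized_regression(X, y, alpha = c(0.5, 1), foldid = foldid)
  expect_true(f$alpha %in% c(0.5, 1))
  expect_true("S2" %in% f$selected)
  expect_equal(f$importance, abs(f$beta))
  pr <- predict(f, X)
  expect_gt(cor(pr, y), 0.7)
  # selection count never exceeds the sample size here (p < N)
  expect_lte(length(f$selected), min(n, p))
  f2 <- fit_penalized_regression(X, y, alpha = c(0.5, 1), foldid = foldid)
  expect_identical(f$beta, f2$beta)
})

test_that("RBF SVM fits a linear signal and respects its contracts", {
  set.seed(44)
  n <- 100
  X <- matrix(rnorm(n * 3), n, 3)
  colnames(X) <- paste0("S", 1:3)
  y <- 2 * X[, 1]
  f <- fit_svm_rbf(X, y, C_grid = 10, gamma_grid = c(0.05, 0.5), seed = 1)
  expect_gt(cor(predict(f, X), y, method = "spearman"), 0.99)
  # duplicate rows get identical predictions
  Xd <- X[c(1, 1, 2), ]
  pd <- predict(f, Xd)
  expect_equal(pd[1], pd[2])
  # feature cap guardrail for high-dimensional input
  Xbig <- matrix(rnorm(20 * 30), 20, 30)
  colnames(Xbig) <- paste0("S", 1:30)
  expect_error(fit_svm_rbf(Xbig, rnorm(20), feature_cap = 25), "feature cap")
})

test_that("gamma -> 0 makes SVM predictions near-constant on noise", {
  set.seed(45)
  X <- matrix(rnorm(80 * 3), 80, 3); colnames(X) <- paste0("S", 1:3)
  y <- rnorm(80)
  f <- fit_svm_rbf(X, y, C_grid = 1, gamma_grid = 1e-6, seed = 1)
  expect_lt(stats::sd(predict(f, X)), 0.1 * stats::sd(y))
})

test_that("gradient boosting recovers a step with one stump and obeys lr = 0", {
  set.seed(46)
  n <- 200
  x <- sample(0:2, n, replace = TRUE)
  X <- cbind(S1 = as.numeric(x), S2 = rnorm(n))
  y <- ifelse(x >= 1, 3, -3)
  f <- fit_gradient_boosting(X, y, depth_grid = 1, lr_grid = 1,
                             ntrees_grid = 1, seed = 1)
  expect_equal(unname(predict(f, X)), y, tolerance = 1e-6)
  f0 <- fit_gradient_boosting(X, y, depth_grid = 2, lr_grid = 0,
                              ntrees_grid = 5, seed = 1)
  expect_equal(unname(predict(f0, X)), rep(mean(y), n), tolerance = 1e-6)
  expect_error(fit_gradient_boosting(matrix(rnorm(40), 4, 10), rnorm(4),
                                     feature_cap = 5), "feature cap")
})

test_that("boosting accuracy is non-decreasing in trees up to the overfit point", {
  pr <- sim_pair(n = 400, p = 30, n_qtl = 2, h2 = 0.8, seed = 47)
  tr <- 1:300; te <- 301:nrow(pr$geno)
  scs <- vapply(c(10, 50, 500), function(nt) {
    f <- fit_gradient_boosting(pr$geno[tr, ], unname(pr$y[tr]),
                               depth_grid = 3, lr_grid = 0.1,
                               ntrees_grid = nt, seed = 2)
    cor(predict(f, pr$geno[te, ]), pr$y[te], method = "spearman")
  }, numeric(1))
  expect_true(scs[2] >= scs[1] - 0.02)
})

test_that("the genomic relationship matrix matches its definition", {
  # 3 animals x 2 SNPs, worked by hand
  M <- matrix(c(0, 1, 2,
                2, 1, 0), nrow = 3,
              dimnames = list(c("a1", "a2", "a3"), c("s1", "s2")))
  q <- colMeans(M) / 2             # (0.5, 0.5)
  W <- sweep(M, 2, 2 * q)          # centered
  G_hand <- W %*% t(W) / (2 * (0.25 + 0.25))
  expect_equal(compute_grm(M), G_hand, tolerance = 1e-12)
  # centering: column means of M - E are zero when q comes from the data
  expect_equal(colSums(W), c(s1 = 0, s2 = 0))
  # identical individuals share identical rows/columns
  M2 <- rbind(a = c(0, 2, 1), b = c(0, 2, 1), c = c(2, 0, 1))
  colnames(M2) <- paste0("s", 1:3)
  G2 <- compute_grm(M2)
  expect_equal(G2["a", "a"], G2["b", "b"])
  expect_equal(G2["a", "b"], G2["a", "a"])
  expect_error(compute_grm(matrix(2, 3, 2)), "denominator")
  # HWE data gives mean diagonal about 1
  g <- toy_geno(500, 200, maf = 0.3, seed = 48)
  expect_equal(mean(diag(compute_grm(g))), 1, tolerance = 0.05)
})

test_that("Gibbs GBLUP with known variances matches the BLUP oracle", {
  set.seed(49)
  n <- 150
  g <- toy_geno(n, 300, maf = 0.3, seed = 50)
  G <- compute_grm(g)
  su <- 0.5; se <- 0.5
  u_true <- drop(t(chol(G + diag(1e-6, n))) %*% rnorm(n)) * sqrt(su)
  y <- stats::setNames(1 + u_true + rnorm(n, 0, sqrt(se)), rownames(g))
  fit <- fit_gblup_gibbs(y, G, n_iter = 12000, burn_in = 2000, thin = 5,
                         fix_sigma_u = su, fix_sigma_e = se, seed = 1)
  V <- G * su + diag(se, n)
  Vi <- solve(V)
  mu <- sum(Vi %*% y) / sum(Vi)
  u_blup <- drop(su * G %*% Vi %*% (y - mu))
  expect_lt(max(abs(fit$u - u_blup) / fit$u_sd), 0.12)
  expect_gt(cor(fit$u, u_blup), 0.999)
})

test_that("G = I reduces GBLUP to independent shrinkage", {
  set.seed(51)
  n <- 100
  y <- stats::setNames(rnorm(n, 2, 1), sprintf("A%03d", 1:n))
  G <- diag(n); dimnames(G) <- list(names(y), names(y))
  su <- 0.6; se <- 0.4
  fit <- fit_gblup_gibbs(y, G, n_iter = 12000, burn_in = 2000, thin = 5,
                         fix_sigma_u = su, fix_sigma_e = se, seed = 2)
  shrink <- su / (su + se) * (y - mean(y))
  expect_lt(max(abs(fit$u - shrink) / fit$u_sd), 0.15)
})

test_that("a constant phenotype yields near-zero breeding values", {
  n <- 60
  y <- stats::setNames(rep(3, n), sprintf("A%03d", 1:n))
  G <- diag(n); dimnames(G) <- list(names(y), names(y))
  fit <- suppressWarnings(
    fit_gblup_gibbs(y, G, n_iter = 4000, burn_in = 500, thin = 5, seed = 3))
  expect_lt(max(abs(fit$u)), 0.05)
  expect_lt(fit$sigma_u2, 0.05)
})

test_that("two Gibbs chains agree on the genetic variance", {
  set.seed(52)
  n <- 120
  g <- toy_geno(n, 200, maf = 0.3, seed = 53)
  G <- compute_grm(g)
  u_true <- drop(t(chol(G + diag(1e-6, n))) %*% rnorm(n))
  y <- stats::setNames(u_true + rnorm(n), rownames(g))
  f1 <- fit_gblup_gibbs(y, G, n_iter = 8000, burn_in = 1000, thin = 5, seed = 10)
  f2 <- fit_gblup_gibbs(y, G, n_iter = 8000, burn_in = 1000, thin = 5, seed = 20)
  mcse <- function(f) stats::sd(f$samples[, "sigma_u2"]) /
    sqrt(f$ess["sigma_u2"])
  expect_lt(abs(f1$sigma_u2 - f2$sigma_u2),
            3 * sqrt(mcse(f1)^2 + mcse(f2)^2))
})
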