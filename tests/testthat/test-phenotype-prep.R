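test_that("metabolic weight is mean test weight to the 3/4 power", {
  expect_equal(compute_metabolic_weight(1, 1), 1)
  expect_equal(compute_metabolic_weight(16, 16), 8)  # 16^0.75 = 2^3
  # median start/end weights of a growing-pig test: 31 and 130 kg
  expect_equal(compute_metabolic_weight(31, 130), 80.5^0.75)
  expect_equal(round(compute_metabolic_weight(31, 130), 2), 26.87)
  # unit scale factor converts kg to g before the exponent
  expect_equal(compute_metabolic_weight(31, 130, scale = 1000),
               80500^0.75)
  expect_error(compute_metabolic_weight(0, 10), "positive")
  expect_error(compute_metabolic_weight(10, -1), "positive")
})

test_that("Mahalanobis outlier flagging matches hand computation", {
  # hand case: with mean (0,0) and identity covariance, a point 4 SD out on
  # one axis has squared distance 16 > 12
  expect_equal(stats::mahalanobis(c(4, 0), c(0, 0), diag(2)), 16)
  # contract: the mask equals (within-group squared distance <= threshold)
  set.seed(1)
  n <- 60
  tab <- data.frame(ADG = rnorm(n), DFI = rnorm(n), BFT = rnorm(n),
                    MW = rnorm(n), FarmBatch = rep(c("g1", "g2"), n / 2))
  tab[1, c("ADG", "DFI", "BFT", "MW")] <- c(8, -8, 8, -8)  # gross outlier
  d2 <- rep(NA_real_, n)
  for (g in c("g1", "g2")) {
    i <- tab$FarmBatch == g
    x <- as.matrix(tab[i, c("ADG", "DFI", "BFT", "MW")])
    d2[i] <- stats::mahalanobis(x, colMeans(x), stats::cov(x))
  }
  keep <- flag_multivariate_outliers(tab)
  expect_identical(keep, unname(d2 <= 12))
  expect_false(keep[1])
})

test_that("a record at its group mean is always retained", {
  set.seed(2)
  tab <- data.frame(ADG = rnorm(30), DFI = rnorm(30), BFT = rnorm(30),
                    MW = rnorm(30), FarmBatch = rep(c("a", "b"), 15))
  for (g in c("a", "b")) {
    i <- which(tab$FarmBatch == g)[1]
    tab[i, c("ADG", "DFI", "BFT", "MW")] <-
      colMeans(tab[tab$FarmBatch == g, c("ADG", "DFI", "BFT", "MW")])
  }
  keep <- flag_multivariate_outliers(tab)
  expect_true(keep[which(tab$FarmBatch == "a")[1]])
})

test_that("degenerate groups raise errors naming the group", {
  tab <- data.frame(ADG = rnorm(20), DFI = rnorm(20), BFT = rnorm(20),
                    MW = rnorm(20), FarmBatch = c(rep("big", 17), rep("tiny", 3)))
  expect_error(flag_multivariate_outliers(tab), "tiny")
  tab2 <- data.frame(ADG = rnorm(20), DFI = rnorm(20), BFT = rnorm(20),
                     MW = 1, FarmBatch = "cst")  # constant MW: singular cov
  expect_error(flag_multivariate_outliers(tab2), "cst")
})

test_that("RFI is the OLS residual of DFI on ADG, BFT, MW", {
  # exact linear combination leaves zero residuals
  set.seed(3)
  tab <- data.frame(ADG = rnorm(30, 900, 90), BFT = rnorm(30, 12, 2),
                    MW = rnorm(30, 27, 2))
  tab$DFI <- 100 + 1.5 * tab$ADG + 30 * tab$BFT + 20 * tab$MW
  expect_lt(max(abs(derive_rfi(tab))), 1e-8)
  # residuals sum to zero (intercept in the model)
  tab$DFI <- tab$DFI + rnorm(30, 0, 50)
  expect_lt(abs(sum(derive_rfi(tab))), 1e-8)
})

test_that("6-record toy RFI matches the normal-equation oracle", {
  tab <- data.frame(ADG = c(800, 850, 900, 950, 1000, 1050),
                    BFT = c(10, 14, 11, 13, 12, 15),
                    MW = c(25, 26, 27, 28, 26, 29),
                    DFI = c(2100, 2320, 2250, 2400, 2380, 2600))
  beta <- ols_oracle(as.matrix(tab[, c("ADG", "BFT", "MW")]), tab$DFI)
  resid_oracle <- tab$DFI - drop(cbind(1, as.matrix(tab[, c("ADG", "BFT", "MW")])) %*% beta)
  expect_equal(unname(derive_rfi(tab)), resid_oracle, tolerance = 1e-10)
  expect_error(derive_rfi(transform(tab, MW = ADG)), "rank")
})

test_that("adjustment reduces to centering when there is nothing to adjust", {
  set.seed(4)
  rfi <- rnorm(25)
  adj <- adjust_rfi(rfi, age = rep(70, 25), length = rep(90, 25),
                    farmbatch = rep("fb1", 25))
  expect_equal(adj, rfi - mean(rfi))
})

test_that("a batch-mean pattern is adjusted away entirely", {
  fb <- rep(c("a", "b"), each = 12)
  rfi <- ifelse(fb == "a", 3, -3)
  adj <- adjust_rfi(rfi, age = rep(70, 24), length = rep(90, 24), farmbatch = fb)
  expect_lt(max(abs(adj)), 1e-10)
})

test_that("2-level toy adjustment matches the OLS-with-dummies oracle", {
  set.seed(5)
  fb <- rep(c("a", "b"), each = 6)
  age <- c(55, 60, 65, 70, 75, 80, 58, 63, 68, 73, 78, 83)
  len <- c(95, 70, 88, 61, 119, 84, 102, 66, 91, 115, 74, 108)
  rfi <- rnorm(12, 0, 100)
  X <- cbind(fb == "b", age, len)
  beta <- ols_oracle(X, rfi)
  resid_oracle <- rfi - drop(cbind(1, X) %*% beta)
  adj <- adjust_rfi(rfi, age, len, fb, min_records = 2)
  expect_equal(unname(adj), resid_oracle, tolerance = 1e-10)
})

test_that("FarmBatch levels below the record floor are dropped with warning", {
  fb <- c(rep("big1", 15), rep("big2", 15), rep("small", 4))
  rfi <- rnorm(34)
  expect_warning(adj <- adjust_rfi(rfi, rnorm(34, 70), rnorm(34, 90), fb),
                 "small")
  expect_true(all(is.na(adj[fb == "small"])))
  expect_false(anyNA(adj[fb != "small"]))
})

test_that("adjusted RFI is orthogonal to the design and adjustment is idempotent", {
  set.seed(6)
  n <- 120
  fb <- factor(rep(sprintf("fb%d", 1:6), each = 20))
  age <- round(runif(n, 50, 105)); len <- round(runif(n, 60, 120))
  rfi <- rnorm(n, 0, 100) + as.integer(fb) * 5 + 0.8 * age
  adj <- adjust_rfi(rfi, age, len, fb)
  X <- scale(stats::model.matrix(~ fb + age + len)[, -1])
  expect_lt(max(abs(crossprod(X, adj))), 1e-8)
  expect_equal(adjust_rfi(adj, age, len, fb), adj, tolerance = 1e-10)
})
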