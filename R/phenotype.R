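#' Metabolic weight from start and end test weights
#'
#' `MW = ((Wstart + Wend) / 2) ^ 0.75`, i.e. mean test weight raised to the
#' 3/4 allometric exponent. Units follow the inputs (kg by default; pass
#' `scale` to convert, e.g. `scale = 1000` for g).
#'
#' @param wstart,wend weights at the beginning and end of the test (> 0),
#'   recycled to a common length.
#' @param scale multiplicative factor applied to the mean weight before
#'   exponentiation (default 1, i.e. keep input units).
#' @return numeric vector of metabolic weights.
#' @export
compute_metabolic_weight <- function(wstart, wend, scale = 1) {
  if (any(wstart <= 0, na.rm = TRUE) || any(wend <= 0, na.rm = TRUE))
    stop("weights must be positive")
  (scale * (wstart + wend) / 2)^0.75
}

#' Flag multivariate outlier records within farm-batch groups
#'
#' Computes the squared Mahalanobis distance of each record from its
#' FarmBatch group centre, using the group's classical mean and covariance of
#' the modeled traits, and flags records with distance above `threshold` for
#' removal (default 12).
#'
#' @param table data frame holding the columns in `vars` and `group`.
#' @param threshold squared-distance cutoff; records above it are dropped.
#' @param vars trait columns entering the distance (default ADG, DFI, BFT, MW).
#' @param group grouping column (default `"FarmBatch"`).
#' @return logical vector, `TRUE` for retained records.
#' @export
flag_multivariate_outliers <- function(table, threshold = 12,
                                       vars = c("ADG", "DFI", "BFT", "MW"),
                                       group = "FarmBatch") {
  stopifnot(all(c(vars, group) %in% names(table)))
  keep <- rep(NA, nrow(table))
  for (g in unique(table[[group]])) {
    idx <- which(table[[group]] == g)
    x <- as.matrix(table[idx, vars, drop = FALSE])
    if (length(idx) <= length(vars))
      stop(sprintf("group '%s' has %d records, need more than %d",
                   g, length(idx), length(vars)))
    S <- stats::cov(x)
    d2 <- tryCatch(stats::mahalanobis(x, colMeans(x), S),
                   error = function(e)
                     stop(sprintf("singular covariance in group '%s'", g),
                          call. = FALSE))
    keep[idx] <- d2 <= threshold
  }
  keep
}

#' Residual feed intake as the residual of DFI on ADG, BFT and MW
#'
#' Fits the ordinary least-squares regression of daily feed intake on average
#' daily gain, backfat thickness and metabolic weight (with intercept) and
#' returns its residuals: animals eating more than their growth, fatness and
#' maintenance requirements predict get positive RFI.
#'
#' @param table data frame with columns DFI, ADG, BFT, MW (outliers already
#'   removed).
#' @return numeric vector of RFI values, named by `animal_id` when present.
#' @export
derive_rfi <- function(table) {
  stopifnot(all(c("DFI", "ADG", "BFT", "MW") %in% names(table)))
  X <- stats::model.matrix(~ ADG + BFT + MW, table)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design in RFI regression")
  fit <- stats::lm(DFI ~ ADG + BFT + MW, data = table)
  r <- stats::residuals(fit)
  if (!is.null(table$animal_id)) names(r) <- table$animal_id
  r
}

#' Pre-adjust RFI for macro-environmental effects
#'
#' Fits `rfi ~ FarmBatch + Age + Length` (fixed effects, with intercept) and
#' returns the residuals, the adjusted records used downstream as the
#' prediction target. FarmBatch levels with fewer than `min_records` records
#' are dropped with a warning; their records are excluded (returned as `NA`).
#'
#' @param rfi numeric RFI vector.
#' @param age,length numeric covariates: age at test start and days on test.
#' @param farmbatch factor of farm-by-batch levels.
#' @param min_records minimum records per retained FarmBatch level.
#' @return numeric vector of adjusted RFI, `NA` for excluded records.
#' @export
adjust_rfi <- function(rfi, age, length, farmbatch, min_records = 10) {
  farmbatch <- factor(farmbatch)
  n_by <- table(farmbatch)
  small <- names(n_by)[n_by < min_records]
  keep <- !(farmbatch %in% small) & !is.na(rfi)
  if (length(small))
    warning(sprintf("dropping FarmBatch level(s) with < %d records: %s",
                    min_records, paste(small, collapse = ", ")))
  dat <- data.frame(rfi = rfi[keep], Age = age[keep], Length = length[keep],
                    FarmBatch = droplevels(farmbatch[keep]))
  if (nlevels(dat$FarmBatch) > 1) {
    fit <- stats::lm(rfi ~ FarmBatch + Age + Length, data = dat)
  } else if (stats::var(dat$Age) > 0 || stats::var(dat$Length) > 0) {
    fit <- stats::lm(rfi ~ Age + Length, data = dat)
  } else {
    fit <- stats::lm(rfi ~ 1, data = dat)
  }
  out <- rep(NA_real_, length(rfi))
  out[keep] <- stats::residuals(fit)
  names(out) <- names(rfi)
  out
}

#' Full phenotype pre-processing: outliers, RFI derivation, adjustment
#'
#' Convenience wrapper chaining [flag_multivariate_outliers()],
#' [derive_rfi()] and [adjust_rfi()]. Records flagged as outliers are
#' removed before the RFI regression.
#'
#' @param table phenotype data frame (see [simulate_phenotypes()] for the
#'   expected columns).
#' @param threshold Mahalanobis squared-distance cutoff.
#' @param min_records minimum records per FarmBatch level.
#' @return data frame with `animal_id`, `retained`, `rfi`, `rfi_adj`
#'   (`NA` where the record was excluded at either stage).
#' @export
prepare_phenotypes <- function(table, threshold = 12, min_records = 10) {
  keep <- flag_multivariate_outliers(table, threshold = threshold)
  sub <- table[keep, , drop = FALSE]
  rfi <- derive_rfi(sub)
  adj <- adjust_rfi(rfi, sub$Age, sub$Length, sub$FarmBatch,
                    min_records = min_records)
  out <- data.frame(animal_id = table$animal_id, retained = keep,
                    rfi = NA_real_, rfi_adj = NA_real_,
                    stringsAsFactors = FALSE)
  out$rfi[keep] <- rfi
  out$rfi_adj[keep] <- adj
  out$retained <- keep & !is.na(out$rfi_adj)
  out
}
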