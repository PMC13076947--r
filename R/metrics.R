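#' Stratified k-fold assignment
#'
#' Deals records into `k` folds round-robin within each stratum after a
#' seeded shuffle, so per-fold class proportions track the global ones and
#' fold sizes within a stratum differ by at most one. Strata with fewer than
#' `k` members are merged into the largest remaining stratum, with a warning.
#'
#' @param strata Character/factor vector, one stratum label per record.
#' @param k Number of folds (default 10).
#' @param seed Optional seed for the shuffle.
#' @return An integer vector of fold ids in `1:k`.
#' @export
stratified_kfold <- function(strata, k = 10L, seed = NULL) {
  n <- length(strata)
  if (k < 2L) stop("k must be >= 2")
  if (n < k) stop("fewer records than folds")
  if (!is.null(seed)) set.seed(seed)
  strata <- as.character(strata)
  sizes <- table(strata)
  small <- names(sizes)[sizes < k]
  if (length(small) > 0 && length(sizes) > length(small)) {
    target <- names(sizes)[which.max(ifelse(names(sizes) %in% small, -1, sizes))]
    warning("strata smaller than k merged into '", target, "': ",
            paste(small, collapse = ", "))
    strata[strata %in% small] <- target
  } else if (length(small) == length(sizes)) {
    strata[] <- "all"
  }
  folds <- integer(n)
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Regression metrics
#'
#' Mean squared error, its square root, and the Pearson correlation between
#' observed and predicted scores. When either vector is constant the
#' correlation is undefined and returned as `NA` with a warning rather than
#' silently zero.
#'
#' @param y,y_hat Numeric vectors of equal, non-zero length.
#' @return A named list with `mse`, `rmse`, `pcc`.
#' @export
regression_metrics <- function(y, y_hat) {
  if (length(y) != length(y_hat)) {
    stop(sprintf("length mismatch: %d vs %d", length(y), length(y_hat)))
  }
  if (length(y) == 0L) stop("empty input")
  mse <- mean((y - y_hat)^2)
  pcc <- if (stats::sd(y) == 0 || stats::sd(y_hat) == 0) {
    warning("constant vector: Pearson correlation undefined")
    NA_real_
  } else {
    stats::cor(y, y_hat)
  }
  list(mse = mse, rmse = sqrt(mse), pcc = pcc)
}

#' Student-t confidence interval for the fold-mean MSE
#'
#' `mean +/- t_{(1+level)/2, k-1} * sd / sqrt(k)` over per-fold MSE values —
#' the conventional interval for a cross-validated error estimate.
#'
#' @param per_fold_mse Numeric vector of per-fold MSEs (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(lo, hi)`.
#' @export
mse_confidence_interval <- function(per_fold_mse, level = 0.95) {
  kk <- length(per_fold_mse)
  if (kk < 2L) stop("need at least 2 folds for a confidence interval")
  m <- mean(per_fold_mse)
  half <- stats::qt((1 + level) / 2, df = kk - 1L) * stats::sd(per_fold_mse) / sqrt(kk)
  c(lo = m - half, hi = m + half)
}

#' Binary classification metrics from continuous predictions
#'
#' Ranks continuous predicted synergy scores against binary truth:
#' AUC uses the rank (Mann-Whitney) formulation with midrank tie correction;
#' AUPR integrates the precision-recall curve stepwise over distinct score
#' thresholds. Accuracy, F1 and Cohen's kappa binarize the predictions at
#' `threshold` (the metric's synergy cut, so classification is a deterministic
#' view of the regression output). With a single truth class, AUC and AUPR are
#' undefined and returned as `NA`.
#'
#' @param labels Binary truth: a factor from [binarize_labels()], or a
#'   logical/0-1 vector (`TRUE`/1 = positive).
#' @param scores Continuous predicted scores.
#' @param threshold Score cut above which (inclusive) a prediction is called
#'   positive.
#' @return Named list: `auc`, `aupr`, `acc`, `f1`, `kappa`.
#' @export
classification_metrics <- function(labels, scores, threshold) {
  if (is.factor(labels)) labels <- labels == "positive"
  pos <- as.logical(labels)
  if (length(pos) != length(scores)) stop("length mismatch")
  n1 <- sum(pos)
  n0 <- sum(!pos)

  if (n1 == 0L || n0 == 0L) {
    auc <- NA_real_
    aupr <- NA_real_
  } else {
    r <- rank(scores)  # midranks
    auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    aupr <- average_precision(pos, scores)
  }

  pred_pos <- scores >= threshold
  tp <- sum(pred_pos & pos); fp <- sum(pred_pos & !pos)
  fn <- sum(!pred_pos & pos); tn <- sum(!pred_pos & !pos)
  n <- length(pos)
  acc <- (tp + tn) / n
  f1 <- if (2 * tp + fp + fn == 0) NA_real_ else 2 * tp / (2 * tp + fp + fn)
  p_o <- acc
  p_e <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e)
  list(auc = auc, aupr = aupr, acc = acc, f1 = f1, kappa = kappa)
}

# Step integration of the precision-recall curve over distinct thresholds
# (descending); ties are handled by processing whole score groups.
average_precision <- function(pos, scores) {
  ord <- order(scores, decreasing = TRUE)
  pos <- pos[ord]
  scores <- scores[ord]
  n1 <- sum(pos)
  groups <- cumsum(!duplicated(scores))
  tp_cum <- cumsum(pos)
  pred_cum <- seq_along(pos)
  last_of_group <- !duplicated(groups, fromLast = TRUE)
  tp_k <- tp_cum[last_of_group]
  pred_k <- pred_cum[last_of_group]
  prec <- tp_k / pred_k
  rec <- tp_k / n1
  sum(diff(c(0, rec)) * prec)
}
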