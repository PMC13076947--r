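test_that("stratified folds are balanced, seeded and proportionate", {
  folds <- stratified_kfold(rep("a", 20), k = 10, seed = 1)
  expect_true(all(table(folds) == 2))
  expect_identical(folds, stratified_kfold(rep("a", 20), k = 10, seed = 1))

  set.seed(2)
  strata <- sample(c("ant", "add", "syn"), 600, replace = TRUE,
                   prob = c(0.4, 0.5, 0.1))
  folds <- stratified_kfold(strata, k = 5, seed = 3)
  global <- table(strata) / 5
  for (f in 1:5) {
    per <- table(factor(strata[folds == f], levels = names(global)))
    expect_true(all(abs(per - global) <= 1))
  }
})

test_that("undersized strata are merged with a warning", {
  strata <- c(rep("big", 30), rep("rare", 2))
  expect_warning(folds <- stratified_kfold(strata, k = 5, seed = 4), "merged")
  expect_true(all(table(folds) %in% c(6, 7)))
  expect_error(stratified_kfold(rep("a", 3), k = 5), "fewer records")
})

test_that("regression metrics match closed forms and loop oracles", {
  m <- regression_metrics(1:5, 1:5)
  expect_equal(m$mse, 0)
  expect_equal(m$rmse, 0)
  expect_equal(m$pcc, 1)

  m2 <- regression_metrics(c(0, 1, 2), c(2, 1, 0))
  expect_equal(m2$pcc, -1)
  expect_equal(m2$mse, 8 / 3)

  set.seed(5)
  y <- stats::rnorm(50); p <- stats::rnorm(50)
  m3 <- regression_metrics(y, p)
  mse_o <- 0; for (i in 1:50) mse_o <- mse_o + (y[i] - p[i])^2 / 50
  pcc_o <- sum((y - mean(y)) * (p - mean(p))) /
    sqrt(sum((y - mean(y))^2) * sum((p - mean(p))^2))
  expect_lt(abs(m3$mse - mse_o), 1e-12)
  expect_lt(abs(m3$rmse - sqrt(mse_o)), 1e-12)
  expect_lt(abs(m3$pcc - pcc_o), 1e-12)

  expect_warning(mc <- regression_metrics(rep(1, 4), 1:4), "constant")
  expect_true(is.na(mc$pcc))
  expect_error(regression_metrics(1:3, 1:4), "mismatch")
})

test_that("the fold-MSE confidence interval matches the textbook t formula", {
  expect_equal(mse_confidence_interval(rep(3, 5)), c(lo = 3, hi = 3))
  ci2 <- mse_confidence_interval(c(0, 2))
  expect_equal(unname(mean(ci2)), 1)
  set.seed(6)
  v <- stats::rchisq(10, df = 4)
  ci <- mse_confidence_interval(v)
  half <- stats::qt(0.975, 9) * stats::sd(v) / sqrt(10)
  expect_lt(abs(ci[["lo"]] - (mean(v) - half)), 1e-10)
  expect_lt(abs(ci[["hi"]] - (mean(v) + half)), 1e-10)
  expect_error(mse_confidence_interval(1), "at least 2")
})

test_that("classification metrics match brute-force oracles", {
  set.seed(7)
  for (case in 1:5) {
    n <- 30
    labels <- stats::runif(n) < 0.35
    scores <- stats::rnorm(n) + labels
    if (case == 3) scores <- round(scores)  # force ties
    got <- classification_metrics(labels, scores, threshold = 0.5)

    # all-pairs AUC with tie credit
    pos_s <- scores[labels]; neg_s <- scores[!labels]
    cmp <- outer(pos_s, neg_s, function(a, b) (a > b) + 0.5 * (a == b))
    expect_lt(abs(got$auc - mean(cmp)), 1e-10)

    # exhaustive PR step integration over distinct thresholds
    th <- sort(unique(scores), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (k in seq_along(th)) {
      called <- scores >= th[k]
      prec[k] <- sum(called & labels) / sum(called)
      rec[k] <- sum(called & labels) / sum(labels)
    }
    aupr_o <- sum(diff(c(0, rec)) * prec)
    expect_lt(abs(got$aupr - aupr_o), 1e-10)

    # confusion-matrix arithmetic
    called <- scores >= 0.5
    tp <- sum(called & labels); fp <- sum(called & !labels)
    fn <- sum(!called & labels); tn <- sum(!called & !labels)
    expect_lt(abs(got$acc - (tp + tn) / n), 1e-12)
    expect_lt(abs(got$f1 - 2 * tp / (2 * tp + fp + fn)), 1e-12)
    po <- (tp + tn) / n
    pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
    expect_lt(abs(got$kappa - (po - pe) / (1 - pe)), 1e-10)
  }
})

test_that("AUC behaves at the boundary cases", {
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  perfect <- classification_metrics(labels, c(3, 2, 1, 0), threshold = 1.5)
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$aupr, 1)
  expect_equal(perfect$kappa, 1)

  # chance-level predictions on a large sample: kappa near zero
  set.seed(8)
  lab <- stats::runif(4000) < 0.5
  sc <- stats::rnorm(4000)
  chance <- classification_metrics(lab, sc, threshold = 0)
  expect_lt(abs(chance$kappa), 0.05)

  # monotone transform invariance
  set.seed(9)
  lab2 <- stats::runif(40) < 0.4
  sc2 <- stats::rnorm(40)
  a1 <- classification_metrics(lab2, sc2, threshold = 0)$auc
  a2 <- classification_metrics(lab2, exp(sc2 / 2), threshold = 0)$auc
  expect_equal(a1, a2)

  # single-class truth: ranking metrics undefined, not zero
  one <- classification_metrics(rep(TRUE, 5), 1:5, threshold = 3)
  expect_true(is.na(one$auc) && is.na(one$aupr))
})

test_that("mse_loss agrees with its definition", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 2), c(1, 0)), 2.5)
  set.seed(10)
  y <- stats::rnorm(100); p <- stats::rnorm(100)
  acc <- 0; for (i in 1:100) acc <- acc + (y[i] - p[i])^2
  expect_lt(abs(mse_loss(y, p) - acc / 100), 1e-12)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty")
})
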