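test_that("confusion counts partition the examples at any threshold", {
  cc <- confusion_at_threshold(c(1, -1), c(1L, 0L), 0)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L))

  sc <- c(-0.4, 0.2, 0.9, -0.9)
  lab <- c(0L, 1L, 1L, 0L)
  low <- confusion_at_threshold(sc, lab, min(sc) - 1)
  expect_equal(low$FN, 0L)
  expect_equal(low$TN, 0L)

  withr::with_seed(17, {
    for (i in 1:15) {
      n <- sample(5:60, 1)
      sc <- rnorm(n); lab <- rbinom(n, 1, 0.4); t <- rnorm(1)
      cc <- confusion_at_threshold(sc, lab, t)
      expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, n)
      expect_equal(cc$TP + cc$FN, sum(lab))
    }
  })
  expect_error(confusion_at_threshold(1:3, c(1L, 0L), 0),
               class = "fadpred_parameter_error")
})

test_that("metric formulas reproduce the hand-computable cases", {
  # perfect prediction
  m <- metrics_from_confusion(list(TP = 7L, TN = 7L, FP = 0L, FN = 0L))
  expect_equal(c(m$Sn, m$Sp, m$Acc, m$MCC), c(100, 100, 100, 1))

  # balanced 10k/class confusion from a published operating point
  cc <- list(TP = 7053L, FN = 2947L, TN = 6873L, FP = 3127L)
  m <- metrics_from_confusion(cc)
  expect_equal(round(m$MCC, 2), 0.39)
  expect_equal(round(m$Sn, 2), 70.53)
  expect_equal(round(m$Acc, 2), 69.63)

  # degenerate predictions: MCC = 0 convention with a warning
  expect_warning(m0 <- metrics_from_confusion(list(TP = 5L, FN = 0L, TN = 0L, FP = 5L)),
                 "MCC")
  expect_equal(m0$MCC, 0)
  # empty truth class is an error, not a convention
  expect_error(metrics_from_confusion(list(TP = 0L, FN = 0L, TN = 5L, FP = 5L)),
               class = "fadpred_metric_error")
})

test_that("random balanced predictions give MCC near zero", {
  withr::with_seed(23, {
    n <- 4000
    lab <- rep(c(0L, 1L), n / 2)
    sc <- rnorm(n)
    m <- metrics_from_confusion(confusion_at_threshold(sc, lab, 0))
    expect_lt(abs(m$MCC), 3 / sqrt(n))
  })
})

test_that("count reconstruction inverts the rate formulas", {
  cc <- reconstruct_counts_from_rates(100, 100, 10)
  expect_equal(unclass(cc)[c("TP", "TN", "FP", "FN")],
               list(TP = 10, TN = 10, FP = 0, FN = 0))

  m <- metrics_from_confusion(reconstruct_counts_from_rates(83.36, 82.36, 10000))
  expect_equal(round(m$Acc, 2), 82.86)
  expect_equal(round(m$MCC, 2), 0.66)

  # round trip: rates -> counts -> rates, to 100/n precision
  withr::with_seed(29, {
    for (i in 1:25) {
      sn <- round(runif(1, 1, 99), 2); sp <- round(runif(1, 1, 99), 2)
      n <- sample(c(100, 1000, 10000), 1)
      m <- metrics_from_confusion(reconstruct_counts_from_rates(sn, sp, n))
      expect_lt(abs(m$Sn - sn), 100 / n)
      expect_lt(abs(m$Sp - sp), 100 / n)
    }
  })
  expect_error(reconstruct_counts_from_rates(101, 50, 10),
               class = "fadpred_parameter_error")
})

test_that("threshold sweep is monotone over the grid", {
  withr::with_seed(31, {
    for (i in 1:10) {
      n <- 200
      lab <- rep(c(0L, 1L), n / 2)
      sc <- runif(n, -1, 1) + 0.3 * lab
      sw <- threshold_sweep(sc, lab)
      expect_equal(nrow(sw), 21L)
      expect_true(all(diff(sw$Sn) <= 1e-12))
      expect_true(all(diff(sw$Sp) >= -1e-12))
    }
  })
})

test_that("sweep endpoints hit the all-positive limit on balanced data", {
  withr::with_seed(37, {
    lab <- rep(c(0L, 1L), 50)
    sc <- runif(100, -0.8, 1)          # all scores above the low endpoint
    sw <- threshold_sweep(sc, lab)
    expect_equal(sw$Sn[1], 100)
    expect_equal(sw$Acc[1], 50)
    expect_equal(sw$MCC[1], 0)
  })
  # perfectly separated scores reach a perfect grid point
  lab <- rep(c(0L, 1L), each = 20)
  sc <- c(runif(20, -0.9, -0.5), runif(20, 0.5, 0.9))
  sw <- threshold_sweep(sc, lab)
  expect_true(any(sw$Sn == 100 & sw$Sp == 100 & sw$Acc == 100))
  expect_error(threshold_sweep(numeric(0), integer(0)),
               class = "fadpred_parameter_error")
  expect_error(threshold_sweep(1, 1L, grid = numeric(0)),
               class = "fadpred_parameter_error")
})

test_that("balanced-threshold selection minimizes |Sn - Sp| with stated tie-breaks", {
  rows <- data.frame(threshold = c(-0.1, 0, 0.1),
                     Sn = c(80, 70, 60), Sp = c(70, 68, 55),
                     Acc = c(75, 69, 57.5), MCC = c(0.5, 0.4, 0.2))
  expect_equal(select_balanced_threshold(rows)$threshold, 0)

  ties <- data.frame(threshold = c(-0.2, 0.3), Sn = c(70, 60), Sp = c(68, 62),
                     Acc = c(69, 61), MCC = c(0.2, 0.45))
  expect_equal(select_balanced_threshold(ties)$threshold, 0.3)   # higher MCC
  ties$MCC <- c(0.3, 0.3)
  expect_equal(select_balanced_threshold(ties)$threshold, -0.2)  # lower threshold
})

test_that("published PSSM-17 sweep selects the highlighted threshold-0 row", {
  tab <- published_performance("pssm", 17)
  sel <- select_balanced_threshold(tab)
  expect_equal(sel$threshold, 0)
  expect_equal(sel$Sn, 83.36)
  expect_equal(sel$Sp, 82.36)
  expect_true(tab$balanced[tab$threshold == 0])
})

test_that("rank AUC matches hand cases and the pROC oracle", {
  # perfectly separated
  expect_equal(roc_auc(c(3, 2, -1, -2), c(1, 1, 0, 0))$auc, 1)
  # ties counted half
  expect_equal(roc_auc(c(1, 1), c(1, 0))$auc, 0.5)

  skip_if_not_installed("pROC")
  withr::with_seed(41, {
    for (i in 1:8) {
      n <- 150
      lab <- rbinom(n, 1, 0.5)
      sc <- rnorm(n) + 0.8 * lab
      ours <- roc_auc(sc, lab)$auc
      oracle <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                               direction = "<")))
      expect_equal(ours, oracle, tolerance = 1e-12)
    }
  })
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(43, {
    lab <- rbinom(300, 1, 0.5)
    sc <- rnorm(300) + lab
    base <- roc_auc(sc, lab)$auc
    for (f in list(function(x) 3 * x - 2, function(x) x^3,
                   function(x) exp(x), function(x) atan(x)))
      expect_equal(roc_auc(f(sc), lab)$auc, base)
  })
})

test_that("label-independent scores give AUC near one half", {
  withr::with_seed(47, {
    lab <- rbinom(5000, 1, 0.5)
    sc <- rnorm(5000)
    expect_lt(abs(roc_auc(sc, lab)$auc - 0.5), 0.03)
  })
  expect_error(roc_auc(rnorm(5), rep(1L, 5)), class = "fadpred_data_error")
})

test_that("ROC curve is monotone from the full score sweep", {
  withr::with_seed(53, {
    lab <- rbinom(80, 1, 0.5)
    sc <- rnorm(80) + lab
    curve <- roc_auc(sc, lab)$curve
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    expect_equal(unlist(curve[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(curve[nrow(curve), ]), c(fpr = 1, tpr = 1))
  })
})

test_that("cross-validation scores each pattern exactly once and averages folds", {
  bench <- small_bench(seed = 8, shift = 5)
  ds <- make_pattern_dataset(bench$chains, 15, seed = 8, quiet = TRUE)
  folds <- assign_folds(ds, 5, seed = 8)
  cv <- crossvalidate(ds, binary_encoder(15), fadpred_preset(15, "binary"),
                      folds)
  expect_false(anyNA(cv$scores$score))
  expect_equal(nrow(cv$scores), nrow(ds$patterns))
  expect_equal(nrow(cv$sweep), 21L)
  expect_length(cv$fold_auc, 5L)
  expect_equal(cv$auc_mean, mean(cv$fold_auc))
  # averaged sweep row = mean of per-fold metric rows at that threshold
  per_fold <- vapply(1:5, function(k) {
    s <- cv$scores[cv$scores$fold == k, ]
    threshold_sweep(s$score, s$label)$Sn[11]
  }, numeric(1))
  expect_equal(cv$sweep$Sn[11], mean(per_fold))
  expect_error(crossvalidate(ds, binary_encoder(15),
                             fadpred_preset(15, "binary"), folds[-1]),
               class = "fadpred_parameter_error")
})

test_that("cross-validation report has the conventional table layout", {
  bench <- small_bench(seed = 9, shift = 5)
  ds <- make_pattern_dataset(bench$chains, 15, seed = 9, quiet = TRUE)
  cv <- crossvalidate(ds, binary_encoder(15), fadpred_preset(15, "binary"),
                      assign_folds(ds, 5, seed = 9))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cv_report(cv, f)
  lines <- readLines(f)
  expect_equal(strsplit(lines[1], "\t")[[1]],
               c("Thes", "Sen", "Spe", "Acc", "MCC", "balanced"))
  expect_equal(length(lines), 23L)                # header + 21 rows + AUC
  expect_equal(sum(grepl("\\*$", lines)), 1L)     # one starred balanced row
  expect_match(lines[23], "^# AUC")
})
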