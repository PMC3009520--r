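#' Confusion counts at a decision threshold
#'
#' TP = interacting residues scored at or above `t`; TN = non-interacting
#' below `t`; FP and FN are the corresponding misclassifications. Counts
#' always sum to `length(scores)`.
#'
#' @param scores Numeric decision values.
#' @param labels 0/1 truth, same length.
#' @param t Threshold; prediction is positive when `score >= t`.
#' @return A list of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_at_threshold <- function(scores, labels, t) {
  if (length(scores) != length(labels))
    stop_parameter("%d scores but %d labels", length(scores), length(labels))
  pred <- scores >= t
  lab <- as.logical(labels)
  structure(list(TP = sum(pred & lab),  FN = sum(!pred & lab),
                 TN = sum(!pred & !lab), FP = sum(pred & !lab)),
            class = "confusion_counts")
}

#' Threshold metrics from confusion counts
#'
#' Sensitivity `Sn = 100 TP / (TP + FN)` (percent coverage of interacting
#' residues), specificity `Sp = 100 TN / (TN + FP)`, overall accuracy
#' `Acc = 100 (TP + TN) / n`, and the Matthews correlation coefficient
#' `MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, where 1 is
#' a perfect prediction and 0 random. When a denominator factor produced by
#' the *predictions* is zero (all-positive or all-negative calls, as at
#' sweep endpoints), MCC is reported as 0 — with a warning unless
#' `quiet = TRUE` — rather than aborting; an empty *truth* class is an
#' error, since Sn or Sp is then undefined.
#'
#' @param cc A `confusion_counts` (or list with TP/TN/FP/FN).
#' @param quiet Suppress the zero-denominator warning.
#' @return A one-row data frame with `Sn`, `Sp`, `Acc` (percent) and `MCC`.
#' @export
metrics_from_confusion <- function(cc, quiet = FALSE) {
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  if (any(c(TP, TN, FP, FN) < 0)) stop_parameter("negative confusion counts")
  if (TP + FN == 0 || TN + FP == 0)
    stop_fadpred("fadpred_metric_error",
                 "a truth class is empty (TP+FN=%d, TN+FP=%d)", TP + FN, TN + FP)
  n <- TP + TN + FP + FN
  den2 <- as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  if (den2 == 0) {
    if (!quiet)
      warn_fadpred("MCC denominator factor is zero (degenerate predictions); reporting MCC = 0")
    mcc <- 0
  } else {
    mcc <- (as.numeric(TP) * TN - as.numeric(FP) * FN) / sqrt(den2)
  }
  data.frame(Sn = 100 * TP / (TP + FN),
             Sp = 100 * TN / (TN + FP),
             Acc = 100 * (TP + TN) / n,
             MCC = mcc)
}

#' Rebuild balanced confusion counts from printed rates
#'
#' Given a sensitivity/specificity pair reported on a class-balanced
#' evaluation with `n_per_class` examples per class, reconstructs the
#' underlying counts (`TP = round(Sn n / 100)` etc.), enabling analytic
#' verification of reported accuracy and MCC values.
#'
#' @param Sn,Sp Percentages in \[0, 100\].
#' @param n_per_class Examples per class (both classes equal).
#' @return A `confusion_counts`.
#' @examples
#' m <- metrics_from_confusion(reconstruct_counts_from_rates(83.36, 82.36, 10000))
#' round(m$Acc, 2)   # 82.86
#' @export
reconstruct_counts_from_rates <- function(Sn, Sp, n_per_class) {
  if (Sn < 0 || Sn > 100 || Sp < 0 || Sp > 100)
    stop_parameter("Sn and Sp must be percentages in [0, 100]")
  TP <- round(Sn * n_per_class / 100)
  TN <- round(Sp * n_per_class / 100)
  structure(list(TP = TP, FN = n_per_class - TP,
                 TN = TN, FP = n_per_class - TN),
            class = "confusion_counts")
}

#' Closed-form balanced metrics from (Sn, Sp)
#'
#' On exactly class-balanced counts the general formulas reduce to
#' `Acc = (Sn + Sp) / 2` and
#' `MCC = (Sn + Sp - 100) / sqrt((Sn + 100 - Sp)(Sp + 100 - Sn))`
#' (percent scale). Used as an independent oracle against
#' [metrics_from_confusion()].
#'
#' @inheritParams reconstruct_counts_from_rates
#' @return A one-row data frame with `Acc` and `MCC`.
#' @export
balanced_metrics_closed_form <- function(Sn, Sp) {
  den <- (Sn + 100 - Sp) * (Sp + 100 - Sn)
  data.frame(Acc = (Sn + Sp) / 2,
             MCC = if (den == 0) 0 else (Sn + Sp - 100) / sqrt(den))
}

#' Threshold sweep
#'
#' Evaluates the confusion metrics over a grid of decision-value thresholds
#' (default -1.0 to +1.0 in steps of 0.1, the conventional reporting grid).
#' Along the grid Sn is nonincreasing and Sp nondecreasing.
#'
#' @param scores,labels As in [confusion_at_threshold()].
#' @param grid Numeric vector of thresholds.
#' @return Data frame with columns `threshold`, `Sn`, `Sp`, `Acc`, `MCC`.
#' @export
threshold_sweep <- function(scores, labels, grid = seq(-1, 1, by = 0.1)) {
  if (length(scores) == 0L) stop_parameter("no scores to sweep")
  if (length(grid) == 0L) stop_parameter("empty threshold grid")
  rows <- lapply(grid, function(t)
    cbind(threshold = t,
          metrics_from_confusion(confusion_at_threshold(scores, labels, t),
                                 quiet = TRUE)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Balanced-threshold selection
#'
#' Picks the sweep row where sensitivity and specificity are closest
#' (minimum |Sn - Sp|); ties go to the higher MCC, then the lower
#' threshold. This is the operating point conventionally highlighted in
#' per-threshold performance tables.
#'
#' @param rows Data frame from [threshold_sweep()].
#' @return The selected single row.
#' @export
select_balanced_threshold <- function(rows) {
  if (nrow(rows) == 0L) stop_parameter("no sweep rows")
  gap <- abs(rows$Sn - rows$Sp)
  ord <- order(gap, -rows$MCC, rows$threshold)
  rows[ord[1L], , drop = FALSE]
}

#' Rank-based ROC AUC
#'
#' AUC computed as the rank statistic: the probability that a random
#' interacting residue outscores a random non-interacting one, with ties
#' counted half (equivalent to the Wilcoxon/Mann-Whitney statistic). Being
#' rank-based it is threshold-independent and invariant under any strictly
#' increasing transform of the scores. The returned curve comes from the
#' full sorted-score sweep, not a fixed grid.
#'
#' @param scores,labels As in [confusion_at_threshold()]; both classes must
#'   be present.
#' @return A list of class `roc_result` with `auc` and `curve` (data frame
#'   of `fpr` = 1 - Sp and `tpr` = Sn as fractions, ordered and monotone).
#' @export
roc_auc <- function(scores, labels) {
  lab <- as.logical(labels)
  n1 <- sum(lab); n0 <- sum(!lab)
  if (n1 == 0L || n0 == 0L)
    stop_data("ROC needs both classes (got %d positive, %d negative)", n1, n0)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[lab]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
  ord <- order(scores, decreasing = TRUE)
  tpr <- cumsum(lab[ord]) / n1
  fpr <- cumsum(!lab[ord]) / n0
  keep <- !duplicated(scores[ord], fromLast = TRUE)   # one point per cutoff
  curve <- data.frame(fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
  structure(list(auc = auc, curve = curve), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Five-fold cross-validation with threshold sweep
#'
#' For each fold, trains on the remaining folds and scores the held-out
#' patterns; per-threshold metrics are then averaged across folds with
#' unweighted means (fold sizes differ by at most one pattern, so the
#' difference from pooling is O(1/n)). AUC is reported both as the mean of
#' per-fold AUCs and pooled over all held-out scores.
#'
#' @param dataset A `pattern_dataset`.
#' @param encoder Encoder closure from [binary_encoder()] or
#'   [profile_encoder()].
#' @param config An [svm_config].
#' @param folds Integer fold vector from [assign_folds()] (one entry per
#'   pattern row).
#' @param grid Threshold grid for the sweep.
#' @param seed Seed recorded into the fold models.
#' @return A list of class `cv_result`: `sweep` (fold-averaged metrics per
#'   threshold), `balanced` (selected balanced row), `auc_mean`,
#'   `auc_pooled`, `fold_auc`, and `scores` (held-out score, label and fold
#'   per pattern — each pattern is scored exactly once).
#' @export
crossvalidate <- function(dataset, encoder, config, folds,
                          grid = seq(-1, 1, by = 0.1), seed = 1L) {
  stopifnot(inherits(dataset, "pattern_dataset"))
  pat <- dataset$patterns
  if (length(folds) != nrow(pat))
    stop_parameter("fold vector length %d != %d patterns", length(folds), nrow(pat))
  ks <- sort(unique(folds))
  x <- encoder(pat)
  scheme <- attr(encoder, "scheme")

  sweeps <- list(); fold_auc <- numeric(0)
  sc_all <- rep(NA_real_, nrow(pat))
  for (k in ks) {
    tr <- folds != k; te <- !tr
    if (length(unique(pat$label[tr])) < 2L || length(unique(pat$label[te])) < 2L)
      stop_data("fold %d leaves a single-class train or test set", k)
    model <- train_svm(x[tr, , drop = FALSE], pat$label[tr], config,
                       scheme = scheme, window_size = dataset$window_size,
                       seed = seed)
    sc <- decision_scores(model, x[te, , drop = FALSE])
    sc_all[te] <- sc
    sweeps[[length(sweeps) + 1L]] <- threshold_sweep(sc, pat$label[te], grid)
    fold_auc <- c(fold_auc, roc_auc(sc, pat$label[te])$auc)
  }

  avg <- sweeps[[1L]]
  for (col in c("Sn", "Sp", "Acc", "MCC"))
    avg[[col]] <- rowMeans(vapply(sweeps, function(s) s[[col]],
                                  numeric(nrow(avg))))
  pooled <- roc_auc(sc_all, pat$label)

  structure(list(
    sweep = avg,
    balanced = select_balanced_threshold(avg),
    auc_mean = mean(fold_auc),
    auc_pooled = pooled$auc,
    fold_auc = fold_auc,
    scores = data.frame(fold = folds, score = sc_all, label = pat$label)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  b <- x$balanced
  cat(sprintf(paste0("<cv_result> balanced threshold %.1f: Sn %.2f, Sp %.2f, ",
                     "Acc %.2f, MCC %.3f; AUC %.3f (fold mean), %.3f (pooled)\n"),
              b$threshold, b$Sn, b$Sp, b$Acc, b$MCC, x$auc_mean, x$auc_pooled))
  invisible(x)
}

#' Write a per-threshold performance report
#'
#' TSV in the conventional table layout: one row per threshold with
#' `Thes`, `Sen`, `Spe`, `Acc`, `MCC` columns, the balanced row marked,
#' and AUC in a trailing comment.
#'
#' @param cv A `cv_result`.
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_cv_report <- function(cv, file) {
  df <- data.frame(Thes = sprintf("%.1f", cv$sweep$threshold),
                   Sen = round(cv$sweep$Sn, 2), Spe = round(cv$sweep$Sp, 2),
                   Acc = round(cv$sweep$Acc, 2), MCC = round(cv$sweep$MCC, 2),
                   balanced = ifelse(cv$sweep$threshold ==
                                       cv$balanced$threshold, "*", ""))
  con <- file(file, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sprintf("# AUC\tfold_mean=%.4f\tpooled=%.4f",
                     cv$auc_mean, cv$auc_pooled), con)
  invisible(file)
}

#' Published reference performance tables
#'
#' Per-threshold performance originally reported for the six FADPred models
#' (windows 15/17/19 x binary/PSSM encodings, five-fold cross-validation on
#' the 198-chain flavoprotein benchmark). Columns: `scheme`, `window`,
#' `threshold`, `Sn`, `Sp`, `Acc`, `MCC`, `balanced` (the highlighted
#' operating point), and `consistent` — `FALSE` for the few rows whose
#' printed Acc/MCC disagree beyond print precision with values recomputed
#' from their own printed Sn/Sp (typographic errors in the source tables).
#'
#' @param scheme Optional filter, `"binary"` or `"pssm"`.
#' @param window Optional filter, 15/17/19.
#' @return Data frame of reference rows.
#' @export
published_performance <- function(scheme = NULL, window = NULL) {
  path <- system.file("extdata", "published_performance.tsv",
                      package = "fadpred", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$balanced <- as.logical(tab$balanced)
  tab$consistent <- as.logical(tab$consistent)
  if (!is.null(scheme)) tab <- tab[tab$scheme == scheme, ]
  if (!is.null(window)) tab <- tab[tab$window == window, ]
  rownames(tab) <- NULL
  tab
}
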