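#' Random undersampling to the minority-class size
#'
#' Downsamples every class, without replacement, to the size of the
#' smallest class so the classifier sees balanced training data. Classes
#' already at the minority size are kept untouched; row order of the
#' survivors is preserved.
#'
#' @param table Feature table with a `label` column and >= 2 classes.
#' @param seed Integer seed; identical seeds give identical selections.
#' @return The balanced table.
#' @examples
#' \dontrun{balanced <- random_undersample(features, seed = 7)}
#' @export
random_undersample <- function(table, seed = 1) {
  y <- table$label
  counts <- table(y)
  if (length(counts) < 2) {
    stop_seizr("need at least 2 classes to rebalance",
               "seizr_error_invalid_argument")
  }
  if (any(counts == 0)) {
    stop_seizr("empty class in table", "seizr_error_invalid_argument")
  }
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(names(counts), function(cl) {
      idx <- which(y == cl)
      if (length(idx) == m) idx else sort(sample(idx, m))
    }))
  })
  out <- table[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "window_config") <- attr(table, "window_config")
  out
}

#' Stratified k-fold plan
#'
#' Splits rows into `k` disjoint, exhaustive folds with per-class counts
#' differing by at most 1 across folds.
#'
#' @param table Feature table with a `label` column; every class must have
#'   at least `k` rows.
#' @param k Number of folds, >= 2 (default 10).
#' @param seed Integer seed for the within-class shuffles.
#' @return An object of class `fold_plan`: list `folds` of row-index
#'   vectors, plus `k` and `seed`.
#' @export
stratified_kfold <- function(table, k = 10, seed = 1) {
  if (!is.numeric(k) || k < 2 || k != round(k)) {
    stop_seizr("'k' must be an integer >= 2", "seizr_error_invalid_argument")
  }
  y <- table$label
  counts <- table(y)
  small <- names(counts)[counts < k]
  if (length(small)) {
    stop_seizr(sprintf("class(es) smaller than k = %d: %s", k,
                       paste(small, collapse = ", ")),
               "seizr_error_invalid_argument")
  }
  folds <- with_seed(seed, {
    assign_fold <- integer(nrow(table))
    fold_totals <- integer(k)
    for (cl in names(counts)) {
      idx <- sample(which(y == cl))
      n_cl <- length(idx)
      base <- n_cl %/% k
      extra <- n_cl %% k
      # spread the remainder over the currently smallest folds so overall
      # fold sizes also differ by at most 1
      per_fold <- rep(base, k)
      if (extra > 0) {
        grow <- order(fold_totals, seq_len(k))[seq_len(extra)]
        per_fold[grow] <- per_fold[grow] + 1L
      }
      assign_fold[idx] <- rep(seq_len(k), times = per_fold)
      fold_totals <- fold_totals + per_fold
    }
    lapply(seq_len(k), function(f) which(assign_fold == f))
  })
  structure(list(folds = folds, k = as.integer(k), seed = seed),
            class = "fold_plan")
}

#' Confusion counts from labels
#'
#' K x K confusion matrix (rows = truth, columns = prediction) plus the
#' per-class one-vs-rest TP/TN/FP/FN counts the binary metrics are built
#' from.
#'
#' @param true_labels,predicted Equal-length label vectors.
#' @param levels Optional label set; defaults to the union of both vectors.
#' @return An object of class `confusion_counts` with `matrix`,
#'   `per_class` (data frame: class, TP, TN, FP, FN) and `n`.
#' @export
confusion <- function(true_labels, predicted, levels = NULL) {
  if (length(true_labels) != length(predicted)) {
    stop_seizr("label vectors must have equal length",
               "seizr_error_invalid_argument")
  }
  if (is.null(levels)) {
    levels <- sort(unique(c(as.character(true_labels),
                            as.character(predicted))))
  }
  tr <- factor(true_labels, levels = levels)
  pr <- factor(predicted, levels = levels)
  m <- table(truth = tr, prediction = pr)
  n <- sum(m)
  per <- do.call(rbind, lapply(levels, function(cl) {
    tp <- m[cl, cl]
    fn <- sum(m[cl, ]) - tp
    fp <- sum(m[, cl]) - tp
    tn <- n - tp - fn - fp
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               stringsAsFactors = FALSE)
  }))
  structure(list(matrix = m, per_class = per, n = n),
            class = "confusion_counts")
}

binary_metrics <- function(tp, tn, fp, fn) {
  safe <- function(num, den) if (den == 0) 0 else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  c(sensitivity = safe(tp, tp + fn),
    specificity = safe(tn, tn + fp),
    precision = safe(tp, tp + fp),
    accuracy = safe(tp + tn, tp + tn + fp + fn),
    f1 = safe(2 * tp, 2 * tp + fp + fn),
    mcc = if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity, specificity, precision, accuracy, F1 and the Matthews
#' correlation coefficient, computed one-vs-rest per class and
#' macro-averaged (unweighted mean over classes). Cells with a zero
#' denominator yield 0 and are flagged rather than erroring. The multiclass
#' MCC defaults to the macro average of the per-class binary MCCs; the
#' Gorodkin RK generalization is available via `mcc_method = "gorodkin"`.
#'
#' @param counts A `confusion_counts` from [confusion()].
#' @param mcc_method `"macro"` (default) or `"gorodkin"` for the reported
#'   multiclass `macro["mcc"]`.
#' @return An object of class `metrics_report`: `per_class` data frame,
#'   `macro` named vector, `overall_accuracy` (trace / n), `flags`.
#' @export
metrics <- function(counts, mcc_method = c("macro", "gorodkin")) {
  mcc_method <- match.arg(mcc_method)
  if (!inherits(counts, "confusion_counts")) {
    stop_seizr("'counts' must come from confusion()",
               "seizr_error_invalid_argument")
  }
  if (counts$n == 0) {
    stop_seizr("empty confusion matrix", "seizr_error_invalid_argument")
  }
  pc <- counts$per_class
  vals <- t(vapply(seq_len(nrow(pc)), function(i) {
    binary_metrics(pc$TP[i], pc$TN[i], pc$FP[i], pc$FN[i])
  }, numeric(6)))
  per_class <- cbind(pc, as.data.frame(vals))
  flags <- character(0)
  for (i in seq_len(nrow(pc))) {
    dens <- c(sensitivity = pc$TP[i] + pc$FN[i],
              specificity = pc$TN[i] + pc$FP[i],
              precision = pc$TP[i] + pc$FP[i])
    zero <- names(dens)[dens == 0]
    if (length(zero)) {
      flags <- c(flags, sprintf("%s: zero denominator for %s (reported 0)",
                                pc$class[i], paste(zero, collapse = ", ")))
    }
  }
  macro <- colMeans(vals)
  if (mcc_method == "gorodkin") macro["mcc"] <- mcc_gorodkin(counts$matrix)
  structure(list(per_class = per_class,
                 macro = macro,
                 overall_accuracy = sum(diag(counts$matrix)) / counts$n,
                 mcc_method = mcc_method,
                 flags = flags),
            class = "metrics_report")
}

# RK multiclass MCC (Gorodkin 2004), computed from the K x K matrix.
mcc_gorodkin <- function(m) {
  m <- as.matrix(m)
  n <- sum(m)
  t_k <- rowSums(m)   # truth totals
  p_k <- colSums(m)   # prediction totals
  num <- sum(diag(m)) * n - sum(t_k * p_k)
  den <- sqrt(n^2 - sum(p_k^2)) * sqrt(n^2 - sum(t_k^2))
  if (den == 0) 0 else num / den
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> overall accuracy %.4f (%s MCC %.4f)\n",
              x$overall_accuracy, x$mcc_method, x$macro[["mcc"]]))
  out <- x$per_class[, c("class", "sensitivity", "specificity",
                         "precision", "f1", "mcc")]
  out[-1] <- lapply(out[-1], round, 4)
  print(out, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Cross-validated classification report
#'
#' Stratified k-fold cross-validation of the RBF-SVM: each fold's model is
#' fitted (and standardized) on the training rows only, the held-out rows
#' are predicted, and the held-out predictions from all folds are pooled
#' into one confusion matrix from which the metrics are computed.
#'
#' @param table Feature table; balance it first (e.g.
#'   [random_undersample()]) if the classes are skewed.
#' @param cfg An [svm_config()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold assignment.
#' @param mcc_method Passed to [metrics()].
#' @return An object of class `cv_report`: `metrics`, `confusion`,
#'   `per_fold_accuracy`, `fold_plan`, `cfg`.
#' @export
cross_validated_report <- function(table, cfg = svm_config(), k = 10,
                                   seed = 1, mcc_method = "macro") {
  plan <- stratified_kfold(table, k = k, seed = seed)
  pred <- character(nrow(table))
  per_fold <- numeric(plan$k)
  for (f in seq_len(plan$k)) {
    test_idx <- plan$folds[[f]]
    fit <- svm_fit(table[-test_idx, , drop = FALSE], cfg)
    pred[test_idx] <- svm_predict(fit, table[test_idx, , drop = FALSE])
    per_fold[f] <- mean(pred[test_idx] == table$label[test_idx])
  }
  cm <- confusion(table$label, pred)
  structure(list(metrics = metrics(cm, mcc_method = mcc_method),
                 confusion = cm,
                 per_fold_accuracy = per_fold,
                 fold_plan = plan,
                 cfg = cfg),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-fold CV, pooled accuracy %.4f\n",
              x$fold_plan$k, x$metrics$overall_accuracy))
  print(x$metrics)
  invisible(x)
}

#' One-way ANOVA screen for a feature column
#'
#' Classical one-way fixed-effects F test of equal group means
#' (equal-variance form), used to screen each feature for differences
#' across seizure types. Input with zero variance everywhere is flagged as
#' degenerate instead of producing an F statistic.
#'
#' @param feature_column Numeric response values.
#' @param labels Group labels, >= 2 groups with >= 2 values each.
#' @return List with `statistic` (F), `p_value`, `df` (between, within),
#'   `degenerate` flag.
#' @examples
#' anova_oneway(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
#'              rep(c("a", "b", "c"), each = 3))$statistic  # 3
#' @export
anova_oneway <- function(feature_column, labels) {
  g <- factor(labels)
  if (nlevels(g) < 2) {
    stop_seizr("need at least 2 groups", "seizr_error_invalid_argument")
  }
  sizes <- table(g)
  if (any(sizes < 2)) {
    stop_seizr(sprintf("group(s) with fewer than 2 values: %s",
                       paste(names(sizes)[sizes < 2], collapse = ", ")),
               "seizr_error_invalid_argument")
  }
  if (!all(is.finite(feature_column))) {
    stop_seizr("non-finite feature values", "seizr_error_data")
  }
  if (stats::var(feature_column) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                df = c(nlevels(g) - 1L, length(feature_column) - nlevels(g)),
                degenerate = TRUE))
  }
  ft <- stats::oneway.test(feature_column ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic),
       p_value = unname(ft$p.value),
       df = unname(ft$parameter),
       degenerate = FALSE)
}

#' ANOVA screen over every feature column
#'
#' @param table Feature table.
#' @param alpha Significance level used for the `significant` flag.
#' @return Data frame with one row per feature column: `feature`,
#'   `F`, `p_value`, `significant`, `degenerate`.
#' @export
anova_screen <- function(table, alpha = 0.05) {
  cols <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                  c("channel_id", "label"))
  out <- do.call(rbind, lapply(cols, function(cl) {
    a <- anova_oneway(table[[cl]], table$label)
    data.frame(feature = cl, F = a$statistic, p_value = a$p_value,
               significant = isTRUE(a$p_value < alpha),
               degenerate = a$degenerate, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
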