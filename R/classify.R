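# Linear max-margin classification of centrality feature tables under
# leave-one-subject-out cross-validation, scored by the balanced accuracy
# (sensitivity + specificity) / 2.

task_groups <- function(task) {
  switch(task,
    control_vs_adhd = list(negative = c("control"),
                           positive = c("inattentive", "combined"),
                           negative_label = "control", positive_label = "adhd"),
    inattentive_vs_combined = list(negative = c("inattentive"),
                                   positive = c("combined"),
                                   negative_label = "inattentive",
                                   positive_label = "combined"),
    abort(sprintf("unknown task '%s'", task))
  )
}

#' Assemble one classification feature table
#'
#' Selects subjects by task (controls vs all patients, or inattentive vs
#' combined subtype) and scope (one site or `"all"` sites pooled), and pivots
#' the requested centrality measure to a subjects x ROIs matrix. The positive
#' class is the patient group (`"adhd"`) in the control-vs-patient task and
#' the combined subtype in the subtype task, so sensitivity always means
#' patient detection. A scope in which either class has fewer than two
#' subjects is rejected: no leave-one-out fold would have both classes
#' available for training.
#'
#' @param centralities Long centrality tibble from [compute_centralities()].
#' @param measure,graph_kind,cutoff One feature configuration (`cutoff`
#'   ignored for `graph_kind = "weighted"`).
#' @param task `"control_vs_adhd"` or `"inattentive_vs_combined"`.
#' @param scope A site label, or `"all"` for the pooled analysis
#'   (concatenation of all sites, no harmonization).
#' @return A `feature_table` object: feature matrix `x` (rownames = subject
#'   ids), factor `labels` (negative level first), `sites`, and the selection
#'   metadata.
#' @export
build_feature_table <- function(centralities, measure, graph_kind,
                                cutoff = NULL, task = "control_vs_adhd",
                                scope = "all") {
  tg <- task_groups(task)
  sel <- dplyr::filter(centralities, .data$measure == !!measure,
                       .data$graph_kind == !!graph_kind)
  if (graph_kind == "unweighted") {
    if (is.null(cutoff)) abort("`cutoff` is required for unweighted features")
    sel <- dplyr::filter(sel, abs(.data$cutoff - !!cutoff) < 1e-12)
  } else {
    cutoff <- NA_real_
  }
  if (!identical(scope, "all")) sel <- dplyr::filter(sel, .data$site == !!scope)
  sel <- dplyr::filter(sel, .data$group %in% c(tg$negative, tg$positive))
  if (!nrow(sel)) abort("no subjects matched the requested configuration")
  wide <- tidyr::pivot_wider(sel, id_cols = c("subject_id", "site", "group"),
                             names_from = "roi", values_from = "value",
                             names_prefix = "roi_")
  x <- as.matrix(wide[, grep("^roi_", names(wide))])
  rownames(x) <- wide$subject_id
  if (anyNA(x)) abort("feature table contains missing values")
  labels <- factor(ifelse(wide$group %in% tg$positive,
                          tg$positive_label, tg$negative_label),
                   levels = c(tg$negative_label, tg$positive_label))
  counts <- table(labels)
  if (any(counts < 2)) {
    abort(sprintf(
      "class '%s' has %d subject(s) in scope '%s'; need at least 2 per class",
      names(counts)[which.min(counts)], min(counts), scope))
  }
  structure(
    list(x = x, labels = labels, sites = wide$site,
         positive_class = tg$positive_label, task = task, scope = scope,
         measure = measure, graph_kind = graph_kind, cutoff = cutoff),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s/%s%s | task %s | scope %s | %d x %d (%s)\n",
              x$measure, x$graph_kind,
              if (is.na(x$cutoff)) "" else sprintf("@%.2f", x$cutoff),
              x$task, x$scope, nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}

# standardize with training statistics; zero-variance features pass through
# centered only (unit divisor)
fold_scaler <- function(xtr) {
  mu <- colMeans(xtr)
  sigma <- apply(xtr, 2, sd)
  sigma[sigma < 1e-12] <- 1
  list(mu = mu, sigma = sigma)
}

scale_with <- function(x, scaler) {
  sweep(sweep(x, 2, scaler$mu), 2, scaler$sigma, "/")
}

# majority label with deterministic tie-break towards the negative class
# (first factor level)
majority_label <- function(y) {
  counts <- table(y)
  names(counts)[which.max(counts)]
}

svm_fit <- function(x, y, cost) {
  e1071::svm(x, y, kernel = "linear", cost = cost, scale = FALSE)
}

#' Leave-one-subject-out classification of a feature table
#'
#' For each subject, a linear support vector machine (cost `cost`, no kernel)
#' is trained on all remaining subjects — features standardized with
#' training-fold mean and standard deviation only, the held-out row
#' transformed with those same statistics — and the held-out subject is
#' predicted. Degenerate folds are handled deterministically: a single-class
#' training fold predicts that class; a training fold whose standardized
#' features are all zero (identical rows) predicts the training majority
#' class, ties going to the negative class.
#'
#' @param table A [build_feature_table()] result.
#' @param cost SVM regularization constant (default 1; never tuned on test
#'   folds).
#' @return A `classification_result`: per-fold predictions plus
#'   `sensitivity`, `specificity` and `score = (sensitivity + specificity)/2`.
#' @export
loocv_classify <- function(table, cost = 1) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$x
  y <- table$labels
  n <- nrow(x)
  preds <- character(n)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) == 1L) {
      preds[i] <- levels(ytr)
      next
    }
    scaler <- fold_scaler(xtr)
    xs <- scale_with(xtr, scaler)
    if (max(abs(xs)) < 1e-10) {
      preds[i] <- majority_label(y[-i])
      next
    }
    fit <- svm_fit(xs, ytr, cost)
    preds[i] <- as.character(predict(fit, scale_with(x[i, , drop = FALSE], scaler)))
  }
  predicted <- factor(preds, levels = levels(y))
  cs <- confusion_stats(predicted, y, table$positive_class)
  structure(
    list(subject_id = rownames(x), predicted = predicted, actual = y,
         sensitivity = cs[["sensitivity"]], specificity = cs[["specificity"]],
         score = balanced_score(cs[["sensitivity"]], cs[["specificity"]]),
         positive_class = table$positive_class,
         n_pos = sum(y == table$positive_class),
         n_neg = sum(y != table$positive_class),
         task = table$task, scope = table$scope, measure = table$measure,
         graph_kind = table$graph_kind, cutoff = table$cutoff, cost = cost),
    class = "classification_result"
  )
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf(
    "<classification_result> %s | %s/%s%s | scope %s\n  sens %.3f  spec %.3f  score %.3f (%d%%)  [n+ = %d, n- = %d]\n",
    x$task, x$measure, x$graph_kind,
    if (is.na(x$cutoff)) "" else sprintf("@%.2f", x$cutoff),
    x$scope, x$sensitivity, x$specificity, x$score, report_percent(x$score),
    x$n_pos, x$n_neg))
  invisible(x)
}

#' Sensitivity and specificity from predictions
#'
#' Sensitivity is recall on the positive class (`TP / (TP + FN)`),
#' specificity recall on the negative class (`TN / (TN + FP)`).
#'
#' @param predicted,actual Equal-length label vectors.
#' @param positive_class The label counted as positive; must occur in
#'   `actual`, as must at least one other label.
#' @return Named numeric vector `c(sensitivity = , specificity = )`.
#' @export
confusion_stats <- function(predicted, actual, positive_class) {
  if (length(predicted) != length(actual)) abort("length mismatch")
  pos <- actual == positive_class
  if (!any(pos)) abort(sprintf("class '%s' absent from `actual`", positive_class))
  if (all(pos)) abort("negative class absent from `actual`")
  c(sensitivity = mean(predicted[pos] == positive_class),
    specificity = mean(predicted[!pos] != positive_class))
}

#' Balanced classification score
#'
#' The arithmetic mean of sensitivity and specificity — the accuracy summary
#' robust to class imbalance (a constant-majority classifier scores exactly
#' 0.5).
#'
#' @param sensitivity,specificity Fractions in \[0, 1\].
#' @return `(sensitivity + specificity) / 2`.
#' @seealso [report_percent()] for the integer-percent reporting convention.
#' @export
balanced_score <- function(sensitivity, specificity) {
  if (any(sensitivity < 0 | sensitivity > 1) || any(specificity < 0 | specificity > 1)) {
    abort("sensitivity and specificity must lie in [0, 1]")
  }
  (sensitivity + specificity) / 2
}

#' Report a fraction as an integer percent
#'
#' Rounds half away from zero (0.765 -> 77), the convention used in the
#' result tables.
#'
#' @param x Fraction(s) in \[0, 1\].
#' @return Integer percent(s).
#' @export
report_percent <- function(x) {
  as.integer(floor(x * 100 + 0.5))
}
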