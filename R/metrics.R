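# Classification metrics and prediction-score statistics for five-grade DR
# classifiers run through the toolkit.

check_prediction_records <- function(records, need_probs = FALSE) {
  req <- c("image_id", "true_grade", "predicted_grade")
  if (!all(req %in% names(records))) {
    stop_fundus("prediction records need image_id, true_grade, predicted_grade",
                "fundusXAI_input_error")
  }
  if (any(!records$true_grade %in% 0:4) ||
      any(!records$predicted_grade %in% 0:4)) {
    stop_fundus("grades must lie in 0-4", "fundusXAI_data_error")
  }
  if (need_probs && !all(prob_cols() %in% names(records))) {
    stop_fundus("prediction records need probability columns p0..p4",
                "fundusXAI_input_error")
  }
  invisible(records)
}

prob_cols <- function() paste0("p", 0:4)

#' Confusion matrix over DR grades
#'
#' @param records Data.frame with `true_grade` and `predicted_grade` in 0-4.
#' @param normalize If `TRUE`, rows are normalized to proportions.
#' @return 5x5 matrix, rows = true grade, columns = predicted grade.
#' @export
confusion_matrix <- function(records, normalize = FALSE) {
  check_prediction_records(records)
  m <- table(factor(records$true_grade, levels = 0:4),
             factor(records$predicted_grade, levels = 0:4))
  m <- unclass(m)
  dimnames(m) <- list(true = 0:4, predicted = 0:4)
  if (normalize) {
    rs <- rowSums(m)
    m <- sweep(m, 1, ifelse(rs == 0, 1, rs), "/")
  }
  m
}

#' Overall classification metrics
#'
#' Accuracy, macro one-vs-rest F1 and specificity, and macro one-vs-rest
#' AUC-ROC from the per-class probability vectors (via pROC; classes absent
#' from the truth, or present without counter-examples, are skipped in the
#' macro average). AUC is `NA` with a warning when fewer than two classes
#' occur.
#'
#' @param records Data.frame with `true_grade`, `predicted_grade` and
#'   probability columns `p0..p4` (needed for AUC only).
#' @return Named list: `accuracy`, `f1`, `specificity`, `auc`.
#' @export
classification_metrics <- function(records) {
  check_prediction_records(records)
  n <- nrow(records)
  acc <- mean(records$true_grade == records$predicted_grade)
  f1s <- c(); specs <- c()
  for (g in 0:4) {
    tp <- sum(records$true_grade == g & records$predicted_grade == g)
    fp <- sum(records$true_grade != g & records$predicted_grade == g)
    fn <- sum(records$true_grade == g & records$predicted_grade != g)
    tn <- n - tp - fp - fn
    if (tp + fn == 0) next  # class absent: no one-vs-rest positives
    f1s <- c(f1s, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
    specs <- c(specs, if (tn + fp == 0) NA_real_ else tn / (tn + fp))
  }
  auc <- NA_real_
  if (length(unique(records$true_grade)) < 2) {
    warning("AUC undefined with a single observed class", call. = FALSE)
  } else {
    check_prediction_records(records, need_probs = TRUE)
    aucs <- c()
    for (g in 0:4) {
      y <- records$true_grade == g
      if (!any(y) || all(y)) next
      roc <- pROC::roc(response = y, predictor = records[[paste0("p", g)]],
                       levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
      aucs <- c(aucs, as.numeric(pROC::auc(roc)))
    }
    auc <- mean(aucs)
  }
  list(accuracy = acc, f1 = mean(f1s), specificity = mean(specs, na.rm = TRUE),
       auc = auc)
}

#' Prediction-score statistics per (grade, correctness) stratum
#'
#' The reported score of a *correct* prediction is the probability assigned
#' to the true class; for an *incorrect* prediction it is the probability of
#' the (wrong) predicted class. Each (true grade, correctness) stratum gets
#' count, min, max, mean, median and sample standard deviation (`NA`,
#' rendered as dashes, for empty strata; std is 0 for singletons).
#'
#' @param records Data.frame with grades and probability columns `p0..p4`.
#' @return Data.frame: grade, correct, count, min, max, mean, median, std.
#' @export
score_statistics <- function(records) {
  check_prediction_records(records, need_probs = TRUE)
  pm <- as.matrix(records[, prob_cols()])
  correct <- records$true_grade == records$predicted_grade
  score <- ifelse(correct,
                  pm[cbind(seq_len(nrow(pm)), records$true_grade + 1L)],
                  pm[cbind(seq_len(nrow(pm)), records$predicted_grade + 1L)])
  out <- list()
  for (g in 0:4) {
    for (corr in c(TRUE, FALSE)) {
      s <- score[records$true_grade == g & correct == corr]
      out[[length(out) + 1L]] <- data.frame(
        grade = g, correct = corr, count = length(s),
        min = if (length(s)) min(s) else NA_real_,
        max = if (length(s)) max(s) else NA_real_,
        mean = if (length(s)) mean(s) else NA_real_,
        median = if (length(s)) median(s) else NA_real_,
        std = if (length(s) > 1) sd(s) else if (length(s) == 1) 0 else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
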