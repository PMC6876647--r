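#' Confusion-matrix performance metrics
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV TP/(TP+FP),
#' NPV TN/(TN+FN) and accuracy (TP+TN)/(TP+TN+FP+FN), with contraction
#' as the positive class. A zero denominator marks that single metric
#' `NA` with a warning rather than raising an error, so undefined
#' values never average in as false zeros.
#'
#' @param TP,TN,FP,FN nonnegative integer counts; their sum must be
#'   positive.
#' @return named numeric vector
#'   `c(sensitivity, specificity, PPV, NPV, accuracy)`.
#' @examples
#' confusionMetrics(TP = 84, FN = 16, TN = 78, FP = 22)
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
  counts <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (sum(counts) == 0) stop("all counts are zero")
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (zero denominator); marked NA")
      return(NA_real_)
    }
    num / den
  }
  c(sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"),
    PPV = safe(TP, TP + FP, "PPV"),
    NPV = safe(TN, TN + FN, "NPV"),
    accuracy = (TP + TN) / sum(counts))
}

#' Area under the ROC curve
#'
#' Probability that a randomly chosen contraction segment scores higher
#' than a randomly chosen non-contraction segment, ties counted 1/2
#' (the normalized Mann-Whitney statistic, equal to the trapezoidal
#' area under the ROC curve). Computed with pROC with the score
#' direction fixed (higher score = contraction), never auto-detected.
#'
#' @param labels vector of `"contraction"` / `"non_contraction"`
#'   labels; both classes must be present.
#' @param scores numeric scores (e.g. leaf class probabilities).
#' @return AUC in [0, 1].
#' @export
aucScore <- function(labels, scores) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2)
    stop("AUC requires both classes")
  as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = as.numeric(scores),
    levels = c("non_contraction", "contraction"),
    direction = "<", quiet = TRUE)))
}

#' Kruskal-Wallis fold-repeatability test
#'
#' Rank-based comparison of metric values across groups (by default the
#' cross-validation folds), used to check that the folds behave
#' interchangeably. If every value is identical there is no rank
#' variation and the test is reported as H = 0, p = 1 by convention.
#'
#' @param values numeric metric values.
#' @param groups grouping vector (>= 2 groups, >= 2 values per group).
#' @return list with `statistic` (H) and `p.value`.
#' @export
foldRepeatability <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("need at least 2 values per group")
  ok <- !is.na(values)
  values <- values[ok]; groups <- droplevels(groups[ok])
  if (nlevels(groups) < 2) stop("need at least 2 groups after NA removal")
  if (length(unique(values)) == 1)
    return(list(statistic = 0, p.value = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p.value = kt$p.value)
}

#' Per-channel metrics report from a cross-validated run
#'
#' Assembles the evaluation of one [runChannel()] result: per-fold
#' confusion-matrix metrics and AUC, their means over folds (the
#' headline summary), and the Kruskal-Wallis fold-repeatability test
#' (default grouping: each fold's metric values form one group).
#'
#' @param run result of [runChannel()].
#' @return list with `perFold` (data.frame, one row per fold),
#'   `mean` (named vector of fold-averaged metrics), and `repeatability`
#'   (H statistic and p-value).
#' @export
channelReport <- function(run) {
  oof <- run$oof
  k <- max(oof$fold)
  metricNames <- c("AUC", "sensitivity", "specificity", "PPV", "NPV",
                   "accuracy")
  perFold <- as.data.frame(matrix(NA_real_, k, length(metricNames),
                                  dimnames = list(NULL, metricNames)))
  for (f in seq_len(k)) {
    rows <- oof[oof$fold == f, ]
    cm <- withCallingHandlers(
      confusionMetrics(
        TP = sum(rows$label == "contraction" & rows$predicted == "contraction"),
        TN = sum(rows$label == "non_contraction" &
                 rows$predicted == "non_contraction"),
        FP = sum(rows$label == "non_contraction" &
                 rows$predicted == "contraction"),
        FN = sum(rows$label == "contraction" &
                 rows$predicted == "non_contraction")),
      warning = function(w) invokeRestart("muffleWarning"))
    auc <- if (length(unique(rows$label)) == 2)
      aucScore(rows$label, rows$score) else NA_real_
    perFold[f, ] <- c(auc, cm)
  }
  perFold$fold <- seq_len(k)

  means <- colMeans(perFold[, metricNames], na.rm = TRUE)
  long <- stats::na.omit(data.frame(
    fold = rep(perFold$fold, length(metricNames)),
    value = unlist(perFold[, metricNames], use.names = FALSE)))
  rep <- tryCatch(foldRepeatability(long$value, long$fold),
                  error = function(e) list(statistic = NA_real_,
                                           p.value = NA_real_))
  list(perFold = perFold, mean = means, repeatability = rep)
}
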