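#' Confusion matrix of observed versus predicted behaviours
#'
#' Rows are the observed (video-coded) behaviours, columns the behaviours
#' predicted by the classifier.
#'
#' @param observed,predicted Equal-length label vectors.
#' @param classes Class order for rows and columns.
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(observed, predicted, classes = SHEEP_BEHAVIOURS) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  bad <- setdiff(unique(c(observed, predicted)), classes)
  if (length(bad) > 0) stop("labels outside the class set: ", paste(bad, collapse = ", "))
  cm <- table(observed = factor(observed, levels = classes),
              predicted = factor(predicted, levels = classes))
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

# one-vs-rest collapse of a multiclass confusion matrix
ovr_counts <- function(cm, class) {
  tp <- cm[class, class]
  fp <- sum(cm[, class]) - tp
  fn <- sum(cm[class, ]) - tp
  tn <- sum(cm) - tp - fp - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

#' Per-class precision, recall, F-score and specificity
#'
#' Each behaviour is collapsed one-vs-rest: precision = TP/(TP+FP), recall =
#' TP/(TP+FN), F-score = the harmonic mean of the two (0 when both are 0),
#' specificity = TN/(TN+FP). A metric with an empty denominator is reported
#' as `NA` (undefined), not 0.
#'
#' @param cm A [confusion_matrix()].
#' @return Data frame, one row per class, columns `precision`, `recall`,
#'   `f_score`, `specificity`; fractions in `[0, 1]`.
#' @export
class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), sum(cm) > 0)
  res <- lapply(rownames(cm), function(cl) {
    k <- ovr_counts(cm, cl)
    precision <- if (k$tp + k$fp == 0) NA_real_ else k$tp / (k$tp + k$fp)
    recall <- if (k$tp + k$fn == 0) NA_real_ else k$tp / (k$tp + k$fn)
    f_score <- if (is.na(precision) || is.na(recall)) NA_real_
      else if (precision + recall == 0) 0
      else 2 * precision * recall / (precision + recall)
    specificity <- if (k$tn + k$fp == 0) NA_real_ else k$tn / (k$tn + k$fp)
    data.frame(class = cl, precision = precision, recall = recall,
               f_score = f_score, specificity = specificity)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overall accuracy of a confusion matrix
#'
#' The fraction of windows classified correctly: the matrix trace over its
#' total, the multiclass generalization of (TP+TN)/(TP+TN+FP+FN).
#'
#' @param cm A [confusion_matrix()].
#' @return Fraction in `[0, 1]`.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"), sum(cm) > 0)
  sum(diag(cm)) / sum(cm)
}

#' Full metric set for one configuration
#'
#' @param cm A [confusion_matrix()].
#' @return List with `per_class` (data frame from [class_metrics()]) and
#'   `overall_accuracy`.
#' @export
metric_set <- function(cm) {
  list(per_class = class_metrics(cm), overall_accuracy = overall_accuracy(cm))
}

#' Weighted Cohen's kappa between two label sequences
#'
#' Chance-corrected agreement between two classifications of the same
#' windows (here: ear-mounted versus collar-mounted classifiers), computed
#' as `kappa = 1 - sum(w * O) / sum(w * E)` where O are observed joint
#' proportions, E the outer-product expected proportions, and w the
#' disagreement weights. `"linear"` (equal-step) weights `|i - j|/(k - 1)`
#' over the fixed class order are the default; `"unweighted"` uses 0/1
#' disagreement and reduces to plain Cohen's kappa.
#'
#' @param labels_a,labels_b Equal-length label vectors (length >= 1).
#' @param classes Fixed class order.
#' @param weighting `"linear"` or `"unweighted"`.
#' @return List with `kappa`, `weighting`, `classes` and a `degenerate` flag
#'   (TRUE when both sequences are constant and equal, where kappa = 1 by
#'   convention).
#' @export
weighted_kappa <- function(labels_a, labels_b, classes = SHEEP_BEHAVIOURS,
                           weighting = c("linear", "unweighted")) {
  weighting <- match.arg(weighting)
  if (length(labels_a) != length(labels_b) || length(labels_a) == 0)
    stop("label sequences must have equal positive length")
  k <- length(classes)
  i <- matrix(seq_len(k), k, k)
  w <- if (weighting == "linear") abs(i - t(i)) / (k - 1) else (i != t(i)) * 1
  O <- table(factor(labels_a, levels = classes),
             factor(labels_b, levels = classes)) / length(labels_a)
  E <- outer(rowSums(O), colSums(O))
  denom <- sum(w * E)
  degenerate <- denom == 0
  kappa <- if (degenerate) 1 else 1 - sum(w * O) / denom
  list(kappa = kappa, weighting = weighting, classes = classes,
       degenerate = degenerate)
}
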