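# Classification metrics and rater-agreement analysis.

#' Area under the ROC curve
#'
#' Computed as the Mann–Whitney pair statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, with ties
#' counted 1/2. Implemented via midranks, which is exactly equivalent.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param labels binary 0/1 labels; both classes must be present.
#' @return AUROC in [0, 1].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion counts and per-class precision / recall / F1
#'
#' Each class is treated in turn as the positive class; the `average` row is
#' the unweighted (macro) mean of the two classes. Metrics with a zero
#' denominator are defined as 0 with a warning.
#'
#' @param predictions binary 0/1 predicted classes.
#' @param labels binary 0/1 true labels.
#' @param average `"macro"` (default) or `"micro"`.
#' @return list with `counts` (TP, FP, TN, FN w.r.t. class 1) and `metrics`, a
#'   data frame with rows `class 0`, `class 1`, `average`.
#' @export
confusion_and_prf <- function(predictions, labels, average = c("macro", "micro")) {
  average <- match.arg(average)
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length")
  }
  predictions <- as.integer(predictions)
  labels <- as.integer(labels)
  stopifnot(all(predictions %in% 0:1), all(labels %in% 0:1))
  tp <- sum(predictions == 1 & labels == 1)
  fp <- sum(predictions == 1 & labels == 0)
  tn <- sum(predictions == 0 & labels == 0)
  fn <- sum(predictions == 0 & labels == 1)
  counts <- c(TP = tp, FP = fp, TN = tn, FN = fn)
  guarded <- function(num, den, what) {
    if (den == 0) {
      warning("zero denominator for ", what, "; defining it as 0")
      return(0)
    }
    num / den
  }
  per_class <- function(cls) {
    TPc <- sum(predictions == cls & labels == cls)
    FPc <- sum(predictions == cls & labels != cls)
    FNc <- sum(predictions != cls & labels == cls)
    prec <- guarded(TPc, TPc + FPc, paste0("precision of class ", cls))
    rec <- guarded(TPc, TPc + FNc, paste0("recall of class ", cls))
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    c(precision = prec, recall = rec, f1 = f1)
  }
  m0 <- per_class(0L)
  m1 <- per_class(1L)
  avg <- if (average == "macro") {
    (m0 + m1) / 2
  } else {
    acc <- (tp + tn) / length(labels)  # micro P = R = F1 = accuracy (binary)
    c(precision = acc, recall = acc, f1 = acc)
  }
  metrics <- as.data.frame(rbind(`class 0` = m0, `class 1` = m1,
                                 average = avg))
  list(counts = counts, metrics = metrics)
}

#' Pearson correlation coefficient
#'
#' @param x,y numeric vectors of equal length >= 2 with nonzero variance.
#' @return sample Pearson correlation in [-1, 1].
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson correlation undefined: zero variance in an input")
  }
  stats::cor(x, y)
}

#' Welch two-sample t test
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param paired use the paired test instead.
#' @return list with `statistic` (t) and `p_value` (two-sided).
#' @export
two_sample_t_test <- function(sample_a, sample_b, paired = FALSE) {
  if (length(sample_a) < 2 || length(sample_b) < 2) {
    stop("each sample must contain at least 2 values")
  }
  tt <- stats::t.test(sample_a, sample_b, paired = paired, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Rater-agreement analysis
#'
#' Given a feature-by-rater score table (plus model score columns), computes
#' the full pairwise Pearson matrix, each entity's mean (SD) correlation with
#' the human raters (excluding self-correlation for raters), and correlations
#' against the gold standard, defined as the per-feature arithmetic mean of
#' the rater scores. A rater can be excluded for leave-one-rater-out
#' reanalysis.
#'
#' @param scores data frame or matrix, rows = features, columns = raters and
#'   models.
#' @param raters character vector of rater column names (>= 2).
#' @param models character vector of model column names; defaults to all
#'   remaining columns.
#' @param exclude_rater optional rater column to drop before the analysis.
#' @return an `agreement_analysis` list: `matrix` (symmetric, unit diagonal),
#'   `summary` (mean/SD agreement with raters per entity), `gold` (the
#'   averaged scores) and `gold_correlation` (models vs gold standard).
#' @export
agreement_analysis <- function(scores, raters,
                               models = setdiff(colnames(scores), raters),
                               exclude_rater = NULL) {
  scores <- as.data.frame(scores)
  stopifnot(all(raters %in% colnames(scores)),
            all(models %in% colnames(scores)))
  if (!is.null(exclude_rater)) raters <- setdiff(raters, exclude_rater)
  if (length(raters) < 2) stop("need at least 2 raters")
  if (nrow(scores) < 3) stop("need at least 3 features")
  cols <- c(raters, models)
  m <- matrix(1, length(cols), length(cols), dimnames = list(cols, cols))
  for (i in seq_along(cols)) {
    for (j in seq_along(cols)) {
      if (i < j) {
        r <- pearson(scores[[cols[i]]], scores[[cols[j]]])
        m[i, j] <- r
        m[j, i] <- r
      }
    }
  }
  summary <- do.call(rbind, lapply(cols, function(cl) {
    others <- setdiff(raters, cl)  # self excluded for raters, no-op for models
    vals <- m[cl, others]
    data.frame(entity = cl, type = if (cl %in% raters) "rater" else "model",
               mean = mean(vals), sd = stats::sd(vals),
               stringsAsFactors = FALSE)
  }))
  gold <- rowMeans(scores[, raters, drop = FALSE])
  gold_correlation <- vapply(models, function(cl) pearson(scores[[cl]], gold),
                             numeric(1))
  structure(list(matrix = m, summary = summary, gold = gold,
                 gold_correlation = gold_correlation, raters = raters,
                 models = models),
            class = "agreement_analysis")
}
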