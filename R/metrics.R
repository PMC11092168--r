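#' Classification metrics from pooled predictions
#'
#' Computes precision, recall, F1, accuracy and (optionally) AUC, each as a
#' percentage. Precision/recall/F1 are averaged over classes: `"macro"`
#' (unweighted mean, the symmetric default) or `"weighted"` (by class
#' support). A class never predicted has precision 0 by convention (so a
#' constant classifier on balanced binary data scores macro-F1 33.3, not
#' 50); a class absent from the truth is undefined and excluded from the
#' average with a warning. AUC is one-vs-rest macro over the normalized
#' score columns, reducing to the standard binary AUC when C = 2; it is
#' `NA` when `score` is `NULL` (the binary predecessor returns labels only,
#' with no score or confidence).
#'
#' @param truth named integer vector of true class codes (1..C).
#' @param predicted integer vector of predicted codes, aligned with
#'   `truth`.
#' @param score optional matrix (length(truth) x C) of class scores.
#' @param C number of classes (default: max code observed).
#' @param average `"macro"` or `"weighted"`.
#' @return named numeric vector: `precision`, `recall`, `f1`, `accuracy`,
#'   `auc` (percentages).
#' @export
computeMetrics <- function(truth, predicted, score = NULL,
                           C = max(truth, predicted),
                           average = c("macro", "weighted")) {
  average <- match.arg(average)
  stopifnot(length(truth) == length(predicted))
  cls <- seq_len(C)
  cm <- table(factor(truth, cls), factor(predicted, cls))
  tp <- diag(cm)
  support <- rowSums(cm)
  predTot <- colSums(cm)
  present <- support > 0
  if (!all(present))
    warning("class(es) absent from the truth excluded from averaging: ",
            paste(cls[!present], collapse = ", "))
  prec <- ifelse(predTot > 0, tp / predTot, 0)
  rec <- ifelse(support > 0, tp / support, NA_real_)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  wts <- if (average == "macro") as.numeric(present)
  else as.numeric(support)
  wts <- wts / sum(wts)
  avg <- function(v) sum(v[present] * wts[present])
  auc <- NA_real_
  if (!is.null(score)) {
    aucs <- vapply(cls, function(c) {
      pos <- truth == c
      if (!any(pos) || all(pos)) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(
        response = pos, predictor = score[, c],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    }, numeric(1))
    w2 <- wts[!is.na(aucs)]
    auc <- 100 * sum(aucs[!is.na(aucs)] * w2) / sum(w2)
  }
  c(precision = 100 * avg(prec), recall = 100 * avg(rec),
    f1 = 100 * avg(f1), accuracy = 100 * mean(truth == predicted),
    auc = auc)
}

#' Wilcoxon signed-rank comparisons with Benjamini-Hochberg correction
#'
#' Runs a two-sided paired signed-rank test for every comparison and
#' adjusts the resulting p-values for multiple testing by the
#' Benjamini-Hochberg false-discovery-rate step-up
#' (\eqn{p_{(i)} m / i} with cumulative-minimum enforcement, via
#' [stats::p.adjust()]). Alternatively pass raw p-values directly via `p`
#' to apply the correction alone. Comparisons whose paired differences are
#' all zero get p = 1 with a warning.
#'
#' @param comparisons named list; each element is a list/data.frame with
#'   numeric vectors `a` and `b` of equal length (paired scores of the two
#'   methods across units, e.g. folds).
#' @param p alternatively, a numeric vector of raw p-values.
#' @return data.frame with `comparison`, `p`, `pAdjusted`.
#' @examples
#' wilcoxonFdr(p = c(0.01, 0.02, 0.04))
#' @export
wilcoxonFdr <- function(comparisons = NULL, p = NULL) {
  if (is.null(p)) {
    if (is.null(comparisons) || !length(comparisons))
      stop("provide either 'comparisons' or raw p-values 'p'")
    nm <- names(comparisons)
    if (is.null(nm)) nm <- paste0("cmp", seq_along(comparisons))
    p <- vapply(comparisons, function(cc) {
      a <- cc$a; b <- cc$b
      stopifnot(length(a) == length(b))
      if (length(a) < 5L)
        warning("fewer than 5 paired observations", call. = FALSE)
      d <- a - b
      if (all(d == 0)) {
        warning("all paired differences are zero; p = 1", call. = FALSE)
        return(1)
      }
      suppressWarnings(
        stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
    }, numeric(1))
  } else {
    nm <- names(p)
    if (is.null(nm)) nm <- paste0("cmp", seq_along(p))
  }
  data.frame(comparison = nm, p = as.numeric(p),
             pAdjusted = stats::p.adjust(p, method = "BH"),
             row.names = NULL)
}
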