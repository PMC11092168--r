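#' Specify a weak base learner
#'
#' The boosting loop is learner-agnostic; any classifier that accepts
#' instance weights and returns class probabilities fits. Two are wired in:
#' `"rf"`, a random forest via ranger (default 50 trees, single thread for
#' reproducibility), and `"tree"`, a single decision tree via rpart.
#'
#' @param method `"rf"` or `"tree"`.
#' @param numTrees number of trees for `"rf"` (default 50).
#' @param ... further arguments: for `"tree"`, passed to
#'   [rpart::rpart.control()] (e.g. `maxdepth = 1` for decision stumps,
#'   the canonical boosting weak learner); ignored for `"rf"`.
#' @return a list of class `learnerSpec`.
#' @export
learnerSpec <- function(method = c("rf", "tree"), numTrees = 50, ...) {
  method <- match.arg(method)
  structure(list(method = method, numTrees = numTrees, args = list(...)),
            class = "learnerSpec")
}

#' Fit a weak hypothesis on one view's training slice
#'
#' Fits the base learner on the present samples of one view with the shared
#' instance weights restricted to those samples and renormalized, so the
#' learner sees a proper distribution. If the slice contains a single class,
#' a constant hypothesis predicting that class with probability 1 is
#' returned (no model is fitted).
#'
#' @param x numeric matrix of training rows (samples x features).
#' @param y integer class codes in 1..C for those rows.
#' @param w nonnegative case weights for those rows (renormalized
#'   internally).
#' @param C total number of classes.
#' @param viewId id of the view being fitted.
#' @param spec a [learnerSpec()].
#' @param seed integer seed for the learner's internal randomness.
#' @return a [WeakHypothesis-class].
#' @export
fitWeakLearner <- function(x, y, w, C, viewId, spec = learnerSpec(),
                           seed = 1L) {
  stopifnot(nrow(x) == length(y), length(w) == length(y))
  w <- w / sum(w)
  if (length(unique(y)) == 1L)
    return(new("WeakHypothesis", viewId = viewId, model = NULL,
               method = spec$method, nClasses = as.integer(C),
               featureIds = colnames(x), constant = as.integer(y[1L])))
  yf <- factor(y, levels = seq_len(C))
  model <- switch(spec$method,
    rf = {
      df <- as.data.frame(x, check.names = FALSE)
      df[[".class"]] <- yf
      # ranger drops factor levels absent from the slice; the probability
      # matrix is re-expanded onto 1..C in predictProb, so muffle its note
      withCallingHandlers(
        ranger::ranger(
          dependent.variable.name = ".class", data = df,
          num.trees = spec$numTrees, probability = TRUE,
          case.weights = w, seed = seed, num.threads = 1L),
        warning = function(w) {
          if (grepl("Dropped unused factor level", conditionMessage(w)))
            invokeRestart("muffleWarning")
        })
    },
    tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("V", seq_len(ncol(df)))
      df[[".class"]] <- yf
      ctrl <- do.call(rpart::rpart.control, spec$args)
      rpart::rpart(.class ~ ., data = df, weights = w, method = "class",
                   control = ctrl)
    })
  new("WeakHypothesis", viewId = viewId, model = model,
      method = spec$method, nClasses = as.integer(C),
      featureIds = colnames(x), constant = 0L)
}

# Align a prediction matrix onto hypothesis feature order
.alignFeatures <- function(h, x) {
  miss <- setdiff(h@featureIds, colnames(x))
  if (length(miss))
    stop("view '", h@viewId, "' is missing feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  x[, h@featureIds, drop = FALSE]
}

#' Predict class probabilities from a weak hypothesis
#'
#' @param h a [WeakHypothesis-class].
#' @param x numeric matrix of rows from `h`'s view (aligned by feature id).
#' @return matrix (nrow(x) x C) of class probabilities; rows sum to 1.
#' @export
predictProb <- function(h, x) {
  C <- h@nClasses
  if (nrow(x) == 0L)
    return(matrix(numeric(0), 0L, C, dimnames = list(NULL, seq_len(C))))
  if (h@constant > 0L) {
    p <- matrix(0, nrow(x), C, dimnames = list(rownames(x), seq_len(C)))
    p[, h@constant] <- 1
    return(p)
  }
  x <- .alignFeatures(h, x)
  p <- switch(h@method,
    rf = {
      df <- as.data.frame(x, check.names = FALSE)
      stats::predict(h@model, data = df, num.threads = 1L)$predictions
    },
    tree = {
      df <- as.data.frame(x)
      colnames(df) <- paste0("V", seq_len(ncol(df)))
      stats::predict(h@model, newdata = df, type = "prob")
    })
  # map columns back onto the full class set 1..C
  out <- matrix(0, nrow(x), C, dimnames = list(rownames(x), seq_len(C)))
  out[, as.integer(colnames(p))] <- p
  out
}

#' Predict hard class labels from a weak hypothesis
#'
#' Argmax of [predictProb()] with ties broken toward the smallest class
#' index.
#'
#' @inheritParams predictProb
#' @return named integer vector of class codes in 1..C.
#' @export
predictLabel <- function(h, x) {
  p <- predictProb(h, x)
  stats::setNames(max.col(p, ties.method = "first"), rownames(x))
}
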