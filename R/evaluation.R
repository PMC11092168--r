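#' Cross-validated evaluation of one method
#'
#' Runs the full protocol for one method under a shared [FoldPlan-class]:
#' per fold, the model is fitted on the training samples only (imputation
#' means, where a method needs them, are computed on the training fold and
#' reused for its test fold), out-of-fold predictions are pooled over all
#' folds, and the five metrics are computed from the pooled predictions
#' with [computeMetrics()]. Per-fold metrics are also returned (they are
#' the pairing units for [wilcoxonFdr()]), as are fold-averaged winner
#' shares for the bandit-driven methods. Methods:
#'
#' * `"irboost"` — the multi-class incomplete-view boosted ensemble
#'   ([fitIrboost()]); works on incomplete views directly.
#' * `"rboost"` — the binary complete-view predecessor ([fitRboostBinary()])
#'   run after per-fold mean imputation; reports no AUC (it returns labels
#'   only, with no score or confidence).
#' * `"concat-rf"` — per-fold mean imputation, feature concatenation, one
#'   base learner on the wide matrix ([fitConcat()]).
#' * `"rf-sv"` — the single-view base learner on one view (`view=`),
#'   evaluated on that view's samples only.
#'
#' @param ds a [MultiViewDataset-class].
#' @param plan a [FoldPlan-class] built on `ds` (shared across methods so
#'   comparisons are paired).
#' @param method one of `"irboost"`, `"rboost"`, `"concat-rf"`, `"rf-sv"`.
#' @param view view id, required for `method = "rf-sv"`.
#' @param spec base [learnerSpec()].
#' @param T boosting iterations for the bandit methods (default 50).
#' @param sigma,gamma bandit parameters.
#' @param seed integer seed; fold f uses `seed + f`.
#' @param average metric averaging, `"macro"` (default) or `"weighted"`.
#' @return list with `method`, `pooled` (named metric vector, percentages),
#'   `perFold` (data.frame of per-fold metrics), `winnerShare` (named
#'   numeric over views, or NULL), `predictions` (data.frame of pooled
#'   out-of-fold predictions).
#' @export
evaluateMethod <- function(ds, plan, method = c("irboost", "rboost",
                                                "concat-rf", "rf-sv"),
                           view = NULL, spec = learnerSpec("rf", 50),
                           T = 50L, sigma = 0.15, gamma = 0.3, seed = 1L,
                           average = "macro") {
  method <- match.arg(method)
  stopifnot(is(ds, "MultiViewDataset"), is(plan, "FoldPlan"))
  y <- sampleLabels(ds)
  C <- nClasses(ds)
  if (method == "rf-sv") {
    if (is.null(view)) stop("method 'rf-sv' requires a 'view' id")
    vtab <- getView(ds, view)
    scope <- sampleIds(vtab)
  } else scope <- allSamples(ds)
  pooledCode <- stats::setNames(rep(NA_integer_, length(scope)), scope)
  pooledScore <- if (method == "rboost") NULL else
    matrix(NA_real_, length(scope), C, dimnames = list(scope, seq_len(C)))
  perFold <- vector("list", plan@k)
  shares <- NULL
  for (f in seq_len(plan@k)) {
    sp <- foldSplit(plan, f)
    train <- intersect(sp$train, scope)
    test <- intersect(sp$test, scope)
    if (!length(test)) next
    fseed <- as.integer(seed) + f
    if (method == "irboost") {
      dsTrain <- suppressMessages(restrictToSamples(ds, train))
      ens <- fitIrboost(dsTrain, T = T, spec = spec, sigma = sigma,
                        gamma = gamma, seed = fseed)
      dsTest <- suppressMessages(restrictToSamples(ds, test))
      pr <- predictEnsemble(ens, dsTest)
      code <- pr$code[test]; score <- pr$score[test, , drop = FALSE]
      shr <- winnerCounts(ens) / nRounds(ens)
      shares <- if (is.null(shares)) shr else shares + shr
    } else if (method == "rboost") {
      full <- meanImputeUnion(ds, trainIds = train)
      ens <- fitRboostBinary(restrictToSamples(full, train), T = T,
                             spec = spec, sigma = sigma, gamma = gamma,
                             seed = fseed)
      pr <- predictEnsemble(ens, restrictToSamples(full, test))
      code <- pr$code[test]; score <- NULL
      shr <- winnerCounts(ens) / nRounds(ens)
      shares <- if (is.null(shares)) shr else shares + shr
    } else if (method == "concat-rf") {
      fit <- fitConcat(ds, spec = spec, seed = fseed, trainIds = train)
      score <- predictProb(fit$model, fit$x[test, , drop = FALSE])
      code <- max.col(score, ties.method = "first")
    } else {  # rf-sv
      m <- featureMatrix(vtab)
      h <- fitWeakLearner(m[train, , drop = FALSE], y[train],
                          rep(1, length(train)), C, view, spec, fseed)
      score <- predictProb(h, m[test, , drop = FALSE])
      code <- max.col(score, ties.method = "first")
    }
    pooledCode[test] <- code
    if (!is.null(pooledScore)) pooledScore[test, ] <- score
    perFold[[f]] <- data.frame(fold = f, t(computeMetrics(
      y[test], code, score, C = C, average = average)))
  }
  done <- !is.na(pooledCode)
  pooled <- computeMetrics(y[scope][done], pooledCode[done],
                           if (is.null(pooledScore)) NULL
                           else pooledScore[done, , drop = FALSE],
                           C = C, average = average)
  if (!is.null(shares)) shares <- shares / plan@k
  list(method = method, view = view, pooled = pooled,
       perFold = do.call(rbind, perFold), winnerShare = shares,
       predictions = data.frame(sample = scope[done],
                                truth = y[scope][done],
                                predicted = pooledCode[done]))
}

#' Evaluate the single-view baseline on every view
#'
#' Runs `method = "rf-sv"` for each view of the dataset and summarizes the
#' worst, average and best pooled value of every metric across views — the
#' standard way to report a grid of single-view models against the
#' multi-view ones.
#'
#' @inheritParams evaluateMethod
#' @return list with `perView` (data.frame of pooled metrics, one row per
#'   view) and `summary` (data.frame with rows worst/average/best).
#' @export
evaluateSingleViews <- function(ds, plan, spec = learnerSpec("rf", 50),
                                seed = 1L, average = "macro") {
  res <- lapply(viewNames(ds), function(v)
    evaluateMethod(ds, plan, "rf-sv", view = v, spec = spec, seed = seed,
                   average = average)$pooled)
  perView <- data.frame(view = viewNames(ds), do.call(rbind, res))
  metr <- c("precision", "recall", "f1", "accuracy", "auc")
  summary <- rbind(
    worst = vapply(metr, function(m) min(perView[[m]]), numeric(1)),
    average = vapply(metr, function(m) mean(perView[[m]]), numeric(1)),
    best = vapply(metr, function(m) max(perView[[m]]), numeric(1)))
  list(perView = perView, summary = as.data.frame(summary))
}

#' Compare several methods under one fold plan
#'
#' Convenience wrapper: evaluates each requested method with
#' [evaluateMethod()] under the same plan and assembles a summary table
#' (one row per method, pooled metrics as percentages).
#'
#' @inheritParams evaluateMethod
#' @param methods character vector of method names (see
#'   [evaluateMethod()]).
#' @return list with `summary` (data.frame) and `results` (the full
#'   per-method lists).
#' @export
compareMethods <- function(ds, plan, methods = c("irboost", "concat-rf"),
                           spec = learnerSpec("rf", 50), T = 50L,
                           sigma = 0.15, gamma = 0.3, seed = 1L,
                           average = "macro") {
  results <- lapply(methods, function(m)
    evaluateMethod(ds, plan, m, spec = spec, T = T, sigma = sigma,
                   gamma = gamma, seed = seed, average = average))
  names(results) <- methods
  summary <- data.frame(method = methods,
                        do.call(rbind, lapply(results, `[[`, "pooled")),
                        row.names = NULL)
  list(summary = summary, results = results)
}
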