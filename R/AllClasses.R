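#' @import methods
NULL

#' ViewTable: one feature view of a set of samples
#'
#' A single view is a numeric samples-by-features matrix together with a view
#' identifier. Sample and feature identifiers live in the matrix dimnames and
#' are the single source of truth; samples are matched across views by
#' identifier, never by position. A sample that is missing from a view is
#' simply absent from the matrix — in-row missing values (NA/NaN) are
#' rejected, because the boosting core must never impute silently (imputation
#' is an explicit baseline operation, see [meanImputeUnion()]).
#'
#' @slot viewId single character, the view identifier.
#' @slot features numeric matrix, one row per sample (rownames = sample ids,
#'   colnames = feature ids).
#' @export
setClass("ViewTable",
  representation(viewId = "character", features = "matrix"))

setValidity("ViewTable", function(object) {
  msg <- character()
  if (length(object@viewId) != 1L || is.na(object@viewId) ||
      !nzchar(object@viewId))
    msg <- c(msg, "'viewId' must be a single non-empty string")
  f <- object@features
  if (!is.numeric(f))
    msg <- c(msg, "'features' must be a numeric matrix")
  # a view may be empty (0 rows, e.g. after restriction); R drops the
  # rownames of a zero-row subset to NULL, which is accepted then
  if (nrow(f) > 0L &&
      (is.null(rownames(f)) || anyNA(rownames(f)) ||
         !all(nzchar(rownames(f)))))
    msg <- c(msg, "'features' must have non-empty sample ids as rownames")
  else if (anyDuplicated(rownames(f)))
    msg <- c(msg, sprintf("duplicate sample id(s) in view '%s': %s",
      object@viewId,
      paste(unique(rownames(f)[duplicated(rownames(f))]), collapse = ", ")))
  if (is.null(colnames(f)) || anyDuplicated(colnames(f)))
    msg <- c(msg, "'features' must have unique feature ids as colnames")
  if (ncol(f) < 1L)
    msg <- c(msg, "a view must have at least one feature")
  if (is.numeric(f) && length(f) && !all(is.finite(f)))
    msg <- c(msg, paste0("view '", object@viewId, "' contains non-finite ",
      "values; missingness must be expressed by absence of the sample, ",
      "never by in-row sentinels"))
  if (length(msg)) msg else TRUE
})

#' LabelEncoding: bijection between external labels and classes 1..C
#'
#' External class labels (arbitrary strings or numbers) are encoded as the
#' consecutive integers 1..C. Code 0 is reserved as the artificial
#' "unknown prediction" label returned for samples absent from a view; it
#' never corresponds to a real class, so an absent sample's modified
#' prediction can never agree with a true label.
#'
#' @slot levels character vector of C external labels, in encoding order.
#' @export
setClass("LabelEncoding", representation(levels = "character"))

setValidity("LabelEncoding", function(object) {
  if (length(object@levels) < 1L) return("at least one class is required")
  if (anyDuplicated(object@levels)) return("class labels must be unique")
  TRUE
})

#' MultiViewDataset: K views with shared integer labels
#'
#' Container for a multi-view dataset with possibly incomplete views: each
#' view covers a subset N_j of the full sample set N = union of all N_j.
#' Labels are stored as internal codes 1..C over all of N together with the
#' [LabelEncoding-class] that maps them back to external labels. The
#' `metadata` list is free-form (the synthetic generator stores its
#' ground-truth record there).
#'
#' @slot views list of [ViewTable-class] objects with unique view ids.
#' @slot labels named integer vector over all samples, values in 1..C.
#' @slot encoding a [LabelEncoding-class].
#' @slot metadata list of arbitrary annotations.
#' @export
setClass("MultiViewDataset",
  representation(views = "list", labels = "integer",
                 encoding = "LabelEncoding", metadata = "list"))

setValidity("MultiViewDataset", function(object) {
  msg <- character()
  if (length(object@views) < 1L)
    msg <- c(msg, "at least one view is required")
  if (!all(vapply(object@views, is, logical(1), "ViewTable")))
    msg <- c(msg, "'views' must be a list of ViewTable objects")
  else {
    ids <- vapply(object@views, function(v) v@viewId, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, "view ids must be unique")
    all_s <- unique(unlist(lapply(object@views,
                                  function(v) rownames(v@features))))
    lab <- object@labels
    if (is.null(names(lab)) || anyDuplicated(names(lab)))
      msg <- c(msg, "'labels' must be uniquely named by sample id")
    else {
      unl <- setdiff(all_s, names(lab))
      if (length(unl))
        msg <- c(msg, sprintf("unlabeled sample(s): %s",
                              paste(unl, collapse = ", ")))
    }
    C <- length(object@encoding@levels)
    if (length(lab) && (anyNA(lab) || any(lab < 1L) || any(lab > C)))
      msg <- c(msg, "label codes must lie in 1..C (0 is reserved)")
  }
  if (length(msg)) msg else TRUE
})

#' FilterSpec: a feature-filtering criterion for OTU tables
#'
#' @slot mode one of `"frequency"` (threshold = minimum number of samples in
#'   which a feature must be present), `"prevalence"` (threshold = minimum
#'   fraction of samples, in (0, 1]) or `"none"`.
#' @slot threshold numeric(1); ignored (and absent, `NA`) for mode `"none"`.
#' @export
setClass("FilterSpec",
  representation(mode = "character", threshold = "numeric"))

setValidity("FilterSpec", function(object) {
  m <- object@mode
  if (length(m) != 1L || !m %in% c("frequency", "prevalence", "none"))
    return("'mode' must be one of 'frequency', 'prevalence', 'none'")
  th <- object@threshold
  if (m == "none") {
    if (!is.na(th)) return("mode 'none' carries no threshold")
  } else {
    if (length(th) != 1L || is.na(th) || th <= 0)
      return("'threshold' must be a single positive number")
    if (m == "prevalence" && th > 1)
      return("prevalence threshold must lie in (0, 1]")
    if (m == "frequency" && th != round(th))
      return("frequency threshold must be a positive integer")
  }
  TRUE
})

#' BanditState: adversarial bandit over K views
#'
#' State of the exponentially weighted average forecaster used to pick the
#' winning view: selection probabilities `p`, cumulative importance-weighted
#' reward estimates `reward`, the learning rate `sigma` and the exploration
#' rate `gamma`. The mixing term guarantees `p_j >= gamma/K` for every arm.
#' Random draws use R's global RNG stream (seed it once per fit).
#'
#' @slot K integer, number of arms (views).
#' @slot prob numeric length-K probability vector.
#' @slot reward numeric length-K cumulative reward estimates.
#' @slot sigma learning-rate parameter (> 0), default 0.15.
#' @slot gamma exploration parameter in (0, 1), default 0.3.
#' @export
setClass("BanditState",
  representation(K = "integer", prob = "numeric", reward = "numeric",
                 sigma = "numeric", gamma = "numeric"))

setValidity("BanditState", function(object) {
  msg <- character()
  K <- object@K
  if (length(K) != 1L || K < 1L) msg <- c(msg, "'K' must be >= 1")
  if (length(object@sigma) != 1L || object@sigma <= 0)
    msg <- c(msg, "'sigma' must be a single positive number")
  if (length(object@gamma) != 1L || object@gamma <= 0 || object@gamma >= 1)
    msg <- c(msg, "'gamma' must lie in (0, 1)")
  if (length(object@prob) != K || length(object@reward) != K)
    msg <- c(msg, "'prob' and 'reward' must have length K")
  else {
    if (abs(sum(object@prob) - 1) > 1e-12)
      msg <- c(msg, "'prob' must sum to 1 (within 1e-12)")
    if (any(object@prob < object@gamma / K - 1e-12))
      msg <- c(msg, "every probability must be >= gamma/K")
  }
  if (length(msg)) msg else TRUE
})

#' WeakHypothesis: one fitted base model on one view
#'
#' Wraps a fitted base learner (random forest or decision tree) together
#' with the view it was trained on, the feature ids it expects, and the full
#' set of class codes 1..C (so probability vectors always have C components
#' even when the training slice lacked some classes). A single-class
#' training slice yields a constant hypothesis (`constant` > 0) predicting
#' that class with probability 1.
#'
#' @slot viewId view the model was fitted on.
#' @slot model the fitted base model (ranger or rpart), or NULL for a
#'   constant hypothesis.
#' @slot method `"rf"` or `"tree"`.
#' @slot nClasses integer C.
#' @slot featureIds character, feature ids in training order.
#' @slot constant integer; 0 for a genuine model, otherwise the class
#'   predicted unconditionally.
#' @export
setClass("WeakHypothesis",
  representation(viewId = "character", model = "ANY", method = "character",
                 nClasses = "integer", featureIds = "character",
                 constant = "integer"))

#' WeakRound: one boosting iteration
#'
#' @slot t iteration index.
#' @slot viewId the winning view selected by the bandit.
#' @slot hypothesis the fitted [WeakHypothesis-class].
#' @slot edge weighted agreement statistic in [-1, 1].
#' @slot alpha combination weight (0 for rounds with edge <= 0, which are
#'   retained for auditability but excluded from the combined classifier).
#' @export
setClass("WeakRound",
  representation(t = "integer", viewId = "character",
                 hypothesis = "WeakHypothesis", edge = "numeric",
                 alpha = "numeric"))

setValidity("WeakRound", function(object) {
  if (abs(object@edge) > 1 + 1e-9) return("|edge| must be <= 1")
  if (!is.finite(object@alpha)) return("'alpha' must be finite")
  TRUE
})

#' Ensemble: the combined multi-view boosted classifier
#'
#' Ordered list of boosting rounds plus the winner-frequency tally. The
#' number of times each view wins is an indicator of its relevance, which is
#' the natural readout when views correspond to competing preprocessing
#' pipelines. `trace` holds the per-iteration bandit log (iteration, winning
#' view, edge, reward, selection probability) and `probTrace` the post-update
#' probability vectors, sufficient to replay the forecaster offline
#' (see [replayBanditTrace()]). `weightTrace` stores the shared instance
#' weights after each iteration.
#'
#' @slot rounds list of [WeakRound-class].
#' @slot type `"irboost"` (multi-class, probability-vector combination) or
#'   `"rboost"` (binary, sign of the weighted vote).
#' @slot nClasses integer C.
#' @slot encoding the [LabelEncoding-class] of the training data.
#' @slot viewIds character, all candidate view ids (bandit arm order).
#' @slot winnerCounts named integer, times each view won.
#' @slot T integer, total iterations.
#' @slot sigma,gamma bandit parameters used.
#' @slot trace data.frame bandit trace.
#' @slot probTrace numeric matrix (T x K) of post-update probabilities.
#' @slot weightTrace numeric matrix (T x |N|) of shared weights.
#' @export
setClass("Ensemble",
  representation(rounds = "list", type = "character", nClasses = "integer",
                 encoding = "LabelEncoding", viewIds = "character",
                 winnerCounts = "integer", T = "integer",
                 sigma = "numeric", gamma = "numeric",
                 trace = "data.frame", probTrace = "matrix",
                 weightTrace = "matrix"))

setValidity("Ensemble", function(object) {
  if (sum(object@winnerCounts) != object@T)
    return("winner counts must sum to the number of iterations")
  if (!object@type %in% c("irboost", "rboost"))
    return("'type' must be 'irboost' or 'rboost'")
  TRUE
})

#' FoldPlan: a global cross-validation fold assignment
#'
#' One fold per sample across all views, so a sample that appears in several
#' views is never simultaneously in the training set (via one view) and the
#' test set (via another). Within every view the induced fold sizes are
#' near-equal (differ by at most 1 whenever the balancing pass converges).
#'
#' @slot assignment named integer vector: sample id -> fold in 1..k.
#' @slot k number of folds.
#' @slot seed seed used to build the plan.
#' @export
setClass("FoldPlan",
  representation(assignment = "integer", k = "integer", seed = "integer"))

setValidity("FoldPlan", function(object) {
  if (object@k < 2L) return("'k' must be >= 2")
  if (is.null(names(object@assignment)))
    return("'assignment' must be named by sample id")
  if (any(object@assignment < 1L) || any(object@assignment > object@k))
    return("fold labels must lie in 1..k")
  TRUE
})
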