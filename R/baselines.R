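#' Complete all views by per-feature mean imputation
#'
#' Extends every view to the full sample set N, filling the rows of absent
#' samples with the per-feature mean observed in that view. The means are
#' computed over `trainIds` only (intersected with each view's present
#' samples), so that in a cross-validation setting test-fold values never
#' leak into the imputation; by default all present samples are used.
#' Originally present rows are never altered. This is the standard
#' workaround that lets complete-view-only methods (the binary predecessor
#' algorithm, feature concatenation) run on incomplete data; the
#' incomplete-view boosting core never imputes.
#'
#' @param ds a [MultiViewDataset-class].
#' @param trainIds sample ids over which imputation means are computed
#'   (default: each view's own present samples).
#' @return a [MultiViewDataset-class] with all views complete.
#' @export
meanImputeUnion <- function(ds, trainIds = NULL) {
  stopifnot(is(ds, "MultiViewDataset"))
  n <- allSamples(ds)
  views <- lapply(views(ds), function(v) {
    m <- featureMatrix(v)
    src <- if (is.null(trainIds)) rownames(m)
    else intersect(rownames(m), trainIds)
    if (!length(src))
      stop("view '", viewId(v),
           "' has no observed training samples to impute from")
    mu <- colMeans(m[src, , drop = FALSE])
    if (anyNA(mu)) stop("feature with no observed values in view '",
                        viewId(v), "'")
    absent <- setdiff(n, rownames(m))
    if (!length(absent))
      return(new("ViewTable", viewId = viewId(v),
                 features = m[n, , drop = FALSE]))
    fill <- matrix(mu, length(absent), ncol(m), byrow = TRUE,
                   dimnames = list(absent, colnames(m)))
    new("ViewTable", viewId = viewId(v),
        features = rbind(m, fill)[n, , drop = FALSE])
  })
  new("MultiViewDataset", views = views, labels = ds@labels,
      encoding = ds@encoding, metadata = ds@metadata)
}

#' Concatenate all views into a single feature matrix
#'
#' Horizontal concatenation after [meanImputeUnion()]: the result has
#' \eqn{\sum_j q_j} columns in view order then feature order, with feature
#' ids disambiguated by a view-id prefix. This is the representation used
#' by the feature-concatenation baseline.
#'
#' @param ds a [MultiViewDataset-class].
#' @param trainIds passed to [meanImputeUnion()].
#' @return numeric matrix, samples (all of N) x sum of q_j.
#' @export
concatViews <- function(ds, trainIds = NULL) {
  full <- meanImputeUnion(ds, trainIds)
  mats <- lapply(views(full), function(v) {
    m <- featureMatrix(v)
    colnames(m) <- paste(viewId(v), colnames(m), sep = ".")
    m
  })
  do.call(cbind, mats)
}

#' Fit a single-view baseline classifier
#'
#' Standard supervised fit of the base learner on one view's present
#' samples with uniform weights. Running this over every view of a grid and
#' reporting the worst / average / best metric is the single-view reference
#' the multi-view model is compared against.
#'
#' @param view a [ViewTable-class].
#' @param labels named labels (external or codes) covering the view's
#'   samples.
#' @param spec a [learnerSpec()].
#' @param seed integer seed.
#' @return list with the fitted [WeakHypothesis-class] (`model`), the
#'   [LabelEncoding-class] used, and `constant` flag (TRUE when the
#'   training slice had a single class).
#' @export
fitSingleView <- function(view, labels, spec = learnerSpec("rf", 50),
                          seed = 1L) {
  stopifnot(is(view, "ViewTable"))
  ids <- sampleIds(view)
  miss <- setdiff(ids, names(labels))
  if (length(miss)) stop("unlabeled sample(s): ",
                         paste(miss, collapse = ", "))
  enc <- encodeLabels(labels[ids])
  y <- encode(enc, labels[ids])
  h <- fitWeakLearner(featureMatrix(view), y, rep(1, length(y)),
                      length(enc@levels), viewId(view), spec,
                      as.integer(seed))
  list(model = h, encoding = enc, constant = h@constant > 0L)
}

#' Fit the feature-concatenation baseline
#'
#' Mean-imputes, concatenates all views ([concatViews()]) and fits a single
#' model on the resulting wide matrix.
#'
#' @param ds a [MultiViewDataset-class].
#' @param spec a [learnerSpec()].
#' @param seed integer seed.
#' @param trainIds samples to fit on (and to compute imputation means
#'   from); default all of N.
#' @return list with the fitted [WeakHypothesis-class] (`model`), the
#'   concatenated matrix (`x`) and the dataset encoding.
#' @export
fitConcat <- function(ds, spec = learnerSpec("rf", 50), seed = 1L,
                      trainIds = NULL) {
  x <- concatViews(ds, trainIds)
  if (is.null(trainIds)) trainIds <- allSamples(ds)
  y <- sampleLabels(ds)[trainIds]
  h <- fitWeakLearner(x[trainIds, , drop = FALSE], y, rep(1, length(y)),
                      nClasses(ds), "concat", spec, as.integer(seed))
  list(model = h, x = x, encoding = ds@encoding)
}
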